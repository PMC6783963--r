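#' Principal component analysis of a trait matrix
#'
#' Centred (and by default unit-scaled) PCA with a deterministic sign
#' convention: within each component the loading of largest magnitude is
#' positive. Scaling matters for fatty-acid profiles, whose variables span
#' from trace (<0.1%) to dominant (~80%) abundances. Missing values are
#' refused rather than imputed.
#'
#' @param q a [quantitative_matrix()] or numeric matrix.
#' @param scale. unit-scale the variables (default TRUE).
#' @return list of class `pca_result`: `scores` (samples x PCs),
#'   `loadings` (variables x PCs), `var_frac` (per-component variance
#'   fractions summing to 1), `sdev`.
#' @export
pca <- function(q, scale. = TRUE) {
  x <- unclass(q)
  if (nrow(x) < 2L || ncol(x) < 2L) stop_schema("need n >= 2 and p >= 2")
  if (anyNA(x)) {
    bad <- rownames(x)[rowSums(is.na(x)) > 0][1]
    stop_schema("missing values (e.g. sample %s); imputation refused", bad)
  }
  if (scale.) {
    v <- apply(x, 2, stats::var)
    if (any(v == 0)) {
      stop_schema("zero-variance column '%s' cannot be scaled",
                  colnames(x)[v == 0][1])
    }
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = scale.)
  flip <- apply(pr$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  pr$rotation <- sweep(pr$rotation, 2, flip, `*`)
  pr$x <- sweep(pr$x, 2, flip, `*`)
  structure(list(scores = pr$x, loadings = pr$rotation,
                 var_frac = pr$sdev^2 / sum(pr$sdev^2), sdev = pr$sdev),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples, %d components; PC1+PC2 = %.1f%%\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$var_frac[1:min(2, length(x$var_frac))])))
  invisible(x)
}

#' Partitioning Around Medoids (PAM)
#'
#' k-medoids clustering (BUILD + SWAP until no improving swap), minimising
#' the total dissimilarity of samples to their cluster medoid; deterministic
#' given the input.
#'
#' @param x numeric feature matrix or a [dist_matrix()].
#' @param k number of clusters, `1 <= k < n`.
#' @return list of class `pam_result`: `partition` (named integer vector),
#'   `medoids` (ids), `objective` (total dissimilarity after SWAP).
#' @export
pam_cluster <- function(x, k) {
  n <- if (inherits(x, "dist_matrix")) nrow(x) else nrow(as.matrix(x))
  if (k < 1 || k >= n + 1) stop_schema("k must be in [1, %d]", n)
  fit <- if (inherits(x, "dist_matrix")) {
    cluster::pam(as_dist(x), k = k, diss = TRUE)
  } else {
    cluster::pam(as.matrix(x), k = k)
  }
  part <- fit$clustering
  ids <- if (inherits(x, "dist_matrix")) rownames(x) else rownames(as.matrix(x))
  structure(list(partition = part,
                 medoids = ids[fit$id.med],
                 objective = unname(fit$objective["swap"])),
            class = "pam_result")
}

#' Gap statistic for choosing the number of clusters
#'
#' Compares the log within-cluster dispersion of PAM partitions with its
#' expectation under a reference null (uniform over the observed per-feature
#' ranges): `gap(k) = mean_b log W*_kb - log W_k`, with W the
#' squared-dissimilarity dispersion of the original formulation. The number
#' of clusters is chosen by the firstSEmax rule: the smallest k whose gap is
#' within one simulation standard error of the first local maximum.
#'
#' @param x numeric feature matrix (e.g. the first two PC scores).
#' @param k_max largest k to evaluate (from 1).
#' @param B number of reference replicates (default 50).
#' @param seed optional seed (the curve is reproducible given it).
#' @return data.frame of class `gap_curve` with columns `k`, `logW`,
#'   `E_logW`, `gap`, `SE`; attributes `chosen_k`, `B`, `seed`.
#' @export
gap_statistic <- function(x, k_max = 8, B = 50, seed = NULL) {
  x <- as.matrix(x)
  if (k_max >= nrow(x)) stop_schema("k_max must be < n")
  gs <- with_seed(seed, cluster::clusGap(
    x,
    FUNcluster = function(x, k)
      list(cluster = cluster::pam(x, k, cluster.only = TRUE)),
    K.max = k_max, B = B, d.power = 2, spaceH0 = "original",
    verbose = FALSE))
  tab <- as.data.frame(gs$Tab)
  out <- data.frame(k = seq_len(k_max), logW = tab$logW,
                    E_logW = tab$E.logW, gap = tab$gap, SE = tab$SE.sim)
  chosen <- cluster::maxSE(tab$gap, tab$SE.sim, method = "firstSEmax")
  structure(out, class = c("gap_curve", "data.frame"),
            chosen_k = chosen, B = B, seed = seed)
}

#' Silhouette widths of a partition
#'
#' Per-sample silhouette `s(i) = (b - a) / max(a, b)` with a the mean
#' within-cluster distance (excluding self) and b the smallest mean distance
#' to another cluster; singleton clusters get width 0. Widths lie in
#' \[-1, 1\]; the overall mean diagnoses cluster quality.
#'
#' @param partition named integer cluster vector (>= 2 clusters).
#' @param d a [dist_matrix()] over the same samples.
#' @return list of class `silhouette_report`: `widths` (per sample),
#'   `cluster_means`, `mean`.
#' @export
silhouette_report <- function(partition, d) {
  if (length(unique(partition)) < 2L) {
    stop_schema("silhouette needs >= 2 clusters")
  }
  if (!is.null(names(partition))) {
    if (!setequal(names(partition), rownames(d))) {
      stop_schema("partition and distance matrix cover different samples")
    }
    partition <- partition[rownames(d)]
  }
  sil <- cluster::silhouette(as.integer(factor(partition)), as_dist(d))
  widths <- sil[, "sil_width"]
  names(widths) <- rownames(d)
  cl <- sil[, "cluster"]
  structure(list(widths = widths,
                 cluster_means = tapply(widths, cl, mean),
                 mean = mean(widths)),
            class = "silhouette_report")
}

#' @export
print.silhouette_report <- function(x, ...) {
  cat(sprintf("silhouette_report: mean width %.3f over %d samples\n",
              x$mean, length(x$widths)))
  invisible(x)
}
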