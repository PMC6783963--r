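#' Dice-Sorensen similarity matrix
#'
#' Pairwise genetic similarity `s = 2a / (2a + b + c)` on the binary allele
#' presence/absence profiles, computed over the columns of loci typed in
#' both samples (pairwise-complete); a sample with several missing loci is
#' still placeable as long as it shares at least one typed locus with every
#' other sample.
#'
#' @param m an [allele_matrix()].
#' @return symmetric similarity matrix with unit diagonal.
#' @export
dice_similarity <- function(m) {
  n <- nrow(m)
  s <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
  if (!anyNA(m)) {
    shared <- tcrossprod(m)            # a_ij = shared present alleles
    tot <- rowSums(m)
    denom <- outer(tot, tot, "+")
    s <- 2 * shared / denom
    diag(s) <- 1
    dimnames(s) <- list(rownames(m), rownames(m))
    return(s)
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(ok)) {
        stop_schema("samples %s and %s share no typed locus",
                    rownames(m)[i], rownames(m)[j])
      }
      a <- sum(m[i, ok] * m[j, ok])
      denom <- sum(m[i, ok]) + sum(m[j, ok])
      s[i, j] <- s[j, i] <- if (denom == 0) 0 else 2 * a / denom
    }
  }
  s
}

#' Dice-Sorensen genetic distance matrix
#'
#' Transforms pairwise Dice similarity s into a dissimilarity. The default
#' `sqrt(1 - s)` is the standard Euclidean-embeddable transform for Dice
#' similarities; `transform = "linear"` gives plain `1 - s`.
#'
#' @param m an [allele_matrix()].
#' @param transform `"sqrt"` (default) or `"linear"`.
#' @return a [dist_matrix()] tagged `dice_sorensen`.
#' @export
genetic_distance_matrix <- function(m, transform = c("sqrt", "linear")) {
  transform <- match.arg(transform)
  s <- dice_similarity(m)
  d <- 1 - s
  d[d < 0] <- 0                       # numeric fuzz
  if (transform == "sqrt") d <- sqrt(d)
  dist_matrix(d, metric = "dice_sorensen")
}

#' Ward dendrogram of a distance matrix
#'
#' Agglomerative clustering with the Ward criterion (Ward.D2: the
#' Lance-Williams update on squared dissimilarities, merge heights on the
#' original distance scale). Deterministic given the input order; ties are
#' resolved by `stats::hclust`'s fixed ordering.
#'
#' @param d a [dist_matrix()] or `dist`.
#' @return an `hclust` object (n - 1 merges, non-decreasing heights).
#' @export
ward_tree <- function(d) {
  dd <- if (inherits(d, "dist")) d else as_dist(d)
  if (attr(dd, "Size") < 2L) stop_schema("need >= 2 samples")
  stats::hclust(dd, method = "ward.D2")
}

#' Cut a dendrogram into k clusters
#'
#' @param tree an `hclust` object.
#' @param k number of clusters, `1 <= k <= n`.
#' @return named integer partition vector.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels %||% tree$order)
  if (k < 1 || k > n) stop_schema("k must be in [1, %d]", n)
  stats::cutree(tree, k = k)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same samples:
#' 1 for identical partitions (up to relabelling), expectation about 0 for
#' independent random labellings.
#'
#' @param p1,p2 partition vectors; if named, they are aligned by name and
#'   must cover the same sample set.
#' @return ARI (scalar).
#' @export
adjusted_rand_index <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) {
      stop_schema("partitions cover different sample sets")
    }
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    stop_schema("partitions differ in length")
  }
  mclust::adjustedRandIndex(p1, p2)
}

#' Read an admixture proportion (Q) matrix
#'
#' Plain numeric table, one row per sample and K columns of admixture
#' proportions q; whitespace- or comma-separated, with or without header.
#' Rows must sum to 1 (tolerance 0.02, to accommodate printed rounding);
#' they are renormalised exactly.
#'
#' @param path file path.
#' @param sample_ids optional ids; defaults to first non-numeric column or
#'   row numbers.
#' @return matrix of class `q_matrix` (rows sum to 1).
#' @export
read_q_matrix <- function(path, sample_ids = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE,
                          comment.char = "#", fill = TRUE)
  if (ncol(df) == 1L) {                      # maybe comma separated
    df <- utils::read.table(path, header = FALSE, sep = ",",
                            stringsAsFactors = FALSE)
  }
  if (all(vapply(df[1, ], function(x)
    is.na(suppressWarnings(as.numeric(x))), logical(1)))) {
    df <- df[-1, , drop = FALSE]             # header row
  }
  if (!is.numeric(df[[1]]) &&
      anyNA(suppressWarnings(as.numeric(df[[1]])))) {
    sample_ids <- sample_ids %||% as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  q <- as.matrix(as.data.frame(lapply(df, function(x)
    suppressWarnings(as.numeric(x)))))
  if (anyNA(q)) stop_schema("malformed Q-matrix row (non-numeric entry)")
  if (any(q < 0 | q > 1)) stop_schema("q values must lie in [0, 1]")
  rs <- rowSums(q)
  if (any(abs(rs - 1) > 0.02)) {
    stop_schema("Q-matrix row(s) do not sum to 1: %s",
                paste(which(abs(rs - 1) > 0.02), collapse = ", "))
  }
  q <- q / rs
  rownames(q) <- sample_ids %||% as.character(seq_len(nrow(q)))
  colnames(q) <- paste0("Q", seq_len(ncol(q)))
  structure(q, class = c("q_matrix", class(q)))
}

#' Hard cluster assignment from admixture proportions
#'
#' Each sample is assigned to the cluster with maximal q; ties go to the
#' lowest column index with a warning.
#'
#' @param q a [read_q_matrix()] result (or numeric matrix).
#' @return named integer partition vector.
#' @export
hard_assignment <- function(q) {
  q <- unclass(q)
  top <- apply(q, 1, max)
  ties <- rowSums(abs(q - top) < 1e-12) > 1L
  if (any(ties)) {
    warning(sprintf("tied maximal q for sample(s) %s; lowest index used",
                    paste(rownames(q)[ties], collapse = ", ")))
  }
  p <- max.col(q, ties.method = "first")
  names(p) <- rownames(q)
  p
}

#' Evanno delta-K from per-K log-likelihood runs
#'
#' Post-processes replicate admixture log-likelihoods L(K) (e.g. from an
#' external model-based clustering program) into the Evanno second-difference
#' statistic `deltaK(K) = |L(K+1) - 2 L(K) + L(K-1)| / sd(L(K))`, defined for
#' interior K; the arg-max is the suggested number of clusters.
#'
#' @param runs named list: names are K values (consecutive integers), each
#'   element a numeric vector of log-likelihoods over independent runs.
#' @return data.frame with columns `K`, `mean_L`, `sd_L`, `delta_K` and
#'   attribute `best_K`. K with zero run-to-run sd get `delta_K = NA` with a
#'   warning (division by zero flagged, K excluded from the arg-max).
#' @export
evanno_delta_k <- function(runs) {
  ks <- as.integer(names(runs))
  if (anyNA(ks) || is.unsorted(ks) || any(diff(ks) != 1L)) {
    stop_schema("runs must be named by consecutive K values")
  }
  if (length(ks) < 3L) stop_schema("need >= 3 consecutive K")
  mean_l <- vapply(runs, mean, numeric(1))
  sd_l <- vapply(runs, stats::sd, numeric(1))
  delta <- rep(NA_real_, length(ks))
  for (i in seq(2L, length(ks) - 1L)) {
    second <- abs(mean_l[i + 1] - 2 * mean_l[i] + mean_l[i - 1])
    if (is.na(sd_l[i]) || sd_l[i] == 0) {
      warning(sprintf("sd of L(K=%d) is zero; delta K undefined there", ks[i]))
    } else {
      delta[i] <- second / sd_l[i]
    }
  }
  out <- data.frame(K = ks, mean_L = unname(mean_l), sd_L = unname(sd_l),
                    delta_K = delta)
  best <- if (all(is.na(delta))) NA_integer_ else ks[which.max(delta)]
  attr(out, "best_K") <- best
  out
}
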