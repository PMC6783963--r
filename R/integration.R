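#' Euclidean distance matrix
#'
#' Plain L2 distances between sample rows; used for projected (UTM, metres)
#' geographic coordinates and for morphometric traits (quantitative on the
#' real scale). An optional z-scaling flag is provided for heterogeneous
#' units; the default is raw.
#'
#' @param q numeric matrix (samples x variables), no missing values.
#' @param scale. z-scale columns first (default FALSE).
#' @return a [dist_matrix()] tagged `euclidean`.
#' @export
euclidean_matrix <- function(q, scale. = FALSE) {
  x <- unclass(as.matrix(q))
  if (anyNA(x)) {
    bad <- rownames(x)[rowSums(is.na(x)) > 0][1]
    stop_schema("missing value for sample %s", bad)
  }
  if (scale.) x <- scale(x)
  dist_matrix(as.matrix(stats::dist(x, method = "euclidean")),
              metric = "euclidean")
}

#' Canberra distance matrix
#'
#' `d(x, y) = sum_j |x_j - y_j| / (|x_j| + |y_j|)`, with terms where both
#' values are exactly zero contributing 0. The metric weights differences in
#' low-abundance variables heavily, so an acid present at trace level in one
#' sample and absent in another contributes a full unit (the bio-marker
#' behaviour wanted for fatty-acid profiles).
#'
#' @param q non-negative numeric matrix (samples x variables).
#' @return a [dist_matrix()] tagged `canberra`.
#' @export
canberra_matrix <- function(q) {
  x <- unclass(as.matrix(q))
  if (anyNA(x)) stop_schema("missing values not allowed")
  if (any(x < 0)) stop_schema("Canberra distance requires non-negative values")
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (j in seq_len(ncol(x))) {
    num <- abs(outer(x[, j], x[, j], "-"))
    den <- outer(x[, j], x[, j], "+")
    term <- ifelse(den == 0, 0, num / den)
    d <- d + term
  }
  dist_matrix(d, metric = "canberra")
}

# all permutations of 1..n (n small), as a list
.all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in .all_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson correlation r of the n(n-1)/2 upper-triangle
#' entries. Significance is one-tailed for positive association: the rows
#' and columns of the second matrix are jointly permuted and
#' `p = (1 + #permutations with r* >= r) / (n_perm + 1)`. With
#' `exact = TRUE` all n! permutations are enumerated (small n only) and
#' `p = #perms with r* >= r / n!` (the identity included).
#'
#' @param d1,d2 [dist_matrix()] objects over the same samples in the same
#'   order.
#' @param n_perm number of Monte-Carlo permutations.
#' @param seed optional seed.
#' @param exact enumerate all permutations instead of sampling.
#' @return list of class `mantel_result`: `r`, `p`, `n_perm`, `seed`,
#'   `metrics` (pair of metric tags).
#' @export
mantel_test <- function(d1, d2, n_perm = 100000, seed = NULL, exact = FALSE) {
  m1 <- unclass(as.matrix(d1)); m2 <- unclass(as.matrix(d2))
  n <- nrow(m1)
  if (n != nrow(m2)) stop_schema("matrices differ in size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop_schema("matrices must cover the same samples in the same order")
  }
  if (n < 4L) stop_schema("need n >= 4")
  ut <- upper.tri(m1)
  x <- m1[ut]
  y <- m2[ut]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_schema("constant distance matrix; correlation undefined")
  }
  r <- stats::cor(x, y)
  if (exact) {
    if (n > 8L) stop_schema("exact enumeration limited to n <= 8")
    perms <- .all_perms(n)
    rstar <- vapply(perms, function(p) stats::cor(x, m2[p, p][ut]),
                    numeric(1))
    p <- mean(rstar >= r - 1e-12)
    n_perm <- length(perms)
  } else {
    hits <- with_seed(seed, {
      h <- 0L
      for (b in seq_len(n_perm)) {
        perm <- sample.int(n)
        if (stats::cor(x, m2[perm, perm][ut]) >= r - 1e-12) h <- h + 1L
      }
      h
    })
    p <- (1 + hits) / (n_perm + 1)
  }
  structure(list(r = r, p = p, n_perm = n_perm, seed = seed,
                 metrics = c(attr(d1, "metric") %||% "unknown",
                             attr(d2, "metric") %||% "unknown")),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (%s vs %s): r = %.3f, p = %.4g (%d permutations)\n",
              x$metrics[1], x$metrics[2], x$r, x$p, x$n_perm))
  invisible(x)
}

#' Bundle the four macro-descriptor distance matrices
#'
#' Geographic (Euclidean on UTM metres), morphometric (Euclidean),
#' fatty-acid (Canberra) and SSR (Dice-Sorensen) distances over one shared
#' sample set in one shared order.
#'
#' @param geographic,morphometric,fatty_acids,ssr [dist_matrix()] objects.
#' @return named list of class `descriptor_set`.
#' @export
descriptor_set <- function(geographic, morphometric, fatty_acids, ssr) {
  mats <- list(geographic = geographic, morphometric = morphometric,
               fatty_acids = fatty_acids, ssr = ssr)
  ids <- rownames(mats[[1]])
  for (nm in names(mats)) {
    if (!identical(rownames(mats[[nm]]), ids)) {
      stop_schema("descriptor '%s' has a different sample set/order", nm)
    }
  }
  structure(mats, class = "descriptor_set")
}

#' Mantel correlations among all macro-descriptor pairs
#'
#' Runs the Mantel test for all 6 unordered pairs of the descriptor set,
#' optionally on a sample subset (e.g. clone-group members only).
#'
#' @param ds a [descriptor_set()].
#' @param n_perm permutations per test.
#' @param seed optional base seed (each pair gets `seed + pair index`).
#' @param samples optional character vector restricting the analysis.
#' @return data.frame with one row per pair: `d1`, `d2`, `r`, `p`.
#' @export
descriptor_correlations <- function(ds, n_perm = 10000, seed = NULL,
                                    samples = NULL) {
  mats <- ds
  if (!is.null(samples)) {
    mats <- lapply(ds, function(m) {
      keep <- rownames(m) %in% samples
      dist_matrix(unclass(m)[keep, keep], metric = attr(m, "metric"))
    })
  }
  nm <- names(ds)
  pairs <- utils::combn(nm, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    mt <- mantel_test(mats[[a]], mats[[b]], n_perm = n_perm,
                      seed = if (is.null(seed)) NULL else seed + i)
    data.frame(d1 = a, d2 = b, r = mt$r, p = mt$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
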