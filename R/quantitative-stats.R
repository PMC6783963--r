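#' Shapiro-Wilk normality test
#'
#' Gate check for the parametric one-way ANOVA assumptions; on rejection the
#' pipeline falls back to the Kruskal-Wallis test.
#'
#' @param x numeric vector, 3 <= n <= 5000.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    stop_schema("Shapiro-Wilk requires 3 <= n <= 5000")
  }
  if (stats::var(x) == 0) stop_schema("constant input (zero variance)")
  r <- stats::shapiro.test(x)
  list(W = unname(r$statistic), p = r$p.value)
}

#' Levene test of homoscedasticity (mean-centred)
#'
#' Classic Levene one-way F on absolute deviations from the group means
#' (`center = mean`, as originally defined; `center = median` gives the
#' Brown-Forsythe variant).
#'
#' @param values numeric vector.
#' @param groups group labels aligned with `values`.
#' @param center `mean` (default) or `median`.
#' @return list with `F`, `df` (length 2) and `p`.
#' @export
levene_test <- function(values, groups, center = mean) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop_schema("need >= 2 groups")
  if (any(table(groups) < 2L)) stop_schema("every group needs n >= 2")
  r <- car::leveneTest(values, groups, center = center)
  list(F = r$`F value`[1], df = c(r$Df[1], r$Df[2]), p = r$`Pr(>F)`[1])
}

#' Kruskal-Wallis rank test
#'
#' Nonparametric one-way ANOVA: H statistic with tie correction, p-value
#' from the chi-squared distribution with k - 1 df.
#'
#' @param values numeric vector.
#' @param groups group labels aligned with `values`.
#' @return list with `H`, `df`, `p`, and `n` (per-group counts).
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2L) stop_schema("need >= 2 groups")
  if (length(values) < 3L) stop_schema("need total n >= 3")
  if (length(unique(values)) == 1L) {
    warning("all values tied; H = 0, p = 1")
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1,
                n = table(groups)))
  }
  r <- stats::kruskal.test(values, groups)
  list(H = unname(r$statistic), df = unname(r$parameter), p = r$p.value,
       n = table(groups))
}

#' Siegel-Castellan nonparametric post-hoc comparisons
#'
#' After a Kruskal-Wallis test, compares all group pairs on mean ranks:
#' pair (i, j) is significant when
#' `|Ri - Rj| >= z(alpha / (k (k - 1))) * sqrt((N (N + 1) / 12) (1/ni + 1/nj))`,
#' i.e. a normal critical value Bonferroni-corrected over the k(k-1)/2
#' two-sided pairwise comparisons.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param alpha family significance level (default 0.05).
#' @return data.frame with one row per unordered pair: `group1`, `group2`,
#'   `rank_diff`, `critical`, `significant`.
#' @export
kw_posthoc_siegel_castellan <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  k <- nlevels(groups)
  if (k < 2L) stop_schema("need >= 2 groups")
  n_tot <- length(values)
  rk <- rank(values)
  mean_rank <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  z <- stats::qnorm(1 - alpha / (k * (k - 1)))
  pairs <- utils::combn(levels(groups), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    rank_diff = NA_real_, critical = NA_real_,
                    significant = NA, stringsAsFactors = FALSE)
  for (r in seq_len(ncol(pairs))) {
    g1 <- pairs[1, r]; g2 <- pairs[2, r]
    se <- sqrt(n_tot * (n_tot + 1) / 12 * (1 / n_g[[g1]] + 1 / n_g[[g2]]))
    diff <- abs(mean_rank[[g1]] - mean_rank[[g2]])
    out$rank_diff[r] <- diff
    out$critical[r] <- z * se
    out$significant[r] <- diff >= z * se
  }
  out
}

#' Spearman rank correlation test
#'
#' Tie-corrected rho with a t-approximation p-value; optionally a
#' permutation p-value.
#'
#' @param x,y numeric vectors, n >= 4.
#' @param n_perm if > 0, a two-sided permutation p-value on `|rho|` with
#'   that many shuffles of `y` (seeded via `seed`).
#' @param seed optional seed for the permutation option.
#' @return list with `rho` and `p`.
#' @export
spearman_test <- function(x, y, n_perm = 0, seed = NULL) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop_schema("need n >= 4")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_schema("constant input; correlation undefined")
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (n_perm > 0) {
    hits <- with_seed(seed, {
      h <- 0L
      for (b in seq_len(n_perm)) {
        if (abs(stats::cor(x, sample(y), method = "spearman")) >=
            abs(rho) - 1e-12) h <- h + 1L
      }
      h
    })
    return(list(rho = rho, p = (1 + hits) / (n_perm + 1)))
  }
  r <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                        exact = FALSE))
  list(rho = unname(r$estimate), p = r$p.value)
}

#' MUFA/PUFA ratio per sample
#'
#' Ratio of summed mono-unsaturated to summed poly-unsaturated fatty-acid
#' percentages, a nutritional quality index of olive oil.
#'
#' @param q a fatty-acid [quantitative_matrix()] (percent).
#' @param classes named character vector mapping acid columns to
#'   `"MUFA"`/`"PUFA"`/`"other"`; defaults to [default_fatty_classes()].
#' @return numeric vector of per-sample ratios; samples with zero PUFA sum
#'   are `Inf` with a warning (excluded from any summary).
#' @export
mufa_pufa_ratio <- function(q, classes = default_fatty_classes()) {
  known <- intersect(colnames(q), names(classes))
  if (length(known) == 0L) stop_schema("no classified fatty-acid columns")
  mufa_cols <- known[classes[known] == "MUFA"]
  pufa_cols <- known[classes[known] == "PUFA"]
  if (length(pufa_cols) == 0L) stop_schema("no PUFA columns present")
  mufa <- rowSums(q[, mufa_cols, drop = FALSE])
  pufa <- rowSums(q[, pufa_cols, drop = FALSE])
  ratio <- mufa / pufa
  if (any(pufa == 0)) {
    warning(sprintf("%d sample(s) with zero PUFA sum flagged as Inf",
                    sum(pufa == 0)))
    ratio[pufa == 0] <- Inf
  }
  names(ratio) <- rownames(q)
  ratio
}

#' Per-variable nonparametric group-comparison report
#'
#' For every variable of a quantitative matrix: the Kruskal-Wallis H, df and
#' p versus the grouping, plus (optionally) the Siegel-Castellan pairwise
#' significance grid, mirroring the usual site-comparison table layout.
#'
#' @param q a [quantitative_matrix()].
#' @param groups group labels aligned with `rownames(q)`.
#' @param alpha family significance level for the post-hoc grid.
#' @param posthoc include pairwise grids?
#' @param bonferroni also flag KW p-values against `alpha / n_variables`?
#' @return list with `tests` (data.frame) and `posthoc` (named list of
#'   data.frames).
#' @export
group_comparison_report <- function(q, groups, alpha = 0.05, posthoc = TRUE,
                                    bonferroni = FALSE) {
  stopifnot(length(groups) == nrow(q))
  vars <- colnames(q)
  tests <- do.call(rbind, lapply(vars, function(v) {
    kw <- kruskal_wallis(q[, v], groups)
    data.frame(variable = v, H = kw$H, df = kw$df, p = kw$p,
               significant = kw$p < alpha, stringsAsFactors = FALSE)
  }))
  if (bonferroni) tests$significant_bonf <- tests$p < alpha / length(vars)
  ph <- NULL
  if (posthoc) {
    ph <- lapply(vars, function(v)
      kw_posthoc_siegel_castellan(q[, v], groups, alpha = alpha))
    names(ph) <- vars
  }
  list(tests = tests, posthoc = ph)
}
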