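#' Allele frequencies at one locus
#'
#' Frequencies are estimated over the 2N allele draws of the samples with a
#' non-missing call at the locus.
#'
#' @param g a [genotype_table()].
#' @param locus locus name.
#' @return list with `freq` (named numeric vector, names = allele sizes in
#'   bp, sums to 1) and `N` (number of typed samples).
#' @export
allele_frequencies <- function(g, locus) {
  j <- match(locus, g$loci)
  if (is.na(j)) stop_schema("unknown locus: %s", locus)
  ok <- !is.na(g$a1[, j])
  if (!any(ok)) stop_schema("locus %s has no non-missing calls", locus)
  alleles <- c(g$a1[ok, j], g$a2[ok, j])
  tab <- table(alleles)
  freq <- as.numeric(tab) / length(alleles)
  names(freq) <- names(tab)
  freq <- freq[order(as.numeric(names(freq)))]
  list(freq = freq, N = sum(ok))
}

#' Expected heterozygosity from a frequency vector
#'
#' The biased (GenAlEx-style) estimator `He = 1 - sum(f^2)`.
#' @param f numeric frequency vector.
#' @export
he_from_freqs <- function(f) 1 - sum(f^2)

#' Effective number of alleles from a frequency vector
#'
#' `Ne = 1 / sum(f^2)`; equals the allele count for equifrequent alleles and
#' is otherwise smaller.
#' @param f numeric frequency vector.
#' @export
ne_from_freqs <- function(f) 1 / sum(f^2)

#' Unbiased expected heterozygosity
#'
#' Small-sample correction `uHe = (2N / (2N - 1)) * He`.
#' @param he expected heterozygosity.
#' @param N number of typed diploid samples.
#' @export
uhe_from_he <- function(he, N) 2 * N / (2 * N - 1) * he

#' Observed, expected and unbiased heterozygosity at one locus
#'
#' @inheritParams allele_frequencies
#' @return named numeric vector `c(Ho, He, uHe)`. `Ho` is the fraction of
#'   typed samples with two distinct alleles; `He = 1 - sum(f^2)`;
#'   `uHe = 2N/(2N-1) * He`.
#' @export
heterozygosities <- function(g, locus) {
  j <- match(locus, g$loci)
  if (is.na(j)) stop_schema("unknown locus: %s", locus)
  ok <- !is.na(g$a1[, j])
  if (!any(ok)) stop_schema("locus %s has no non-missing calls", locus)
  af <- allele_frequencies(g, locus)
  ho <- mean(g$a1[ok, j] != g$a2[ok, j])
  he <- he_from_freqs(af$freq)
  c(Ho = ho, He = he, uHe = uhe_from_he(he, af$N))
}

#' Brookfield null-allele frequency estimator
#'
#' Estimator 1 of Brookfield for codominant markers without an observed
#' null-homozygote class: `r = (He - Ho) / (1 + He)`, clamped at 0 when
#' observed heterozygosity exceeds expectation.
#'
#' @param He expected heterozygosity in \[0, 1\].
#' @param Ho observed heterozygosity in \[0, 1\].
#' @return estimated null-allele frequency in \[0, 1).
#' @export
brookfield_null <- function(He, Ho) {
  stopifnot(He >= 0, He <= 1, Ho >= 0, Ho <= 1)
  max(0, (He - Ho) / (1 + He))
}

# log of the permutation-varying part of the conditional probability of a
# genotype array given its allele counts: log(2^het) - sum(log n_g!).
# (N!, allele-count factorials and (2N)! are invariant under reshuffling of
# the allele vector, so they cancel in the comparison.)
.log_array_prob_part <- function(v1, v2) {
  code <- pmin(v1, v2) * 4096 + pmax(v1, v2)
  tab <- tabulate(match(code, unique(code)))
  sum(v1 != v2) * log(2) - sum(lgamma(tab + 1))
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Exact-test convention: the statistic is the conditional probability of
#' the observed genotype array given the allele counts; the null
#' distribution is sampled by reshuffling the 2N-allele vector and re-pairing
#' it into N genotypes. The p-value is
#' `(1 + #permutations with probability <= observed) / (n_perm + 1)`.
#'
#' @inheritParams allele_frequencies
#' @param n_perm number of permutations.
#' @param seed optional integer seed for reproducibility.
#' @return p-value with attributes `n_perm` and `statistic` (observed log
#'   probability part).
#' @export
hwe_exact_mc <- function(g, locus, n_perm = 100000, seed = NULL) {
  j <- match(locus, g$loci)
  if (is.na(j)) stop_schema("unknown locus: %s", locus)
  ok <- !is.na(g$a1[, j])
  if (sum(ok) < 2L) stop_schema("need >= 2 typed samples at %s", locus)
  v1 <- g$a1[ok, j]; v2 <- g$a2[ok, j]
  alleles <- c(v1, v2)
  if (length(unique(alleles)) < 2L) {
    warning(sprintf("locus %s is monomorphic; HWE p = 1", locus))
    return(structure(1.0, n_perm = n_perm, statistic = 0))
  }
  obs <- .log_array_prob_part(v1, v2)
  n <- length(v1)
  hits <- with_seed(seed, {
    h <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(alleles)
      p1 <- perm[seq_len(n)]; p2 <- perm[n + seq_len(n)]
      if (.log_array_prob_part(p1, p2) <= obs + 1e-9) h <- h + 1L
    }
    h
  })
  structure((1 + hits) / (n_perm + 1), n_perm = n_perm, statistic = obs)
}

#' Probability of genetic identity (Pgen) of a multilocus genotype
#'
#' The probability that a given multilocus genotype arises by chance under
#' random mating from the population allele frequencies: the product over
#' non-missing loci of `f^2` (homozygote) or `2 f f'` (heterozygote). Very
#' small values for repeated genotypes indicate clonal (vegetative) origin.
#'
#' @param g a [genotype_table()].
#' @param sample_id sample to evaluate.
#' @param freqs optional list of per-locus frequency vectors (as returned by
#'   [allele_frequencies()]`$freq`); pooled whole-table frequencies by
#'   default.
#' @param sites optional character vector of site labels aligned with
#'   `g$sample_ids`; when given, frequencies are pooled within the sample's
#'   site only.
#' @return list with `pgen`, `factors` (named per-locus), and
#'   `skipped_loci` (missing for this sample, contributing factor 1).
#' @export
pgen <- function(g, sample_id, freqs = NULL, sites = NULL) {
  i <- match(sample_id, g$sample_ids)
  if (is.na(i)) stop_schema("unknown sample: %s", sample_id)
  gg <- g
  if (!is.null(sites)) {
    stopifnot(length(sites) == length(g$sample_ids))
    keep <- sites == sites[i]
    gg <- genotype_table(g$sample_ids[keep], g$loci,
                         g$a1[keep, , drop = FALSE],
                         g$a2[keep, , drop = FALSE])
  }
  if (is.null(freqs)) {
    freqs <- lapply(gg$loci, function(l) allele_frequencies(gg, l)$freq)
    names(freqs) <- gg$loci
  }
  factors <- numeric(0)
  skipped <- character(0)
  for (l in g$loci) {
    j <- match(l, g$loci)
    a <- g$a1[i, j]; b <- g$a2[i, j]
    if (is.na(a)) {
      skipped <- c(skipped, l)
      next
    }
    f <- freqs[[l]]
    fa <- f[as.character(a)]; fb <- f[as.character(b)]
    if (is.na(fa) || is.na(fb)) {
      stop_schema("allele without frequency at locus %s for sample %s",
                  l, sample_id)
    }
    factors[l] <- if (a == b) fa^2 else 2 * fa * fb
  }
  list(pgen = prod(factors), factors = factors, skipped_loci = skipped)
}

#' Binary allele presence/absence matrix
#'
#' One column per distinct (locus, allele) pair; a homozygote sets one
#' column, a heterozygote two. Columns of a locus missing for a sample are
#' `NA` (masked), never 0: absence of evidence is not evidence of absence.
#'
#' @param g a [genotype_table()].
#' @return numeric matrix (samples x alleles) of 0/1/NA with column names
#'   `locus.allele` and attribute `locus` (column -> locus map).
#' @export
allele_matrix <- function(g) {
  cols <- list()
  for (l in g$loci) {
    j <- match(l, g$loci)
    alle <- sort(unique(stats::na.omit(c(g$a1[, j], g$a2[, j]))))
    cols[[l]] <- alle
  }
  total <- sum(lengths(cols))
  m <- matrix(NA_real_, length(g$sample_ids), total,
              dimnames = list(g$sample_ids, NULL))
  locus_of <- character(total)
  nm <- character(total)
  k <- 0L
  for (l in g$loci) {
    j <- match(l, g$loci)
    alle <- cols[[l]]
    idx <- k + seq_along(alle)
    locus_of[idx] <- l
    nm[idx] <- paste(l, alle, sep = ".")
    typed <- !is.na(g$a1[, j])
    block <- matrix(NA_real_, length(g$sample_ids), length(alle))
    block[typed, ] <- 0
    p1 <- match(g$a1[typed, j], alle)
    p2 <- match(g$a2[typed, j], alle)
    block[cbind(which(typed), p1)] <- 1
    block[cbind(which(typed), p2)] <- 1
    m[, idx] <- block
    k <- k + length(alle)
  }
  colnames(m) <- nm
  attr(m, "locus") <- locus_of
  m
}

#' Group samples into multilocus genotypes (clones/genets)
#'
#' Two samples belong to the same multilocus genotype when their genotypes
#' agree at every locus typed in both, allowing at most
#' `max_mismatch_loci` disagreeing loci and treating alleles within
#' `allele_tolerance_bp` base pairs as identical (somatic variants of a
#' vegetatively propagated genet typically differ by 2-3 bp). Groups are
#' connected components of this pairwise relation.
#'
#' @param g a [genotype_table()].
#' @param max_mismatch_loci maximum number of mismatching loci tolerated.
#' @param allele_tolerance_bp per-allele size tolerance in bp.
#' @return named integer vector of genotype-group labels (1..G), with
#'   attributes `n_genotypes` and `group_sizes`.
#' @export
find_clones <- function(g, max_mismatch_loci = 0, allele_tolerance_bp = 0) {
  n <- length(g$sample_ids)
  all_missing <- rowSums(!is.na(g$a1)) == 0L
  if (any(all_missing)) {
    warning(sprintf("%d sample(s) missing at every locus kept as singletons",
                    sum(all_missing)))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  tol <- allele_tolerance_bp
  for (i in seq_len(n - 1L)) {
    if (all_missing[i]) next
    for (k in seq.int(i + 1L, n)) {
      if (all_missing[k]) next
      both <- !is.na(g$a1[i, ]) & !is.na(g$a1[k, ])
      if (!any(both)) next
      mism <- sum(abs(g$a1[i, both] - g$a1[k, both]) > tol |
                  abs(g$a2[i, both] - g$a2[k, both]) > tol)
      if (mism <= max_mismatch_loci) {
        ri <- find(i); rk <- find(k)
        if (ri != rk) parent[rk] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- match(roots, unique(roots))
  names(labels) <- g$sample_ids
  structure(labels, n_genotypes = length(unique(labels)),
            group_sizes = as.integer(table(labels)))
}

#' Per-locus diversity summary table
#'
#' GenAlEx-style per-locus report: typed sample count N, allele count Na,
#' effective alleles Ne, observed/expected/unbiased heterozygosity, the
#' Brookfield null-allele frequency, and the Monte-Carlo exact
#' Hardy-Weinberg p-value with a significance flag.
#'
#' @param g a [genotype_table()].
#' @param n_perm permutations for the HWE test (skipped when `n_perm = 0`).
#' @param seed optional seed for the HWE permutations.
#' @param alpha significance level for the HWE flag.
#' @return data.frame with one row per locus.
#' @export
locus_summary <- function(g, n_perm = 10000, seed = NULL, alpha = 0.001) {
  rows <- lapply(seq_along(g$loci), function(k) {
    l <- g$loci[k]
    af <- allele_frequencies(g, l)
    het <- heterozygosities(g, l)
    p <- if (n_perm > 0) {
      as.numeric(hwe_exact_mc(g, l, n_perm = n_perm,
                              seed = if (is.null(seed)) NULL else seed + k))
    } else NA_real_
    data.frame(locus = l, N = af$N, Na = length(af$freq),
               Ne = ne_from_freqs(af$freq),
               Ho = het[["Ho"]], He = het[["He"]], uHe = het[["uHe"]],
               r_null = brookfield_null(het[["He"]], het[["Ho"]]),
               hwe_p = p,
               hwe_sig = if (is.na(p)) NA else p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
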