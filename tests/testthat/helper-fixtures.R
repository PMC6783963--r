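# fixtures built in code: tiny genotype tables and brute-force oracles

# genotype table from a list: list(S1 = list(UDO6 = c(146, 172), ...), ...)
gt_from_list <- function(calls) {
  ids <- names(calls)
  loci <- unique(unlist(lapply(calls, names)))
  a1 <- a2 <- matrix(NA_real_, length(ids), length(loci),
                     dimnames = list(ids, loci))
  for (i in seq_along(ids)) {
    for (l in names(calls[[i]])) {
      pair <- calls[[i]][[l]]
      a1[i, l] <- pair[1]; a2[i, l] <- pair[2]
    }
  }
  genotype_table(ids, loci, a1, a2)
}

# genotype table whose allele inventory exactly matches a locus -> alleles
# list: samples pair up consecutive pool alleles so every allele appears.
gt_with_inventory <- function(pools) {
  n <- max(vapply(pools, function(a) ceiling(length(a) / 2), numeric(1)))
  ids <- sprintf("S%d", seq_len(n))
  a1 <- a2 <- matrix(NA_real_, n, length(pools),
                     dimnames = list(ids, names(pools)))
  for (j in seq_along(pools)) {
    pool <- pools[[j]]
    for (i in seq_len(n)) {
      p <- 2 * i - 1
      if (p <= length(pool)) {
        a1[i, j] <- pool[p]
        a2[i, j] <- pool[min(p + 1, length(pool))]
      } else {
        a1[i, j] <- pool[1]; a2[i, j] <- pool[1]
      }
    }
  }
  genotype_table(ids, names(pools), a1, a2)
}

# exhaustive PAM oracle: minimal mean dissimilarity over all medoid subsets
brute_pam_objective <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  best <- Inf
  sets <- utils::combn(n, k)
  for (c in seq_len(ncol(sets))) {
    obj <- mean(apply(d[, sets[, c], drop = FALSE], 1, min))
    best <- min(best, obj)
  }
  best
}

# all permutations of 1..n (independent of the package's internal helper)
perms_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perms_of(n - 1)
  res <- NULL
  for (r in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      res <- rbind(res, append(sub[r, ], n, after = pos - 1))
    }
  }
  res
}

# exact two-allele HWE oracle: enumerate genotype-count configurations
hwe_exact_two_allele <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  prob <- function(h) {            # h heterozygotes, consistent counts
    paa <- (n_a - h) / 2; pbb <- (n_b - h) / 2
    if (paa < 0 || pbb < 0 || paa != round(paa)) return(NA_real_)
    exp(lfactorial(n) - lfactorial(paa) - lfactorial(h) - lfactorial(pbb) +
          h * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n))
  }
  hs <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  ps <- vapply(hs, prob, numeric(1))
  obs <- prob(n_ab)
  sum(ps[!is.na(ps) & ps <= obs + 1e-12])
}

site_partition <- function(samples) {
  stats::setNames(as.integer(factor(samples$site)), samples$sample_id)
}
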