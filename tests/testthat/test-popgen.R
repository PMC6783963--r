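test_that("allele frequencies count 2N draws from typed samples", {
  g <- gt_from_list(list(S1 = list(L = c(140, 144)),
                         S2 = list(L = c(140, 140))))
  af <- allele_frequencies(g, "L")
  expect_equal(af$freq, c(`140` = 0.75, `144` = 0.25))
  expect_equal(af$N, 2)

  mono <- gt_from_list(list(S1 = list(L = c(100, 100)),
                            S2 = list(L = c(100, 100))))
  expect_equal(allele_frequencies(mono, "L")$freq, c(`100` = 1))
  expect_error(allele_frequencies(g, "nope"), "unknown locus")
})

test_that("heterozygosity identities hold on reference and random loci", {
  # published whole-collection frequencies: sums and closed forms
  fr <- ref_allele_freqs()
  for (l in unique(fr$locus)) {
    f <- fr$freq[fr$locus == l]
    expect_equal(sum(f), 1, tolerance = 0.005)   # printed rounding
    expect_true(ne_from_freqs(f) <= length(f))
    expect_equal(ne_from_freqs(f) * sum(f^2), 1)
  }
  # random genotype tables: He from estimated freqs == 1 - sum(f^2); uHe >= He
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    alle <- sample(seq(100, 140, by = 2), 4)
    a1 <- sample(alle, n, replace = TRUE)
    a2 <- sample(alle, n, replace = TRUE)
    g <- genotype_table(sprintf("s%d", 1:n), "L", cbind(a1), cbind(a2))
    het <- heterozygosities(g, "L")
    f <- allele_frequencies(g, "L")$freq
    expect_equal(het[["He"]], 1 - sum(f^2))
    expect_gte(het[["uHe"]], het[["He"]])
    expect_equal(het[["uHe"]] / het[["He"]], 2 * n / (2 * n - 1))
  }
  # all-homozygous single allele
  mono <- gt_from_list(list(S1 = list(L = c(100, 100)),
                            S2 = list(L = c(100, 100))))
  het <- heterozygosities(mono, "L")
  expect_equal(unname(het[c("Ho", "He")]), c(0, 0))
})

test_that("effective alleles: equifrequent symmetry and hand value", {
  expect_equal(ne_from_freqs(rep(1 / 7, 7)), 7)
  expect_equal(ne_from_freqs(c(0.5, 0.25, 0.25)), 1 / 0.375)
})

test_that("Brookfield estimator matches closed form and is monotone", {
  expect_equal(brookfield_null(0.5, 0.25), 0.25 / 1.5)
  expect_equal(brookfield_null(0.6, 0.6), 0)
  expect_equal(brookfield_null(0.3, 0.9), 0)   # clamped
  # monotone: decreasing in Ho, increasing in He
  hos <- seq(0, 0.6, by = 0.1)
  rs <- vapply(hos, function(h) brookfield_null(0.7, h), numeric(1))
  expect_true(all(diff(rs) <= 0))
  hes <- seq(0.3, 0.9, by = 0.1)
  rs2 <- vapply(hes, function(h) brookfield_null(h, 0.2), numeric(1))
  expect_true(all(diff(rs2) >= 0))
})

test_that("HWE MC test: monomorphic, reproducibility, exact two-allele oracle", {
  mono <- gt_from_list(list(S1 = list(L = c(100, 100)),
                            S2 = list(L = c(100, 100))))
  expect_warning(p <- hwe_exact_mc(mono, "L", n_perm = 10), "monomorphic")
  expect_equal(as.numeric(p), 1)

  # a heterozygote-deficient two-allele array, n = 6
  g <- gt_from_list(list(S1 = list(L = c(100, 100)), S2 = list(L = c(100, 100)),
                         S3 = list(L = c(104, 104)), S4 = list(L = c(104, 104)),
                         S5 = list(L = c(100, 104)), S6 = list(L = c(100, 100))))
  p1 <- hwe_exact_mc(g, "L", n_perm = 2000, seed = 7)
  p2 <- hwe_exact_mc(g, "L", n_perm = 2000, seed = 7)
  expect_identical(as.numeric(p1), as.numeric(p2))  # bit-reproducible

  # exact enumeration oracle over all two-allele genotype configurations
  a1 <- g$a1[, 1]; a2 <- g$a2[, 1]
  n_het <- sum(a1 != a2)
  n_hom_a <- sum(a1 == 100 & a2 == 100)
  n_hom_b <- sum(a1 == 104 & a2 == 104)
  p_exact <- hwe_exact_two_allele(n_hom_a, n_het, n_hom_b)
  p_mc <- as.numeric(hwe_exact_mc(g, "L", n_perm = 20000, seed = 3))
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(p_mc - p_exact), 4 * se + 1e-4)

  # across-seed spread consistent with binomial MC error
  ps <- vapply(1:8, function(s)
    as.numeric(hwe_exact_mc(g, "L", n_perm = 2000, seed = s)), numeric(1))
  expect_lt(stats::sd(ps), 3 * sqrt(p_exact * (1 - p_exact) / 2000))
})

test_that("Pgen multiplies per-locus factors over non-missing loci", {
  freqs <- list(L1 = c(`100` = 0.3, `102` = 0.2, `104` = 0.5),
                L2 = c(`200` = 0.5, `202` = 0.5))
  g <- gt_from_list(list(S1 = list(L1 = c(100, 102), L2 = c(200, 200)),
                         S2 = list(L1 = c(NA, NA), L2 = c(200, 202))))
  r <- pgen(g, "S1", freqs = freqs)
  expect_equal(r$pgen, (2 * 0.3 * 0.2) * 0.25)
  expect_equal(unname(r$factors), c(0.12, 0.25))
  # missing locus contributes factor 1 and is reported
  r2 <- pgen(g, "S2", freqs = freqs)
  expect_equal(r2$skipped_loci, "L1")
  expect_equal(r2$pgen, 2 * 0.5 * 0.5)
  # all loci monomorphic homozygous -> Pgen 1
  mono <- gt_from_list(list(S1 = list(L = c(100, 100)),
                            S2 = list(L = c(100, 100))))
  expect_equal(pgen(mono, "S1")$pgen, 1)
})

test_that("Pgen of every simulated sample is in (0,1] and factors multiply", {
  sim <- simulate_dataset(default_sim_config(), seed = 3)
  g <- sim$genotypes
  ids <- g$sample_ids[1:25]
  for (id in ids) {
    r <- pgen(g, id)
    expect_true(r$pgen > 0 && r$pgen <= 1)
    expect_equal(sum(log(r$factors)), log(r$pgen), tolerance = 1e-12)
  }
})

test_that("allele matrix: columns, masking, and row sums", {
  g <- gt_from_list(list(S1 = list(L1 = c(140, 144), L2 = c(200, 200)),
                         S2 = list(L1 = c(140, 140), L2 = c(NA, NA)),
                         S3 = list(L1 = c(144, 148), L2 = c(200, 202))))
  m <- allele_matrix(g)
  expect_equal(ncol(m), 3 + 2)
  expect_equal(sum(m["S1", ]), 3)  # het (2 cols) + hom (1 col)
  # masked, not zero, at the missing locus
  expect_true(all(is.na(m["S2", attr(m, "locus") == "L2"])))
  expect_equal(sum(m["S2", ], na.rm = TRUE), 1)
  # fully typed rows: 2L - #homozygous loci
  expect_equal(sum(m["S3", ]), 2 * 2 - 0)
  sim <- simulate_dataset(default_sim_config(), seed = 8)
  ms <- allele_matrix(sim$genotypes)
  full <- rowSums(missing_mask(sim$genotypes)) == 0
  hom <- rowSums(sim$genotypes$a1 == sim$genotypes$a2, na.rm = TRUE)
  expect_equal(rowSums(ms, na.rm = TRUE)[full],
               (2 * length(sim$genotypes$loci) - hom)[full])
})

test_that("clone detection groups identical and near-identical profiles", {
  prof <- list(L1 = c(140, 144), L2 = c(200, 202), L3 = c(300, 300))
  variant <- prof; variant$L2 <- c(200, 204)  # one allele moved 2 bp
  g <- gt_from_list(list(A = prof, B = prof, C = variant,
                         D = list(L1 = c(150, 152), L2 = c(210, 212),
                                  L3 = c(302, 304))))
  cl0 <- find_clones(g)
  expect_equal(unname(cl0["A"]), unname(cl0["B"]))
  expect_false(cl0["C"] == cl0["A"])
  cl2 <- find_clones(g, allele_tolerance_bp = 2)
  expect_equal(unname(cl2["C"]), unname(cl2["A"]))
  expect_false(cl2["D"] == cl2["A"])
  # planted duplicates: 10 samples, 3 copies -> 7 unique genotypes
  set.seed(21)
  base <- lapply(1:7, function(i)
    list(L1 = sort(sample(seq(100, 120, 2), 2, TRUE)),
         L2 = sort(sample(seq(200, 220, 2), 2, TRUE)),
         L3 = sort(sample(seq(300, 320, 2), 2, TRUE))))
  calls <- c(base, base[c(1, 3, 5)])
  names(calls) <- sprintf("S%d", 1:10)
  cl <- find_clones(gt_from_list(calls))
  expect_equal(attr(cl, "n_genotypes"), 7)
  # sample missing everywhere stays a singleton, with a warning
  gna <- genotype_table(c("x", "y"), "L", rbind(NA, 100), rbind(NA, 100))
  expect_warning(cln <- find_clones(gna), "singleton")
  expect_equal(attr(cln, "n_genotypes"), 2)
})

test_that("locus summary reports one row per locus with coherent indices", {
  sim <- simulate_dataset(default_sim_config(), seed = 5)
  s <- locus_summary(sim$genotypes, n_perm = 200, seed = 9)
  expect_equal(nrow(s), 6)
  expect_true(all(s$Ne <= s$Na))
  expect_true(all(s$uHe >= s$He))
  expect_true(all(s$r_null >= 0))
  expect_true(all(s$hwe_p > 0 & s$hwe_p <= 1))
})
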