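test_that("Dice similarity: hand values, symmetry, missing-data handling", {
  g <- gt_from_list(list(
    A = list(L1 = c(100, 102), L2 = c(200, 202), L3 = c(300, 302),
             L4 = c(400, 402)),
    B = list(L1 = c(100, 102), L2 = c(200, 202), L3 = c(300, 304),
             L4 = c(400, 406))))
  m <- allele_matrix(g)
  s <- dice_similarity(m)
  # 8 present alleles each, 6 shared (100,102,200,202,300,400) -> 12/16
  expect_equal(s["A", "B"], 0.75)
  expect_equal(s, t(s))
  expect_equal(diag(s), c(A = 1, B = 1))

  ident <- gt_from_list(list(A = list(L = c(100, 102)),
                             B = list(L = c(100, 102))))
  expect_equal(dice_similarity(allele_matrix(ident))["A", "B"], 1)
  disj <- gt_from_list(list(A = list(L = c(100, 102)),
                            B = list(L = c(104, 106))))
  expect_equal(dice_similarity(allele_matrix(disj))["A", "B"], 0)

  # pairwise-complete loci: a 4-of-6-missing sample is still placeable
  g2 <- gt_from_list(list(
    P8 = list(L1 = c(100, 102), L2 = c(NA, NA), L3 = c(NA, NA),
              L4 = c(NA, NA), L5 = c(NA, NA), L6 = c(500, 500)),
    Q = list(L1 = c(100, 102), L2 = c(200, 200), L3 = c(300, 300),
             L4 = c(400, 400), L5 = c(450, 450), L6 = c(500, 502))))
  s2 <- dice_similarity(allele_matrix(g2))
  expect_equal(s2["P8", "Q"], 2 * 3 / (3 + 4))  # shared L1 both + L6 one
  # no shared typed locus -> error
  g3 <- gt_from_list(list(A = list(L1 = c(100, 100), L2 = c(NA, NA)),
                          B = list(L1 = c(NA, NA), L2 = c(200, 200))))
  expect_error(dice_similarity(allele_matrix(g3)), "no typed locus")
})

test_that("genetic distance transform: sqrt default, linear flag", {
  g <- gt_from_list(list(
    A = list(L1 = c(100, 102), L2 = c(200, 202), L3 = c(300, 302),
             L4 = c(400, 402)),
    B = list(L1 = c(100, 102), L2 = c(200, 202), L3 = c(300, 304),
             L4 = c(400, 406))))
  m <- allele_matrix(g)
  expect_equal(genetic_distance_matrix(m)["A", "B"], sqrt(0.25))
  expect_equal(genetic_distance_matrix(m, "linear")["A", "B"], 0.25)
  ident <- gt_from_list(list(A = list(L = c(100, 102)),
                             B = list(L = c(100, 102))))
  expect_equal(genetic_distance_matrix(allele_matrix(ident))["A", "B"], 0)
})

test_that("Ward tree matches a hand Lance-Williams run and is monotone", {
  # two samples: single merge at their distance
  d2 <- dist_matrix(matrix(c(0, .4, .4, 0), 2, 2,
                           dimnames = list(c("A", "B"), NULL)), "euclidean")
  t2 <- ward_tree(d2)
  expect_equal(t2$height, 0.4)

  # 4-point instance vs an independent greedy Ward.D2 oracle on squared
  # distances (Lance-Williams update), checking merge heights
  set.seed(4)
  x <- matrix(rnorm(8), 4, 2, dimnames = list(letters[1:4], NULL))
  d <- as.matrix(dist(x))
  t4 <- ward_tree(dist_matrix(d, "euclidean"))

  lw_heights <- local({
    d2m <- d^2
    active <- as.list(1:4)
    sizes <- rep(1, 4)
    heights <- numeric(0)
    dd <- d2m
    idx <- 1:4
    for (step in 1:3) {
      ut <- which(upper.tri(dd), arr.ind = TRUE)
      vals <- dd[upper.tri(dd)]
      best <- ut[which.min(vals), ]
      i <- best[1]; j <- best[2]
      heights <- c(heights, sqrt(dd[i, j]))
      ni <- sizes[i]; nj <- sizes[j]
      newrow <- vapply(seq_along(sizes), function(k) {
        if (k %in% c(i, j)) return(NA_real_)
        nk <- sizes[k]
        ((ni + nk) * dd[i, k] + (nj + nk) * dd[j, k] - nk * dd[i, j]) /
          (ni + nj + nk)
      }, numeric(1))
      keep <- setdiff(seq_along(sizes), c(i, j))
      dd <- rbind(cbind(dd[keep, keep, drop = FALSE], newrow[keep]),
                  c(newrow[keep], 0))
      sizes <- c(sizes[keep], ni + nj)
    }
    heights
  })
  expect_equal(t4$height, lw_heights, tolerance = 1e-10)
  expect_true(all(diff(t4$height) >= -1e-12))
})

test_that("well-separated site clusters are recovered by a k=2 cut", {
  cfg <- default_sim_config()
  cfg$sites <- cfg$sites[cfg$sites$site %in% c("CE", "OIR"), ]
  # make the two sites' allele pools disjoint halves of each locus pool
  for (l in names(cfg$loci)) {
    fr <- cfg$loci[[l]]$freqs[c("CE", "OIR"), , drop = FALSE]
    half <- seq_len(floor(ncol(fr) / 2))
    fr["CE", ] <- 0; fr["CE", half] <- 1 / length(half)
    fr["OIR", ] <- 0
    fr["OIR", -half] <- 1 / (ncol(fr) - length(half))
    cfg$loci[[l]]$freqs <- fr
  }
  sim <- simulate_dataset(cfg, seed = 10)
  d <- genetic_distance_matrix(allele_matrix(sim$genotypes))
  part <- cut_tree(ward_tree(d), 2)
  expect_equal(adjusted_rand_index(part, site_partition(sim$samples)), 1)
})

test_that("tree cutting: singleton/identity edges, refinement, clone heights", {
  sim <- simulate_dataset(default_sim_config(), seed = 2)
  d <- genetic_distance_matrix(allele_matrix(sim$genotypes))
  tr <- ward_tree(d)
  n <- nrow(d)
  expect_equal(length(unique(cut_tree(tr, n))), n)
  expect_equal(length(unique(cut_tree(tr, 1))), 1)
  expect_error(cut_tree(tr, 0), "k must be")
  # nested cuts are refinements
  p3 <- cut_tree(tr, 3); p5 <- cut_tree(tr, 5)
  tab <- table(p5, p3)
  expect_true(all(rowSums(tab > 0) == 1))
  # identical profiles (clones without somatic variants) merge at height 0
  profs <- list(L1 = c(100, 102), L2 = c(200, 200))
  g <- gt_from_list(list(A = profs, B = profs,
                         C = list(L1 = c(110, 112), L2 = c(210, 212))))
  t0 <- ward_tree(genetic_distance_matrix(allele_matrix(g)))
  expect_equal(min(t0$height), 0)
  expect_equal(cut_tree(t0, 2)[["A"]], cut_tree(t0, 2)[["B"]])
})

test_that("ARI: hand value, relabelling invariance, null expectation", {
  p1 <- c(1, 1, 1, 2, 2, 2)
  p2 <- c(1, 1, 2, 2, 2, 2)
  expect_equal(adjusted_rand_index(p1, p2), 0.3243, tolerance = 1e-4)
  expect_equal(adjusted_rand_index(p1, p1), 1)
  # invariant to label permutation of either partition
  relab <- c(2, 2, 2, 1, 1, 1)
  expect_equal(adjusted_rand_index(p1, p2),
               adjusted_rand_index(relab, p2))
  # named partitions aligned by name; mismatched sets error
  a <- stats::setNames(p1, letters[1:6])
  b <- stats::setNames(p2[c(2, 1, 3:6)], letters[c(2, 1, 3:6)])
  expect_equal(adjusted_rand_index(a, b), 0.3243, tolerance = 1e-4)
  expect_error(adjusted_rand_index(a, stats::setNames(p2, letters[2:7])),
               "different sample sets")
  # expectation about 0 under random labelling
  set.seed(99)
  aris <- replicate(1000, adjusted_rand_index(sample(1:3, 40, TRUE),
                                              sample(1:3, 40, TRUE)))
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("Q-matrix reading and hard assignment", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.90 0.10", "0.20 0.80", "0.50 0.50"), f)
  q <- read_q_matrix(f)
  expect_equal(dim(q), c(3, 2))
  expect_equal(rowSums(q), rep(1, 3), ignore_attr = TRUE)
  expect_warning(p <- hard_assignment(q), "tied")
  expect_equal(unname(p), c(1, 2, 1))
  # malformed row
  fbad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.9 0.1", "0.9 x"), fbad)
  expect_error(read_q_matrix(fbad), "malformed")
  # 3-column fixture: partition sizes by hand
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.8 0.1 0.1", "0.1 0.8 0.1", "0.2 0.1 0.7",
               "0.7 0.2 0.1", "0.1 0.2 0.7"), f3)
  p3 <- hard_assignment(read_q_matrix(f3))
  expect_equal(as.integer(table(p3)), c(2L, 1L, 2L))
})

test_that("Evanno delta-K second differences and degenerate input", {
  mk <- function(m) m + c(-1, 1) / sqrt(2)  # two runs, mean m, sd 1
  runs <- list(`1` = mk(-100), `2` = mk(-80), `3` = mk(-75), `4` = mk(-74))
  dk <- evanno_delta_k(runs)
  expect_equal(dk$delta_K, c(NA, 15, 4, NA))
  expect_equal(attr(dk, "best_K"), 2L)
  # linear L(K) -> all interior delta K zero
  lin <- list(`1` = mk(-100), `2` = mk(-90), `3` = mk(-80), `4` = mk(-70))
  expect_equal(evanno_delta_k(lin)$delta_K, c(NA, 0, 0, NA))
  # constant runs at an interior K -> flagged, excluded
  const <- list(`1` = mk(-100), `2` = c(-80, -80), `3` = mk(-75),
                `4` = mk(-74))
  expect_warning(dkc <- evanno_delta_k(const), "zero")
  expect_true(is.na(dkc$delta_K[2]))
  expect_error(evanno_delta_k(list(`1` = mk(1), `3` = mk(2), `4` = mk(3))),
               "consecutive")
})
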