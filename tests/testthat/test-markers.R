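test_that("the threshold grid has 21 percentiles + 18 interior values = 39", {
  set.seed(101)
  expr <- rnbinom(200, mu = 2, size = 1)
  g <- auc_grid(expr, rep(c(TRUE, FALSE), 100))
  expect_length(g$thresholds, 39)
  expect_equal(g$thresholds[1:21],
               unname(quantile(expr, seq(0, 1, by = 0.05), type = 7)))
  even <- g$thresholds[22:39]
  expect_length(even, 18)
  expect_true(all(even > min(expr) & even < max(expr)))
  expect_equal(diff(even), rep((max(expr) - min(expr)) / 19, 17))
  # the two trivial endpoints are appended to the ROC
  expect_true(all(c(0, 1) %in% g$roc_points$fpr))
})

test_that("grid AUC: perfect separation, toy ties, and endpoint degeneracy", {
  g1 <- auc_grid(c(5, 4, 3, 0, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(g1$auc, 1)
  # TM {3,1}, non-TM {2,0}: exact pair-count AUC = (3 of 4 pairs) = 0.75
  expr <- c(3, 1, 2, 0); lab <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(oracle_rank_auc(expr, lab), 0.75)
  expect_lt(abs(auc_grid(expr, lab)$auc - 0.75), 0.02)
  # constant expression: only the trivial endpoints remain informative
  gc <- auc_grid(rep(2, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(gc$auc, 0.5)
  expect_error(auc_grid(1:4, rep(TRUE, 4)), "non-TM")
})

test_that("grid AUC tracks the exact rank AUC and directions are complementary", {
  set.seed(7)
  max_err <- 0
  for (i in 1:40) {
    n <- sample(100:300, 1)
    lab <- seq_len(n) %in% sample(n, n %/% 4)
    expr <- rnbinom(n, mu = 2, size = 1) + ifelse(lab, rpois(n, 1.2), 0)
    g <- auc_grid(expr, lab)
    max_err <- max(max_err, abs(g$auc - oracle_rank_auc(expr, lab)))
    # complementarity on tie-free data
    e2 <- rnorm(n)
    expect_lt(abs(auc_grid(e2, lab)$auc +
                    auc_grid(e2, lab, direction = "negation")$auc - 1), 0.02)
  }
  expect_lte(max_err, 0.02)
})

test_that("XL-mHG: closed-form top-block case and constant input", {
  # all 3 TM at the very top of 8 distinct values, X = 1, L = 8:
  # the minimal tail is 1/C(8,3) and exactly one placement achieves it
  r <- xlmhg_test(8:1, c(TRUE, TRUE, TRUE, rep(FALSE, 5)), X_frac = 0.15, L = 8)
  expect_equal(r$p, 1 / choose(8, 3), tolerance = 1e-12)
  expect_equal(r$mhg_stat, 1 / choose(8, 3), tolerance = 1e-12)
  rc <- xlmhg_test(rep(1, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(rc$p, 1)
  expect_equal(rc$mhg_stat, 1)
  expect_error(xlmhg_test(1:4, rep(FALSE, 4)), "K")
})

test_that("XL-mHG exact p matches brute-force enumeration on small mixed configs", {
  set.seed(55)
  for (i in 1:25) {
    N <- sample(5:9, 1)
    K <- sample(seq_len(N - 1), 1)
    expr <- sample(c(rnorm(N - 2), rep(0.5, 2)))  # inject ties
    lab <- seq_len(N) %in% sample(N, K)
    X_frac <- sample(c(0.15, 0.5), 1)
    L <- sample(c(max(1, floor(0.35 * N)), N), 1)
    got <- xlmhg_test(expr, lab, X_frac = X_frac, L = L)
    X <- ceiling(X_frac * K)
    expect_equal(got$mhg_stat, oracle_xlmhg_stat(expr, lab, X, L), tolerance = 1e-12)
    expect_equal(got$p, oracle_xlmhg_p(expr, lab, X, L), tolerance = 1e-12)
  }
})

test_that("XL-mHG p decreases as the planted effect grows", {
  set.seed(66)
  n <- 400
  lab <- seq_len(n) %in% sample(n, 60)
  noise <- rnbinom(n, mu = 2, size = 2)
  ps <- vapply(c(0, 0.5, 1, 2, 3), function(effect) {
    expr <- noise + ifelse(lab, rpois(n, effect), 0)
    xlmhg_test(expr, lab)$p
  }, 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("the selected cutoff_val reproduces the minimizing top-n set", {
  set.seed(77)
  n <- 300
  lab <- seq_len(n) %in% sample(n, 50)
  expr <- rnorm(n, mean = ifelse(lab, 1, 0))
  r <- xlmhg_test(expr, lab)
  expect_identical(sum(expr > r$cutoff_val), r$cutoff_rank)
  # negation on non-negative expression: the |threshold| selects the bottom-n set
  expr2 <- rnorm(n, mean = ifelse(lab, 9, 10))
  rn <- xlmhg_test(expr2, lab, direction = "negation")
  expect_identical(sum(expr2 < rn$cutoff_val), rn$cutoff_rank)
})

test_that("BH adjustment: hand-computed values, bounds, order invariance", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(2)
  p <- runif(50)
  o <- sample(50)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("consensus ranking filters by support, drops exclusions, sorts by mean AUC", {
  mk <- function(qA, qB, qC, qX) tibble::tibble(
    gene = c("A", "B", "C", "CD8A"), direction = "positive",
    q = c(qA, qB, qC, qX), auc = c(0.70, 0.77, 0.9, 0.99)
  )
  results <- list(
    s1 = mk(0.01, 0.01, 0.01, 0.001), s2 = mk(0.01, 0.01, 0.01, 0.001),
    s3 = mk(0.01, 0.01, 0.01, 0.001), s4 = mk(0.01, 0.01, 0.2, 0.001),
    s5 = mk(0.01, 0.2, 0.2, 0.001), s6 = mk(0.2, 0.2, 0.2, 0.001)
  )
  # support: A = 5, B = 4, C = 3, CD8A = 6 (excluded)
  cr <- consensus_rank(results, min_samples = 4)
  expect_setequal(cr$gene, c("A", "B"))
  expect_identical(cr$gene[1], "B")  # mean AUC 0.77 ranks above 0.70
  expect_false("CD8A" %in% cr$gene)
  expect_warning(consensus_rank(results, min_samples = 7), "no marker")
})

test_that("hypergeometric overlap test matches direct combinatorics", {
  # universe 10, |A| = |B| = 5, overlap 5: P = 1 / C(10,5) = 1/252
  r <- overlap_test(letters[1:5], letters[1:5], universe = 10)
  expect_equal(r$p, 1 / choose(10, 5), tolerance = 1e-12)
  # tiny disjoint sets in a large universe: p ~ 1 is impossible to beat
  r2 <- overlap_test(c("a", "b"), c("c", "d"), universe = 1000)
  expect_gt(r2$p, 0.99)
  # |A| = universe forces the overlap
  r3 <- overlap_test(letters[1:6], letters[2:4], universe = 6)
  expect_equal(r3$p, 1)
  expect_error(overlap_test(letters[1:8], letters[1:2], universe = 6), "universe")
})

test_that("AUC similarity: diagonal identity, determinism, strata split", {
  set.seed(4)
  auc <- tibble::tibble(gene = sprintf("g%02d", 1:20), direction = "positive",
                        auc = runif(20, 0.3, 0.9))
  tables <- list(s1 = auc, s2 = auc, s3 = auc, s4 = auc)
  patients <- c(s1 = "P1", s2 = "P1", s3 = "P2", s4 = "P3")
  sim <- auc_similarity(tables, patients)
  expect_equal(sim$r, c(1, 1))  # identical AUC vectors: R = 1 despite swaps
  expect_setequal(sim$stratum, c("within-patient", "between-patient"))
  # within-patient stratum has exactly the (s1, s2) pair = 20 points
  expect_identical(sim$n_points[sim$stratum == "within-patient"], 20L)
  sim2 <- auc_similarity(tables, patients)
  expect_identical(attr(sim, "points"), attr(sim2, "points"))  # seed 27 default
  # independent AUC vectors decorrelate
  set.seed(9)
  tabs <- purrr::map(1:4, ~dplyr::mutate(auc, auc = runif(20, 0.3, 0.9)))
  names(tabs) <- names(patients)
  sim3 <- auc_similarity(tabs, patients, seed = 27)
  expect_true(all(abs(sim3$r) < 0.5))
  expect_error(auc_similarity(purrr::map(tabs, ~.x[1:2, ]), patients), "3 genes")
})

test_that("rank_markers returns one row per gene and direction with q-values", {
  s <- simulate_paired_sample(sim_config(n_blood = 300, n_tumor = 200, n_genes = 20,
                                         seed = 12))
  b <- normalize_log_tp10k(s$bundle)
  truth <- s$truth$cells
  blood <- truth[truth$compartment == "blood" & truth$paired_chain, ]
  tm <- setNames(blood$is_tm, blood$barcode)
  res <- rank_markers(b, tm, genes = c("MKPOS1", "MKNEG1", "G00001"))
  expect_identical(nrow(res), 6L)
  expect_true(all(res$q >= res$p))
  expect_lt(res$q[res$gene == "MKPOS1" & res$direction == "positive"], 0.05)
  expect_lt(res$q[res$gene == "MKNEG1" & res$direction == "negation"], 0.05)
  expect_gt(min(res$auc[res$gene == "MKPOS1"]), 0)
})
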