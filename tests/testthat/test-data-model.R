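test_that("MTX round-trip preserves the matrix and orderings", {
  set.seed(11)
  counts <- matrix(rpois(60, 1), nrow = 6,
                   dimnames = list(paste0("G", 1:6), paste0("c", 1:10)))
  b <- toy_bundle(counts)
  dir <- withr::local_tempdir()
  write_sample_files(b, dir)
  b2 <- load_sample(file.path(dir, "matrix.mtx"), file.path(dir, "features.tsv"),
                    file.path(dir, "barcodes.tsv"), file.path(dir, "cell_meta.tsv"),
                    min_features = 0, min_cells_per_gene = 0)
  expect_identical(as.matrix(b2$counts), as.matrix(b$counts))
  expect_identical(rownames(b2$counts), rownames(b$counts))
  expect_identical(colnames(b2$counts), colnames(b$counts))
})

test_that("load_sample applies structural filters and flags bad inputs", {
  counts <- matrix(0L, nrow = 4, ncol = 3,
                   dimnames = list(paste0("G", 1:4), paste0("c", 1:3)))
  counts[1:3, 1] <- 1L  # cell 1 expresses 3 genes
  counts[1:2, 2] <- 1L  # cell 2 expresses 2 genes
  counts[1, 3] <- 1L    # cell 3 expresses 1 gene
  b <- toy_bundle(counts)
  dir <- withr::local_tempdir()
  write_sample_files(b, dir)

  loaded <- load_sample(file.path(dir, "matrix.mtx"), file.path(dir, "features.tsv"),
                        file.path(dir, "barcodes.tsv"),
                        min_features = 3, min_cells_per_gene = 0)
  expect_identical(colnames(loaded$counts), "c1")
  expect_identical(loaded$qc_log$cells_dropped_min_features, 2L)

  # features file shorter than the declared gene dimension -> format error
  writeLines(paste0("G", 1:3), file.path(dir, "features.tsv"))
  expect_error(
    load_sample(file.path(dir, "matrix.mtx"), file.path(dir, "features.tsv"),
                file.path(dir, "barcodes.tsv")),
    class = "tmcell_format_error"
  )
  writeLines(paste0("G", 1:4), file.path(dir, "features.tsv"))
  writeLines(c("c1", "c1", "c3"), file.path(dir, "barcodes.tsv"))
  expect_error(
    load_sample(file.path(dir, "matrix.mtx"), file.path(dir, "features.tsv"),
                file.path(dir, "barcodes.tsv")),
    class = "tmcell_input_error"
  )
})

test_that("log TP10K normalization matches the closed form and back-sums to 10000", {
  counts <- matrix(c(1, 9999, 0,
                     5, 1995, 0,
                     2, 3, 5), nrow = 3, byrow = TRUE,
                   dimnames = list(c("A", "B", "C"), c("c1", "c2", "c3")))
  # column totals: c1 = 8, ... construct targeted cells instead:
  counts <- matrix(0, 3, 3, dimnames = dimnames(counts))
  counts["A", "c1"] <- 1; counts["B", "c1"] <- 9999            # total 10000
  counts["A", "c2"] <- 5; counts["B", "c2"] <- 1995            # total 2000
  counts["A", "c3"] <- 2; counts["B", "c3"] <- 3; counts["C", "c3"] <- 5
  b <- normalize_log_tp10k(toy_bundle(counts))
  expect_equal(b$normalized["A", "c1"], log(2), tolerance = 1e-12)
  expect_equal(b$normalized["C", "c1"], 0)
  expect_equal(b$normalized["A", "c2"], log(26), tolerance = 1e-12)
  # sum over genes of exp(x) - 1 recovers 10000 per cell
  back <- Matrix::colSums(exp(as.matrix(b$normalized)) - 1)
  expect_equal(unname(back), rep(10000, 3), tolerance = 1e-6)
  # raw counts untouched
  expect_identical(as.matrix(b$counts), counts)

  empty <- toy_bundle(matrix(c(1, 0, 0, 0), 2, 2,
                             dimnames = list(c("A", "B"), c("c1", "c2"))))
  expect_error(normalize_log_tp10k(empty), "QC")
})

test_that("scaling yields per-gene zero mean / unit variance, zero-variance genes zeroed", {
  set.seed(21)
  counts <- matrix(rpois(400, 3), nrow = 8,
                   dimnames = list(paste0("G", 1:8), paste0("c", 1:50)))
  counts[8, ] <- 0  # zero-variance gene
  b <- scale_genes(normalize_log_tp10k(toy_bundle(counts)))
  mus <- rowMeans(b$scaled)
  vars <- apply(b$scaled, 1, stats::var)
  expect_true(all(abs(mus) < 1e-8))
  expect_true(all(abs(vars[1:7] - 1) < 1e-6))
  expect_true(all(b$scaled[8, ] == 0))
})

test_that("housekeeping rule requires expression of more than half the list", {
  hk <- paste0("HK", 1:10)
  counts <- matrix(0, nrow = 12, ncol = 2,
                   dimnames = list(c(hk, "X1", "X2"), c("pass6", "fail5")))
  counts[hk[1:6], "pass6"] <- 1
  counts[hk[1:5], "fail5"] <- 1
  counts["X1", ] <- 5  # keep totals nonzero
  b <- qc_filter_cells(toy_bundle(counts), qc_params(housekeeping_genes = hk))
  expect_identical(colnames(b$counts), "pass6")
  expect_identical(b$qc_log$qc_removed$housekeeping, 1L)
})

test_that("mitochondrial rules: human cap at 500 genes, mouse one-sided SD rule", {
  mito <- paste0("MT", 1:600)
  counts <- matrix(0, nrow = 601, ncol = 2,
                   dimnames = list(c(mito, "X"), c("hi", "lo")))
  counts[mito[1:501], "hi"] <- 1
  counts[mito[1:499], "lo"] <- 1
  counts["X", ] <- 1
  b <- qc_filter_cells(toy_bundle(counts),
                       qc_params(mito_genes = mito, human_mito_cap = 500))
  expect_identical(colnames(b$counts), "lo")

  # mouse: all cells with identical mito load (SD = 0) are all retained
  counts2 <- matrix(1, nrow = 5, ncol = 4,
                    dimnames = list(paste0("Mt", 1:5), paste0("c", 1:4)))
  bm <- qc_filter_cells(toy_bundle(counts2, species = "mouse"),
                        qc_params(mito_genes = paste0("Mt", 1:5)))
  expect_identical(ncol(bm$counts), 4L)

  # mouse: a clear high outlier is removed, the rest kept
  counts3 <- matrix(0, nrow = 100, ncol = 12,
                    dimnames = list(paste0("Mt", 1:100), paste0("c", 1:12)))
  for (i in 1:11) counts3[1:sample(8:12, 1), i] <- 1
  counts3[, 12] <- 1
  bm3 <- qc_filter_cells(toy_bundle(counts3, species = "mouse"),
                         qc_params(mito_genes = paste0("Mt", 1:100)))
  expect_false("c12" %in% colnames(bm3$counts))
  expect_true(all(paste0("c", 1:11) %in% colnames(bm3$counts)))
})

test_that("qc_filter_cells is idempotent for the human rules", {
  set.seed(5)
  hk <- paste0("HK", 1:10)
  mito <- paste0("MT", 1:40)
  counts <- matrix(rbinom(60 * 30, 1, 0.5), nrow = 60,
                   dimnames = list(c(hk, mito, paste0("X", 1:10)), paste0("c", 1:30)))
  prm <- qc_params(housekeeping_genes = hk, mito_genes = mito, human_mito_cap = 25)
  once <- qc_filter_cells(toy_bundle(counts), prm)
  twice <- qc_filter_cells(once, prm)
  expect_identical(colnames(twice$counts), colnames(once$counts))
})

test_that("human cluster retention follows rules (a)+(b) and (a)+(c)", {
  make_cluster <- function(n, props) {
    genes <- c("CD3E", "CD3D", "CD3G", "CD8A", "CD8B", "FOXP3", "CD4", "MKI67", "X")
    m <- matrix(0, length(genes), n, dimnames = list(genes, NULL))
    for (g in names(props)) {
      k <- round(props[[g]] * n)
      if (k > 0) m[g, seq_len(k)] <- 1
    }
    m["X", ] <- 1
    m
  }
  n <- 100
  # kept via (b): 35% of cells co-express >=2 CD3 genes, CD8B 40%, FOXP3 2%, CD4 1%
  kept_b <- make_cluster(n, list(CD3E = 0.35, CD3D = 0.35, CD8B = 0.40,
                                 FOXP3 = 0.02, CD4 = 0.01))
  # kept via (c): proliferating, MKI67 75%, CD8A 25%, CD3 rule satisfied
  kept_c <- make_cluster(n, list(CD3E = 0.40, CD3D = 0.40, MKI67 = 0.75,
                                 CD8A = 0.25, FOXP3 = 0.10, CD4 = 0.10))
  # dropped: CD3 rule fails
  dropped <- make_cluster(n, list(CD3E = 0.10, CD8B = 0.90))
  counts <- cbind(kept_b, kept_c, dropped)
  colnames(counts) <- paste0("c", seq_len(3 * n))
  meta <- tibble::tibble(barcode = colnames(counts),
                         cluster = rep(c("b", "c", "drop"), each = n))
  out <- select_cd8_clusters(toy_bundle(counts, meta = meta))
  expect_setequal(out$qc_log$clusters$kept, c("b", "c"))
  expect_identical(out$qc_log$clusters$dropped, "drop")
})

test_that("mouse cluster with 10% Cd3e+ cells is dropped", {
  genes <- c("Cd3e", "Cd3d", "Cd3g", "Cd8a", "Foxp3", "X")
  m <- matrix(0, length(genes), 50, dimnames = list(genes, paste0("c", 1:50)))
  m["Cd3e", 1:5] <- 1
  m["Cd8a", 1:40] <- 1
  m["X", ] <- 1
  meta <- tibble::tibble(barcode = colnames(m), cluster = "k0")
  out <- select_cd8_clusters(toy_bundle(m, species = "mouse", meta = meta))
  expect_identical(out$qc_log$clusters$kept, character(0))
  expect_identical(ncol(out$counts), 0L)
})

test_that("positivity calls use strict thresholds", {
  counts <- matrix(c(0, 1, 3, 0, 0, 0), nrow = 2, byrow = TRUE,
                   dimnames = list(c("PDCD1", "ZERO"), c("c1", "c2", "c3")))
  b <- toy_bundle(counts)
  expect_identical(unname(call_positive(b, "PDCD1", 0)), c(FALSE, TRUE, TRUE))
  expect_identical(unname(call_positive(b, "PDCD1", 2)), c(FALSE, FALSE, TRUE))
  expect_identical(unname(call_positive(b, "ZERO", 0)), rep(FALSE, 3))
  expect_error(call_positive(b, "MISSING"), "not found")
})
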