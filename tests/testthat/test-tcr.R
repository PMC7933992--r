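test_that("clonotype keys are full chain sets; unpaired cells are excluded", {
  chains <- chain_tbl(
    list("A", "TRA", "CAXF"), list("A", "TRB", "CBXF"),
    list("B", "TRB", "CBXF"), list("B", "TRA", "CAXF"),
    list("C", "TRA", "CAXF"), list("C", "TRA", "CA2F"), list("C", "TRB", "CBXF"),
    list("D", "TRA", "CAXF"),
    list("E", "TRA", "CAXF"), list("E", "TRA", "CAXF"), list("E", "TRB", "CBXF")
  )
  cl <- assign_clonotypes(chains)
  key <- function(bc) cl$clone_key[cl$barcode == bc]
  expect_identical(key("A"), key("B"))        # same chain set, order-independent
  expect_false(identical(key("A"), key("C"))) # extra alpha chain -> new clone
  expect_true(is.na(key("D")))                # alpha only -> excluded
  expect_identical(key("E"), key("A"))        # duplicate chain deduplicated
})

test_that("non-productive chains are dropped from keys by default", {
  chains <- chain_tbl(
    list("A", "TRA", "CAXF"), list("A", "TRB", "CBXF"),
    list("B", "TRA", "CAXF"), list("B", "TRB", "CBXF"), list("B", "TRB", "CNPF")
  )
  chains$productive[5] <- FALSE
  cl <- assign_clonotypes(chains)
  expect_identical(cl$clone_key[cl$barcode == "A"], cl$clone_key[cl$barcode == "B"])
  cl2 <- assign_clonotypes(chains, include_nonproductive = TRUE)
  expect_false(identical(cl2$clone_key[cl2$barcode == "A"],
                         cl2$clone_key[cl2$barcode == "B"]))
})

test_that("clone assignment is invariant to record and cell order", {
  set.seed(31)
  chains <- chain_tbl(
    list("A", "TRA", "CAXF"), list("A", "TRB", "CBXF"),
    list("B", "TRA", "CAYF"), list("B", "TRB", "CBYF"),
    list("C", "TRA", "CAXF"), list("C", "TRB", "CBXF")
  )
  base <- assign_clonotypes(chains)
  for (i in 1:5) {
    shuf <- assign_clonotypes(chains[sample.int(nrow(chains)), ])
    shuf <- shuf[match(base$barcode, shuf$barcode), ]
    expect_identical(shuf$clone_key, base$clone_key)
  }
})

test_that("blood/tumor matching labels follow exact key identity", {
  mk <- function(bcs, keys) tibble::tibble(barcode = bcs, clone_key = keys)
  blood <- mk(paste0("b", 1:4), c("k1", "k1", "k1", "k2"))
  tumor <- mk(paste0("t", 1:7), c(rep("k2", 5), "k3", "k3"))
  lab <- label_matching(blood, tumor)
  expect_identical(sum(lab$label == "TM"), 1L)              # one blood cell in k2
  expect_identical(sum(lab$label == "blood-matching"), 5L)  # five tumor cells in k2
  expect_identical(sum(lab$label == "non-TM"), 3L)
  # disjoint clone sets -> zero TM
  lab2 <- label_matching(mk("b1", "ka"), mk("t1", "kb"))
  expect_identical(sum(lab2$label == "TM"), 0L)
  # excluded cells carry their own label
  lab3 <- label_matching(mk(c("b1", "b2"), c("k1", NA)), mk("t1", "k1"))
  expect_identical(lab3$label[lab3$barcode == "b2"], "excluded-no-paired-chains")
})

test_that("matching symmetry: distinct TM keys equal distinct blood-matching keys", {
  for (seed in 1:3) {
    s <- simulate_paired_sample(sim_config(n_blood = 400, n_tumor = 300,
                                           n_genes = 20, markers = NULL,
                                           seed = seed))
    cl <- assign_clonotypes(s$bundle$tcr)
    comp <- s$bundle$cell_meta$compartment[match(cl$barcode, s$bundle$cell_meta$barcode)]
    lab <- label_matching(cl[comp == "blood", ], cl[comp == "tumor", ])
    tm_keys <- unique(lab$clone_key[lab$label == "TM"])
    bm_keys <- unique(lab$clone_key[lab$label == "blood-matching"])
    expect_setequal(tm_keys, bm_keys)
  }
})

test_that("consensus matching keeps agreements and excludes conflicts", {
  calls <- tibble::tibble(barcode = c("a", "b", "c", "d"),
                          tm_a = c(TRUE, FALSE, TRUE, FALSE),
                          tm_b = c(TRUE, FALSE, FALSE, TRUE))
  out <- consensus_cluster_matching(calls)
  expect_identical(out$label, c("TM", "non-TM", "conflicted", "conflicted"))
  expect_identical(unname(attr(out, "counts")["conflicted"]), 2L)
  agree <- consensus_cluster_matching(calls[1:2, ])
  expect_identical(unname(attr(agree, "counts")["conflicted"]), 0L)
  expect_error(consensus_cluster_matching(tm_a = c(a = TRUE), tm_b = c(b = TRUE)),
               "same cells")
})

test_that("clone sizes, expansion values and log-scale correlation", {
  cl <- tibble::tibble(
    barcode = paste0("c", 1:4),
    clone_key = c("k1", "k1", "k1", "k2"),
    clone_id = c(1L, 1L, 1L, 2L)
  )
  sizes <- clone_size_table(cl)
  expect_identical(sizes$size[sizes$clone_key == "k1"], 3L)
  cells <- attr(sizes, "cells")
  expect_identical(cells$expansion[match(paste0("c", 1:4), cells$barcode)],
                   c(3L, 3L, 3L, 1L))
  # toy blood/tumor sizes (k1: 4 vs 8, k2: 1 vs 2, k3: 2 vs 3): monotone -> rho 1
  blood <- tibble::tibble(clone_key = c("k1", "k2", "k3"), size = c(4L, 1L, 2L))
  tumor <- tibble::tibble(clone_key = c("k1", "k2", "k3"), size = c(8L, 2L, 3L))
  expect_equal(clone_size_correlation(blood, tumor)$rho, 1)
})

test_that("pseudobulk sums clone members and applies the CPM floor", {
  counts <- matrix(c(1, 0, 4,
                     2, 5, 0,
                     0, 0, 1), nrow = 3, byrow = TRUE,
                   dimnames = list(c("gA", "gB", "gC"), c("c1", "c2", "c3")))
  b <- toy_bundle(counts)
  labels <- tibble::tibble(barcode = c("c1", "c2", "c3"),
                           clone_key = c("k1", "k1", "k2"),
                           label = c("TM", "TM", "TM"))
  pb <- pseudobulk_by_clone(b, labels, class = "TM", cpm_min = 0)
  expect_equal(unlist(pb[pb$clone_key == "k1", c("gA", "gB", "gC")]),
               c(gA = 1, gB = 7, gC = 0))
  expect_equal(unlist(pb[pb$clone_key == "k2", c("gA", "gB", "gC")]),
               c(gA = 4, gB = 0, gC = 1))
  # aggregate totals 13 counts; a floor above gC's 1/13 share drops gC only
  pb2 <- pseudobulk_by_clone(b, labels, class = "TM",
                             cpm_min = 1e6 * 1.5 / 13)
  expect_setequal(setdiff(names(pb2), "clone_key"), c("gA", "gB"))
  expect_warning(pseudobulk_by_clone(b, labels, class = "missing"), "no cells")
})

test_that("contig CSV round-trip through read_contigs", {
  s <- simulate_paired_sample(sim_config(n_blood = 50, n_tumor = 40, n_genes = 10,
                                         markers = NULL, seed = 7))
  dir <- withr::local_tempdir()
  write_sample_files(s$bundle, dir)
  chains <- read_contigs(file.path(dir, "contigs.csv"))
  expect_true(all(c("barcode", "chain", "cdr3", "productive") %in% names(chains)))
  expect_type(chains$productive, "logical")
  cl1 <- assign_clonotypes(s$bundle$tcr)
  cl2 <- assign_clonotypes(chains)
  cl2 <- cl2[match(cl1$barcode, cl2$barcode), ]
  expect_identical(cl1$clone_key, cl2$clone_key)
})
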