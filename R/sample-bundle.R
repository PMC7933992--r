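#' Construct a per-sample single-cell bundle
#'
#' A `tm_bundle` holds one sample's genes-by-cells UMI count matrix together
#' with optional derived layers (log TP10K `normalized`, per-gene centered and
#' unit-variance `scaled`), per-cell metadata, and optional TCR chain records.
#' Blood and tumor cells of one subject live in the same bundle, distinguished
#' by the `compartment` column of `cell_meta`.
#'
#' @param counts genes x cells matrix of non-negative integer UMI counts
#'   (dense or `Matrix` sparse). Row names are gene symbols, column names cell
#'   barcodes.
#' @param cell_meta data frame keyed by `barcode`, one row per cell. Extra
#'   columns (`patient_id`, `compartment`, `cluster`, ...) are preserved.
#' @param species `"human"` or `"mouse"`; drives QC and cluster-retention
#'   defaults.
#' @param sample_id label for this sample.
#' @param tcr optional tibble of TCR chain records (see [assign_clonotypes()]).
#' @return An object of class `tm_bundle`.
#' @export
sample_bundle <- function(counts, cell_meta = NULL, species = c("human", "mouse"),
                          sample_id = "sample", tcr = NULL) {
  species <- match.arg(species)
  if (!methods::is(counts, "CsparseMatrix")) {
    counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  }
  counts <- methods::as(counts, "dMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_input("counts must carry gene row names and barcode column names")
  }
  if (anyDuplicated(colnames(counts))) {
    stop_input("duplicate cell barcodes in counts matrix")
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop_input("counts must be non-negative integers")
  }
  if (is.null(cell_meta)) {
    cell_meta <- tibble::tibble(barcode = colnames(counts))
  }
  cell_meta <- tibble::as_tibble(cell_meta)
  if (!"barcode" %in% names(cell_meta)) stop_input("cell_meta must have a 'barcode' column")
  if (anyDuplicated(cell_meta$barcode)) stop_input("duplicate barcodes in cell_meta")
  if (!setequal(cell_meta$barcode, colnames(counts))) {
    stop_input("cell_meta barcodes do not match counts column names")
  }
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$barcode), ]
  structure(
    list(sample_id = sample_id, species = species, counts = counts,
         normalized = NULL, scaled = NULL, cell_meta = cell_meta,
         tcr = tcr, qc_log = list()),
    class = "tm_bundle"
  )
}

#' @export
print.tm_bundle <- function(x, ...) {
  cat("<tm_bundle> ", x$sample_id, " (", x$species, "): ",
      nrow(x$counts), " genes x ", ncol(x$counts), " cells\n", sep = "")
  if ("compartment" %in% names(x$cell_meta)) {
    print(table(x$cell_meta$compartment))
  }
  layers <- c("normalized", "scaled")[!vapply(x[c("normalized", "scaled")], is.null, TRUE)]
  if (length(layers)) cat("layers:", paste(layers, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.tm_bundle <- function(x) dim(x$counts)

#' Gene symbols of a bundle
#' @param bundle a `tm_bundle`.
#' @return Character vector of gene symbols in matrix order.
#' @export
gene_ids <- function(bundle) rownames(bundle$counts)

subset_cells <- function(bundle, keep) {
  bundle$counts <- bundle$counts[, keep, drop = FALSE]
  if (!is.null(bundle$normalized)) bundle$normalized <- bundle$normalized[, keep, drop = FALSE]
  if (!is.null(bundle$scaled)) bundle$scaled <- bundle$scaled[, keep, drop = FALSE]
  bundle$cell_meta <- bundle$cell_meta[match(colnames(bundle$counts), bundle$cell_meta$barcode), ]
  bundle
}

read_tsv_column <- function(path, col = 1L) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE, progress = FALSE)
  as.character(x[[min(col, ncol(x))]])
}

#' Load a sample from 10x-style MTX + TSV files
#'
#' Reads a MatrixMarket count matrix with companion features/barcodes files
#' (optionally gzipped) and per-cell metadata, then applies the two structural
#' filters used when the count object is created: genes must be expressed in
#' at least `min_cells_per_gene` cells, and cells must express at least
#' `min_features` genes. Drop counts are recorded in the bundle's `qc_log`.
#'
#' @param counts_path MatrixMarket `.mtx` file.
#' @param features_path features TSV; the gene symbol is taken from the second
#'   column when present (10x convention), else the first.
#' @param barcodes_path barcodes TSV, one barcode per line.
#' @param meta_path optional cell metadata TSV with header containing at least
#'   `barcode`; typically also `patient_id`, `compartment`, `cluster`.
#' @param sample_id,species forwarded to [sample_bundle()].
#' @param min_features minimum expressed genes per retained cell (default 400).
#' @param min_cells_per_gene minimum expressing cells per retained gene
#'   (default 3).
#' @param genes_as_rows set `FALSE` if the MTX stores cells as rows.
#' @return A `tm_bundle` with raw counts only.
#' @export
load_sample <- function(counts_path, features_path, barcodes_path,
                        meta_path = NULL, sample_id = "sample",
                        species = c("human", "mouse"),
                        min_features = 400, min_cells_per_gene = 3,
                        genes_as_rows = TRUE) {
  for (p in c(counts_path, features_path, barcodes_path, meta_path)) {
    if (!is.null(p) && !file.exists(p)) stop_input("file not found: ", p)
  }
  m <- Matrix::readMM(counts_path)
  if (!genes_as_rows) m <- Matrix::t(m)
  features <- read_tsv_column(features_path, col = 2L)
  barcodes <- read_tsv_column(barcodes_path, col = 1L)
  if (nrow(m) != length(features)) {
    stop_format(counts_path, " declares ", nrow(m), " genes but ",
                features_path, " lists ", length(features))
  }
  if (ncol(m) != length(barcodes)) {
    stop_format(counts_path, " declares ", ncol(m), " cells but ",
                barcodes_path, " lists ", length(barcodes))
  }
  if (anyDuplicated(barcodes)) stop_input("duplicate barcodes in ", barcodes_path)
  rownames(m) <- make.unique(features)
  colnames(m) <- barcodes
  meta <- if (!is.null(meta_path)) {
    readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  } else NULL
  if (!is.null(meta)) meta <- meta[meta$barcode %in% barcodes, ]

  n_expr_cells <- Matrix::rowSums(m > 0)
  keep_genes <- n_expr_cells >= min_cells_per_gene
  n_expr_genes <- Matrix::colSums(m > 0)
  keep_cells <- n_expr_genes >= min_features
  m <- m[keep_genes, keep_cells, drop = FALSE]
  if (!is.null(meta)) meta <- meta[meta$barcode %in% colnames(m), ]
  b <- sample_bundle(m, meta, species = match.arg(species), sample_id = sample_id)
  b$qc_log$genes_dropped_min_cells <- sum(!keep_genes)
  b$qc_log$cells_dropped_min_features <- sum(!keep_cells)
  b
}

#' Write a bundle back to MTX/TSV (and optional contig CSV) files
#'
#' Emits the exact input dialect consumed by [load_sample()] and
#' [read_contigs()]; used by the synthetic generator and for round-trip tests.
#'
#' @param bundle a `tm_bundle`.
#' @param dir output directory (created if needed).
#' @param chains optional TCR chain tibble written as `contigs.csv`.
#' @return `dir`, invisibly.
#' @export
write_sample_files <- function(bundle, dir, chains = bundle$tcr) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(bundle$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(bundle$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(bundle$counts), file.path(dir, "barcodes.tsv"))
  readr::write_tsv(bundle$cell_meta, file.path(dir, "cell_meta.tsv"), progress = FALSE)
  if (!is.null(chains)) {
    out <- tibble::tibble(
      barcode = chains$barcode, is_cell = "True", high_confidence = "True",
      chain = chains$chain,
      v_gene = chains[["v_gene"]] %||% "", j_gene = chains[["j_gene"]] %||% "",
      cdr3 = chains$cdr3, cdr3_nt = chains[["cdr3_nt"]] %||% "",
      productive = ifelse(chains[["productive"]] %||% TRUE, "True", "False"),
      raw_clonotype_id = chains[["raw_clonotype_id"]] %||% ""
    )
    readr::write_csv(out, file.path(dir, "contigs.csv"), progress = FALSE)
  }
  invisible(dir)
}

#' Log TP10K normalization
#'
#' Populates the `normalized` layer with `ln(1 + 10000 * c / total)` where
#' `total` is the cell's UMI sum; the raw counts are left untouched.
#'
#' @param bundle a `tm_bundle` with counts.
#' @return The bundle with a `normalized` layer.
#' @export
normalize_log_tp10k <- function(bundle) {
  totals <- Matrix::colSums(bundle$counts)
  if (any(totals == 0)) {
    stop_input(sum(totals == 0), " cell(s) have zero total counts; run QC filtering first")
  }
  norm <- bundle$counts
  # per-entry column totals for the sparse slot vector
  reps <- rep.int(totals, diff(norm@p))
  norm@x <- log1p(norm@x / reps * 1e4)
  bundle$normalized <- norm
  bundle
}

#' Center and scale genes to zero mean / unit variance
#'
#' Computed on the normalized layer over the currently retained cells (run
#' after QC and CD8 cluster selection; merge samples first when scores will be
#' compared across samples). Genes with zero variance become all-zero rows.
#'
#' @param bundle a `tm_bundle` with a normalized layer.
#' @return The bundle with a dense `scaled` layer.
#' @export
scale_genes <- function(bundle) {
  if (is.null(bundle$normalized)) stop_input("normalize_log_tp10k() must be run first")
  x <- as.matrix(bundle$normalized)
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  sc <- (x - mu) / ifelse(s > 0, s, 1)
  sc[s == 0, ] <- 0
  bundle$scaled <- sc
  bundle
}

#' QC parameter block
#'
#' Defaults follow the study design: Seurat-style structural thresholds
#' (400 features, 3 cells), a housekeeping-gene rule (a cell passes if it
#' expresses more than half of the list), and a mitochondrial-gene rule
#' (humans: at most 500 of the 1,158 MitoCarta genes expressed; mice: within
#' two SDs above the across-cell mean count of expressed mitochondrial genes).
#'
#' @param min_features,min_cells_per_gene structural thresholds used at load
#'   time.
#' @param housekeeping_genes,mito_genes character vectors; `NULL` disables the
#'   corresponding rule.
#' @param human_mito_cap maximum number of expressed mitochondrial genes for a
#'   retained human cell.
#' @param mouse_mito_sd SD multiplier for the mouse rule.
#' @return A `tm_qc_params` list.
#' @export
qc_params <- function(min_features = 400, min_cells_per_gene = 3,
                      housekeeping_genes = NULL, mito_genes = NULL,
                      human_mito_cap = 500, mouse_mito_sd = 2) {
  stopifnot(min_features >= 0, min_cells_per_gene >= 0,
            human_mito_cap >= 0, mouse_mito_sd >= 0)
  structure(list(min_features = min_features,
                 min_cells_per_gene = min_cells_per_gene,
                 housekeeping_genes = housekeeping_genes,
                 mito_genes = mito_genes,
                 human_mito_cap = human_mito_cap,
                 mouse_mito_sd = mouse_mito_sd),
            class = "tm_qc_params")
}

#' Filter cells on housekeeping and mitochondrial gene rules
#'
#' A cell passes the housekeeping rule if it expresses (count > 0) strictly
#' more than half of the listed genes. The mitochondrial rule is
#' species-specific: human cells are removed when they express more than
#' `human_mito_cap` of the listed mitochondrial genes; mouse cells when the
#' number of expressed mitochondrial genes exceeds the across-cell mean by
#' more than `mouse_mito_sd` standard deviations (one-sided: only
#' high-mitochondrial cells are flagged as damaged).
#'
#' @param bundle a `tm_bundle`.
#' @param params a [qc_params()] block with the relevant gene lists.
#' @return The filtered bundle; per-rule removal counts are appended to
#'   `qc_log`.
#' @export
qc_filter_cells <- function(bundle, params = qc_params()) {
  if (is.null(bundle$species)) stop_config("bundle species is not set")
  keep <- rep(TRUE, ncol(bundle$counts))
  removed <- list()
  if (!is.null(params$housekeeping_genes)) {
    hk <- params$housekeeping_genes
    if (!length(hk)) stop_config("housekeeping gene list is empty")
    present <- intersect(hk, rownames(bundle$counts))
    n_expr <- if (length(present)) {
      Matrix::colSums(bundle$counts[present, , drop = FALSE] > 0)
    } else rep(0, ncol(bundle$counts))
    pass_hk <- n_expr > length(hk) / 2
    removed$housekeeping <- sum(keep & !pass_hk)
    keep <- keep & pass_hk
  }
  if (!is.null(params$mito_genes)) {
    mt <- intersect(params$mito_genes, rownames(bundle$counts))
    n_mito <- if (length(mt)) {
      Matrix::colSums(bundle$counts[mt, , drop = FALSE] > 0)
    } else rep(0, ncol(bundle$counts))
    pass_mt <- if (bundle$species == "human") {
      n_mito <= params$human_mito_cap
    } else {
      s <- sd(n_mito)
      if (is.na(s) || s == 0) rep(TRUE, length(n_mito))
      else n_mito <= mean(n_mito) + params$mouse_mito_sd * s
    }
    removed$mito <- sum(keep & !pass_mt)
    keep <- keep & pass_mt
  }
  out <- subset_cells(bundle, keep)
  out$qc_log <- c(bundle$qc_log, list(qc_removed = removed))
  out
}

#' Cluster-retention rules for CD8 T cell selection
#'
#' Human clusters are kept when (a) more than 30% of cells express at least
#' two of CD3E/CD3D/CD3G, and either (b) CD8B or CD8A is expressed in more
#' than 30% of cells while FOXP3 and CD4 are each expressed in fewer than 5%,
#' or (c) MKI67 is expressed in more than 70% of cells (proliferating
#' clusters) with CD8A or CD8B in more than 20%. Mouse clusters are kept when
#' more than 30% of cells express any of Cd3e/Cd3d/Cd3g, more than 30%
#' co-express Cd3e and Cd8a, and fewer than 5% express Foxp3.
#'
#' @param species `"human"` or `"mouse"`.
#' @return A `tm_cluster_rules` list of gene names and proportion thresholds.
#' @export
cluster_rules <- function(species = c("human", "mouse")) {
  species <- match.arg(species)
  if (species == "human") {
    structure(list(
      species = "human",
      cd3_genes = c("CD3E", "CD3D", "CD3G"), cd3_min_genes = 2L, cd3_prop = 0.30,
      cd8a = "CD8A", cd8b = "CD8B", cd8_prop = 0.30,
      foxp3 = "FOXP3", cd4 = "CD4", contam_prop = 0.05,
      mki67 = "MKI67", mki67_prop = 0.70, cd8_prop_proliferating = 0.20
    ), class = "tm_cluster_rules")
  } else {
    structure(list(
      species = "mouse",
      cd3_genes = c("Cd3e", "Cd3d", "Cd3g"), cd3_min_genes = 1L, cd3_prop = 0.30,
      cd3e = "Cd3e", cd8a = "Cd8a", cd3e_cd8a_prop = 0.30,
      foxp3 = "Foxp3", contam_prop = 0.05
    ), class = "tm_cluster_rules")
  }
}

prop_expressing <- function(m, genes, min_genes = 1L) {
  present <- intersect(genes, rownames(m))
  if (!length(present)) return(0)
  n <- Matrix::colSums(m[present, , drop = FALSE] > 0)
  mean(n >= min_genes)
}

#' Retain cells in clusters passing the CD8 selection rules
#'
#' @param bundle a `tm_bundle` whose `cell_meta` carries a `cluster` column
#'   (labels computed externally, e.g. by Seurat).
#' @param rules a [cluster_rules()] object; defaults to the bundle's species.
#' @return The bundle restricted to kept clusters; kept/dropped cluster ids
#'   recorded in `qc_log$clusters`.
#' @export
select_cd8_clusters <- function(bundle, rules = cluster_rules(bundle$species)) {
  cl <- bundle$cell_meta$cluster
  if (is.null(cl) || any(is.na(cl))) stop_input("every cell needs a cluster label")
  kept <- character()
  for (k in unique(cl)) {
    m <- bundle$counts[, cl == k, drop = FALSE]
    ok <- if (rules$species == "human") {
      a <- prop_expressing(m, rules$cd3_genes, rules$cd3_min_genes) > rules$cd3_prop
      b <- (prop_expressing(m, rules$cd8b) > rules$cd8_prop ||
              prop_expressing(m, rules$cd8a) > rules$cd8_prop) &&
        prop_expressing(m, rules$foxp3) < rules$contam_prop &&
        prop_expressing(m, rules$cd4) < rules$contam_prop
      cc <- prop_expressing(m, rules$mki67) > rules$mki67_prop &&
        (prop_expressing(m, rules$cd8a) > rules$cd8_prop_proliferating ||
           prop_expressing(m, rules$cd8b) > rules$cd8_prop_proliferating)
      a && (b || cc)
    } else {
      prop_expressing(m, rules$cd3_genes, rules$cd3_min_genes) > rules$cd3_prop &&
        prop_expressing(m, c(rules$cd3e, rules$cd8a), 2L) > rules$cd3e_cd8a_prop &&
        prop_expressing(m, rules$foxp3) < rules$contam_prop
    }
    if (ok) kept <- c(kept, as.character(k))
  }
  out <- subset_cells(bundle, cl %in% kept)
  out$qc_log$clusters <- list(kept = kept,
                              dropped = setdiff(as.character(unique(cl)), kept))
  out
}

#' Call cells positive for a transcript
#'
#' With `threshold = 0` a cell is positive when it has any reads (count > 0),
#' the convention used for PD-1 positivity; with a larger threshold (e.g. a
#' marker-test `cutoff_val`) a cell is positive when its expression strictly
#' exceeds it.
#'
#' @param bundle a `tm_bundle`.
#' @param gene gene symbol.
#' @param threshold expression cutoff (strict `>`).
#' @param layer `"counts"` (default) or `"normalized"`.
#' @return Named logical vector over cells.
#' @export
call_positive <- function(bundle, gene, threshold = 0, layer = c("counts", "normalized")) {
  layer <- match.arg(layer)
  m <- bundle[[layer]]
  if (is.null(m)) stop_input("layer '", layer, "' not populated")
  if (!gene %in% rownames(m)) stop_input("gene not found: ", gene)
  x <- as.numeric(m[gene, ])
  setNames(x > threshold, colnames(m))
}

#' Extract a cells-by-genes tibble from a bundle
#'
#' @param bundle a `tm_bundle`.
#' @param genes gene symbols to extract as columns.
#' @param layer matrix layer to pull values from.
#' @return A tibble with the bundle's `cell_meta` columns followed by one
#'   column per gene.
#' @export
cell_gene_table <- function(bundle, genes, layer = c("counts", "normalized", "scaled")) {
  layer <- match.arg(layer)
  m <- bundle[[layer]]
  if (is.null(m)) stop_input("layer '", layer, "' not populated")
  missing <- setdiff(genes, rownames(m))
  if (length(missing)) stop_input("genes not found: ", paste(missing, collapse = ", "))
  vals <- t(as.matrix(m[genes, , drop = FALSE]))
  dplyr::bind_cols(bundle$cell_meta, tibble::as_tibble(vals))
}

#' Read a gene list from a plain-text or GMT file
#'
#' @param path one symbol per line, or a GMT file (set name, description, then
#'   genes per line); all GMT sets are unioned unless `set` is given.
#' @param set optional GMT set name.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path, set = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (grepl("\\.gmt$", path, ignore.case = TRUE) || any(grepl("\t.*\t", lines))) {
    parts <- strsplit(lines, "\t")
    names(parts) <- vapply(parts, `[[`, "", 1L)
    if (!is.null(set)) parts <- parts[set]
    unique(unlist(lapply(parts, function(p) p[-(1:2)])))
  } else {
    unique(trimws(lines))
  }
}
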