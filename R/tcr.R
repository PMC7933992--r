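#' Read a Cell Ranger-style contig annotation CSV
#'
#' Accepts the `filtered_contig_annotations.csv` dialect; only `barcode`,
#' `chain`, `cdr3` and `productive` are required. `productive` strings
#' ("True"/"TRUE"/"true") are coerced to logical.
#'
#' @param path CSV file.
#' @return A tibble of TCR chain records.
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) stop_input("contig file not found: ", path)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("barcode", "chain", "cdr3")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop_format(path, " lacks required columns: ", paste(missing, collapse = ", "))
  }
  if (!"productive" %in% names(x)) x$productive <- TRUE
  if (!is.logical(x$productive)) {
    x$productive <- tolower(as.character(x$productive)) %in% c("true", "t", "1")
  }
  tibble::as_tibble(x)
}

#' Assign clonotypes from TCR chain records
#'
#' Two cells belong to the same clone when the full sets of their detected
#' alpha and beta CDR3 amino-acid sequences are identical; a cell needs at
#' least one TRA and one TRB chain to receive a clonotype, otherwise it is
#' excluded. Chains are deduplicated within a cell before key construction.
#'
#' @param chains tibble with columns `barcode`, `chain` (TRA/TRB), `cdr3`
#'   and optionally `productive`, `v_gene`, `j_gene`.
#' @param include_nonproductive keep non-productive chains in the key
#'   (default `FALSE`: they do not define antigen specificity).
#' @param use_vj extend the key with V/J gene segments.
#' @return A tibble with one row per cell: `barcode`, `clone_key` (`NA` for
#'   excluded cells), `clone_id` (stable integer within this call), and
#'   `n_tra`/`n_trb` chain counts.
#' @export
assign_clonotypes <- function(chains, include_nonproductive = FALSE, use_vj = FALSE) {
  if (nrow(chains) == 0) {
    warn("empty chain table: no clonotypes assigned")
    return(tibble::tibble(barcode = character(), clone_key = character(),
                          clone_id = integer(), n_tra = integer(), n_trb = integer()))
  }
  if (!all(chains$chain %in% c("TRA", "TRB"))) {
    stop_input("chain values must be TRA or TRB")
  }
  ch <- chains
  if (!include_nonproductive && "productive" %in% names(ch)) {
    ch <- ch[ch$productive, ]
  }
  if (any(!nzchar(ch$cdr3)) || any(is.na(ch$cdr3))) stop_input("empty cdr3 sequence")
  token <- if (use_vj) {
    paste0(ch$chain, ":", ch$v_gene, ":", ch$cdr3, ":", ch$j_gene)
  } else {
    paste0(ch$chain, ":", ch$cdr3)
  }
  per_cell <- tibble::tibble(barcode = ch$barcode, chain = ch$chain, token = token) |>
    dplyr::distinct(.data$barcode, .data$token, .keep_all = TRUE) |>
    dplyr::group_by(.data$barcode) |>
    dplyr::summarise(
      clone_key = paste(sort(.data$token), collapse = ";"),
      n_tra = sum(.data$chain == "TRA"),
      n_trb = sum(.data$chain == "TRB"),
      .groups = "drop"
    )
  paired <- per_cell$n_tra >= 1 & per_cell$n_trb >= 1
  per_cell$clone_key[!paired] <- NA_character_
  keys <- sort(unique(per_cell$clone_key[paired]))
  per_cell$clone_id <- match(per_cell$clone_key, keys)
  # cells seen only without any productive chains still appear, excluded
  all_cells <- unique(chains$barcode)
  out <- dplyr::left_join(tibble::tibble(barcode = all_cells), per_cell, by = "barcode")
  out$n_tra[is.na(out$n_tra)] <- 0L
  out$n_trb[is.na(out$n_trb)] <- 0L
  out
}

#' Label blood cells as tumor-matching (TM) by exact clonotype identity
#'
#' A blood cell is TM when its clone key occurs among tumor cells; a tumor
#' cell is blood-matching when its key occurs in blood. Cells without a
#' paired-chain clonotype are labelled `excluded-no-paired-chains`. When a
#' subject has several tumor resections, pass their clonotype tables unioned
#' (a blood cell matches if it matches any resection).
#'
#' @param blood,tumor clonotype tibbles from [assign_clonotypes()] (columns
#'   `barcode`, `clone_key`).
#' @return A tibble with `barcode`, `compartment`, `clone_key`, `label`
#'   (`TM`, `non-TM`, `blood-matching`, `non-matching`,
#'   `excluded-no-paired-chains`).
#' @export
label_matching <- function(blood, tumor) {
  if (is.null(blood) || is.null(tumor)) stop_input("both compartments are required")
  blood_keys <- unique(blood$clone_key[!is.na(blood$clone_key)])
  tumor_keys <- unique(tumor$clone_key[!is.na(tumor$clone_key)])
  lab_blood <- dplyr::case_when(
    is.na(blood$clone_key) ~ "excluded-no-paired-chains",
    blood$clone_key %in% tumor_keys ~ "TM",
    TRUE ~ "non-TM"
  )
  lab_tumor <- dplyr::case_when(
    is.na(tumor$clone_key) ~ "excluded-no-paired-chains",
    tumor$clone_key %in% blood_keys ~ "blood-matching",
    TRUE ~ "non-matching"
  )
  dplyr::bind_rows(
    tibble::tibble(barcode = blood$barcode, compartment = "blood",
                   clone_key = blood$clone_key, label = lab_blood),
    tibble::tibble(barcode = tumor$barcode, compartment = "tumor",
                   clone_key = tumor$clone_key, label = lab_tumor)
  )
}

#' Consensus TM labels from two TCR-clustering algorithms
#'
#' Blood cells can alternatively be called TM when their TCR falls in a
#' sequence-similarity cluster (e.g. GLIPH2 or iSMART output) containing at
#' least one tumor TCR. Given the two per-cell boolean calls, cells on which
#' the algorithms agree keep the agreed label; disagreements are marked
#' `conflicted` and excluded from downstream statistics.
#'
#' @param calls tibble with columns `barcode`, `tm_a`, `tm_b` (logical), or
#'   two named logical vectors passed as `tm_a`/`tm_b` over identical cells.
#' @param tm_a,tm_b alternative interface: named logical vectors.
#' @return A tibble `barcode`, `label` (`TM`, `non-TM`, `conflicted`), with a
#'   `counts` attribute giving the tally per label.
#' @export
consensus_cluster_matching <- function(calls = NULL, tm_a = NULL, tm_b = NULL) {
  if (is.null(calls)) {
    if (is.null(names(tm_a)) || is.null(names(tm_b)) ||
        !setequal(names(tm_a), names(tm_b))) {
      stop_input("tm_a and tm_b must be named over the same cells")
    }
    tm_b <- tm_b[names(tm_a)]
    calls <- tibble::tibble(barcode = names(tm_a), tm_a = unname(tm_a),
                            tm_b = unname(tm_b))
  }
  if (!all(c("barcode", "tm_a", "tm_b") %in% names(calls))) {
    stop_input("calls needs columns barcode, tm_a, tm_b")
  }
  label <- dplyr::case_when(
    calls$tm_a & calls$tm_b ~ "TM",
    !calls$tm_a & !calls$tm_b ~ "non-TM",
    TRUE ~ "conflicted"
  )
  out <- tibble::tibble(barcode = calls$barcode, label = label)
  attr(out, "counts") <- c(TM = sum(label == "TM"),
                           `non-TM` = sum(label == "non-TM"),
                           conflicted = sum(label == "conflicted"))
  out
}

#' Clone sizes and per-cell clonal expansion
#'
#' @param clonotypes tibble from [assign_clonotypes()]; excluded cells are
#'   ignored.
#' @return A tibble `clone_key`, `size` sorted by decreasing size, with a
#'   per-cell `expansion` tibble (`barcode`, `clone_key`, `expansion`) as the
#'   `cells` attribute.
#' @export
clone_size_table <- function(clonotypes) {
  cl <- clonotypes[!is.na(clonotypes$clone_key), ]
  sizes <- cl |>
    dplyr::count(.data$clone_key, name = "size") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$clone_key)
  cells <- tibble::tibble(
    barcode = cl$barcode, clone_key = cl$clone_key,
    expansion = sizes$size[match(cl$clone_key, sizes$clone_key)]
  )
  attr(sizes, "cells") <- cells
  sizes
}

#' Blood-tumor clonal expansion correlation
#'
#' Spearman correlation of log10 clone sizes across the two compartments,
#' restricted to clones detected in both.
#'
#' @param blood_sizes,tumor_sizes clone-size tibbles from [clone_size_table()].
#' @return A one-row tibble with `rho`, `p`, and `n_clones`.
#' @export
clone_size_correlation <- function(blood_sizes, tumor_sizes) {
  shared <- dplyr::inner_join(blood_sizes, tumor_sizes, by = "clone_key",
                              suffix = c("_blood", "_tumor"))
  if (nrow(shared) < 3) stop_input("need at least 3 shared clones")
  ct <- suppressWarnings(cor.test(log10(shared$size_blood), log10(shared$size_tumor),
                                  method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n_clones = nrow(shared))
}

#' Clone-collapsed pseudobulk counts
#'
#' Sums raw counts over the member cells of each clone for a chosen label
#' class, then drops genes below a counts-per-million floor in the aggregate
#' (pre-filter for downstream differential-expression tools).
#'
#' @param bundle a `tm_bundle` with raw counts.
#' @param labels tibble from [label_matching()] (columns `barcode`,
#'   `clone_key`, `label`).
#' @param class label class to aggregate (e.g. `"TM"` or `"blood-matching"`).
#' @param cpm_min minimum aggregate counts-per-million for a retained gene.
#' @return A tibble with `clone_key` and one column per retained gene.
#' @export
pseudobulk_by_clone <- function(bundle, labels, class = "TM", cpm_min = 1) {
  sel <- labels[labels$label == class & !is.na(labels$clone_key), ]
  sel <- sel[sel$barcode %in% colnames(bundle$counts), ]
  if (nrow(sel) == 0) {
    warn(paste0("no cells with label '", class, "'"))
    return(tibble::tibble(clone_key = character()))
  }
  m <- bundle$counts[, sel$barcode, drop = FALSE]
  groups <- factor(sel$clone_key)
  # clone indicator matrix: cells x clones
  ind <- Matrix::sparseMatrix(i = seq_len(nrow(sel)), j = as.integer(groups), x = 1,
                              dims = c(nrow(sel), nlevels(groups)))
  agg <- as.matrix(m %*% ind)  # genes x clones
  colnames(agg) <- levels(groups)
  total <- sum(agg)
  cpm <- Matrix::rowSums(agg) / total * 1e6
  agg <- agg[cpm >= cpm_min, , drop = FALSE]
  out <- tibble::as_tibble(t(agg))
  dplyr::bind_cols(tibble::tibble(clone_key = levels(groups)), out)
}
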