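#' Pipeline configuration
#'
#' Assemble (and lightly validate) the configuration consumed by
#' [run_pipeline()]. Either a sample manifest (paths to MTX/TSV/contig files
#' per sample) or a simulation block must be supplied.
#'
#' @param samples named list; each element is a list with `dir` (a directory
#'   written by [write_sample_files()]) or explicit `counts`, `features`,
#'   `barcodes`, `meta`, `contigs` paths, plus optional `patient_id`.
#' @param simulate alternative to `samples`: list with `n_samples` and any
#'   [sim_config()] overrides; one paired sample is generated per sample.
#' @param qc list with optional `housekeeping_genes`/`mito_genes` vectors (or
#'   file paths) and [qc_params()] overrides; `NULL` skips the QC stage.
#' @param load list of [load_sample()] overrides (`min_features`,
#'   `min_cells_per_gene`).
#' @param marker list of [rank_markers()] overrides (`X_frac`, `L`, `genes`).
#' @param consensus list of [consensus_rank()] overrides.
#' @param gates list with `n_top` literals to gate over (default 4) and the
#'   universal `threshold` (default 0.001).
#' @param resampling list with `B` (default 1000 for pipeline runs; the study
#'   scale is 10,000) and `ci`.
#' @param out_dir output directory for per-stage TSV/JSON files (`NULL`: keep
#'   results in memory only).
#' @param seed global seed; all stage seeds derive from it.
#' @return A `tm_pipeline_config` list.
#' @export
pipeline_config <- function(samples = NULL, simulate = NULL, qc = NULL,
                            load = list(), marker = list(), consensus = list(),
                            gates = list(n_top = 4, threshold = 0.001),
                            resampling = list(B = 1000, ci = c(2.5, 97.5)),
                            out_dir = NULL, seed = 1) {
  if (is.null(samples) && is.null(simulate)) {
    stop_config("either a sample manifest or a simulation block is required")
  }
  structure(list(samples = samples, simulate = simulate, qc = qc, load = load,
                 marker = marker, consensus = consensus, gates = gates,
                 resampling = resampling, out_dir = out_dir, seed = seed),
            class = "tm_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match [pipeline_config()]
#'   arguments.
#' @return A `tm_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)),
          class = "tmcell_stage_error", parent = e)
  })
}

acquire_samples <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    n_samples <- sim$n_samples %||% 1L
    sim$n_samples <- NULL
    seeds <- split_seed(config$seed, n_samples)
    sims <- purrr::map(seq_len(n_samples), function(i) {
      args <- sim
      args$seed <- seeds[i]
      args$sample_id <- sprintf("S%d", i)
      args$patient_id <- args$patient_id %||% sprintf("P%d", i)
      do.call(sim_config, args)
    })
    out <- purrr::map(sims, function(cfg) {
      s <- simulate_paired_sample(cfg)
      list(bundle = s$bundle, chains = s$bundle$tcr, truth = s$truth)
    })
    names(out) <- purrr::map_chr(sims, "sample_id")
    return(out)
  }
  out <- purrr::imap(config$samples, function(s, nm) {
    if (!is.null(s$dir)) {
      s$counts <- s$counts %||% file.path(s$dir, "matrix.mtx")
      s$features <- s$features %||% file.path(s$dir, "features.tsv")
      s$barcodes <- s$barcodes %||% file.path(s$dir, "barcodes.tsv")
      s$meta <- s$meta %||% file.path(s$dir, "cell_meta.tsv")
      s$contigs <- s$contigs %||% file.path(s$dir, "contigs.csv")
    }
    bundle <- load_sample(s$counts, s$features, s$barcodes, meta_path = s$meta,
                          sample_id = nm, species = s$species %||% "human",
                          min_features = config$load$min_features %||% 400,
                          min_cells_per_gene = config$load$min_cells_per_gene %||% 3)
    chains <- read_contigs(s$contigs)
    list(bundle = bundle, chains = chains, truth = NULL)
  })
  out
}

match_sample <- function(bundle, chains) {
  clon <- assign_clonotypes(chains)
  clon <- clon[clon$barcode %in% bundle$cell_meta$barcode, ]
  comp <- bundle$cell_meta$compartment[match(clon$barcode, bundle$cell_meta$barcode)]
  labels <- label_matching(clon[comp == "blood", ], clon[comp == "tumor", ])
  list(clonotypes = clon, labels = labels)
}

tm_vector <- function(labels) {
  blood <- labels[labels$compartment == "blood" &
                    labels$label %in% c("TM", "non-TM"), ]
  setNames(blood$label == "TM", blood$barcode)
}

#' Run the full TM-identification and gate-discovery pipeline
#'
#' Stages: acquire (load or simulate) -> QC -> normalize/scale -> clonotype
#' matching -> clonal expansion statistics -> per-sample marker tests (AUC
#' grid + XL-mHG + BH) -> consensus ranking -> gate enumeration and evaluation
#' on the pooled blood cells -> bootstrap/permutation uncertainty for the best
#' gate. Per-stage tables are written to `out_dir` (TSV/JSON) when set, along
#' with a `manifest.json` recording completed stages; results are returned as
#' a `tm_report` list. Fully deterministic given the config seed.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @return A `tm_report` list: `samples`, `labels`, `expansion`, `markers`,
#'   `consensus`, `gate_evals`, `best_gate`, `resampling`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- config$out_dir
  manifest <- list(stages = character(), complete = FALSE, seed = config$seed)
  emit <- function(name, tbl) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      readr::write_tsv(tbl, file.path(out_dir, paste0(name, ".tsv")), progress = FALSE)
    }
  }
  finish_stage <- function(name) {
    manifest$stages <<- c(manifest$stages, name)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE)
    }
  }

  samples <- run_stage("acquire", acquire_samples(config))
  finish_stage("acquire")

  samples <- run_stage("qc_normalize", purrr::map(samples, function(s) {
    b <- s$bundle
    if (!is.null(config$qc)) {
      qc <- config$qc
      for (f in c("housekeeping_genes", "mito_genes")) {
        if (is.character(qc[[f]]) && length(qc[[f]]) == 1 && file.exists(qc[[f]])) {
          qc[[f]] <- read_gene_list(qc[[f]])
        }
      }
      b <- qc_filter_cells(b, do.call(qc_params, qc))
      if (!is.null(qc$cluster_rules) && isTRUE(qc$cluster_rules)) {
        b <- select_cd8_clusters(b)
      }
    }
    b <- scale_genes(normalize_log_tp10k(b))
    s$bundle <- b
    s
  }))
  finish_stage("qc_normalize")

  matched <- run_stage("tcr_matching", purrr::map(samples, function(s) {
    match_sample(s$bundle, s$chains)
  }))
  labels_all <- dplyr::bind_rows(purrr::map(matched, "labels"), .id = "sample_id")
  emit("labels", labels_all)
  finish_stage("tcr_matching")

  expansion <- run_stage("expansion", purrr::map(matched, function(m) {
    blood <- m$clonotypes[m$labels$compartment[match(m$clonotypes$barcode,
                                                     m$labels$barcode)] == "blood" &
                            !is.na(m$clonotypes$clone_key), ]
    sizes <- clone_size_table(blood)
    cells <- attr(sizes, "cells")
    lab <- m$labels$label[match(cells$barcode, m$labels$barcode)]
    keep <- lab %in% c("TM", "non-TM")
    if (length(unique(lab[keep])) == 2) {
      ranksum_compare(cells$expansion[keep], lab[keep] == "TM")
    } else {
      tibble::tibble(statistic = NA_real_, p = NA_real_,
                     n1 = sum(lab[keep] == "TM"), n2 = sum(lab[keep] == "non-TM"),
                     method = "skipped")
    }
  }) |> dplyr::bind_rows(.id = "sample_id"))
  emit("expansion", expansion)
  finish_stage("expansion")

  marker_tables <- run_stage("markers", purrr::imap(samples, function(s, nm) {
    tm <- tm_vector(matched[[nm]]$labels)
    rank_markers(s$bundle, tm,
                 genes = config$marker$genes,
                 X_frac = config$marker$X_frac %||% 0.15,
                 L = config$marker$L)
  }))
  # per-sample marker TSVs use the external "marker"/"marker_negation" dialect
  for (nm in names(marker_tables)) {
    emit(paste0("markers_", nm), dplyr::mutate(
      marker_tables[[nm]],
      direction = ifelse(.data$direction == "negation", "marker_negation", "marker")
    ))
  }
  finish_stage("markers")

  consensus <- run_stage("consensus", do.call(consensus_rank, c(
    list(results = marker_tables),
    config$consensus[intersect(names(config$consensus),
                               c("q_cut", "min_samples", "exclusion"))]
  )))
  emit("consensus", consensus)
  finish_stage("consensus")

  n_top <- config$gates$n_top %||% 4
  top <- head(consensus, n_top)
  gate_report <- run_stage("gates", {
    if (nrow(top) == 0) {
      list(evals = tibble::tibble(), best = NULL, pooled = NULL)
    } else {
      literals <- lit_string(top$gene,
                             ifelse(top$direction == "negation", "low", "high"))
      pooled <- purrr::imap(samples, function(s, nm) {
        tm <- tm_vector(matched[[nm]]$labels)
        tbl <- cell_gene_table(s$bundle, top$gene, layer = "counts")
        tbl <- tbl[match(names(tm), tbl$barcode), c("barcode", top$gene)]
        tbl$is_tm <- unname(tm)
        tbl
      }) |> dplyr::bind_rows(.id = "sample_id")
      evals <- evaluate_gates(pooled, enumerate_gates(literals),
                              threshold = config$gates$threshold %||% 0.001)
      list(evals = evals, best = select_best_gate(evals), pooled = pooled)
    }
  })
  if (nrow(gate_report$evals)) emit("gates", gate_report$evals)
  finish_stage("gates")

  resamp <- run_stage("resampling", {
    if (is.null(gate_report$best)) NULL else {
      best_gate <- parse_gate(gate_report$best$gate)
      thr <- config$gates$threshold %||% 0.001
      prm <- resampling_params(B = config$resampling$B %||% 1000,
                               ci = config$resampling$ci %||% c(2.5, 97.5),
                               seed = split_seed(config$seed, 3)[3])
      stat_for <- function(metric) {
        function(d) {
          if (length(unique(d$is_tm)) < 2) return(NA_real_)
          evaluate_gate(d, best_gate, threshold = thr)[[metric]]
        }
      }
      res <- list(
        sensitivity = resampling_summary(gate_report$pooled, stat_for("sensitivity"),
                                         prm, name = "sensitivity"),
        specificity = resampling_summary(gate_report$pooled, stat_for("specificity"),
                                         prm, name = "specificity")
      )
      if (!is.null(out_dir)) {
        jsonlite::write_json(purrr::map(res, function(r) {
          list(statistic = r$name, estimate = r$point, ci_lo = r$ci_lo,
               ci_hi = r$ci_hi, empirical_p = format_empirical_p(r),
               B = r$B, seed = r$seed)
        }), file.path(out_dir, "best_gate.json"), auto_unbox = TRUE, digits = NA)
      }
      res
    }
  })
  finish_stage("resampling")

  sample_summary <- purrr::imap(matched, function(m, nm) {
    tm <- tm_vector(m$labels)
    tibble::tibble(sample_id = nm, n_cells = ncol(samples[[nm]]$bundle$counts),
                   n_paired_blood = length(tm), n_tm = sum(tm),
                   tm_fraction = mean(tm))
  }) |> dplyr::bind_rows()
  emit("sample_summary", sample_summary)

  manifest$complete <- TRUE
  finish_stage("report")
  structure(
    list(samples = sample_summary, labels = labels_all, expansion = expansion,
         markers = marker_tables, consensus = consensus,
         gate_evals = gate_report$evals, best_gate = gate_report$best,
         resampling = resamp, config = config),
    class = "tm_report"
  )
}

#' @export
print.tm_report <- function(x, ...) {
  cat("<tm_report>\n\nSamples:\n")
  print(x$samples)
  cat("\nTop consensus markers:\n")
  print(head(x$consensus, 8))
  if (!is.null(x$best_gate)) {
    cat("\nBest gate: ", x$best_gate$gate,
        "  (sensitivity ", signif(x$best_gate$sensitivity, 3),
        ", specificity ", signif(x$best_gate$specificity, 3),
        ", penalty ", signif(x$best_gate$penalty, 4), ")\n", sep = "")
  }
  if (!is.null(x$resampling)) {
    for (r in x$resampling) print(r)
  }
  invisible(x)
}
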