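#' Simulation configuration
#'
#' The stated world for the paired blood/tumor generator: clone sizes follow a
#' geometric law (many singletons, a heavy-ish expanded tail), a planted
#' fraction of blood cells belongs to clones also seeded into the tumor (the
#' TM component), background gene means are log-normal, counts are negative
#' binomial with extra dropout, and per-cell TCR chain records include
#' multi-chain clones and cells with a missing chain.
#'
#' @param n_blood,n_tumor cells per compartment.
#' @param n_genes background genes (markers are added on top).
#' @param markers tibble with `gene`, `direction` (`"positive"` = higher in TM
#'   blood cells, `"negation"` = lower), and `lfc` (|log2 fold change|); the
#'   default plants four markers at |lfc| = 1.5, two per direction.
#' @param shared_clone_fraction planted fraction of blood cells in
#'   tumor-shared clones.
#' @param clone_geom_p geometric parameter of the clone-size law
#'   (size = 1 + Geom(p)).
#' @param nb_mean_meanlog,nb_mean_sdlog log-normal law of background gene
#'   means.
#' @param marker_base_mean baseline mean of marker genes (kept high enough
#'   that a downshift is observable).
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param dropout_extra extra per-entry dropout probability.
#' @param multi_chain_fraction fraction of clones carrying a second alpha or
#'   beta chain (clone-level, so clone identity is preserved).
#' @param missing_chain_fraction fraction of cells whose alpha or beta chain
#'   went undetected (excluded from matching).
#' @param species,patient_id,sample_id metadata for the generated bundle.
#' @param seed master RNG seed; all generator randomness derives from it.
#' @return A `tm_sim_config` list.
#' @export
sim_config <- function(n_blood = 1500, n_tumor = 1000, n_genes = 300,
                       markers = tibble::tibble(
                         gene = c("MKPOS1", "MKPOS2", "MKNEG1", "MKNEG2"),
                         direction = c("positive", "positive", "negation", "negation"),
                         lfc = 1.5),
                       shared_clone_fraction = 0.1, clone_geom_p = 0.5,
                       nb_mean_meanlog = log(0.3), nb_mean_sdlog = 1,
                       marker_base_mean = 4, nb_dispersion = 0.5,
                       dropout_extra = 0.02,
                       multi_chain_fraction = 0.10, missing_chain_fraction = 0.10,
                       species = "human", patient_id = "P1", sample_id = "sim",
                       seed = 1) {
  assert_prob(shared_clone_fraction, "shared_clone_fraction")
  assert_prob(dropout_extra, "dropout_extra")
  assert_prob(multi_chain_fraction, "multi_chain_fraction")
  assert_prob(missing_chain_fraction, "missing_chain_fraction")
  stopifnot(n_blood >= 1, n_tumor >= 1, n_genes >= 1, nb_dispersion > 0,
            clone_geom_p > 0, clone_geom_p < 1)
  if (!is.null(markers)) {
    stopifnot(all(markers$direction %in% c("positive", "negation")),
              all(markers$lfc >= 0))
  }
  structure(as.list(environment()), class = "tm_sim_config")
}

draw_clone_sizes <- function(n_cells, p) {
  sizes <- integer()
  while (sum(sizes) < n_cells) {
    sizes <- c(sizes, rgeom(max(64, n_cells %/% 2), p) + 1L)
  }
  cut <- which(cumsum(sizes) >= n_cells)[1]
  sizes <- sizes[seq_len(cut)]
  sizes[cut] <- sizes[cut] - (sum(sizes) - n_cells)
  sizes[sizes > 0]
}

random_cdr3 <- function(n, min_len = 8, max_len = 20) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  len <- sample(min_len:max_len, n, replace = TRUE)
  vapply(len, function(l) {
    paste0("C", paste(sample(aa, l - 2, replace = TRUE), collapse = ""), "F")
  }, "")
}

clone_chain_table <- function(n_clones, multi_chain_fraction) {
  repeat {
    tra <- random_cdr3(n_clones)
    trb <- random_cdr3(n_clones)
    extra_chain <- runif(n_clones) < multi_chain_fraction
    extra_is_tra <- runif(n_clones) < 0.5
    extra <- random_cdr3(n_clones)
    key <- paste(tra, trb, ifelse(extra_chain, extra, ""), extra_is_tra)
    if (!anyDuplicated(key)) {
      return(tibble::tibble(tra = tra, trb = trb, extra_chain = extra_chain,
                            extra_is_tra = extra_is_tra, extra = extra))
    }
  }
}

#' Simulate a paired blood/tumor sample with planted TM structure
#'
#' Blood and tumor clones are drawn from the clone-size law; a subset of blood
#' clones whose total cell count hits the planted `shared_clone_fraction` (as
#' closely as clone granularity allows) is also seeded into the tumor. Counts
#' are negative binomial on log-normal gene means; marker-gene means are
#' multiplied by `2^(+/- lfc)` in TM blood cells. Per-cell TCR chain records
#' carry CDR3 amino-acid strings (C...F convention); multi-chain clones and
#' missing-chain cells are injected at the configured rates.
#'
#' @param config a [sim_config()].
#' @param write_dir optional directory: write MTX/TSV/contig-CSV files plus
#'   `ground_truth.json`.
#' @return A list: `bundle` (a `tm_bundle`, TCR records attached), `truth`
#'   (per-cell labels, clone table, marker table with Monte-Carlo true AUC,
#'   planted TM fraction).
#' @export
simulate_paired_sample <- function(config = sim_config(), write_dir = NULL) {
  seeds <- split_seed(config$seed, 4)
  n_blood <- config$n_blood
  n_tumor <- config$n_tumor

  # --- clonal structure ------------------------------------------------------
  cl <- withr::with_seed(seeds[1], {
    blood_sizes <- draw_clone_sizes(n_blood, config$clone_geom_p)
    nb <- length(blood_sizes)
    target <- round(config$shared_clone_fraction * n_blood)
    ord <- sample.int(nb)
    shared <- logical(nb)
    left <- target
    for (i in ord) {
      if (blood_sizes[i] <= left) {
        shared[i] <- TRUE
        left <- left - blood_sizes[i]
        if (left == 0) break
      }
    }
    n_shared <- sum(shared)
    if (config$shared_clone_fraction > 0 && n_shared == 0 && target > 0) {
      stop_input("infeasible config: no clone fits the shared-cell target")
    }
    tumor_shared_sizes <- if (n_shared) rgeom(n_shared, config$clone_geom_p) + 1L else integer()
    if (sum(tumor_shared_sizes) > n_tumor) {
      tumor_shared_sizes <- rep(1L, n_shared)
      if (n_shared > n_tumor) stop_input("infeasible config: more shared clones than tumor cells")
    }
    rest <- n_tumor - sum(tumor_shared_sizes)
    tumor_only_sizes <- if (rest > 0) draw_clone_sizes(rest, config$clone_geom_p) else integer()
    list(blood_sizes = blood_sizes, shared = shared,
         tumor_shared_sizes = tumor_shared_sizes, tumor_only_sizes = tumor_only_sizes)
  })
  nb <- length(cl$blood_sizes)
  nt_only <- length(cl$tumor_only_sizes)
  clone_ids <- sprintf("CL%05d", seq_len(nb + nt_only))
  blood_clone_of_cell <- rep(seq_len(nb), cl$blood_sizes)
  shared_idx <- which(cl$shared)
  tumor_clone_of_cell <- c(rep(shared_idx, cl$tumor_shared_sizes),
                           rep(nb + seq_len(nt_only), cl$tumor_only_sizes))
  barcodes <- c(sprintf("%s_blood_%05d", config$sample_id, seq_len(n_blood)),
                sprintf("%s_tumor_%05d", config$sample_id, seq_len(n_tumor)))
  compartment <- rep(c("blood", "tumor"), c(n_blood, n_tumor))
  clone_of_cell <- c(blood_clone_of_cell, tumor_clone_of_cell)
  is_tm <- compartment == "blood" & cl$shared[clone_of_cell]

  # --- expression ------------------------------------------------------------
  markers <- config$markers
  n_mk <- if (is.null(markers)) 0L else nrow(markers)
  genes <- c(if (n_mk) markers$gene, sprintf("G%05d", seq_len(config$n_genes)))
  counts <- withr::with_seed(seeds[2], {
    mu <- c(if (n_mk) rep(config$marker_base_mean, n_mk),
            rlnorm(config$n_genes, config$nb_mean_meanlog, config$nb_mean_sdlog))
    mu_mat <- matrix(mu, nrow = length(genes), ncol = length(barcodes))
    if (n_mk) {
      fold <- 2^(ifelse(markers$direction == "positive", 1, -1) * markers$lfc)
      mu_mat[seq_len(n_mk), is_tm] <- mu_mat[seq_len(n_mk), is_tm] * fold
    }
    x <- matrix(rnbinom(length(mu_mat), mu = as.vector(mu_mat),
                        size = 1 / config$nb_dispersion),
                nrow = length(genes))
    if (config$dropout_extra > 0) {
      x <- x * matrix(rbinom(length(x), 1, 1 - config$dropout_extra), nrow = nrow(x))
    }
    x
  })
  rownames(counts) <- genes
  colnames(counts) <- barcodes

  # --- TCR chains ------------------------------------------------------------
  tcr <- withr::with_seed(seeds[3], {
    chains <- clone_chain_table(nb + nt_only, config$multi_chain_fraction)
    drop_chain <- runif(length(barcodes)) < config$missing_chain_fraction
    drop_tra <- runif(length(barcodes)) < 0.5
    recs <- purrr::map(seq_along(barcodes), function(i) {
      k <- clone_of_cell[i]
      chain <- c("TRA", "TRB")
      cdr3 <- c(chains$tra[k], chains$trb[k])
      if (chains$extra_chain[k]) {
        chain <- c(chain, if (chains$extra_is_tra[k]) "TRA" else "TRB")
        cdr3 <- c(cdr3, chains$extra[k])
      }
      if (drop_chain[i]) {
        keep <- if (drop_tra[i]) chain != "TRA" else chain != "TRB"
        chain <- chain[keep]; cdr3 <- cdr3[keep]
      }
      tibble::tibble(barcode = barcodes[i], chain = chain, cdr3 = cdr3)
    }) |> dplyr::bind_rows()
    recs$v_gene <- ifelse(recs$chain == "TRA", "TRAV1", "TRBV1")
    recs$j_gene <- ifelse(recs$chain == "TRA", "TRAJ1", "TRBJ1")
    recs$productive <- TRUE
    recs$raw_clonotype_id <- clone_ids[clone_of_cell[match(recs$barcode, barcodes)]]
    list(recs = recs, paired = !drop_chain)
  })

  meta <- tibble::tibble(barcode = barcodes, sample_id = config$sample_id,
                         patient_id = config$patient_id,
                         compartment = compartment, cluster = "CD8")
  bundle <- sample_bundle(counts, meta, species = config$species,
                          sample_id = config$sample_id, tcr = tcr$recs)

  # --- ground truth ----------------------------------------------------------
  auc_true <- if (n_mk) withr::with_seed(seeds[4], {
    vapply(seq_len(n_mk), function(j) {
      fold <- 2^(ifelse(markers$direction[j] == "positive", 1, -1) * markers$lfc[j])
      draw <- function(mu) {
        x <- rnbinom(20000, mu = mu, size = 1 / config$nb_dispersion)
        x * rbinom(20000, 1, 1 - config$dropout_extra)
      }
      x_tm <- draw(config$marker_base_mean * fold)
      x_non <- draw(config$marker_base_mean)
      mean(x_tm > x_non) + 0.5 * mean(x_tm == x_non)
    }, 0)
  }) else numeric()
  truth <- list(
    cells = tibble::tibble(barcode = barcodes, compartment = compartment,
                           clone_id = clone_ids[clone_of_cell],
                           is_tm = is_tm, paired_chain = tcr$paired),
    clones = tibble::tibble(
      clone_id = clone_ids,
      blood_size = c(tabulate(blood_clone_of_cell, nb), rep(0L, nt_only)),
      tumor_size = tabulate(tumor_clone_of_cell, nb + nt_only),
      shared = c(cl$shared, rep(FALSE, nt_only))
    ),
    markers = if (n_mk) dplyr::mutate(markers, auc_true = auc_true) else markers,
    planted_tm_fraction = mean(is_tm[compartment == "blood"])
  )
  if (!is.null(write_dir)) {
    write_sample_files(bundle, write_dir, chains = tcr$recs)
    jsonlite::write_json(truth, file.path(write_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(bundle = bundle, truth = truth)
}

#' Simulate a dataset whose TM labels realize a planted boolean gate
#'
#' Each gate literal gets an independent Bernoulli(0.5) pass state per cell;
#' marker counts are drawn so the state is exactly recovered by the universal
#' 0.001-UMI threshold (`^low` passes iff the count is zero). The TM label is
#' the gate's truth value, flipped independently with probability `noise`.
#' Background genes follow the config's negative-binomial law.
#'
#' @param config a [sim_config()]; `n_blood` sets the cell count.
#' @param gate a `tm_gate` or gate string over at most 4 literals.
#' @param noise label-flip probability (default 0.05).
#' @param decoys optional extra literal strings (e.g. `"M4^low"`) simulated
#'   with the same Bernoulli(0.5) pass states but without any effect on the TM
#'   label; candidate markers for recovery tests.
#' @param marker_lambda Poisson intensity of nonzero marker counts.
#' @return A list: `bundle` (blood-only), `truth` (per-cell `is_tm`, literal
#'   states, the planted gate).
#' @export
planted_gate_dataset <- function(config = sim_config(), gate, noise = 0.05,
                                 decoys = character(), marker_lambda = 1.5) {
  if (is.character(gate)) gate <- parse_gate(gate)
  assert_prob(noise, "noise")
  literals <- gate$literals
  if (length(decoys)) {
    parts <- strsplit(decoys, "^", fixed = TRUE)
    literals <- dplyr::bind_rows(literals, tibble::tibble(
      gene = vapply(parts, `[[`, "", 1),
      direction = vapply(parts, `[[`, "", 2)
    ))
    if (anyDuplicated(literals$gene)) stop_input("decoys duplicate gate markers")
  }
  m_gate <- nrow(gate$literals)
  m <- nrow(literals)
  n <- config$n_blood
  seeds <- split_seed(config$seed, 2)
  dat <- withr::with_seed(seeds[1], {
    states <- matrix(runif(n * m) < 0.5, nrow = n)
    idx <- as.integer(states[, seq_len(m_gate), drop = FALSE] %*%
                        bitwShiftL(1L, seq_len(m_gate) - 1L)) + 1L
    tm <- gate$table[idx]
    flip <- runif(n) < noise
    tm[flip] <- !tm[flip]
    nonzero <- matrix(1L + rpois(n * m, marker_lambda), nrow = n)
    on <- ifelse(matrix(literals$direction, n, m, byrow = TRUE) == "high",
                 states, !states)
    list(states = states, tm = tm, marker_counts = ifelse(on, nonzero, 0L))
  })
  bg <- withr::with_seed(seeds[2], {
    mu <- rlnorm(config$n_genes, config$nb_mean_meanlog, config$nb_mean_sdlog)
    matrix(rnbinom(config$n_genes * n, mu = rep(mu, n), size = 1 / config$nb_dispersion),
           nrow = config$n_genes)
  })
  genes <- c(literals$gene, sprintf("G%05d", seq_len(config$n_genes)))
  counts <- rbind(t(dat$marker_counts), bg)
  rownames(counts) <- genes
  colnames(counts) <- sprintf("%s_blood_%05d", config$sample_id, seq_len(n))
  meta <- tibble::tibble(barcode = colnames(counts), sample_id = config$sample_id,
                         patient_id = config$patient_id, compartment = "blood",
                         cluster = "CD8")
  bundle <- sample_bundle(counts, meta, species = config$species,
                          sample_id = config$sample_id)
  truth <- list(
    cells = tibble::tibble(barcode = colnames(counts), is_tm = dat$tm),
    states = dat$states,
    gate = gate
  )
  list(bundle = bundle, truth = truth)
}
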