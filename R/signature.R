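#' Score a gene signature per cell with binned control genes
#'
#' Per-cell score = mean scaled expression of the signature genes minus the
#' mean scaled expression of a control gene set. Control genes are drawn
#' (seeded, without replacement) from expression bins: all genes are ranked by
#' their average log TP10K expression and cut into `n_bins` equal-size bins,
#' and each signature gene contributes up to `ctrl_size` control genes sampled
#' from its own bin. Cells that will be compared must be merged into one
#' bundle before centering/scaling, since scores are relative quantities.
#'
#' @param bundle a `tm_bundle` with `normalized` and `scaled` layers.
#' @param signature character vector of gene symbols.
#' @param n_bins number of average-expression bins (default 25).
#' @param ctrl_size control genes drawn per signature gene (default 50).
#' @param seed RNG seed for the control draw.
#' @return A tibble `barcode`, `score`; the control gene set and seed are
#'   attached as attributes.
#' @export
score_signature <- function(bundle, signature, n_bins = 25, ctrl_size = 50, seed = 0) {
  stopifnot(n_bins >= 1, ctrl_size >= 1)
  if (is.null(bundle$scaled) || is.null(bundle$normalized)) {
    stop_input("bundle needs normalized and scaled layers (run normalize_log_tp10k() then scale_genes())")
  }
  all_genes <- rownames(bundle$scaled)
  sig <- intersect(signature, all_genes)
  if (!length(sig)) {
    stop_input("no signature genes found in the data; missing: ",
               paste(signature, collapse = ", "))
  }
  if (length(sig) < length(signature)) {
    warn(paste0("signature genes absent from data and skipped: ",
                paste(setdiff(signature, sig), collapse = ", ")))
  }
  gene_means <- Matrix::rowMeans(bundle$normalized)
  bins <- dplyr::ntile(rank(gene_means, ties.method = "first"), n_bins)
  names(bins) <- all_genes
  ctrl <- withr::with_seed(seed, {
    unique(unlist(lapply(sig, function(g) {
      pool <- setdiff(all_genes[bins == bins[[g]]], signature)
      if (!length(pool)) return(character())
      sample(pool, min(ctrl_size, length(pool)))
    })))
  })
  sig_mean <- colMeans(bundle$scaled[sig, , drop = FALSE])
  ctrl_mean <- if (length(ctrl)) colMeans(bundle$scaled[ctrl, , drop = FALSE]) else 0
  out <- tibble::tibble(barcode = colnames(bundle$scaled),
                        score = unname(sig_mean - ctrl_mean))
  attr(out, "control_genes") <- ctrl
  attr(out, "seed") <- seed
  out
}

rank_midranks <- function(x) rank(x, ties.method = "average")

#' Wilcoxon rank-sum comparison of two groups
#'
#' Midranks for ties; exact p by exhaustive enumeration of group assignments
#' when both groups have at most `exact_max` observations, otherwise a normal
#' approximation with the standard tie-corrected variance. Two-sided.
#'
#' @param scores numeric values.
#' @param groups logical or two-level vector aligned with `scores`; `TRUE`
#'   (or the first level) defines group one.
#' @param exact_max exact-enumeration size threshold per group (default 10).
#' @return One-row tibble: `statistic` (group-one rank sum), `p`, `n1`, `n2`,
#'   `method`.
#' @export
ranksum_compare <- function(scores, groups, exact_max = 10) {
  if (!is.logical(groups)) groups <- groups == sort(unique(groups))[1]
  n1 <- sum(groups); n2 <- sum(!groups); n <- n1 + n2
  if (n1 == 0 || n2 == 0) stop_input("both groups must be non-empty")
  r <- rank_midranks(scores)
  w_obs <- sum(r[groups])
  mu <- n1 * (n + 1) / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- combn(n, n1)
    w_all <- colSums(matrix(r[idx], nrow = n1))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    method <- "exact"
  } else {
    tt <- table(r)
    v <- n1 * n2 / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      p <- min(1, 2 * pnorm(-abs(w_obs - mu) / sqrt(v)))
    }
    method <- "normal"
  }
  tibble::tibble(statistic = w_obs, p = p, n1 = n1, n2 = n2, method = method)
}

#' Summarise signature scores per clone
#'
#' @param scores tibble from [score_signature()].
#' @param cells tibble mapping `barcode` to `clone_key` (e.g. the `cells`
#'   attribute of [clone_size_table()]).
#' @return A tibble `clone_key`, `mean_score`, `n_cells`.
#' @export
clone_signature_summary <- function(scores, cells) {
  dplyr::inner_join(scores, cells[, c("barcode", "clone_key")], by = "barcode") |>
    dplyr::group_by(.data$clone_key) |>
    dplyr::summarise(mean_score = mean(.data$score), n_cells = dplyr::n(),
                     .groups = "drop")
}

#' Paired (signed-rank) comparison of clone-level signature means
#'
#' Restricted to clones present in both summaries (e.g. the same clone
#' observed in blood and in tumor). Zero differences are dropped; exact p by
#' sign-flip enumeration when at most `exact_max` nonzero differences remain,
#' otherwise a tie-corrected normal approximation. Two-sided.
#'
#' @param summary_a,summary_b tibbles from [clone_signature_summary()].
#' @param exact_max exact-enumeration threshold (default 15).
#' @return One-row tibble: `statistic` (positive-rank sum), `p`, `n`
#'   (nonzero paired clones), `method`.
#' @export
paired_clone_compare <- function(summary_a, summary_b, exact_max = 15) {
  shared <- dplyr::inner_join(summary_a, summary_b, by = "clone_key",
                              suffix = c("_a", "_b"))
  d <- shared$mean_score_a - shared$mean_score_b
  d <- d[d != 0]
  n <- length(d)
  if (n < 2) stop_input("need at least 2 shared clones with nonzero score difference")
  r <- rank_midranks(abs(d))
  v_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.numeric(signs %*% r)
    p <- mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
    method <- "exact"
  } else {
    v <- sum(r^2) / 4
    p <- if (v <= 0) 1 else min(1, 2 * pnorm(-abs(v_obs - mu) / sqrt(v)))
    method <- "normal"
  }
  tibble::tibble(statistic = v_obs, p = p, n = n, method = method)
}
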