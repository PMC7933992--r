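#' ROC grid and AUC for one gene
#'
#' Builds the 39-candidate-threshold set used throughout the marker analysis:
#' every fifth percentile of the gene's expression (21 values including the
#' 0th and 100th percentiles, linear interpolation) combined with 18 evenly
#' spaced expression values strictly between the minimum and maximum (to cover
#' heavily skewed distributions). For each threshold, cells above it (positive
#' direction) or below it (negation direction) are predicted TM; sensitivity
#' and 1-specificity are recorded, the trivial points (0,0) and (1,1) are
#' appended, and the AUC is the trapezoid integral over x-sorted points.
#'
#' @param expr per-cell expression values of one gene.
#' @param labels logical TM indicator aligned with `expr`.
#' @param direction `"positive"` (high expression predicts TM) or
#'   `"negation"` (low expression predicts TM).
#' @param gene optional gene symbol carried into the result.
#' @return A `tm_roc` object: list with `gene`, `direction`, `thresholds`
#'   (length 39), `roc_points` tibble (`fpr`, `sens`), and `auc`.
#' @export
auc_grid <- function(expr, labels, direction = c("positive", "negation"), gene = NA_character_) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(expr) != length(labels)) stop_input("expr and labels lengths differ")
  if (!any(labels) || all(labels)) stop_input("both TM and non-TM cells are required")
  pct <- quantile(expr, probs = seq(0, 1, by = 0.05), type = 7, names = FALSE)
  even <- seq(min(expr), max(expr), length.out = 20)[2:19]
  thresholds <- c(pct, even)
  pos <- if (direction == "positive") {
    outer(expr, thresholds, ">")
  } else {
    outer(expr, thresholds, "<")
  }
  sens <- c(colMeans(pos[labels, , drop = FALSE]), 0, 1)
  fpr <- c(colMeans(pos[!labels, , drop = FALSE]), 0, 1)
  o <- order(fpr, sens)
  structure(
    list(gene = gene, direction = direction, thresholds = thresholds,
         roc_points = tibble::new_tibble(list(fpr = fpr[o], sens = sens[o]),
                                         nrow = length(o)),
         auc = trapezoid(fpr, sens),
         n_tm = sum(labels), n = length(labels)),
    class = "tm_roc"
  )
}

#' @export
print.tm_roc <- function(x, ...) {
  cat("<tm_roc> ", if (!is.na(x$gene)) paste0(x$gene, " ") else "",
      "(", x$direction, "): AUC = ", signif(x$auc, 4),
      " over ", length(x$thresholds), " thresholds\n", sep = "")
  invisible(x)
}

#' XL-mHG parameters
#'
#' The study's parameterization of the minimal-hypergeometric marker scan:
#' `X` is a fraction of the TM count (default 0.15, so at least
#' `ceiling(0.15 * K)` TM cells must sit above a candidate cutoff) and the
#' cutoff depth is capped at `L = min(10 * K, floor(0.35 * N))`, where `K` is
#' the number of TM cells and `N` the number of cells with at least one alpha
#' and one beta chain.
#'
#' @param K number of TM cells.
#' @param N total number of (paired-chain) cells.
#' @param X_frac minimum TM fraction above the cutoff, as a fraction of `K`.
#' @param L cutoff cap; defaults to the study rule.
#' @return A list with `X_frac`, `X` (absolute count), `K`, `N`, `L`.
#' @export
xlmhg_params <- function(K, N, X_frac = 0.15, L = NULL) {
  if (K < 1) stop_input("K must be at least 1")
  if (N < 2 || K > N) stop_input("need N >= 2 and K <= N")
  assert_prob(X_frac, "X_frac")
  if (X_frac <= 0) stop_input("X_frac must be positive")
  if (is.null(L)) L <- min(10 * K, floor(0.35 * N))
  if (L < 1) stop_input("L must be at least 1 (N too small for the 0.35*N cap)")
  list(X_frac = X_frac, X = ceiling(X_frac * K), K = K, N = N, L = as.integer(min(L, N)))
}

# Exact XL-mHG p-value: dynamic program counting label-placement paths on the
# (cutoff, #TM-above) lattice that avoid the rejection region, with periodic
# rescaling and a log-space final ratio. `bmin[n]` is the smallest rejected TM
# count at cutoff n (NA when cutoff n cannot reject).
xlmhg_dp_p <- function(N, K, bmin) {
  w <- c(1, rep(0, K))
  logscale <- 0
  for (n in seq_len(N)) {
    w <- w + c(0, w[seq_len(K)])
    if (!is.na(bmin[n])) w[(bmin[n] + 1):(K + 1)] <- 0
    if (n %% 64L == 0L) {
      mx <- max(w)
      if (mx > 1e280) {
        w <- w / mx
        logscale <- logscale + log(mx)
      }
    }
  }
  surv <- w[K + 1]
  if (surv <= 0) return(1)
  p <- -expm1(log(surv) + logscale - lchoose(N, K))
  min(max(p, 0), 1)
}

#' XL-minimal-hypergeometric marker test
#'
#' Cells are ranked by decreasing expression (negation markers are negated
#' before ranking). For every admissible cutoff depth `n` -- at most `L` deep,
#' falling between distinct expression values, and with at least
#' `ceiling(X_frac * K)` TM cells above it -- the hypergeometric upper-tail
#' probability of seeing that many TM cells in the top `n` is computed;
#' `mhg_stat` is the minimum over admissible cutoffs. The exact p-value
#' P(stat <= observed) under random label placement is computed by a
#' path-counting dynamic program over the cutoff/label lattice. The selected
#' threshold (`cutoff_val`) is the midpoint between the expression values
#' flanking the minimizing cutoff, reported as an absolute value.
#'
#' @param expr per-cell expression of one gene.
#' @param labels logical TM indicator.
#' @param X_frac,L see [xlmhg_params()].
#' @param direction `"positive"` or `"negation"`.
#' @param gene optional gene symbol carried into the result.
#' @return One-row tibble: `gene`, `direction`, `mhg_stat`, `p`, `cutoff_val`,
#'   `cutoff_rank` (depth of the minimizing cutoff), `K`, `N`, `L`.
#' @export
xlmhg_test <- function(expr, labels, X_frac = 0.15, L = NULL,
                       direction = c("positive", "negation"), gene = NA_character_) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(expr) != length(labels)) stop_input("expr and labels lengths differ")
  prm <- xlmhg_params(K = sum(labels), N = length(labels), X_frac = X_frac, L = L)
  e <- if (direction == "negation") -expr else expr
  ord <- order(e, decreasing = TRUE)
  v <- e[ord]
  lab <- labels[ord]
  N <- prm$N; K <- prm$K
  b <- cumsum(lab)
  distinct_after <- v[seq_len(N - 1)] > v[seq_len(N - 1) + 1]
  allowed <- which(distinct_after & seq_len(N - 1) <= prm$L)
  adm <- allowed[b[allowed] >= prm$X]
  xlmhg_row <- function(mhg_stat, p, cutoff_val, cutoff_rank) {
    tibble::new_tibble(list(gene = gene, direction = direction,
                            mhg_stat = mhg_stat, p = p, cutoff_val = cutoff_val,
                            cutoff_rank = cutoff_rank, K = K, N = N, L = prm$L),
                       nrow = 1L)
  }
  if (!length(adm)) {
    return(xlmhg_row(1, 1, NA_real_, NA_integer_))
  }
  tails <- phyper(b[adm] - 1, K, N - K, adm, lower.tail = FALSE)
  s <- min(tails)
  n_star <- adm[which.min(tails)]
  cutoff_signed <- (v[n_star] + v[n_star + 1]) / 2
  # rejection region: smallest rejected TM count per allowed cutoff; the
  # hypergeometric tail grows with depth at fixed count, so the boundary is
  # monotone and a single forward pointer suffices. The relative epsilon keeps
  # region membership consistent for mathematically tied tail values.
  s_tol <- s * (1 + 1e-9)
  bmin <- rep(NA_integer_, N)
  bptr <- prm$X
  for (n in allowed) {
    while (bptr <= K && phyper(bptr - 1, K, N - K, n, lower.tail = FALSE) > s_tol) {
      bptr <- bptr + 1L
    }
    if (bptr <= min(n, K)) bmin[n] <- bptr
  }
  # P(S <= s) >= P(at least b* TM in the top n*) = s, so the statistic is a
  # valid floor for the DP value (which can underflow to 0 for extreme inputs)
  p <- max(xlmhg_dp_p(N, K, bmin), s)
  xlmhg_row(s, p, abs(cutoff_signed), n_star)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment across all genes x directions tested within one sample.
#'
#' @param pvals p-values in `[0, 1]`.
#' @return q-values of the same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop_input("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Per-sample marker table: AUC grid + XL-mHG for every gene and direction
#'
#' @param bundle a `tm_bundle`; expression is taken from `layer`.
#' @param tm named logical vector of TM labels over the paired-chain cells to
#'   analyse (names are barcodes present in the bundle).
#' @param genes genes to test (default: all genes in the bundle).
#' @param layer expression layer for ranking/thresholds (default normalized).
#' @param X_frac,L XL-mHG parameters (see [xlmhg_params()]).
#' @param directions directions to test.
#' @return A tibble (one row per gene x direction): `gene`, `direction`,
#'   `mhg_stat`, `p`, `q` (BH within this sample), `cutoff_val`, `auc`.
#' @export
rank_markers <- function(bundle, tm, genes = NULL,
                         layer = c("normalized", "counts"),
                         X_frac = 0.15, L = NULL,
                         directions = c("positive", "negation")) {
  layer <- match.arg(layer)
  m <- bundle[[layer]]
  if (is.null(m)) stop_input("layer '", layer, "' not populated")
  if (is.null(names(tm))) stop_input("tm must be a named logical vector (barcodes)")
  cells <- intersect(names(tm), colnames(m))
  if (length(cells) < length(tm)) {
    warn(paste0(length(tm) - length(cells), " labelled cells absent from the bundle"))
  }
  tm <- as.logical(tm[cells])
  m <- as.matrix(m[, cells, drop = FALSE])
  genes <- genes %||% rownames(m)
  rows <- purrr::map(genes, function(g) {
    expr <- m[g, ]
    purrr::map(directions, function(d) {
      res <- xlmhg_test(expr, tm, X_frac = X_frac, L = L, direction = d, gene = g)
      res$auc <- auc_grid(expr, tm, direction = d, gene = g)$auc
      res
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  rows$q <- bh_adjust(rows$p)
  dplyr::relocate(rows, "gene", "direction", "mhg_stat", "p", "q", "cutoff_val", "auc")
}

#' Consensus marker ranking across samples
#'
#' Keeps markers (gene + direction) significant (`q < q_cut`) in at least
#' `min_samples` samples, drops lineage-defining or non-surface genes on the
#' exclusion list, and ranks the survivors by descending mean AUC across
#' samples.
#'
#' @param results named list of per-sample tibbles from [rank_markers()].
#' @param q_cut significance cutoff (default 0.05).
#' @param min_samples minimum supporting samples (default 4, "four of six").
#' @param exclusion genes removed before ranking (default CD8A and the
#'   cytokines CCL4, CCL5, MIF).
#' @return A tibble `gene`, `direction`, `n_significant`, `mean_auc`, `rank`,
#'   sorted by rank; empty (with a warning) when nothing passes.
#' @export
consensus_rank <- function(results, q_cut = 0.05, min_samples = 4,
                           exclusion = c("CD8A", "CCL4", "CCL5", "MIF")) {
  if (length(results) < 2) stop_input("need marker tables from at least 2 samples")
  all <- dplyr::bind_rows(results, .id = "sample_id") |>
    dplyr::filter(!.data$gene %in% exclusion) |>
    dplyr::group_by(.data$gene, .data$direction) |>
    dplyr::summarise(n_significant = sum(.data$q < q_cut),
                     mean_auc = mean(.data$auc), .groups = "drop") |>
    dplyr::filter(.data$n_significant >= min_samples) |>
    dplyr::arrange(dplyr::desc(.data$mean_auc))
  if (nrow(all) == 0) {
    warn("no marker passed the consensus filter")
    return(dplyr::mutate(all, rank = integer()))
  }
  dplyr::mutate(all, rank = dplyr::row_number())
}

#' Hypergeometric marker-set overlap test
#'
#' Upper-tail probability of observing at least the given overlap between two
#' marker sets drawn from a common (homolog-mapped) universe; used to compare
#' marker sets discovered independently in two species.
#'
#' @param set_a,set_b character vectors of marker genes in a shared namespace.
#' @param universe size of the common gene universe.
#' @return One-row tibble: `overlap`, `size_a`, `size_b`, `universe`, `p`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  a <- unique(set_a); b <- unique(set_b)
  k <- length(intersect(a, b))
  if (length(a) > universe || length(b) > universe) {
    stop_input("set sizes exceed the declared universe")
  }
  p <- phyper(k - 1, length(a), universe - length(a), length(b), lower.tail = FALSE)
  tibble::tibble(overlap = k, size_a = length(a), size_b = length(b),
                 universe = universe, p = p)
}

#' Cross-sample similarity of per-gene AUC profiles
#'
#' For every gene measured in all samples and every pair of samples, one point
#' (AUC in sample i, AUC in sample j) is formed; to avoid biasing the x axis
#' toward samples appearing first, coordinates are swapped with probability
#' `swap_prob` under the given seed. Pearson correlation is reported per
#' stratum: sample pairs from the same patient vs pairs from different
#' patients.
#'
#' @param auc_tables named list of per-sample tibbles with `gene`, `direction`,
#'   `auc`; the positive-direction AUC is used (negation markers appear as
#'   values below 0.5).
#' @param patients named character vector mapping sample name to patient id.
#' @param swap_prob coordinate swap probability (default 0.5).
#' @param seed RNG seed for the swap (default 27).
#' @param genes optional restriction (e.g. a surface-gene list).
#' @return A tibble with one row per stratum: `stratum`, `r`, `p`, `n_points`;
#'   the swapped point table is attached as attribute `points`.
#' @export
auc_similarity <- function(auc_tables, patients, swap_prob = 0.5, seed = 27,
                           genes = NULL) {
  if (length(auc_tables) < 2) stop_input("need at least 2 samples")
  assert_prob(swap_prob, "swap_prob")
  pos <- purrr::map(auc_tables, function(t) {
    if ("direction" %in% names(t)) t <- t[t$direction == "positive", ]
    setNames(t$auc, t$gene)
  })
  shared <- Reduce(intersect, purrr::map(pos, names))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  if (length(shared) < 3) stop_input("fewer than 3 genes shared across all samples")
  samples <- names(auc_tables)
  prs <- combn(samples, 2)
  pts <- purrr::map(seq_len(ncol(prs)), function(i) {
    s1 <- prs[1, i]; s2 <- prs[2, i]
    tibble::tibble(
      gene = shared,
      x = unname(pos[[s1]][shared]), y = unname(pos[[s2]][shared]),
      stratum = if (patients[[s1]] == patients[[s2]]) "within-patient" else "between-patient"
    )
  }) |> dplyr::bind_rows()
  swap <- withr::with_seed(seed, runif(nrow(pts)) < swap_prob)
  tmp <- pts$x[swap]
  pts$x[swap] <- pts$y[swap]
  pts$y[swap] <- tmp
  out <- pts |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      r = suppressWarnings(cor(.data$x, .data$y)),
      p = suppressWarnings(cor.test(.data$x, .data$y)$p.value),
      n_points = dplyr::n(), .groups = "drop"
    )
  attr(out, "points") <- pts
  out
}
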