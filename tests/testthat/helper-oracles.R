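# Independent brute-force oracles used to freeze expected values. These stay
# deliberately naive (loops, full enumeration) and never share code with the
# implementation paths they check.

# minimal hypergeometric statistic: direct loop over cutoff depths
oracle_xlmhg_stat <- function(expr, labels, X, L) {
  ord <- order(expr, decreasing = TRUE)
  v <- expr[ord]; lab <- labels[ord]
  N <- length(v); K <- sum(lab)
  best <- 1
  b <- 0
  for (n in seq_len(N - 1)) {
    b <- b + lab[n]
    if (n > L) break
    if (v[n] > v[n + 1] && b >= X) {
      tail_p <- phyper(b - 1, K, N - K, n, lower.tail = FALSE)
      if (tail_p < best) best <- tail_p
    }
  }
  best
}

# exact XL-mHG p-value by enumerating all C(N, K) label placements over the
# sorted expression vector
oracle_xlmhg_p <- function(expr, labels, X, L) {
  v <- sort(expr, decreasing = TRUE)
  N <- length(v); K <- sum(labels)
  s_obs <- oracle_xlmhg_stat(expr, labels, X, L)
  placements <- combn(N, K)
  hits <- 0
  for (i in seq_len(ncol(placements))) {
    lab <- logical(N)
    lab[placements[, i]] <- TRUE
    s <- oracle_xlmhg_stat(v, lab, X, L)
    if (s <= s_obs * (1 + 1e-9)) hits <- hits + 1
  }
  hits / ncol(placements)
}

# exact rank AUC: concordant pairs plus half the ties, by direct pair counting
oracle_rank_auc <- function(expr, labels) {
  pos <- expr[labels]; neg <- expr[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# all monotone nonconstant boolean functions on m variables, enumerated by
# truth-table bitmask (function f: row r is true iff bit r of f is set; row
# index bit j-1 = variable j true). Monotone means no true row has a false
# superset row one bit up.
oracle_monotone_functions <- function(m) {
  nrows <- 2^m
  f <- 0:(2^nrows - 1)
  ok <- rep(TRUE, length(f))
  for (r in 0:(nrows - 1)) {
    for (j in 0:(m - 1)) {
      bit <- bitwShiftL(1L, j)
      if (bitwAnd(r, bit) == 0) {
        bad <- bitwAnd(f, bitwShiftL(1L, r)) > 0 &
          bitwAnd(f, bitwShiftL(1L, r + bit)) == 0
        ok <- ok & !bad
      }
    }
  }
  f <- f[ok]
  f[f != 0 & f != 2^nrows - 1]
}

# quadratic dominance scan for the pareto frontier
oracle_pareto <- function(sens, spec) {
  n <- length(sens)
  vapply(seq_len(n), function(i) {
    !any(sens >= sens[i] & spec >= spec[i] & (sens > sens[i] | spec > spec[i]))
  }, TRUE)
}

# small dense bundle with hand-set counts for QC / normalization tests
toy_bundle <- function(counts, species = "human", meta = NULL) {
  if (is.null(rownames(counts))) rownames(counts) <- paste0("G", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("c", seq_len(ncol(counts)))
  sample_bundle(counts, meta, species = species, sample_id = "toy")
}

# chain records helper: one row per (cell, chain, cdr3)
chain_tbl <- function(...) {
  rows <- list(...)
  tibble::tibble(
    barcode = vapply(rows, `[[`, "", 1),
    chain = vapply(rows, `[[`, "", 2),
    cdr3 = vapply(rows, `[[`, "", 3),
    productive = TRUE
  )
}
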