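#' Resampling parameters
#'
#' @param B iterations (study default 10,000).
#' @param ci percentile pair for the confidence interval (default 2.5/97.5).
#' @param seed RNG seed.
#' @return A `tm_resampling_params` list.
#' @export
resampling_params <- function(B = 10000, ci = c(2.5, 97.5), seed = 0) {
  stopifnot(B >= 1, length(ci) == 2, ci[1] >= 0, ci[1] < ci[2], ci[2] <= 100)
  structure(list(B = as.integer(B), ci = ci, seed = seed),
            class = "tm_resampling_params")
}

resample_stat <- function(data, statistic, n, max_fail) {
  fails <- 0L
  repeat {
    idx <- sample.int(n, n, replace = TRUE)
    val <- statistic(data[idx, , drop = FALSE])
    if (is.finite(val)) return(list(val = val, fails = fails))
    fails <- fails + 1L
    if (fails > max_fail) {
      stop_input("statistic undefined on more than 10% of resamples")
    }
  }
}

#' Percentile bootstrap confidence interval for a gate or marker statistic
#'
#' Cells are resampled with replacement (same size) `B` times and the
#' statistic recomputed with all thresholds held fixed; the CI spans the
#' requested percentiles of the bootstrap distribution. Resamples on which the
#' statistic is undefined (e.g. a missing class; signalled by returning `NA`)
#' are redrawn and logged, keeping exactly `B` valid iterations.
#'
#' @param data data frame with one row per cell (expression columns plus a
#'   label column, as the statistic requires).
#' @param statistic function of such a data frame returning one number.
#' @param params a [resampling_params()] block.
#' @param name label for the statistic in the output.
#' @return A `tm_resampling` object; see [tidy.tm_resampling()].
#' @export
bootstrap_ci <- function(data, statistic, params = resampling_params(),
                         name = "statistic") {
  data <- as.data.frame(data)
  n <- nrow(data)
  point <- statistic(data)
  if (!is.finite(point)) stop_input("statistic undefined on the observed data")
  max_fail <- ceiling(0.1 * params$B)
  draws <- numeric(params$B)
  fails <- 0L
  withr::with_seed(params$seed, {
    for (b in seq_len(params$B)) {
      r <- resample_stat(data, statistic, n, max_fail - fails)
      draws[b] <- r$val
      fails <- fails + r$fails
    }
  })
  ci <- unname(quantile(draws, params$ci / 100, type = 7))
  if (point < ci[1] || point > ci[2]) {
    warn("percentile CI excludes the point estimate")
  }
  structure(
    list(name = name, point = point, ci_lo = ci[1], ci_hi = ci[2],
         B = params$B, seed = params$seed, redraws = fails,
         boot_draws = draws, empirical_p = NA_real_, p_bound = FALSE,
         null_draws = NULL),
    class = "tm_resampling"
  )
}

#' Permutation empirical p-value for a gate or marker statistic
#'
#' Each of the `B` null iterations resamples cells with replacement and then
#' permutes the TM labels within the resample; the empirical p-value is the
#' fraction of null statistics at least as large as the observed point
#' estimate (one-sided: larger statistic = better marker). When the observed
#' value is never reached, the bound `< 1/B` is reported instead of zero
#' (with `B = 10000`, "< 0.0001").
#'
#' @inheritParams bootstrap_ci
#' @param label_col label column permuted under the null (default `"is_tm"`).
#' @return A `tm_resampling` object; see [tidy.tm_resampling()].
#' @export
permutation_p <- function(data, statistic, params = resampling_params(),
                          label_col = "is_tm", name = "statistic") {
  data <- as.data.frame(data)
  if (!label_col %in% names(data)) stop_input("label column not found: ", label_col)
  n <- nrow(data)
  point <- statistic(data)
  if (!is.finite(point)) stop_input("statistic undefined on the observed data")
  max_fail <- ceiling(0.1 * params$B)
  draws <- numeric(params$B)
  fails <- 0L
  withr::with_seed(params$seed, {
    for (b in seq_len(params$B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        d <- data[idx, , drop = FALSE]
        d[[label_col]] <- d[[label_col]][sample.int(n)]
        val <- statistic(d)
        if (is.finite(val)) break
        fails <- fails + 1L
        if (fails > max_fail) {
          stop_input("statistic undefined on more than 10% of resamples")
        }
      }
      draws[b] <- val
    }
  })
  count <- sum(draws >= point)
  structure(
    list(name = name, point = point, ci_lo = NA_real_, ci_hi = NA_real_,
         B = params$B, seed = params$seed, redraws = fails,
         boot_draws = NULL,
         empirical_p = if (count == 0) 1 / params$B else count / params$B,
         p_bound = count == 0,
         null_draws = draws),
    class = "tm_resampling"
  )
}

#' Combined bootstrap CI and permutation p for one statistic
#'
#' @inheritParams permutation_p
#' @return A `tm_resampling` object carrying both the CI and the empirical p.
#' @export
resampling_summary <- function(data, statistic, params = resampling_params(),
                               label_col = "is_tm", name = "statistic") {
  seeds <- split_seed(params$seed, 2)
  ci <- bootstrap_ci(data, statistic,
                     resampling_params(params$B, params$ci, seeds[1]), name)
  pp <- permutation_p(data, statistic,
                      resampling_params(params$B, params$ci, seeds[2]),
                      label_col, name)
  ci$empirical_p <- pp$empirical_p
  ci$p_bound <- pp$p_bound
  ci$null_draws <- pp$null_draws
  ci
}

format_empirical_p <- function(x) {
  if (x$p_bound) paste0("< ", format(1 / x$B, scientific = FALSE)) else
    format(x$empirical_p, scientific = FALSE)
}

#' @export
print.tm_resampling <- function(x, ...) {
  cat("<tm_resampling> ", x$name, ": ", signif(x$point, 4), sep = "")
  if (is.finite(x$ci_lo)) {
    cat(" [", signif(x$ci_lo, 4), ", ", signif(x$ci_hi, 4), "]", sep = "")
  }
  if (!is.na(x$empirical_p)) cat("  empirical p ", format_empirical_p(x), sep = "")
  cat("  (B = ", x$B, ")\n", sep = "")
  invisible(x)
}
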