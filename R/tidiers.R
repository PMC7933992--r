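#' Tidy the ROC points of an AUC grid
#'
#' @param x a `tm_roc` from [auc_grid()].
#' @param ... unused.
#' @return A tibble of (1 - specificity, sensitivity) points.
#' @method tidy tm_roc
#' @export
tidy.tm_roc <- function(x, ...) x$roc_points

#' One-row summary of an AUC grid
#'
#' @param x a `tm_roc` from [auc_grid()].
#' @param ... unused.
#' @return A one-row tibble: `gene`, `direction`, `auc`, `n_thresholds`,
#'   `n_tm`, `n`.
#' @method glance tm_roc
#' @export
glance.tm_roc <- function(x, ...) {
  tibble::tibble(gene = x$gene, direction = x$direction, auc = x$auc,
                 n_thresholds = length(x$thresholds), n_tm = x$n_tm, n = x$n)
}

#' Plot the ROC curve of an AUC grid
#'
#' @param object a `tm_roc` from [auc_grid()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot tm_roc
#' @export
autoplot.tm_roc <- function(object, ...) {
  ggplot(object$roc_points, aes(x = .data$fpr, y = .data$sens)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    geom_step(colour = "#2166AC") +
    geom_point(size = 0.8, colour = "#2166AC") +
    labs(x = "1 - specificity", y = "sensitivity",
         title = if (!is.na(object$gene)) {
           sprintf("%s (%s): AUC = %.3f", object$gene, object$direction, object$auc)
         } else sprintf("AUC = %.3f", object$auc)) +
    coord_equal() +
    theme_minimal()
}

#' Tidy a resampling summary
#'
#' @param x a `tm_resampling` from [bootstrap_ci()], [permutation_p()] or
#'   [resampling_summary()].
#' @param ... unused.
#' @return A one-row tibble: `statistic`, `estimate`, `ci_lo`, `ci_hi`,
#'   `empirical_p`, `p_bound`, `p_label`, `B`.
#' @method tidy tm_resampling
#' @export
tidy.tm_resampling <- function(x, ...) {
  tibble::tibble(statistic = x$name, estimate = x$point,
                 ci_lo = x$ci_lo, ci_hi = x$ci_hi,
                 empirical_p = x$empirical_p, p_bound = x$p_bound,
                 p_label = if (is.na(x$empirical_p)) NA_character_ else format_empirical_p(x),
                 B = x$B)
}

#' One-row run description of a resampling summary
#'
#' @inheritParams tidy.tm_resampling
#' @return A one-row tibble: `B`, `seed`, `redraws`.
#' @method glance tm_resampling
#' @export
glance.tm_resampling <- function(x, ...) {
  tibble::tibble(B = x$B, seed = x$seed, redraws = x$redraws)
}

#' Plot the resampling distribution with the observed value
#'
#' Shows the permutation null (when present, with the observed point estimate
#' as a vertical line) or otherwise the bootstrap distribution with its CI.
#'
#' @param object a `tm_resampling`.
#' @param bins histogram bins.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot tm_resampling
#' @export
autoplot.tm_resampling <- function(object, bins = 50, ...) {
  draws <- object$null_draws %||% object$boot_draws
  kind <- if (!is.null(object$null_draws)) "permutation null" else "bootstrap"
  p <- ggplot(tibble::tibble(draw = draws), aes(x = .data$draw)) +
    geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$point, colour = "#B2182B", linewidth = 0.8) +
    labs(x = object$name, y = "iterations",
         title = sprintf("%s: %s distribution (B = %d)", object$name, kind, object$B)) +
    theme_minimal()
  if (is.finite(object$ci_lo) && kind == "bootstrap") {
    p <- p + geom_vline(xintercept = c(object$ci_lo, object$ci_hi),
                        linetype = "dashed", colour = "#B2182B")
  }
  p
}

#' Plot gate evaluations in sensitivity/specificity space
#'
#' Pareto-optimal gates are highlighted and connected as a staircase; the
#' penalty-minimizing gate is labelled.
#'
#' @param object a `tm_gate_evals` tibble from [evaluate_gates()].
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot tm_gate_evals
#' @export
autoplot.tm_gate_evals <- function(object, ...) {
  d <- tibble::as_tibble(object)
  best <- select_best_gate(d)
  frontier <- dplyr::arrange(d[d$pareto, ], .data$sensitivity)
  ggplot(d, aes(x = .data$sensitivity, y = .data$specificity)) +
    geom_point(aes(colour = .data$pareto), alpha = 0.8) +
    geom_step(data = frontier, direction = "vh", colour = "#B2182B") +
    geom_point(data = best, shape = 21, size = 3, stroke = 1.1,
               colour = "black", fill = "#B2182B") +
    geom_text(data = best, aes(label = .data$gate), vjust = -1, size = 3) +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#B2182B"),
                        name = "pareto") +
    coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "sensitivity", y = "specificity") +
    theme_minimal()
}
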