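stop_input <- function(...) abort(paste0(...), class = "tmcell_input_error")
stop_format <- function(...) abort(paste0(...), class = "tmcell_format_error")
stop_config <- function(...) abort(paste0(...), class = "tmcell_config_error")

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop_input(name, " must lie in [0, 1]")
  }
  invisible(x)
}

# Derive independent child seeds from one user seed; kept below 2^31 so the
# values are valid R integers.
split_seed <- function(seed, n) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max,
                   sample.int(.Machine$integer.max - 1L, n))
}

trapezoid <- function(x, y) {
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}
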