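#' Build an ECG signal tibble
#'
#' Signals are represented throughout the package as tibbles with a time
#' column `t` (seconds, starting at 0) and an amplitude column `value`
#' (millivolts for raw data, dimensionless after min-max normalization).
#' The sampling rate and a free-text provenance label travel along as the
#' attributes `fs` and `label`, and every function that consumes a signal
#' will also fall back to inferring `fs` from the spacing of `t`.
#'
#' @param value Numeric vector of samples; must be non-empty and finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Free-text provenance (record id, `"synthetic"`, ...).
#' @param t0 Time of the first sample in seconds.
#' @return A tibble with columns `t` and `value` and attributes `fs`,
#'   `label`.
#' @examples
#' x <- ecg_signal(sin(2 * pi * 1 * (0:249) / 250), fs = 250)
#' signal_fs(x)
#' @export
ecg_signal <- function(value, fs, label = NULL, t0 = 0) {
  check_samples(value)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).", class = "ecgbw_parameter_error")
  }
  out <- tibble(t = t0 + (seq_along(value) - 1) / fs, value = as.numeric(value))
  attr(out, "fs") <- fs
  attr(out, "label") <- label
  class(out) <- c("ecg_signal", class(out))
  out
}

check_samples <- function(value, arg = "value") {
  if (length(value) == 0L) {
    abort(sprintf("`%s` must contain at least one sample.", arg),
          class = "ecgbw_parameter_error")
  }
  if (!is.numeric(value) || anyNA(value) || any(!is.finite(value))) {
    abort(sprintf("`%s` must be numeric with no missing or non-finite values.", arg),
          class = "ecgbw_parameter_error")
  }
  invisible(value)
}

#' Extract sample values and sampling rate from a signal
#'
#' Accepts either a signal tibble (columns `t`, `value`) or a bare numeric
#' vector plus an explicit `fs`.
#'
#' @param x Signal tibble or numeric vector.
#' @param fs Sampling rate override; required when `x` is a bare vector
#'   and no `fs` attribute is present.
#' @return For `signal_values()` a numeric vector, for `signal_fs()` the
#'   sampling rate in Hz.
#' @export
signal_values <- function(x) {
  if (is.data.frame(x)) {
    if (!"value" %in% names(x)) {
      abort("A signal data frame needs a `value` column.", class = "ecgbw_parameter_error")
    }
    return(as.numeric(x[["value"]]))
  }
  as.numeric(x)
}

#' @rdname signal_values
#' @export
signal_fs <- function(x, fs = NULL) {
  if (!is.null(fs)) return(fs)
  a <- attr(x, "fs")
  if (!is.null(a)) return(a)
  if (is.data.frame(x) && "t" %in% names(x) && nrow(x) >= 2L) {
    dt <- median(diff(x[["t"]]))
    if (is.finite(dt) && dt > 0) return(1 / dt)
  }
  abort("Sampling rate unknown: pass `fs` or use a signal tibble with a `t` column.",
        class = "ecgbw_parameter_error")
}

signal_label <- function(x, default = NULL) {
  a <- attr(x, "label")
  if (is.null(a)) default else a
}

#' Min-max normalize a signal to [0, 1]
#'
#' Rescales a signal so that its minimum maps to 0 and its maximum to 1:
#' `(x - min(x)) / (max(x) - min(x))`.  This is how every ECG excerpt is
#' put on a common amplitude scale before a trend is added, and how the
#' detrended signal is put back on that scale afterwards.
#'
#' @param x Signal tibble or numeric vector.
#' @return Same shape as the input, normalized.  A constant signal has no
#'   range to normalize over and raises a degenerate-signal error.
#' @examples
#' minmax_normalize(c(0, 5, 10))
#' @export
minmax_normalize <- function(x) {
  v <- signal_values(x)
  check_samples(v, "x")
  if (length(v) < 2L) {
    abort("Need at least two samples to normalize.", class = "ecgbw_parameter_error")
  }
  rng <- range(v)
  if (rng[2] <= rng[1]) {
    abort("Degenerate signal: max equals min, cannot min-max normalize.",
          class = "ecgbw_degenerate_error")
  }
  vn <- (v - rng[1]) / (rng[2] - rng[1])
  replace_values(x, vn)
}

replace_values <- function(x, v) {
  if (is.data.frame(x)) {
    x[["value"]] <- v
    x
  } else {
    v
  }
}

#' Superimpose a baseline wander on a normalized ECG
#'
#' Elementwise sum `y[t] = x_n[t] + w[t]` of a (normalized) ECG excerpt and
#' an artificial trend sampled on the same grid.
#'
#' @param x_n Signal tibble or numeric vector (the clean excerpt).
#' @param w Signal of identical length and sampling rate (the trend).
#' @return A signal of the same shape as `x_n`; when both inputs carry
#'   labels the result's label records both parents.
#' @export
superimpose <- function(x_n, w) {
  a <- signal_values(x_n)
  b <- signal_values(w)
  if (length(a) != length(b)) {
    abort(sprintf("Length mismatch: %d vs %d samples.", length(a), length(b)),
          class = "ecgbw_parameter_error")
  }
  fa <- tryCatch(signal_fs(x_n), error = function(e) NULL)
  fb <- tryCatch(signal_fs(w), error = function(e) NULL)
  if (!is.null(fa) && !is.null(fb) && abs(fa - fb) > 1e-9 * fa) {
    abort(sprintf("Sampling rate mismatch: %g vs %g Hz.", fa, fb),
          class = "ecgbw_parameter_error")
  }
  out <- replace_values(x_n, a + b)
  la <- signal_label(x_n); lb <- signal_label(w)
  if (!is.null(la) || !is.null(lb)) {
    attr(out, "label") <- paste(c(la, lb), collapse = " + ")
  }
  out
}
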