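#' Zero MODWT coefficient levels outside a kept range
#'
#' Keeps detail levels `keep_lo..keep_hi` untouched and zeroes every
#' other detail vector.  The final scaling (smooth) vector `V_J` is also
#' zeroed unless `keep_smooth = TRUE`: the smooth holds the DC and
#' slowest trend content, so a detrending range such as "levels 1-7 of
#' 11" must discard it, otherwise the baseline wander survives
#' reconstruction.  The field's shorthand "lvA-B" corresponds to
#' `keep_lo = A, keep_hi = B, keep_smooth = FALSE`.
#'
#' @param w A [modwt()] object (not mutated).
#' @param keep_lo,keep_hi Inclusive detail-level range to preserve,
#'   `1 <= keep_lo <= keep_hi <= w$n_levels`.
#' @param keep_smooth Preserve `V_J`?
#' @return A new `modwt` object.
#' @export
zero_levels <- function(w, keep_lo, keep_hi, keep_smooth = FALSE) {
  check_modwt(w)
  check_level_range(keep_lo, keep_hi, w$n_levels)
  w2 <- w
  drop <- setdiff(seq_len(w$n_levels), seq.int(keep_lo, keep_hi))
  if (length(drop)) w2$W[, drop] <- 0
  if (!keep_smooth) w2$V[] <- 0
  w2
}

check_level_range <- function(keep_lo, keep_hi, J) {
  ok <- length(keep_lo) == 1L && length(keep_hi) == 1L &&
    keep_lo >= 1 && keep_hi <= J && keep_lo <= keep_hi
  if (!ok) {
    abort(sprintf("Invalid level range [%s, %s] for a depth-%d transform.",
                  toString(keep_lo), toString(keep_hi), J),
          class = "ecgbw_parameter_error")
  }
  invisible(TRUE)
}

#' Remove baseline wander by level-selective MODWT reconstruction
#'
#' The detrending pipeline: decompose with [modwt()], zero every detail
#' level outside `keep_lo..keep_hi` plus the smooth ([zero_levels()]),
#' invert, drop the first and last `trim_s` seconds (circular filtering
#' distorts the record edges), and min-max renormalize the retained
#' window back to `[0, 1]`.
#'
#' @param y Signal tibble or numeric vector (the contaminated ECG).
#' @param wavelet Wavelet identifier.
#' @param keep_lo,keep_hi Detail-level range to preserve (default
#'   "lv1-7", which at 250 Hz and J = 11 removes everything below
#'   ~0.98 Hz).
#' @param n_levels Decomposition depth J (default 11, the maximum for a
#'   3500-sample record).
#' @param trim_s Seconds discarded at each end (default 2).
#' @param fs Sampling rate; inferred from a signal tibble.
#' @param keep_smooth Preserve the scaling vector (default `FALSE`; see
#'   [zero_levels()]).
#' @param renormalize Min-max normalize the trimmed result (default
#'   `TRUE`).  A constant post-trim signal cannot be renormalized and
#'   raises a degenerate-signal error.
#' @return A signal tibble covering `[trim_s, duration - trim_s)`;
#'   for a 14-s, 250-Hz record exactly 2500 samples.
#' @examples
#' x <- minmax_normalize(synth_ecg(seed = 1))
#' y <- superimpose(x, make_trend(sinusoid_trend(0.3), 14, 250))
#' d <- detrend_ecg(y, "sym3")
#' nrow(d)
#' @export
detrend_ecg <- function(y, wavelet = "sym3", keep_lo = 1, keep_hi = 7,
                        n_levels = 11, trim_s = 2, fs = NULL,
                        keep_smooth = FALSE, renormalize = TRUE) {
  fs <- signal_fs(y, fs)
  v <- signal_values(y)
  n_trim <- round(trim_s * fs)
  if (length(v) <= 2 * n_trim + 2) {
    abort("Record too short for the requested trim.",
          class = "ecgbw_parameter_error")
  }
  w <- modwt(v, wavelet, n_levels = n_levels, fs = fs)
  xr <- signal_values(imodwt(zero_levels(w, keep_lo, keep_hi,
                                         keep_smooth = keep_smooth)))
  kept <- if (n_trim > 0) xr[(n_trim + 1):(length(xr) - n_trim)] else xr
  if (renormalize) kept <- minmax_normalize(kept)
  ecg_signal(kept, fs = fs, label = signal_label(y, "detrended"),
             t0 = n_trim / fs)
}

#' Extract the baseline wander estimated by a level range
#'
#' Reconstructs from exactly the coefficients that [detrend_ecg()] with
#' the same range discards: the zeroed detail levels plus the smooth.
#' By linearity, the extracted trend plus the (untrimmed, unnormalized)
#' detrended reconstruction equals the input.
#'
#' @inheritParams detrend_ecg
#' @return An untrimmed, unnormalized signal tibble of the same length
#'   as `y`.
#' @export
extract_trend <- function(y, wavelet = "sym3", keep_lo = 1, keep_hi = 7,
                          n_levels = 11, fs = NULL) {
  fs <- signal_fs(y, fs)
  v <- signal_values(y)
  w <- modwt(v, wavelet, n_levels = n_levels, fs = fs)
  check_level_range(keep_lo, keep_hi, w$n_levels)
  dropped <- setdiff(seq_len(w$n_levels), seq.int(keep_lo, keep_hi))
  tr <- signal_values(reconstruct_levels(w, dropped, include_smooth = TRUE))
  ecg_signal(tr, fs = fs, label = "extracted trend")
}

#' Locate an impulse edge from the level-1 detail reconstruction
#'
#' The finest MODWT level responds most strongly to the steepest
#' transition in the record, so the global argmax of the absolute
#' level-1 reconstruction localizes a voltage spike (when one dominates)
#' or otherwise the sharpest QRS slope.  No detection threshold is
#' applied; the argmax is always returned, ties broken toward the
#' earliest sample.
#'
#' @param y Signal tibble or numeric vector.
#' @param wavelet Wavelet identifier (default `"db1"`, whose two-tap
#'   response pins the impulse most tightly).
#' @param fs Sampling rate; inferred from a signal tibble.
#' @return A one-row tibble: `sample` (1-based index), `t` (seconds),
#'   `magnitude` (absolute level-1 response at the argmax).
#' @export
locate_spike <- function(y, wavelet = "db1", fs = NULL) {
  v <- signal_values(y)
  check_samples(v, "y")
  if (max(v) <= min(v)) {
    abort("Constant signal: nothing to localize.",
          class = "ecgbw_degenerate_error")
  }
  fs <- tryCatch(signal_fs(y, fs), error = function(e) NULL)
  w <- modwt(v, wavelet, n_levels = 1)
  d1 <- signal_values(reconstruct_levels(w, 1L, include_smooth = FALSE))
  idx <- which.max(abs(d1))
  tibble(sample = idx,
         t = if (is.null(fs)) NA_real_ else (idx - 1) / fs,
         magnitude = abs(d1)[idx])
}
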