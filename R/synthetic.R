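#' Default P-QRS-T morphology for the synthetic ECG generator
#'
#' Each beat of the synthetic ECG is a sum of five Gaussian bumps placed
#' relative to the R-peak time.  Centers and widths are in seconds,
#' amplitudes in millivolts; the defaults give a dominant R peak, a T
#' wave as the second-largest deflection, and realistic P/Q/S sizes.
#'
#' @param wave,center_s,width_s,amplitude Vectors of equal length
#'   describing the Gaussian bumps.
#' @return A tibble with one row per wave.
#' @export
ecg_morphology <- function(wave = c("P", "Q", "R", "S", "T"),
                           center_s = c(-0.200, -0.032, 0, 0.032, 0.250),
                           width_s = c(0.045, 0.010, 0.014, 0.011, 0.060),
                           amplitude = c(0.12, -0.12, 1.00, -0.22, 0.28)) {
  tibble(wave = wave, center_s = center_s, width_s = width_s,
         amplitude = amplitude)
}

#' Generate a synthetic ECG excerpt
#'
#' Produces a trend-free beat train: R-peak times advance by
#' `60 / heart_rate_bpm` seconds, each interval scaled by
#' `1 + uniform(-rr_jitter_frac, rr_jitter_frac)`, and each beat adds the
#' five Gaussian bumps of `morphology`.  The output is deterministic for
#' a fixed `seed` and contains no additive baseline trend, so it serves
#' as ground truth in semi-synthetic detrending experiments.
#'
#' @param duration_s Excerpt length in seconds (> 0).
#' @param fs Sampling rate in Hz (>= 100).
#' @param heart_rate_bpm Mean heart rate, 30-200 beats/min.
#' @param rr_jitter_frac Fractional beat-to-beat R-R variation in
#'   `[0, 0.2)`.
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param morphology Tibble from [ecg_morphology()].
#' @return A signal tibble of `round(duration_s * fs)` samples with
#'   label `"synthetic"`.
#' @examples
#' x <- synth_ecg(seed = 1)
#' nrow(x)  # 3500 samples at 14 s, 250 Hz
#' @export
synth_ecg <- function(duration_s = 14, fs = 250, heart_rate_bpm = 60,
                      rr_jitter_frac = 0.02, seed = NULL,
                      morphology = ecg_morphology()) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be > 0.", class = "ecgbw_parameter_error")
  }
  if (fs < 100) abort("`fs` must be >= 100 Hz.", class = "ecgbw_parameter_error")
  if (heart_rate_bpm < 30 || heart_rate_bpm > 200) {
    abort("`heart_rate_bpm` must be in [30, 200].", class = "ecgbw_parameter_error")
  }
  if (rr_jitter_frac < 0 || rr_jitter_frac >= 0.2) {
    abort("`rr_jitter_frac` must be in [0, 0.2).", class = "ecgbw_parameter_error")
  }
  n <- round(duration_s * fs)
  tgrid <- (seq_len(n) - 1) / fs
  rr0 <- 60 / heart_rate_bpm
  n_beats <- ceiling(duration_s / rr0) + 3L
  gen <- function() {
    jit <- runif(n_beats, -rr_jitter_frac, rr_jitter_frac)
    cumsum(rr0 * (1 + jit)) - rr0 / 2
  }
  r_times <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  # beats whose support can overlap the record (bumps span ~+-0.5 s)
  r_times <- r_times[r_times > -0.6 & r_times < duration_s + 0.6]
  v <- numeric(n)
  for (r in r_times) {
    for (k in seq_len(nrow(morphology))) {
      mu <- r + morphology$center_s[k]
      v <- v + morphology$amplitude[k] *
        exp(-((tgrid - mu)^2) / (2 * morphology$width_s[k]^2))
    }
  }
  ecg_signal(v, fs = fs, label = "synthetic")
}

#' Artificial baseline-wander specifications
#'
#' Trend specifications are rows of a tibble with columns `trend_id`,
#' `kind` (`"sinusoid"`, `"step"` or `"spike"`), `frequency_hz`,
#' `amplitude`, `phase_rad`, `onset_s`, `width_samples`; irrelevant
#' fields are `NA`.  [make_trend()] renders one specification into a
#' sampled signal `w[t]`:
#' \itemize{
#'   \item sinusoid: `amplitude * sin(2 * pi * frequency_hz * t + phase_rad)`
#'   \item step: 0 before `onset_s`, `amplitude` from `onset_s` on
#'   \item spike: `amplitude` on exactly `width_samples` consecutive
#'     samples starting at `onset_s`, 0 elsewhere
#' }
#'
#' @param frequency_hz Sinusoid frequency in Hz (must stay below fs/2).
#' @param amplitude Trend amplitude, in the units of the signal it will
#'   be added to.
#' @param phase_rad Sinusoid phase in radians.
#' @param onset_s Step/spike onset in seconds from record start.
#' @param width_samples Spike width in samples (>= 1).
#' @param trend_id Identifier carried into result tables.
#' @return A one-row specification tibble.
#' @export
sinusoid_trend <- function(frequency_hz, amplitude = 1, phase_rad = 0,
                           trend_id = sprintf("sin_%.2fHz", frequency_hz)) {
  tibble(trend_id = trend_id, kind = "sinusoid", frequency_hz = frequency_hz,
         amplitude = amplitude, phase_rad = phase_rad, onset_s = NA_real_,
         width_samples = NA_integer_)
}

#' @rdname sinusoid_trend
#' @export
step_trend <- function(onset_s = 7, amplitude = 1, trend_id = "step") {
  tibble(trend_id = trend_id, kind = "step", frequency_hz = NA_real_,
         amplitude = amplitude, phase_rad = NA_real_, onset_s = onset_s,
         width_samples = NA_integer_)
}

#' @rdname sinusoid_trend
#' @export
spike_trend <- function(onset_s = 7, amplitude = 1, width_samples = 1L,
                        trend_id = "spike") {
  tibble(trend_id = trend_id, kind = "spike", frequency_hz = NA_real_,
         amplitude = amplitude, phase_rad = NA_real_, onset_s = onset_s,
         width_samples = as.integer(width_samples))
}

#' The twelve-trend benchmark suite
#'
#' Ten unit-amplitude, zero-phase sinusoids on the uniform grid 0.05,
#' 0.10, ..., 0.50 Hz plus one step and one single-sample spike, both of
#' unit amplitude with onset at mid-record (7 s for the default 14-s
#' excerpt).  At 250 Hz every sinusoid in the suite lies below 1 Hz,
#' i.e. entirely inside MODWT levels 8 and above -- the band a
#' level-selective detrender zeroes.
#'
#' @param duration_s Record duration the suite is meant for (>= 14
#'   recommended); onsets must fall inside it.
#' @param fs Sampling rate in Hz.
#' @param sinusoid_freqs Frequencies of the sinusoidal trends, Hz.
#' @param amplitude Common trend amplitude.
#' @param onset_s Onset of the step and spike trends, seconds.
#' @param spike_width_samples Spike width, samples.
#' @return A 12-row trend-specification tibble.
#' @export
trend_suite <- function(duration_s = 14, fs = 250,
                        sinusoid_freqs = seq(0.05, 0.50, by = 0.05),
                        amplitude = 1, onset_s = 7,
                        spike_width_samples = 1L) {
  if (onset_s < 0 || onset_s >= duration_s) {
    abort("`onset_s` must lie inside the record.", class = "ecgbw_parameter_error")
  }
  dplyr::bind_rows(
    purrr::map(sinusoid_freqs, sinusoid_trend, amplitude = amplitude),
    step_trend(onset_s = onset_s, amplitude = amplitude),
    spike_trend(onset_s = onset_s, amplitude = amplitude,
                width_samples = spike_width_samples)
  )
}

#' @rdname sinusoid_trend
#' @param spec A one-row specification tibble (or a list with the same
#'   fields).
#' @param duration_s Record duration in seconds.
#' @param fs Sampling rate in Hz.
#' @return `make_trend()` returns a signal tibble of
#'   `round(duration_s * fs)` samples labelled by `trend_id`.
#' @examples
#' w <- make_trend(sinusoid_trend(0.05), duration_s = 14, fs = 250)
#' max(abs(w$value))
#' @export
make_trend <- function(spec, duration_s, fs) {
  if (is.data.frame(spec)) {
    if (nrow(spec) != 1L) {
      abort("`spec` must be a single trend specification (one row).",
            class = "ecgbw_parameter_error")
    }
    spec <- as.list(spec)
  }
  n <- round(duration_s * fs)
  tgrid <- (seq_len(n) - 1) / fs
  v <- switch(
    spec$kind,
    sinusoid = {
      f <- spec$frequency_hz
      if (!is.finite(f) || f <= 0 || f >= fs / 2) {
        abort("Sinusoid frequency must lie in (0, fs/2).",
              class = "ecgbw_parameter_error")
      }
      spec$amplitude * sin(2 * pi * f * tgrid + spec$phase_rad)
    },
    step = {
      check_onset(spec$onset_s, duration_s)
      ifelse(tgrid >= spec$onset_s, spec$amplitude, 0)
    },
    spike = {
      check_onset(spec$onset_s, duration_s)
      wdt <- spec$width_samples
      if (!is.finite(wdt) || wdt < 1L) {
        abort("Spike width must be >= 1 sample.", class = "ecgbw_parameter_error")
      }
      i0 <- round(spec$onset_s * fs) + 1L
      idx <- i0:min(i0 + wdt - 1L, n)
      v <- numeric(n)
      v[idx] <- spec$amplitude
      v
    },
    abort(sprintf("Unknown trend kind '%s'.", spec$kind),
          class = "ecgbw_parameter_error")
  )
  ecg_signal(v, fs = fs,
             label = if (!is.null(spec$trend_id)) spec$trend_id else spec$kind)
}

check_onset <- function(onset_s, duration_s) {
  if (!is.finite(onset_s) || onset_s < 0 || onset_s >= duration_s) {
    abort("Trend onset must lie within [0, duration).",
          class = "ecgbw_parameter_error")
  }
  invisible(onset_s)
}
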