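#' Declarative configuration for a full benchmark run
#'
#' A single list drives the whole pipeline: the synthetic-record
#' parameters (or a WFDB directory), the trend suite, the wavelet list,
#' the level ranges, the decomposition depth, the boundary trim and the
#' seed.  `grid_config()` returns the defaults, `read_grid_config()`
#' loads a YAML file with the same keys (missing keys fall back to the
#' defaults), and `run_benchmark()` executes the configured study.
#'
#' @param n_records Number of synthetic records (ignored in WFDB mode).
#' @param duration_s,fs Record geometry.
#' @param heart_rate_bpm,rr_jitter_frac Synthetic-ECG parameters.
#' @param wavelets Wavelet identifiers to compare.
#' @param ranges List of `c(keep_lo, keep_hi)` level ranges.
#' @param n_levels Decomposition depth J.
#' @param trim_s Boundary trim in seconds.
#' @param seed Base seed; record `k` uses `seed + k - 1`.
#' @param sinusoid_freqs,trend_amplitude,trend_onset_s,spike_width_samples
#'   Trend-suite parameters (see [trend_suite()]).
#' @param qtdb_dir Optional local WFDB directory; when set, records are
#'   excerpts sampled from it instead of synthetic ECGs.
#' @param record_ids Record names to use in WFDB mode.
#' @return A named list of class `bw_config`.
#' @export
grid_config <- function(n_records = 10, duration_s = 14, fs = 250,
                        heart_rate_bpm = 60, rr_jitter_frac = 0.02,
                        wavelets = wavelet_names(),
                        ranges = list(c(1, 7), c(1, 8), c(2, 8), c(3, 8),
                                      c(1, 9), c(3, 9)),
                        n_levels = 11, trim_s = 2, seed = 1,
                        sinusoid_freqs = seq(0.05, 0.50, by = 0.05),
                        trend_amplitude = 1, trend_onset_s = 7,
                        spike_width_samples = 1,
                        qtdb_dir = NULL, record_ids = NULL) {
  structure(as.list(environment()), class = "bw_config")
}

#' @rdname grid_config
#' @param path YAML file path.
#' @export
read_grid_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Reading config files requires the `yaml` package.")
  }
  raw <- yaml::read_yaml(path)
  cfg <- grid_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "ecgbw_parameter_error")
  }
  if (!is.null(raw$ranges)) raw$ranges <- lapply(raw$ranges, unlist)
  cfg[names(raw)] <- raw
  cfg
}

#' @rdname grid_config
#' @param config A `bw_config` list.
#' @param verbose Print progress?
#' @return `run_benchmark()` returns the `bw_grid` tibble with the
#'   config attached as attribute `config`.
#' @export
run_benchmark <- function(config = grid_config(), verbose = FALSE) {
  records <- benchmark_records(config)
  trends <- trend_suite(duration_s = config$duration_s, fs = config$fs,
                        sinusoid_freqs = config$sinusoid_freqs,
                        amplitude = config$trend_amplitude,
                        onset_s = config$trend_onset_s,
                        spike_width_samples = config$spike_width_samples)
  g <- run_grid(records, config$wavelets, config$ranges, trends,
                n_levels = config$n_levels, trim_s = config$trim_s,
                verbose = verbose)
  attr(g, "config") <- config
  g
}

benchmark_records <- function(config) {
  if (!is.null(config$qtdb_dir)) {
    ids <- config$record_ids
    if (is.null(ids)) {
      ids <- unique(sub("\\.hea$", "",
                        basename(list.files(config$qtdb_dir, "\\.hea$"))))
    }
    specs <- sample_excerpts(ids, duration_s = config$duration_s,
                             seed = config$seed)
    recs <- purrr::pmap(specs, function(record_id, channel, start_s, duration_s) {
      minmax_normalize(read_wfdb_excerpt(record_id, config$qtdb_dir,
                                         channel = channel, start_s = start_s,
                                         duration_s = duration_s))
    })
    names(recs) <- specs$record_id
  } else {
    seeds <- config$seed + seq_len(config$n_records) - 1
    recs <- lapply(seeds, function(s) {
      minmax_normalize(synth_ecg(duration_s = config$duration_s,
                                 fs = config$fs,
                                 heart_rate_bpm = config$heart_rate_bpm,
                                 rr_jitter_frac = config$rr_jitter_frac,
                                 seed = s))
    })
    names(recs) <- sprintf("synthetic%03d", seq_along(recs))
  }
  recs
}
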