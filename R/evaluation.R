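#' Mean square error between two equal-length signals
#'
#' `mean((a - b)^2)` over the `M` compared samples.
#'
#' @param a,b Signal tibbles or numeric vectors of equal length.
#' @return A non-negative scalar; 0 iff the signals are identical.
#' @examples
#' mse(c(0, 0), c(1, 1))
#' @export
mse <- function(a, b) {
  va <- signal_values(a)
  vb <- signal_values(b)
  if (length(va) != length(vb)) {
    abort(sprintf("Length mismatch: %d vs %d samples.", length(va), length(vb)),
          class = "ecgbw_parameter_error")
  }
  if (length(va) < 1L) abort("Empty signals.", class = "ecgbw_parameter_error")
  mean((va - vb)^2)
}

#' Run one semi-synthetic detrending experiment
#'
#' Renders the trend, superimposes it on the normalized excerpt `x_n`,
#' detrends with the given wavelet and level range ([detrend_ecg()]),
#' and scores the result against `x_n` restricted to the same trimmed
#' window (the reference is trimmed but not renormalized -- its scale
#' was fixed once for the whole excerpt).
#'
#' @param x_n Normalized excerpt (signal tibble or numeric vector with
#'   `fs`); ground truth.
#' @param trend One-row trend specification (see [sinusoid_trend()]).
#' @inheritParams detrend_ecg
#' @param record_id Identifier copied into the result row.
#' @return A one-row tibble: `record_id`, `wavelet`, `keep_lo`,
#'   `keep_hi`, `trend_id`, `trend_kind`, `trend_freq_hz`, `mse`, `m`
#'   (number of compared samples), `error` (`NA` on success).
#' @export
run_experiment <- function(x_n, trend, wavelet = "sym3", keep_lo = 1,
                           keep_hi = 7, n_levels = 11, trim_s = 2,
                           fs = NULL, keep_smooth = FALSE,
                           record_id = NULL) {
  fs <- signal_fs(x_n, fs)
  v <- signal_values(x_n)
  duration_s <- length(v) / fs
  if (is.data.frame(trend)) trend <- as.list(trend)
  w_sig <- make_trend(trend, duration_s = duration_s, fs = fs)
  y <- superimpose(replace_values(x_n, v), w_sig)
  xprime <- detrend_ecg(y, wavelet = wavelet, keep_lo = keep_lo,
                        keep_hi = keep_hi, n_levels = n_levels,
                        trim_s = trim_s, fs = fs, keep_smooth = keep_smooth)
  n_trim <- round(trim_s * fs)
  ref <- v[(n_trim + 1):(length(v) - n_trim)]
  tibble(
    record_id = record_id %||% signal_label(x_n, "record"),
    wavelet = wavelet,
    keep_lo = as.integer(keep_lo), keep_hi = as.integer(keep_hi),
    trend_id = trend$trend_id %||% trend$kind,
    trend_kind = trend$kind,
    trend_freq_hz = trend$frequency_hz %||% NA_real_,
    mse = mse(ref, signal_values(xprime)),
    m = length(ref),
    error = NA_character_
  )
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a) &&
                                              !is.character(a))) b else a

#' Run the full wavelet x level-range x trend x record evaluation grid
#'
#' Evaluates every combination with [run_experiment()].  A failing cell
#' (e.g. a degenerate post-trim normalization) is recorded with its
#' error message rather than dropped, so summaries can count or exclude
#' it.
#'
#' @param records Named list of normalized excerpts (signal tibbles), or
#'   a single signal.  Names become `record_id`s.
#' @param wavelets Character vector of wavelet identifiers.
#' @param ranges List of `c(keep_lo, keep_hi)` pairs, or a data frame
#'   with columns `keep_lo`, `keep_hi`.
#' @param trends Trend-specification tibble (e.g. [trend_suite()]).
#' @inheritParams detrend_ecg
#' @param verbose Print one progress line per record/wavelet block?
#' @return A tibble of class `bw_grid`, one row per combination (rows =
#'   records x wavelets x ranges x trends), with the columns of
#'   [run_experiment()].
#' @examples
#' \donttest{
#' x <- minmax_normalize(synth_ecg(seed = 1))
#' g <- run_grid(list(r1 = x), "sym3", list(c(1, 7)),
#'               trend_suite()[1:2, ])
#' summarize_grid(g)
#' }
#' @export
run_grid <- function(records, wavelets, ranges, trends, n_levels = 11,
                     trim_s = 2, verbose = FALSE) {
  if (is.data.frame(records) || is.numeric(records)) records <- list(records)
  if (length(records) == 0L || length(wavelets) == 0L || length(ranges) == 0L ||
      nrow(trends) == 0L) {
    abort("All of `records`, `wavelets`, `ranges`, `trends` must be non-empty.",
          class = "ecgbw_parameter_error")
  }
  if (is.null(names(records))) {
    names(records) <- sprintf("record%02d", seq_along(records))
  }
  if (is.data.frame(ranges)) {
    ranges <- purrr::pmap(ranges[c("keep_lo", "keep_hi")], ~ c(..1, ..2))
  }
  rows <- list()
  for (rid in names(records)) {
    x_n <- records[[rid]]
    for (wv in wavelets) {
      if (verbose) message(sprintf("grid: record %s, wavelet %s", rid, wv))
      for (rg in ranges) {
        for (k in seq_len(nrow(trends))) {
          tr <- trends[k, ]
          cell <- tryCatch(
            run_experiment(x_n, tr, wavelet = wv, keep_lo = rg[1],
                           keep_hi = rg[2], n_levels = n_levels,
                           trim_s = trim_s, record_id = rid),
            error = function(e) {
              tibble(record_id = rid, wavelet = wv,
                     keep_lo = as.integer(rg[1]), keep_hi = as.integer(rg[2]),
                     trend_id = tr$trend_id, trend_kind = tr$kind,
                     trend_freq_hz = tr$frequency_hz,
                     mse = NA_real_, m = NA_integer_,
                     error = conditionMessage(e))
            }
          )
          rows[[length(rows) + 1L]] <- cell
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bw_grid", class(out))
  out
}

#' Summarize an evaluation grid
#'
#' Mean MSE per group (default: one row per wavelet x level range),
#' failed cells excluded with a warning when present.
#'
#' @param grid A `bw_grid` tibble from [run_grid()].
#' @param group_by Character vector of grouping columns.
#' @return A tibble with the grouping columns plus `mean_mse` and `n`
#'   (cells averaged).
#' @export
summarize_grid <- function(grid, group_by = c("wavelet", "keep_lo", "keep_hi")) {
  if (nrow(grid) == 0L) abort("Empty grid.", class = "ecgbw_parameter_error")
  bad <- !is.na(grid$error)
  if (any(bad)) {
    warning(sprintf("%d failed grid cell(s) excluded from the summary.", sum(bad)))
    grid <- grid[!bad, ]
  }
  grid |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(mean_mse = mean(.data$mse), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$mean_mse)
}

#' Best-performing configurations of a grid
#'
#' Returns every (wavelet, level range) group whose mean MSE lies within
#' `tol` of the minimum -- ties are reported as a set rather than broken
#' arbitrarily (db3 and sym3, being the same filter, always tie).
#'
#' @inheritParams summarize_grid
#' @param tol Absolute tie tolerance on the mean MSE.
#' @return A tibble of tied best rows, as in [summarize_grid()].
#' @export
best_configs <- function(grid, group_by = c("wavelet", "keep_lo", "keep_hi"),
                         tol = 1e-12) {
  s <- summarize_grid(grid, group_by = group_by)
  s[s$mean_mse <= min(s$mean_mse) + tol, ]
}

#' @export
tidy.bw_grid <- function(x, ...) {
  as_tibble(x)
}

#' Glance at an evaluation grid
#'
#' @param x A `bw_grid` tibble.
#' @param ... Unused.
#' @return One row: cell counts, failure count, the minimum mean MSE and
#'   the tied best configurations (comma-separated).
#' @export
glance.bw_grid <- function(x, ...) {
  best <- best_configs(x)
  tibble(
    n_cells = nrow(x),
    n_failed = sum(!is.na(x$error)),
    n_records = dplyr::n_distinct(x$record_id),
    min_mean_mse = min(best$mean_mse),
    best = paste(sprintf("%s lv%d-%d", best$wavelet, best$keep_lo,
                         best$keep_hi), collapse = ", ")
  )
}

#' Heatmap of grid MSEs (wavelet x trend, one facet per level range)
#'
#' @param object A `bw_grid` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bw_grid <- function(object, ...) {
  d <- as_tibble(object)
  d <- d[is.na(d$error), ]
  d$range <- sprintf("lv%d-%d", d$keep_lo, d$keep_hi)
  d <- d |>
    dplyr::group_by(.data$wavelet, .data$range, .data$trend_id) |>
    dplyr::summarise(mse = mean(.data$mse), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$trend_id, y = .data$wavelet,
                                  fill = .data$mse)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(ggplot2::vars(.data$range)) +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "trend", y = "wavelet", fill = "MSE") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Heatmap of mean MSE per wavelet x level range
#'
#' The summary counterpart of [autoplot.bw_grid()]: one tile per
#' (wavelet, range) showing the mean MSE across records and trends.
#'
#' @param grid A `bw_grid` tibble.
#' @return A ggplot object.
#' @export
plot_mse_heatmap <- function(grid) {
  s <- summarize_grid(grid)
  s$range <- sprintf("lv%d-%d", s$keep_lo, s$keep_hi)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$range, y = .data$wavelet,
                                  fill = .data$mean_mse)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.4f", .data$mean_mse)),
                       size = 2.6) +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "preserved level range", y = "wavelet",
                  fill = "mean MSE")
}
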