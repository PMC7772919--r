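# Minimal WFDB (PhysioNet) reader: header (.hea) parsing plus signal
# formats 212 (two 12-bit two's-complement samples packed in 3 bytes, the
# QT Database layout) and 16 (little-endian int16).  Values are converted
# to physical units as (adc - baseline) / gain.

read_wfdb_header <- function(record_id, data_dir) {
  path <- file.path(data_dir, paste0(record_id, ".hea"))
  if (!file.exists(path)) {
    abort(sprintf("WFDB header not found: %s", path), class = "ecgbw_file_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*", "", top[3])) else 250
  n_samp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- lapply(lines[1 + seq_len(n_sig)], function(ln) {
    fld <- strsplit(trimws(ln), "\\s+")[[1]]
    gain_fld <- fld[3]
    gain <- as.numeric(sub("^([-0-9.eE+]+).*", "\\1", gain_fld))
    baseline <- if (grepl("\\(", gain_fld)) {
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_fld))
    } else NA_real_
    units <- if (grepl("/", gain_fld)) sub(".*/", "", gain_fld) else "mV"
    adc_zero <- if (length(fld) >= 5) as.numeric(fld[5]) else 0
    list(file = fld[1], format = as.integer(sub("x.*", "", fld[2])),
         gain = if (is.na(gain) || gain == 0) 200 else gain,
         baseline = if (is.na(baseline)) adc_zero else baseline,
         units = units,
         description = if (length(fld) >= 9) paste(fld[-(1:8)], collapse = " ")
                       else sprintf("sig%d", length(fld)))
  })
  list(record = record_id, fs = fs, n_sig = n_sig, n_samp = n_samp,
       signals = sig)
}

decode_212 <- function(raw_bytes, n_values) {
  b <- as.integer(raw_bytes)
  n_tri <- length(b) %/% 3L
  b1 <- b[3 * seq_len(n_tri) - 2L]
  b2 <- b[3 * seq_len(n_tri) - 1L]
  b3 <- b[3 * seq_len(n_tri)]
  s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8L)   # low nibble of byte 2
  s2 <- b3 + bitwShiftL(bitwAnd(b2, 0xF0L), 4L)   # high nibble of byte 2
  v <- numeric(2L * n_tri)
  v[c(TRUE, FALSE)] <- s1
  v[c(FALSE, TRUE)] <- s2
  v <- ifelse(v > 2047, v - 4096, v)              # 12-bit two's complement
  v[seq_len(min(n_values, length(v)))]
}

encode_212 <- function(adc) {
  if (length(adc) %% 2L == 1L) adc <- c(adc, 0L)
  a <- as.integer(adc)
  if (any(a < -2048L | a > 2047L)) {
    abort("Format 212 stores 12-bit samples (-2048..2047).",
          class = "ecgbw_parameter_error")
  }
  a <- ifelse(a < 0L, a + 4096L, a)
  s1 <- a[c(TRUE, FALSE)]
  s2 <- a[c(FALSE, TRUE)]
  out <- integer(3L * length(s1))
  out[c(TRUE, FALSE, FALSE)] <- bitwAnd(s1, 0xFFL)
  out[c(FALSE, TRUE, FALSE)] <- bitwOr(bitwShiftR(s1, 8L),
                                       bitwShiftL(bitwShiftR(s2, 8L), 4L))
  out[c(FALSE, FALSE, TRUE)] <- bitwAnd(s2, 0xFFL)
  as.raw(out)
}

#' Read an excerpt of a WFDB record
#'
#' Reads `duration_s` seconds of one channel from a local WFDB record
#' (`.hea` header plus signal file, formats 212 and 16) and returns it
#' in physical units at the record's native sampling rate.  The package
#' never downloads data; point `data_dir` at a local copy of, e.g., the
#' PhysioNet QT Database.
#'
#' @param record_id Record name (header is `<record_id>.hea`).
#' @param data_dir Directory holding the WFDB files.
#' @param channel 1-based signal number (ECG records typically have 2).
#' @param start_s Window start in seconds from the beginning.
#' @param duration_s Window length in seconds (default 14).
#' @return A signal tibble with label `record_id` and attribute `fs`.
#' @export
read_wfdb_excerpt <- function(record_id, data_dir, channel = 1L,
                              start_s = 0, duration_s = 14) {
  hdr <- read_wfdb_header(record_id, data_dir)
  if (channel < 1L || channel > hdr$n_sig) {
    abort(sprintf("Channel %d out of range (record has %d).", channel,
                  hdr$n_sig), class = "ecgbw_parameter_error")
  }
  n_want <- round(duration_s * hdr$fs)
  i0 <- round(start_s * hdr$fs)
  if (!is.na(hdr$n_samp) && i0 + n_want > hdr$n_samp) {
    abort(sprintf("Window [%g, %g] s exceeds the record length (%g s).",
                  start_s, start_s + duration_s, hdr$n_samp / hdr$fs),
          class = "ecgbw_range_error")
  }
  sig <- hdr$signals[[channel]]
  sig_files <- vapply(hdr$signals, `[[`, character(1), "file")
  same <- which(sig_files == sig$file)          # channels multiplexed per file
  lane <- match(channel, same)
  n_lanes <- length(same)
  path <- file.path(data_dir, sig$file)
  if (!file.exists(path)) {
    abort(sprintf("WFDB signal file not found: %s", path),
          class = "ecgbw_file_error")
  }
  total <- n_lanes * (i0 + n_want)
  if (sig$format == 212L) {
    n_bytes <- 3L * ceiling(total / 2)
    raw_bytes <- readBin(path, "raw", n = n_bytes)
    if (length(raw_bytes) < n_bytes) {
      abort("Window extends past the end of the signal file.",
            class = "ecgbw_range_error")
    }
    all_v <- decode_212(raw_bytes, total)
  } else if (sig$format == 16L) {
    con <- file(path, "rb"); on.exit(close(con))
    all_v <- readBin(con, "integer", n = total, size = 2L, signed = TRUE,
                     endian = "little")
    if (length(all_v) < total) {
      abort("Window extends past the end of the signal file.",
            class = "ecgbw_range_error")
    }
  } else {
    abort(sprintf("Unsupported WFDB format %d (212 and 16 are supported).",
                  sig$format), class = "ecgbw_file_error")
  }
  lanes <- all_v[seq.int(lane, length(all_v), by = n_lanes)]
  adc <- lanes[(i0 + 1):(i0 + n_want)]
  ecg_signal((adc - sig$baseline) / sig$gain, fs = hdr$fs,
             label = record_id, t0 = start_s)
}

#' Write a (synthetic) WFDB record
#'
#' Digitizes one or more channels to 12-bit ADC units and writes a
#' format-212 WFDB record.  Intended for building small synthetic test
#' records shaped like the QT Database; quantization resolution is
#' `1/gain` physical units.
#'
#' @param values Numeric vector or matrix (one column per channel), in
#'   physical units.
#' @param record_id Record name.
#' @param data_dir Output directory (created if missing).
#' @param fs Sampling rate in Hz.
#' @param gain ADC gain (units per physical unit, default 200 as in the
#'   QT Database).
#' @return The record id, invisibly.
#' @export
write_wfdb <- function(values, record_id, data_dir, fs = 250, gain = 200) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  if (!dir.exists(data_dir)) dir.create(data_dir, recursive = TRUE)
  n_sig <- ncol(values)
  n_samp <- nrow(values)
  adc <- round(values * gain)
  if (any(abs(adc) > 2047)) {
    abort("Signal exceeds the 12-bit ADC range at this gain.",
          class = "ecgbw_parameter_error")
  }
  inter <- as.integer(t(adc))                    # multiplex channels
  dat <- paste0(record_id, ".dat")
  writeBin(encode_212(inter), file.path(data_dir, dat))
  hdr <- c(
    sprintf("%s %d %g %d", record_id, n_sig, fs, n_samp),
    vapply(seq_len(n_sig), function(k) {
      sprintf("%s 212 %g(0)/mV 12 0 %d 0 0 ECG%d", dat, gain,
              as.integer(adc[1, k]), k)
    }, character(1))
  )
  writeLines(hdr, file.path(data_dir, paste0(record_id, ".hea")))
  invisible(record_id)
}

#' Draw reproducible excerpt windows for a set of records
#'
#' One excerpt specification per record: the channel and window start
#' are drawn from a seeded generator, so a study over many records is
#' exactly repeatable.
#'
#' @param record_ids Character vector of record names.
#' @param duration_s Excerpt length in seconds (default 14).
#' @param record_len_s Record length in seconds (default 900, the 15-min
#'   QT Database records); starts satisfy
#'   `start_s + duration_s <= record_len_s`.
#' @param n_channels Channels to draw from (default 2).
#' @param seed Integer seed.
#' @return A tibble: `record_id`, `channel`, `start_s`, `duration_s`.
#' @export
sample_excerpts <- function(record_ids, duration_s = 14, record_len_s = 900,
                            n_channels = 2L, seed = 1L) {
  if (length(record_ids) == 0L) {
    abort("`record_ids` must be non-empty.", class = "ecgbw_parameter_error")
  }
  withr::with_seed(seed, {
    tibble(
      record_id = record_ids,
      channel = sample.int(n_channels, length(record_ids), replace = TRUE),
      start_s = runif(length(record_ids), 0, record_len_s - duration_s),
      duration_s = duration_s
    )
  })
}

#' Read and write result tables and signals as CSV
#'
#' `write_results_csv()`/`read_results_csv()` round-trip a [run_grid()]
#' table; `write_signal_csv()`/`read_signal_csv()` use the two-column
#' `t,value` signal format.
#'
#' @param grid A `bw_grid` tibble (non-empty).
#' @param path File path.
#' @return The path (writers, invisibly) or the parsed object (readers).
#' @export
write_results_csv <- function(grid, path) {
  if (nrow(grid) == 0L) abort("Empty result table.", class = "ecgbw_parameter_error")
  readr::write_csv(as_tibble(grid), path)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           record_id = "c", wavelet = "c", keep_lo = "i",
                           keep_hi = "i", trend_id = "c", trend_kind = "c",
                           trend_freq_hz = "d", mse = "d", m = "i",
                           error = "c"))
  class(out) <- c("bw_grid", class(out))
  out
}

#' @rdname write_results_csv
#' @param x A signal tibble or numeric vector.
#' @param fs Sampling rate, for bare numeric vectors.
#' @export
write_signal_csv <- function(x, path, fs = NULL) {
  v <- signal_values(x)
  fs <- signal_fs(x, fs)
  tt <- if (is.data.frame(x) && "t" %in% names(x)) x[["t"]] else (seq_along(v) - 1) / fs
  readr::write_csv(tibble(t_seconds = tt, value = v), path)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_signal_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(t_seconds = "d", value = "d"))
  if (!all(c("t_seconds", "value") %in% names(d))) {
    abort("Signal CSV needs header columns `t_seconds,value`.",
          class = "ecgbw_file_error")
  }
  dt <- median(diff(d$t_seconds))
  ecg_signal(d$value, fs = 1 / dt, label = basename(path), t0 = d$t_seconds[1])
}
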