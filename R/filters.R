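#' Quadrature-mirror construction of a wavelet filter
#'
#' Derives the high-pass (wavelet) filter from an orthogonal low-pass
#' (scaling) filter by the standard alternating-flip rule
#' `g[k] = (-1)^k * h[L - 1 - k]` (k counted from 0).
#'
#' @param scaling Numeric vector of scaling-filter taps, even length >= 2.
#' @return Numeric vector of wavelet-filter taps, same length.
#' @examples
#' qmf(c(1, 1) / sqrt(2))
#' @export
qmf <- function(scaling) {
  L <- length(scaling)
  if (L == 0L) abort("Empty filter.", class = "ecgbw_parameter_error")
  if (L < 2L || L %% 2L != 0L) {
    abort("A scaling filter must have even length >= 2.",
          class = "ecgbw_parameter_error")
  }
  (-1)^(seq_len(L) - 1L) * rev(scaling)
}

#' Wavelet filter catalogue
#'
#' `wavelet_filter()` returns the scaling/wavelet filter pair for one of
#' the 14 supported orthogonal wavelets: Daubechies db1-db4, Symlets
#' sym3/sym4/sym6/sym10, Coiflets coif1-coif4, the 4-tap Fejer-Korovkin
#' filter fk4, and the 62-tap discrete Meyer approximation dmey.  Taps
#' follow the unit-energy convention (`sum(scaling) = sqrt(2)`,
#' `sum(scaling^2) = 1`) in ascending index order; the wavelet filter is
#' the quadrature mirror of the scaling filter.  db3 and sym3 are the
#' same filter and share identical taps.
#'
#' @param name One of the identifiers listed by [list_wavelets()].
#' @return An object of class `wavelet_filter`: a list with elements
#'   `name`, `scaling` and `wavelet`.
#' @examples
#' f <- wavelet_filter("db2")
#' sum(f$scaling^2)
#' @export
wavelet_filter <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.scaling_taps)) {
    abort(paste0("Unsupported wavelet '", paste(name, collapse = ","),
                 "'. Supported: ", paste(wavelet_names(), collapse = ", "), "."),
          class = "ecgbw_unsupported_wavelet")
  }
  g <- .scaling_taps[[name]]
  structure(list(name = name, scaling = g, wavelet = qmf(g)),
            class = "wavelet_filter")
}

#' @export
print.wavelet_filter <- function(x, ...) {
  cat(sprintf("<wavelet_filter %s: %d taps>\n", x$name, length(x$scaling)))
  invisible(x)
}

#' @rdname wavelet_filter
#' @export
wavelet_names <- function() {
  c("db1", "db2", "db3", "db4",
    "sym3", "sym4", "sym6", "sym10",
    "coif1", "coif2", "coif3", "coif4",
    "fk4", "dmey")
}

#' @rdname wavelet_filter
#' @return `list_wavelets()` returns a tibble with one row per supported
#'   wavelet: `wavelet`, `family` and `taps`.
#' @export
list_wavelets <- function() {
  nm <- wavelet_names()
  tibble(
    wavelet = nm,
    family = c(rep("Daubechies", 4), rep("Symlets", 4), rep("Coiflets", 4),
               "Fejer-Korovkin", "Meyer"),
    taps = vapply(nm, function(n) length(.scaling_taps[[n]]), integer(1),
                  USE.NAMES = FALSE)
  )
}
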