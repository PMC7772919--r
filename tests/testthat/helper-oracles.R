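# Independent oracles used to cross-check the implementation.  These are
# literal transcriptions of the defining formulas (gather-and-sum loops),
# deliberately sharing no code with the package's frequency-domain engine.

# One MODWT filtering stage, straight from the definition:
# out[t] = sum_l taps[l] / sqrt(2) * v[(t - stride * l) mod N]
naive_modwt_filt <- function(v, taps, stride) {
  N <- length(v)
  out <- numeric(N)
  for (t in seq_len(N)) {
    acc <- 0
    for (l in seq_along(taps)) {
      acc <- acc + taps[l] / sqrt(2) * v[((t - 1 - stride * (l - 1)) %% N) + 1]
    }
    out[t] <- acc
  }
  out
}

naive_modwt <- function(x, wavelet, J) {
  f <- wavelet_filter(wavelet)
  V <- x
  W <- vector("list", J)
  for (j in seq_len(J)) {
    stride <- 2^(j - 1)
    W[[j]] <- naive_modwt_filt(V, f$wavelet, stride)
    V <- naive_modwt_filt(V, f$scaling, stride)
  }
  list(W = W, V = V)
}

naive_imodwt <- function(W, V, wavelet) {
  f <- wavelet_filter(wavelet)
  N <- length(V)
  for (j in rev(seq_along(W))) {
    stride <- 2^(j - 1)
    out <- numeric(N)
    for (t in seq_len(N)) {
      acc <- 0
      for (l in seq_along(f$scaling)) {
        idx <- ((t - 1 + stride * (l - 1)) %% N) + 1
        acc <- acc + f$wavelet[l] / sqrt(2) * W[[j]][idx] +
          f$scaling[l] / sqrt(2) * V[idx]
      }
      out[t] <- acc
    }
    V <- out
  }
  V
}

# Brute-force R-peak count: maxima above half the signal range.
count_r_peaks <- function(v, threshold = 0.5) {
  vn <- (v - min(v)) / (max(v) - min(v))
  up <- vn >= threshold
  sum(diff(c(FALSE, up)) == 1L)
}

# Naive per-group mean (list-of-rows loop, no dplyr).
naive_group_means <- function(df, keys, value = "mse") {
  key <- do.call(paste, c(df[keys], sep = "\r"))
  out <- lapply(split(df[[value]], key), mean)
  unlist(out)
}

normalized_ecg <- function(seed, duration_s = 14, fs = 250, ...) {
  minmax_normalize(synth_ecg(duration_s = duration_s, fs = fs, seed = seed, ...))
}

# Wavelets whose taps satisfy the orthonormality identities exactly
# (everything except the approximate 62-tap discrete Meyer filter).
orthogonal_wavelets <- function() setdiff(wavelet_names(), "dmey")
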