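test_that("the transform agrees with a literal gather-and-sum oracle", {
  set.seed(11)
  x <- rnorm(64)
  for (nm in c("db2", "fk4", "sym4")) {
    w <- modwt(x, nm, n_levels = 3)
    o <- naive_modwt(x, nm, 3)
    for (j in 1:3) {
      expect_equal(w$W[, j], o$W[[j]], tolerance = 1e-12,
                   label = paste(nm, "level", j))
    }
    expect_equal(w$V, o$V, tolerance = 1e-12)
    # and the inverse agrees with the naive synthesis loop
    expect_equal(signal_values(imodwt(w)), naive_imodwt(o$W, o$V, nm),
                 tolerance = 1e-11)
  }
})

test_that("a constant signal is annihilated by every detail filter", {
  x <- rep(3.7, 64)
  for (nm in orthogonal_wavelets()) {
    w <- modwt(x, nm, n_levels = 3)
    expect_lt(max(abs(w$W)), 1e-11)
    expect_equal(w$V, x, tolerance = 1e-10, ignore_attr = TRUE)
  }
  # dmey only annihilates constants to its FIR-approximation accuracy
  wd <- modwt(x, "dmey", n_levels = 3)
  expect_lt(max(abs(wd$W)), 3.7 * 5e-3)
})

test_that("the Haar level-1 detail of an impulse is the hand-computed circular difference", {
  w <- modwt(c(1, 0, 0, 0), "db1", n_levels = 1)
  # W1[t] = (x[t] - x[t-1]) / 2 with circular wrap
  expect_equal(w$W[, 1], c(0.5, -0.5, 0, 0), tolerance = 1e-14)
  expect_equal(w$V, c(0.5, 0.5, 0, 0), tolerance = 1e-14)
})

test_that("roundtrip and energy identities hold across lengths and depths", {
  set.seed(5)
  for (N in c(64, 1000)) {
    x <- rnorm(N)
    for (nm in c("db1", "db3", "db4", "sym10", "coif4", "fk4")) {
      J <- floor(log2(N))
      w <- modwt(x, nm, n_levels = J)
      expect_lt(max(abs(signal_values(imodwt(w)) - x)), 1e-9 * max(abs(x)))
      energy <- sum(w$W^2) + sum(w$V^2)
      expect_lt(abs(energy - sum(x^2)) / sum(x^2), 1e-8)
    }
  }
})

test_that("the transform is equivariant under circular shifts", {
  set.seed(6)
  x <- rnorm(128)
  shift <- function(v, k) v[((seq_along(v) - 1 - k) %% length(v)) + 1]
  w0 <- modwt(x, "db3", n_levels = 4)
  w1 <- modwt(shift(x, 5), "db3", n_levels = 4)
  for (j in 1:4) expect_equal(w1$W[, j], shift(w0$W[, j], 5), tolerance = 1e-10)
  expect_equal(w1$V, shift(w0$V, 5), tolerance = 1e-10)
})

test_that("inversion is linear in the coefficients", {
  set.seed(7)
  w1 <- modwt(rnorm(256), "coif1", n_levels = 5)
  w2 <- modwt(rnorm(256), "coif1", n_levels = 5)
  wc <- w1
  wc$W <- 2 * w1$W - 3 * w2$W
  wc$V <- 2 * w1$V - 3 * w2$V
  expect_equal(signal_values(imodwt(wc)),
               2 * signal_values(imodwt(w1)) - 3 * signal_values(imodwt(w2)),
               tolerance = 1e-10)
  # all-zero coefficients invert to the zero signal
  wz <- w1; wz$W[] <- 0; wz$V[] <- 0
  expect_equal(signal_values(imodwt(wz)), numeric(256))
})

test_that("level-selective reconstructions are additive and complete", {
  set.seed(8)
  x <- rnorm(256)
  w <- modwt(x, "db2", n_levels = 5)
  full <- signal_values(imodwt(w))
  expect_equal(signal_values(reconstruct_levels(w, 1:5, include_smooth = TRUE)),
               full, tolerance = 1e-10)
  expect_equal(signal_values(reconstruct_levels(w, integer(0))), numeric(256))
  parts <- lapply(1:5, function(j) signal_values(reconstruct_levels(w, j)))
  smooth <- signal_values(reconstruct_levels(w, integer(0), include_smooth = TRUE))
  expect_equal(Reduce(`+`, parts) + smooth, full, tolerance = 1e-9)
  expect_error(reconstruct_levels(w, 6), class = "ecgbw_parameter_error")
})

test_that("level frequency bands follow the dyadic closed form", {
  b7 <- level_band(250, 7)
  expect_equal(b7$low_hz, 0.9765625)
  expect_equal(b7$high_hz, 1.953125)
  b1 <- level_band(250, 1)
  expect_equal(c(b1$low_hz, b1$high_hz), c(62.5, 125))
  b <- level_band(250, 1:11)
  expect_true(all(diff(b$high_hz) < 0))
  expect_equal(b$low_hz[-11], b$high_hz[-1])  # adjacent-contiguous
})

test_that("malformed inputs are rejected", {
  expect_error(modwt(rnorm(100), "db2", n_levels = 7),
               class = "ecgbw_parameter_error")   # J > floor(log2 N)
  expect_error(modwt(c(1, NA, 3), "db2", n_levels = 1),
               class = "ecgbw_parameter_error")
  expect_error(modwt(rnorm(64), "nonsense", n_levels = 2),
               class = "ecgbw_unsupported_wavelet")
  w <- modwt(rnorm(64), "db2", n_levels = 3)
  w$V <- w$V[1:10]
  expect_error(imodwt(w), class = "ecgbw_parameter_error")
  expect_error(level_band(250, 0), class = "ecgbw_parameter_error")
})

test_that("tidy and glance expose the decomposition in tabular form", {
  x <- synth_ecg(duration_s = 2, fs = 250, seed = 1)
  w <- modwt(x, "db2", n_levels = 4)
  td <- tidy(w)
  expect_equal(nrow(td), 500L * 5L)
  expect_setequal(levels(td$level), c("1", "2", "3", "4", "smooth"))
  g <- glance(w)
  expect_equal(g$n, 500L)
  expect_equal(g$energy, sum(signal_values(x)^2), tolerance = 1e-8)
})
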