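test_that("mse matches its defining sum", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(0, 0), c(1, 1)), 1)
  set.seed(41)
  a <- rnorm(2500); b <- rnorm(2500)
  brute <- 0
  for (t in seq_along(a)) brute <- brute + (a[t] - b[t])^2 / length(a)
  expect_equal(mse(a, b), brute, tolerance = 1e-12)
  expect_error(mse(a, b[1:10]), class = "ecgbw_parameter_error")
})

test_that("the identity configuration scores a numerically zero error", {
  # zero-amplitude trend plus keep-everything range: the pipeline is
  # modwt -> imodwt -> trim, and with a jitter-free excerpt whose
  # extrema recur every beat the renormalization is the identity too
  xn <- minmax_normalize(synth_ecg(seed = 42, rr_jitter_frac = 0))
  r <- run_experiment(xn, sinusoid_trend(0.3, amplitude = 0), "sym3",
                      keep_lo = 1, keep_hi = 11, keep_smooth = TRUE)
  expect_lt(r$mse, 1e-18)
  expect_equal(r$m, 2500L)
})

test_that("db3 and sym3 give bit-identical detrending results", {
  xn <- normalized_ecg(43)
  y <- superimpose(xn, make_trend(sinusoid_trend(0.15), 14, 250))
  d_db3 <- detrend_ecg(y, "db3")
  d_sym3 <- detrend_ecg(y, "sym3")
  expect_identical(d_db3$value, d_sym3$value)
  r1 <- run_experiment(xn, sinusoid_trend(0.15), "db3")
  r2 <- run_experiment(xn, sinusoid_trend(0.15), "sym3")
  expect_identical(r1$mse, r2$mse)
})

test_that("keeping the trend band (lv1-9) scores worse than removing it (lv1-7)", {
  xn <- normalized_ecg(0)
  r7 <- run_experiment(xn, sinusoid_trend(0.3), "sym3", keep_lo = 1, keep_hi = 7)
  r9 <- run_experiment(xn, sinusoid_trend(0.3), "sym3", keep_lo = 1, keep_hi = 9)
  expect_lt(r7$mse, r9$mse)
})

test_that("the grid enumerates the full Cartesian product deterministically", {
  recs <- list(a = normalized_ecg(1), b = normalized_ecg(2))
  su <- trend_suite()
  g <- run_grid(recs, c("db1", "sym3"), list(c(1, 7), c(1, 9)), su,
                n_levels = 11)
  expect_s3_class(g, "bw_grid")
  expect_equal(nrow(g), 2 * 2 * 2 * 12)
  expect_equal(sum(!is.na(g$error)), 0L)
  expect_false(any(duplicated(g[c("record_id", "wavelet", "keep_lo",
                                  "keep_hi", "trend_id")])))
  g2 <- run_grid(recs, c("db1", "sym3"), list(c(1, 7), c(1, 9)), su,
                 n_levels = 11)
  expect_identical(g$mse, g2$mse)
  expect_error(run_grid(list(), "db1", list(c(1, 7)), su),
               class = "ecgbw_parameter_error")
})

test_that("failing cells are recorded with their reason, not dropped", {
  # constant 'excerpt': min-max renormalization of the detrended window
  # is degenerate, the cell must survive with an error marker
  flat <- ecg_signal(rep(0, 3500), fs = 250)
  g <- run_grid(list(flat = flat), "db1",
                list(c(1, 7)), sinusoid_trend(0.05, amplitude = 0),
                n_levels = 11)
  expect_equal(nrow(g), 1L)
  expect_true(is.na(g$mse))
  expect_match(g$error, "[Dd]egenerate")
  expect_warning(s <- summarize_grid(g, group_by = "wavelet"), "excluded")
})

test_that("grid summaries equal naive per-group averaging and report tie sets", {
  recs <- list(a = normalized_ecg(3), b = normalized_ecg(4))
  su <- trend_suite()[1:4, ]
  g <- run_grid(recs, c("db3", "sym3", "db1"), list(c(1, 7), c(1, 9)), su)
  s <- summarize_grid(g)
  ref <- naive_group_means(as.data.frame(g), c("wavelet", "keep_lo", "keep_hi"))
  for (k in seq_len(nrow(s))) {
    key <- paste(s$wavelet[k], s$keep_lo[k], s$keep_hi[k], sep = "\r")
    expect_equal(s$mean_mse[k], unname(ref[key]))
  }
  # single-row summary equals that row's mse
  s1 <- summarize_grid(g[1, ], group_by = "wavelet")
  expect_equal(s1$mean_mse, g$mse[1])
  # db3 and sym3 tie exactly: both in the best set or both out
  b <- best_configs(g)
  in_best <- c("db3", "sym3") %in% b$wavelet
  expect_true(all(in_best) || all(!in_best))
  # grand mean consistency: mean over sinusoid rows equals count-weighted
  # mean of per-frequency means
  sins <- g[g$trend_kind == "sinusoid", ]
  per_f <- summarize_grid(sins, group_by = "trend_freq_hz")
  expect_equal(sum(per_f$mean_mse * per_f$n) / sum(per_f$n), mean(sins$mse))
})

test_that("glance and autoplot summarize a grid", {
  g <- run_grid(list(a = normalized_ecg(5)), c("db1", "db2"),
                list(c(1, 7)), trend_suite()[c(1, 11, 12), ])
  gl <- glance(g)
  expect_equal(gl$n_cells, 6L)
  expect_equal(gl$n_failed, 0L)
  p <- autoplot(g)
  expect_s3_class(p, "ggplot")
  p2 <- plot_mse_heatmap(g)
  expect_s3_class(p2, "ggplot")
})
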