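test_that("dF/F0 normalisation matches hand arithmetic and is scale invariant", {
  expect_equal(compute_dff(c(5, 5, 5))$values, c(0, 0, 0))
  expect_equal(compute_dff(c(8, 10, 12))$values, c(-20, 0, 20))
  # a frame at exactly twice the temporal mean reads 100
  y <- c(6, 2, 2, 2)                             # F0 = 3, peak = 6 = 2*F0
  expect_equal(compute_dff(y)$values[1], 100)
  # invariant to multiplicative rescaling
  set.seed(3)
  for (k in 1:10) {
    raw <- runif(50, 10, 20)
    expect_equal(compute_dff(raw)$values, compute_dff(raw * 7.3)$values)
  }
  expect_error(compute_dff(c(-2, 0, 2)), "F0")
})

test_that("asymmetric least squares baseline hugs the floor of the trace", {
  # flat trace: baseline equals the trace
  flat <- rep(4, 60)
  expect_equal(als_baseline(flat), flat, tolerance = 1e-8)

  # linear ramp without spikes: residual under 1% of the range, and close
  # to the ordinary least-squares line (the oracle for a pure trend)
  y <- seq(0, 40, length.out = 200)
  b <- als_baseline(y)
  expect_lt(max(abs(y - b)), 0.01 * diff(range(y)))
  ols <- unname(stats::lm.fit(cbind(1, seq_along(y)), y)$fitted.values)
  expect_lt(max(abs(b - ols)), 0.01 * diff(range(y)))

  # ramp plus sparse positive transients: heights recovered within 5%
  t <- (0:199) * 3
  spike <- function(t0, A) ifelse(t >= t0, A * exp(-(t - t0) / (15 / log(2))), 0)
  y2 <- y + spike(99, 50) + spike(300, 60) + spike(480, 40)
  det <- y2 - als_baseline(y2)
  got <- det[t %in% c(99, 300, 480)]
  expect_equal(got, c(50, 60, 40), tolerance = 0.05)

  # re-estimating the baseline of a spike-free residual changes ~nothing
  r <- y - b
  expect_lt(max(abs(als_baseline(r))), 1e-6 * diff(range(y)))

  expect_error(als_baseline(rep(1, 5)), "too short")
})

test_that("spike detector finds single transients exactly and applies the height filter", {
  # silence in, silence out
  expect_identical(nrow(detect_spikes(mk_trace(rep(0, 200)))), 0L)
  expect_identical(nrow(detect_spikes(mk_trace(rep(3, 200)))), 0L)

  # one noise-free Gaussian transient of 15 s FWHM
  t <- (0:199) * 3
  sigma <- 15 / (2 * sqrt(2 * log(2)))
  g <- 50 * exp(-(t - 300)^2 / (2 * sigma^2))
  calls <- detect_spikes(mk_trace(g))
  expect_identical(nrow(calls), 1L)
  expect_lte(abs(calls$peak_time - 300), 3)       # within one frame
  expect_lte(abs(calls$fwhm - 15), 3)             # FWHM within one frame
  expect_equal(calls$amplitude, 50, tolerance = 0.02)

  # second transient below 10% of the trace maximum is discarded
  two <- 100 * exp(-(t - 150)^2 / (2 * sigma^2)) +
    5 * exp(-(t - 450)^2 / (2 * sigma^2))
  calls2 <- detect_spikes(mk_trace(two))
  expect_identical(nrow(calls2), 1L)
  expect_lte(abs(calls2$peak_time - 150), 3)
})

test_that("noise-free generator round trip recovers every spike within a frame", {
  for (shape in c("exp", "gaussian")) {
    cfg <- trace_synth_config(seed = 5, n_cells = 12, noise_sd = 0,
                              spike_shape = shape)
    g <- make_traces(cfg)
    for (cell in seq_len(cfg$n_cells)) {
      truth <- g$truth$time_s[g$truth$cell == cell]
      truth <- truth[truth >= 30 & truth <= 560]  # whole transient recorded
      if (!length(truth)) next
      det <- detect_spikes(mk_trace(g$values[, cell], g$times))
      for (t0 in truth) expect_lte(min(abs(det$peak_time - t0)), 3)
    }
  }
})

test_that("spike recall and precision reach 0.95 under the stated regime", {
  # amplitude / noise-sd >= 5, inter-spike interval >= 2 FWHM
  cfg <- trace_synth_config(seed = 11, n_cells = 100, noise_sd = 8,
                            spike_amplitude_mean = 50, spike_amplitude_sd = 5,
                            spike_amplitude_min = 40)
  g <- make_traces(cfg)
  tot <- c(tp = 0L, fn = 0L, fp = 0L)
  for (cell in seq_len(cfg$n_cells)) {
    det <- detect_spikes(subtract_baseline(mk_trace(g$values[, cell], g$times)))
    truth <- g$truth$time_s[g$truth$cell == cell]
    tot <- tot + match_spikes(det$peak_time, truth, tol = cfg$spike_fwhm_s)
  }
  recall <- tot["tp"] / (tot["tp"] + tot["fn"])
  precision <- tot["tp"] / (tot["tp"] + tot["fp"])
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("estimated firing frequency is unbiased at the generating 5 mHz", {
  cfg <- trace_synth_config(seed = 19, n_cells = 120, noise_sd = 8,
                            spike_amplitude_mean = 50, spike_amplitude_sd = 5,
                            spike_amplitude_min = 40)
  g <- make_traces(cfg)
  counts <- vapply(seq_len(cfg$n_cells), function(cell) {
    nrow(detect_spikes(subtract_baseline(mk_trace(g$values[, cell], g$times))))
  }, numeric(1))
  freq <- 1000 * sum(counts) / (cfg$n_cells * cfg$duration_s)
  se <- 1000 * stats::sd(counts) * sqrt(cfg$n_cells) /
    (cfg$n_cells * cfg$duration_s)
  expect_lte(abs(freq - cfg$spike_rate_mHz), 2 * se)
})

test_that("trace statistics convert counts to mHz", {
  spikes <- data.frame(peak_time = c(10, 200, 400), frame = c(3, 66, 133),
                       amplitude = c(40, 55, 47), fwhm = c(15, 14, 16))
  st <- trace_stats(spikes, duration = 600)
  expect_equal(st$frequency, 5)                    # 3 spikes / 600 s = 5 mHz
  expect_equal(st$mean_amplitude, mean(c(40, 55, 47)))
  none <- trace_stats(spikes[0, ], duration = 600)
  expect_equal(none$frequency, 0)
  expect_true(is.na(none$mean_amplitude))
  expect_error(trace_stats(spikes, duration = 0), "duration")
})
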