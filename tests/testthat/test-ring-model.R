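test_that("initial BMP4 gradient pins the printed anchors and is symmetric", {
  s <- init_intact_state(mz_params())
  expect_equal(s$B[c(1, 100)], c(1.1, 1.1))   # cells 0 and 99
  expect_equal(s$B[c(50, 51)], c(2.2, 2.2))   # cells 49 and 50
  expect_true(all(diff(s$B[1:50]) >= 0))      # non-decreasing towards anterior
  expect_equal(s$B, rev(s$B))                 # mirror symmetry
  expect_true(all(s$C == 0) && all(s$V == 0) && all(s$A == 0L))
  expect_identical(s$topology, "periodic")
})

test_that("BMP4 rate follows production switch and combined decay", {
  p <- mz_params(k_B = 1, alpha = 0.1, gamma0 = 0.5, gamma_C = 1, gamma_V = 2,
                 n_cells = 3, D = 0)
  st <- init_intact_state(p)
  # no calcium: pure basal decay
  st$B <- rep(1, 3); st$C <- rep(0, 3); st$V <- rep(0, 3)
  expect_equal(dB_dt(st, p), rep(-p$gamma0, 3))
  # production switches on at the threshold exactly (H(0) = 1)
  st$C <- rep(p$alpha, 3); st$B <- rep(0, 3)
  expect_equal(dB_dt(st, p), rep(p$k_B, 3))
  # hand-evaluated rate, frozen from scalar arithmetic:
  # 1*H(0.2-0.1) - (0.5 + 1*0.2 + 2*0.25)*2 = 1 - 1.2*2 = -1.4
  st$C <- rep(0.2, 3); st$V <- rep(0.25, 3); st$B <- rep(2, 3)
  expect_equal(dB_dt(st, p), rep(-1.4, 3))
})

test_that("calcium transmission is conservative and sourced by streak cells", {
  p <- mz_params(n_cells = 12)
  st <- init_intact_state(p)
  # uniform activity, no sources: pure decay, Laplacian zero
  st$C <- rep(0.7, 12)
  expect_equal(dC_dt(st, p), rep(-p$lambda * 0.7, 12))
  # single committed cell with zero activity: k_C there, nothing elsewhere
  st$C <- rep(0, 12); st$A[5] <- 1L
  expect_equal(dC_dt(st, p), c(rep(0, 4), p$k_C, rep(0, 7)))
  # transmission term sums to zero on a periodic ring (conservation)
  set.seed(42)
  for (k in 1:20) {
    C <- runif(12, 0, 5)
    lap <- mzring:::ring_laplacian(C, "periodic")
    expect_lt(abs(sum(lap)), 1e-10 * max(1, sum(abs(C))))
  }
})

test_that("cVG1 is induced below the BMP4 threshold, boundary included", {
  p <- mz_params(n_cells = 3)
  st <- init_intact_state(p)
  st$B <- rep(p$beta_V + 0.5, 3); st$V <- rep(1, 3)
  expect_equal(dV_dt(st, p), rep(-p$mu, 3))
  st$B <- rep(p$beta_V, 3); st$V <- rep(0, 3)
  expect_equal(dV_dt(st, p), rep(p$k_V, 3))   # H(0) = 1
  ph <- mz_params(n_cells = 3, production_mode = "hill")
  st$B <- rep(2 * ph$beta_V, 3)
  expect_equal(dV_dt(st, ph), rep(ph$k_V / 17, 3))  # beta^4/(beta^4+16 beta^4)
})

test_that("streak latch triggers at the threshold and never resets", {
  p <- mz_params(n_cells = 4)
  st <- init_intact_state(p)
  st$B <- c(p$beta_C, p$beta_C + 0.01, 2, 0.5)
  st <- update_latch(st, p)
  expect_identical(st$A, c(1L, 0L, 0L, 1L))   # boundary commits
  st$B <- rep(2, 4)                            # BMP4 recovers
  st <- update_latch(st, p)
  expect_identical(st$A, c(1L, 0L, 0L, 1L))   # latch holds
})

test_that("euler step fixes equilibria and matches the single-cell closed form", {
  # all rates zero: state is a fixed point, only time advances
  p0 <- mz_params(k_B = 0, k_C = 0, k_V = 0, gamma0 = 0, gamma_C = 0,
                  gamma_V = 0, lambda = 0, mu = 0, D = 0, n_cells = 5)
  st <- init_intact_state(p0)
  st$B <- runif(5); st$C <- runif(5); st$V <- runif(5)
  st$B <- pmax(st$B, p0$beta_C + 0.1)          # keep the latch quiet
  st2 <- euler_step(st, p0)
  expect_equal(st2$B, st$B)
  expect_equal(st2$C, st$C)
  expect_equal(st2$V, st$V)
  expect_equal(st2$t, st$t + p0$dt)

  # isolated committed cell, no transmission: C(t) = k_C/lambda (1 - e^-lambda t)
  p <- mz_params(D = 0, n_cells = 3, dt = 1e-3)
  st <- init_intact_state(p)
  st$A <- c(1L, 0L, 0L)
  st$B <- rep(p$beta_C + 1, 3)                 # above both thresholds
  n_steps <- 500
  for (k in seq_len(n_steps)) st <- euler_step(st, p)
  t_end <- n_steps * p$dt
  closed <- p$k_C / p$lambda * (1 - exp(-p$lambda * t_end))
  expect_equal(st$C[1], closed, tolerance = 5 * p$dt * p$lambda)
  expect_equal(st$C[2:3], c(0, 0))
})

test_that("the scheme converges at first order in dt", {
  run_to <- function(dt, t_end) {
    # smooth regime: production switches pinned on, no latch crossings
    p <- mz_params(alpha = 0, beta_V = 100, beta_C = 0.0, D = 5, dt = dt,
                   n_cells = 10, k_C = 2)
    st <- init_intact_state(p)
    st$A <- c(1L, rep(0L, 9))
    st$C <- seq(0, 1, length.out = 10)
    for (k in seq_len(round(t_end / dt))) st <- euler_step(st, p)
    c(st$B, st$C, st$V)
  }
  t_end <- 0.2
  ref <- run_to(2e-5, t_end)
  e1 <- max(abs(run_to(2e-3, t_end) - ref))
  e2 <- max(abs(run_to(1e-3, t_end) - ref))
  order <- log2(e1 / e2)
  expect_gt(order, 0.8)
  expect_lt(order, 1.2)
})

test_that("the anterior-half cut respects geometry and the streak precondition", {
  p <- mz_params()
  st <- init_intact_state(p)

  sym <- apply_anterior_half_cut(st, scenario_config("anterior_half",
                                                     obliquity_offset = 0))
  n <- length(sym$B)
  expect_identical(sym$topology, "segment")
  expect_identical(sym$cell_ids[1], 10L)           # right edge
  expect_identical(sym$cell_ids[n], 89L)           # left edge
  expect_equal(sym$B[1], sym$B[n])                 # equidistant edges

  obl <- apply_anterior_half_cut(st, scenario_config("anterior_half",
                                                     obliquity_offset = 2))
  expect_lt(obl$B[1], obl$B[length(obl$B)])        # right edge leans posterior

  st_bad <- st
  st_bad$A[30] <- 1L                               # committed cell outside arc
  expect_error(apply_anterior_half_cut(
    st_bad, scenario_config("anterior_half")), "streak identity")

  # with no sources left, total activity decays at exactly rate lambda
  dec <- sym
  set.seed(7)
  dec$C <- runif(n, 0, 2)
  tot0 <- sum(dec$C)
  n_steps <- 200L
  for (k in seq_len(n_steps)) dec <- euler_step(dec, p)
  expect_equal(sum(dec$C), tot0 * exp(-p$lambda * n_steps * p$dt),
               tolerance = 5 * p$dt * p$lambda)
  expect_true(all(dec$A == 0L))
})

test_that("streak arcs are detected across the index seam and match a run-length oracle", {
  p <- mz_params(n_cells = 12)
  st <- init_intact_state(p)
  expect_identical(nrow(detect_streak_segments(st)), 0L)

  st$A <- rep(0L, 12)
  st$A[c(11, 12, 1, 2)] <- 1L                      # cells 10,11,0,1: seam arc
  seg <- detect_streak_segments(st)
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$span, 4L)
  expect_identical(seg$start_id, 10L)
  expect_identical(seg$end_id, 1L)

  set.seed(11)
  for (k in 1:25) {
    st$A <- as.integer(runif(12) < 0.4)
    seg <- detect_streak_segments(st)
    oracle <- brute_force_runs(st$A, periodic = TRUE)
    expect_setequal(seg$span, oracle)
    expect_identical(sum(seg$span), sum(st$A))
  }
})

test_that("simulation is deterministic and decouples when the calcium source is off", {
  p <- mz_params(k_C = 0, n_cells = 20, dt = 1e-4, D = 1000)
  cfg <- scenario_config("anterior_half", pre_cut_duration = 0.3,
                         post_cut_duration = 0.5, cut_left_index = 18,
                         cut_right_index = 1, obliquity_offset = 1)
  r1 <- suppressWarnings(simulate_ring(cfg, p))
  r2 <- suppressWarnings(simulate_ring(cfg, p))
  expect_identical(r1$final, r2$final)
  expect_identical(r1$pre, r2$pre)
  # no calcium source anywhere: C stays zero, B evolves under decay only
  expect_true(all(r1$post$C == 0))
})
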