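test_that("assignment solver is optimal against exhaustive enumeration", {
  set.seed(101)
  for (k in 1:25) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n, 0, 10), n, n)
    if (k %% 3 == 0) cost[runif(n * n) < 0.2] <- Inf  # some forbidden links
    oracle <- brute_force_assignment(ifelse(is.finite(cost), cost, 1e6))
    a <- solve_lap(cost)
    got <- sum(ifelse(is.finite(cost[cbind(1:n, a)]),
                      cost[cbind(1:n, a)], 1e6))
    expect_equal(got, oracle$cost, tolerance = 1e-9)
  }
})

test_that("events link within the distance cutoff and close one-frame gaps", {
  # 50 um apart in consecutive frames: one track
  ev <- data.frame(frame = 0:1, time_s = c(0, 3), x_um = c(0, 30),
                   y_um = c(0, 40))
  tk <- link_events(ev)
  expect_identical(nrow(tk$summary), 1L)
  expect_identical(tk$summary$n_events, 2L)

  # 100 um apart: two singletons
  ev2 <- data.frame(frame = 0:1, time_s = c(0, 3), x_um = c(0, 100),
                    y_um = c(0, 0))
  tk2 <- link_events(ev2)
  expect_identical(nrow(tk2$summary), 2L)
  expect_true(all(tk2$summary$n_events == 1L))

  # nothing at frame 1, but end and start within 90 um and 2 frames: gap closed
  ev3 <- data.frame(frame = c(0, 2), time_s = c(0, 6), x_um = c(0, 50),
                    y_um = c(0, 0))
  tk3 <- link_events(ev3)
  expect_identical(nrow(tk3$summary), 1L)
  expect_equal(tk3$summary$duration_s, 6)

  # beyond the gap window: stays split
  ev4 <- data.frame(frame = c(0, 3), time_s = c(0, 9), x_um = c(0, 50),
                    y_um = c(0, 0))
  expect_identical(nrow(link_events(ev4)$summary), 2L)
})

test_that("a well-separated synthetic field is recovered exactly", {
  cfg <- field_synth_config(seed = 7, n_frames = 150, init_rate_edge = 0.0012,
                            init_rate_far = 0.0003, min_separation_um = 100)
  fl <- make_event_field(cfg)
  expect_gte(length(unique(fl$truth$track_id)), 20)
  tk <- link_events(fl$events)
  expect_identical(partition_signature(tk$events$track_id),
                   partition_signature(fl$truth$track_id))
  # every event in exactly one track
  expect_identical(length(tk$events$track_id), nrow(fl$events))
  expect_false(anyNA(tk$events$track_id))
})

test_that("linking is invariant under translation and rotation", {
  cfg <- field_synth_config(seed = 13, n_frames = 80, init_rate_edge = 0.001,
                            init_rate_far = 0.0005)
  fl <- make_event_field(cfg)
  base <- partition_signature(link_events(fl$events)$events$track_id)
  th <- 0.73
  rot <- fl$events
  x <- rot$x_um; y <- rot$y_um
  rot$x_um <- cos(th) * x - sin(th) * y + 512
  rot$y_um <- sin(th) * x + cos(th) * y - 137
  expect_identical(partition_signature(link_events(rot)$events$track_id), base)
})

test_that("fields with all pairwise distances beyond the cutoff give singletons", {
  ev <- data.frame(frame = rep(0:4, each = 3), time_s = rep(0:4, each = 3) * 3,
                   x_um = rep(c(0, 1000, 2000), 5),
                   y_um = rep(300 * (0:4), each = 3))
  d <- as.matrix(stats::dist(cbind(ev$x_um, ev$y_um)))
  expect_true(all(d[upper.tri(d)] > 90))
  tk <- link_events(ev)
  expect_true(all(tk$summary$n_events == 1L))
})

test_that("a fragment starting beside another track's body is marked as a branch", {
  ev <- data.frame(frame = c(0L, 1L, 2L, 2L, 3L),
                   time_s = c(0, 3, 6, 6, 9),
                   x_um = c(0, 10, 20, 15, 15),
                   y_um = c(0, 0, 0, 30, 60))
  tk <- link_events(ev)
  expect_identical(nrow(tk$summary), 2L)
  main <- tk$summary$track_id[tk$summary$n_events == 3L]
  branch <- tk$summary[tk$summary$n_events == 2L, ]
  expect_identical(branch$split_from, main)      # branch off the main track
  expect_true(is.na(tk$summary$split_from[tk$summary$track_id == main]))
  # with splitting disabled the annotation disappears, membership unchanged
  tk0 <- link_events(ev, splitting = FALSE)
  expect_true(all(is.na(tk0$summary$split_from)))
  expect_identical(partition_signature(tk0$events$track_id),
                   partition_signature(tk$events$track_id))
})

test_that("track durations and quadrant classes follow their definitions", {
  ev <- data.frame(frame = 0:4, time_s = (0:4) * 3, x_um = (0:4) * 10,
                   y_um = 0)
  tk <- link_events(ev)
  expect_equal(track_duration(tk$summary), 12)         # 5 frames at 3 s
  expect_error(track_duration(data.frame(time_s = 1)), "singleton")

  expect_identical(angle_class(45), "Q1")
  expect_identical(angle_class(atan2(1, 1) * 180 / pi), "Q1")    # (1,1)
  expect_identical(angle_class(atan2(1, -1) * 180 / pi), "Q2")   # (-1,1)
  expect_identical(angle_class(0), "Q1")               # boundary: half-open
  expect_identical(angle_class(90), "Q2")
  expect_identical(angle_class(180), "Q3")
  expect_identical(angle_class(270), "Q4")
  expect_identical(angle_class(359.9), "Q4")
  expect_true(is.na(mzring:::track_angle(1, 1, 1, 1)))  # zero displacement

  # quadrant counts over classified tracks sum to the classified total
  cfg <- field_synth_config(seed = 31, n_frames = 100, init_rate_edge = 0.001,
                            init_rate_far = 0.001)
  fl <- make_event_field(cfg)
  summ <- link_events(fl$events)$summary
  classified <- !is.na(summ$quadrant)
  expect_identical(sum(table(summ$quadrant)), sum(classified))
})

test_that("sector histograms separate uniform and log-normal fields", {
  mask <- annulus_sector_mask(120, 120, centre = c(60, 60), r_inner = 30,
                              r_outer = 55, theta_start = 0, theta_span = 180,
                              n_sectors = 4)
  expect_setequal(sort(unique(as.vector(mask))), 0:4)
  sizes <- table(mask[mask > 0])
  expect_lt(diff(range(sizes)) / mean(sizes), 0.05)    # equal arc sectors

  # uniform image: identical histograms, equal counts above threshold
  img <- matrix(7, 120, 120)
  sh <- sector_histogram(img, mask, threshold = 6)
  expect_true(all(sh$above_threshold_count == sh$n_pixels))
  sh_hi <- sector_histogram(img, mask, threshold = 10)
  expect_true(all(sh_hi$above_threshold_count == 0))

  # log-normal pixels: parameters recovered within 5% on >= 1e4 px sectors
  big_mask <- annulus_sector_mask(400, 400, centre = c(200, 200),
                                  r_inner = 80, r_outer = 190,
                                  theta_start = 0, theta_span = 180,
                                  n_sectors = 4)
  expect_gte(min(table(big_mask[big_mask > 0])), 1e4)
  mv <- render_movie(data.frame(frame = integer(), x_um = numeric(),
                                y_um = numeric(), intensity = numeric()),
                     n_frames = 1, image_size = c(400, 400),
                     background_mode = "lognormal",
                     bg_meanlog = 1.2, bg_sdlog = 0.35, seed = 42)
  fit <- sector_histogram(mv$average, big_mask, threshold = 6,
                          binwidth = 0.25)
  expect_true(all(fit$fit_ok))
  expect_true(all(abs(fit$meanlog - 1.2) / 1.2 < 0.05))
  expect_true(all(abs(fit$sdlog - 0.35) / 0.35 < 0.05))
  expect_true(all(abs(fit$peak_centre - exp(1.2 - 0.35^2)) /
                    exp(1.2 - 0.35^2) < 0.05))
})

test_that("active cells are counted as position clusters per region", {
  none <- count_active_cells(data.frame(x_um = numeric(), y_um = numeric()),
                             factor(character(), levels = c("MZ", "AP")))
  expect_identical(unname(none), c(0L, 0L))

  # five firings of one cell: one active cell
  ev <- data.frame(x_um = rep(10, 5), y_um = rep(20, 5))
  expect_identical(unname(count_active_cells(ev, rep("MZ", 5))), 1L)

  # generator cells are >= 13 um apart: counts recover exactly
  cfg <- field_synth_config(seed = 3, n_frames = 100, spacing_um = 14,
                            track_step_um = 14.5,
                            init_rate_edge = 0.0008, init_rate_far = 0.0008)
  fl <- make_event_field(cfg)
  half <- fl$cells$arc_pos_um[fl$truth$cell] <
    max(fl$cells$arc_pos_um) / 2
  regions <- ifelse(half, "near", "far")
  got <- count_active_cells(fl$truth, regions)
  want <- vapply(split(fl$truth$cell, regions),
                 function(cells) length(unique(cells)), integer(1))
  expect_identical(got[names(want)], want)

  expect_error(count_active_cells(ev, c("a", "b", NA, "a", "b")),
               "no region")
})
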