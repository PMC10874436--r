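#' Configuration for the synthetic calcium-trace generator
#'
#' Study conditions emulating marginal-zone recordings: 200 frames at 3 s
#' (10 min) per trace, spontaneous transients at 5 mHz with 15 s FWHM, and
#' additive Gaussian imaging noise. Spike trains are refractory-Poisson:
#' inter-spike intervals are `min_isi_s` plus an exponential variate whose
#' mean is adjusted so the long-run rate equals `spike_rate_mHz`; the
#' refractory floor (two FWHM by default) reflects the indicator's return to
#' baseline between transients.
#'
#' @param seed integer seed; a fixed seed gives bitwise-identical output.
#' @param n_cells number of traces.
#' @param duration_s recording duration (s).
#' @param frame_interval_s frame spacing (s).
#' @param spike_rate_mHz mean firing rate (mHz).
#' @param spike_amplitude_mean,spike_amplitude_sd transient amplitude
#'   distribution (100 x dF/F0 units); draws are truncated below at
#'   `spike_amplitude_min`.
#' @param spike_amplitude_min lower truncation of amplitudes.
#' @param spike_fwhm_s transient full width at half maximum (s).
#' @param spike_shape `"exp"`: fast rise (single frame) with exponential
#'   decay of matched FWHM; `"gaussian"`: symmetric Gaussian transient.
#' @param noise_sd additive Gaussian noise SD (100 x dF/F0 units).
#' @param drift_amplitude peak-to-peak amplitude of a slow sinusoidal
#'   baseline drift (0 disables).
#' @param drift_period_s drift period (s).
#' @param min_isi_s minimum inter-spike interval (s).
#' @return A validated list of class `mz_trace_config`.
#' @export
trace_synth_config <- function(seed = 1,
                               n_cells = 100,
                               duration_s = 600,
                               frame_interval_s = 3,
                               spike_rate_mHz = 5,
                               spike_amplitude_mean = 50,
                               spike_amplitude_sd = 10,
                               spike_amplitude_min = 25,
                               spike_fwhm_s = 15,
                               spike_shape = c("exp", "gaussian"),
                               noise_sd = 5,
                               drift_amplitude = 0,
                               drift_period_s = 300,
                               min_isi_s = 2 * spike_fwhm_s) {
  spike_shape <- match.arg(spike_shape)
  stopifnot(n_cells >= 1, duration_s > 0, frame_interval_s > 0,
            spike_rate_mHz >= 0, spike_amplitude_mean > 0,
            spike_amplitude_sd >= 0, spike_fwhm_s > 0, noise_sd >= 0,
            min_isi_s >= 0)
  if (spike_rate_mHz > 0 && min_isi_s >= 1000 / spike_rate_mHz)
    stop("min_isi_s must be below the mean inter-spike interval")
  structure(as.list(environment()), class = "mz_trace_config")
}

#' Generate synthetic calcium traces with ground truth
#'
#' Draws per-cell refractory-Poisson spike trains, renders each spike as a
#' transient of the configured shape and FWHM (aligned to the frame grid),
#' adds optional slow drift and Gaussian noise, and returns both the traces
#' and the generating truth for recovery tests.
#'
#' @param config an [trace_synth_config()] object.
#' @return A list with
#'   \describe{
#'     \item{times}{frame times (s).}
#'     \item{values}{matrix frames x cells of 100 x dF/F0 values.}
#'     \item{truth}{data.frame `cell`, `time_s` (frame-aligned spike peak),
#'       `amplitude`, `fwhm_s`.}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
make_traces <- function(config) {
  stopifnot(inherits(config, "mz_trace_config"))
  with_seed(config$seed, {
    n_frames <- floor(config$duration_s / config$frame_interval_s)
    times <- (seq_len(n_frames) - 1) * config$frame_interval_s
    values <- matrix(0, n_frames, config$n_cells)
    truth <- vector("list", config$n_cells)
    for (cell in seq_len(config$n_cells)) {
      st <- draw_spike_times(config)
      frames <- unique(round(st / config$frame_interval_s)) + 1L
      frames <- frames[frames >= 1L & frames <= n_frames]
      amps <- draw_amplitudes(length(frames), config)
      y <- numeric(n_frames)
      for (k in seq_along(frames)) {
        y <- y + spike_kernel(times, times[frames[k]], amps[k], config)
      }
      if (config$drift_amplitude > 0)
        y <- y + config$drift_amplitude / 2 *
          sin(2 * pi * times / config$drift_period_s +
                2 * pi * stats::runif(1))
      if (config$noise_sd > 0)
        y <- y + stats::rnorm(n_frames, 0, config$noise_sd)
      values[, cell] <- y
      truth[[cell]] <- if (length(frames))
        data.frame(cell = cell, time_s = times[frames], amplitude = amps,
                   fwhm_s = config$spike_fwhm_s)
      else
        data.frame(cell = integer(), time_s = numeric(),
                   amplitude = numeric(), fwhm_s = numeric())
    }
    list(times = times, values = values, truth = do.call(rbind, truth),
         config = config)
  })
}

# Refractory-Poisson spike times over [0, duration): ISI = floor + Exp with
# mean chosen so the long-run rate matches the configured rate. The first
# spike is drawn from the stationary forward-recurrence distribution of the
# renewal process, so the expected count is exactly rate * duration.
draw_spike_times <- function(config) {
  if (config$spike_rate_mHz <= 0) return(numeric())
  mean_isi <- 1000 / config$spike_rate_mHz
  exp_mean <- mean_isi - config$min_isi_s
  t <- if (stats::runif(1) < config$min_isi_s / mean_isi)
    stats::runif(1, 0, config$min_isi_s)
  else
    config$min_isi_s + stats::rexp(1, 1 / exp_mean)
  out <- numeric()
  while (t < config$duration_s) {
    out <- c(out, t)
    t <- t + config$min_isi_s + stats::rexp(1, 1 / exp_mean)
  }
  out
}

draw_amplitudes <- function(n, config) {
  if (n == 0L) return(numeric())
  a <- stats::rnorm(n, config$spike_amplitude_mean, config$spike_amplitude_sd)
  pmax(a, config$spike_amplitude_min)
}

spike_kernel <- function(times, t0, amplitude, config) {
  if (config$spike_shape == "gaussian") {
    s <- config$spike_fwhm_s / (2 * sqrt(2 * log(2)))
    amplitude * exp(-(times - t0)^2 / (2 * s^2))
  } else {
    tau <- config$spike_fwhm_s / log(2)
    ifelse(times >= t0, amplitude * exp(-(times - t0) / tau), 0)
  }
}

#' Configuration for the synthetic firing-event field
#'
#' Emulates spatially graded initiation of short intercellular calcium
#' tracks along the marginal-zone annulus of an anterior half-embryo: cells
#' sit on the mid-annulus circle at the configured spacing, track
#' initiations are drawn per cell per frame from a linear rate ramp along
#' the arc (highest at the cut edge), and each track hops to a random
#' neighbouring cell within `track_step_um` every `track_step_frames`
#' frames, for a geometrically distributed number of events.
#'
#' Defaults reflect the imaged geometry: marginal zone ~120 um wide at a
#' ~1.5 mm radius, cell spacing ~12 um, 200-frame (10 min) movies.
#'
#' @param seed integer seed.
#' @param n_frames number of frames.
#' @param frame_interval_s frame spacing (s).
#' @param r_inner_um,r_outer_um annulus radii (um).
#' @param spacing_um cell spacing along the annulus (um).
#' @param arc_span_deg angular span of the monitored arc (degrees), starting
#'   at the cut edge (angle 0).
#' @param init_rate_edge,init_rate_far per-cell per-frame track initiation
#'   probability at the cut edge (arc position 0) and at the far end of the
#'   arc; intermediate cells interpolate linearly.
#' @param track_step_um neighbour-hop radius (um); must not exceed the
#'   linking cutoff for recoverable scenarios.
#' @param track_step_frames frames between hops.
#' @param track_mean_events mean number of events per track (geometric).
#' @param intensity_mean,intensity_sd event intensity distribution.
#' @param min_separation_um if positive, reject any new track that would
#'   bring two concurrent tracks (within 2 frames) closer than this;
#'   guarantees unambiguous linking when set above the linking cutoff.
#' @return A validated list of class `mz_field_config`.
#' @export
field_synth_config <- function(seed = 1,
                               n_frames = 200,
                               frame_interval_s = 3,
                               r_inner_um = 1500,
                               r_outer_um = 1620,
                               spacing_um = 12,
                               arc_span_deg = 180,
                               init_rate_edge = 0.003,
                               init_rate_far = 0.0005,
                               track_step_um = 13,
                               track_step_frames = 1,
                               track_mean_events = 4,
                               intensity_mean = 50,
                               intensity_sd = 10,
                               min_separation_um = 0) {
  stopifnot(n_frames >= 1, frame_interval_s > 0, r_outer_um > r_inner_um,
            spacing_um > 0, arc_span_deg > 0, arc_span_deg <= 360,
            init_rate_edge >= 0, init_rate_far >= 0,
            track_step_frames >= 1, track_mean_events >= 1)
  r_mid <- (r_inner_um + r_outer_um) / 2
  if (track_step_um < spacing_um)
    stop("geometry too sparse: track_step_um below the cell spacing ",
         "leaves tracks with no neighbour to hop to")
  structure(as.list(environment()), class = "mz_field_config")
}

#' Generate a synthetic firing-event field with ground-truth tracks
#'
#' @param config an [field_synth_config()] object.
#' @return A list with
#'   \describe{
#'     \item{events}{data.frame `frame` (0-based), `time_s`, `x_um`, `y_um`,
#'       `intensity`, in frame order.}
#'     \item{truth}{the same events with `track_id` (ground-truth
#'       membership) and `cell` (cell index along the arc).}
#'     \item{cells}{data.frame of cell positions `cell`, `arc_pos_um`,
#'       `x_um`, `y_um`.}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
make_event_field <- function(config) {
  stopifnot(inherits(config, "mz_field_config"))
  with_seed(config$seed, {
    r <- config$r_mid
    arc_len <- 2 * pi * r * config$arc_span_deg / 360
    n_cells <- max(2L, floor(arc_len / config$spacing_um))
    arc_pos <- (seq_len(n_cells) - 0.5) * config$spacing_um
    theta <- arc_pos / r
    cells <- data.frame(cell = seq_len(n_cells), arc_pos_um = arc_pos,
                        x_um = r * cos(theta), y_um = r * sin(theta))
    rate <- config$init_rate_edge +
      (config$init_rate_far - config$init_rate_edge) * (arc_pos / arc_len)
    # neighbourhood: cells within one hop
    hop <- config$track_step_um
    rows <- list()
    track_id <- 0L
    for (f0 in seq_len(config$n_frames)) {
      fires <- which(stats::runif(n_cells) < rate)
      for (c0 in fires) {
        n_events <- 1L + stats::rgeom(1, 1 / config$track_mean_events)
        path <- integer(n_events)
        path[1] <- c0
        for (k in seq_len(n_events - 1L)) {
          here <- path[k]
          nb <- which(abs(cells$arc_pos_um - cells$arc_pos_um[here]) <= hop)
          nb <- setdiff(nb, here)
          if (!length(nb)) break
          path[k + 1L] <- nb[sample.int(length(nb), 1L)]
        }
        path <- path[path > 0L]
        frames <- f0 + (seq_along(path) - 1L) * config$track_step_frames
        keep <- frames <= config$n_frames
        path <- path[keep]
        frames <- frames[keep]
        if (!length(path)) next
        cand <- data.frame(frame = frames - 1L,
                           time_s = (frames - 1L) * config$frame_interval_s,
                           x_um = cells$x_um[path],
                           y_um = cells$y_um[path],
                           intensity = pmax(5, stats::rnorm(
                             length(path), config$intensity_mean,
                             config$intensity_sd)),
                           track_id = track_id + 1L,
                           cell = path)
        if (config$min_separation_um > 0 && length(rows) &&
            !separated(cand, rows, config$min_separation_um)) next
        track_id <- track_id + 1L
        rows[[track_id]] <- cand
      }
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(frame = integer(), time_s = numeric(), x_um = numeric(),
                 y_um = numeric(), intensity = numeric(),
                 track_id = integer(), cell = integer())
    truth <- truth[order(truth$frame, truth$x_um, truth$y_um), ]
    rownames(truth) <- NULL
    events <- truth[, c("frame", "time_s", "x_um", "y_um", "intensity")]
    list(events = events, truth = truth, cells = cells, config = config)
  })
}

# TRUE if every event of `cand` is at least `d` away from every event of the
# accepted tracks within a 2-frame window (the linker's reach).
separated <- function(cand, rows, d) {
  prev <- do.call(rbind, rows)
  for (k in seq_len(nrow(cand))) {
    near <- abs(prev$frame - cand$frame[k]) <= 2
    if (!any(near)) next
    dd <- sqrt((prev$x_um[near] - cand$x_um[k])^2 +
                 (prev$y_um[near] - cand$y_um[k])^2)
    if (any(dd < d)) return(FALSE)
  }
  TRUE
}

#' Render firing events into a synthetic image stack
#'
#' Draws each event as a Gaussian blob (scaled by its intensity) on a noisy
#' background, one image per frame, and also returns the temporal-average
#' image used by the sector-histogram analysis. The background can be
#' Gaussian or log-normal (the latter for testing log-normal histogram
#' recovery).
#'
#' @param events data.frame `frame` (0-based), `x_um`, `y_um`, `intensity`.
#' @param n_frames number of frames to render (defaults to max frame + 1).
#' @param image_size integer length-2 `(rows, cols)` in pixels.
#' @param um_per_px pixel size (um).
#' @param origin_um `(x, y)` of the image's top-left pixel centre, in the
#'   event coordinate system.
#' @param psf_sigma_um blob standard deviation (um); the default corresponds
#'   to a ~13 um firing-cell blob.
#' @param background_mode `"gaussian"` or `"lognormal"`.
#' @param bg_mean,bg_sd Gaussian background parameters.
#' @param bg_meanlog,bg_sdlog log-normal background parameters.
#' @param seed integer seed for the background noise.
#' @return List with `stack` (array rows x cols x frames) and `average`
#'   (matrix rows x cols).
#' @export
render_movie <- function(events, n_frames = NULL,
                         image_size = c(64, 64), um_per_px = 10,
                         origin_um = c(0, 0), psf_sigma_um = 6.5,
                         background_mode = c("gaussian", "lognormal"),
                         bg_mean = 2, bg_sd = 0.5,
                         bg_meanlog = 1, bg_sdlog = 0.4,
                         seed = 1) {
  background_mode <- match.arg(background_mode)
  if (is.null(n_frames))
    n_frames <- if (nrow(events)) max(events$frame) + 1L else 1L
  nr <- image_size[1]
  nc <- image_size[2]
  with_seed(seed, {
    n_px <- nr * nc * n_frames
    bg <- if (background_mode == "gaussian")
      stats::rnorm(n_px, bg_mean, bg_sd)
    else
      stats::rlnorm(n_px, bg_meanlog, bg_sdlog)
    stack <- array(bg, dim = c(nr, nc, n_frames))
    if (nrow(events)) {
      px_x <- (events$x_um - origin_um[1]) / um_per_px + 1
      px_y <- (events$y_um - origin_um[2]) / um_per_px + 1
      if (any(px_x < 1 | px_x > nc | px_y < 1 | px_y > nr))
        stop("events fall outside the image bounds")
      s_px <- psf_sigma_um / um_per_px
      half <- ceiling(4 * s_px)
      for (k in seq_len(nrow(events))) {
        f <- events$frame[k] + 1L
        if (f > n_frames) next
        cx <- px_x[k]
        cy <- px_y[k]
        xs <- max(1L, floor(cx - half)):min(nc, ceiling(cx + half))
        ys <- max(1L, floor(cy - half)):min(nr, ceiling(cy + half))
        blob <- outer(ys, xs, function(yy, xx)
          events$intensity[k] * exp(-((xx - cx)^2 + (yy - cy)^2) /
                                      (2 * s_px^2)))
        stack[ys, xs, f] <- stack[ys, xs, f] + blob
      }
    }
    list(stack = stack, average = apply(stack, c(1, 2), mean))
  })
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
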