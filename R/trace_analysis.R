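#' Normalise a raw fluorescence trace to 100 x dF/F0
#'
#' Converts per-frame intensities to percent change relative to the temporal
#' mean of the trace: `100 * (F - F0) / F0` with `F0 = mean(F)`. The result
#' is invariant to multiplicative rescaling of the raw intensities.
#'
#' @param raw numeric vector of per-frame intensities (finite, mean > 0).
#' @param times optional frame times in seconds; defaults to a uniform grid
#'   at `frame_interval`.
#' @param frame_interval frame spacing in seconds (default 3 s, i.e. 200
#'   frames per 10 min movie).
#' @param cell_id,region trace labels carried through to the output.
#' @return An object of class `mz_trace`: list with `times` (s), `values`
#'   (100 x dF/F0), `cell_id`, `region`.
#' @export
#' @examples
#' tr <- compute_dff(c(8, 10, 12))
#' tr$values  # -20, 0, 20
compute_dff <- function(raw, times = NULL, frame_interval = 3,
                        cell_id = NA_character_, region = "unknown") {
  if (!all(is.finite(raw))) stop("raw trace contains non-finite values")
  f0 <- mean(raw)
  if (f0 <= 0) stop("F0 (temporal mean) must be > 0")
  if (is.null(times)) times <- (seq_along(raw) - 1) * frame_interval
  if (length(times) != length(raw)) stop("times and raw differ in length")
  structure(list(times = times, values = 100 * (raw - f0) / f0,
                 cell_id = cell_id, region = region),
            class = "mz_trace")
}

#' Asymmetric least squares baseline
#'
#' Penalised least-squares baseline in the Eilers-Boelens formulation:
#' minimises \eqn{\sum_i w_i (y_i - z_i)^2 + 10^{smooth} \sum_i (\Delta^2
#' z_i)^2}, where points above the running baseline get the small asymmetry
#' weight `asym` and points below get `1 - asym`, so the curve hugs the
#' drifting floor of the trace while ignoring positive transients. Weights
#' are re-estimated for up to `iterations` rounds, stopping early once the
#' fraction of points whose weight changed falls below `threshold`.
#'
#' The `smooth` setting is the base-10 logarithm of the roughness penalty
#' (smoothing factor 4 means a penalty of 10^4), matching the convention of
#' common peak-analysis software.
#'
#' @param trace an `mz_trace`, or a numeric vector of (detrended or raw)
#'   values.
#' @param asym asymmetry factor `p` in (0, 1); weights are `p` above the
#'   baseline and `1 - p` below.
#' @param smooth log10 of the second-difference roughness penalty.
#' @param iterations maximum number of reweighting iterations.
#' @param threshold convergence criterion: stop when the fraction of changed
#'   weights drops below this value.
#' @return Numeric vector: the baseline, to be subtracted from the values.
#' @export
als_baseline <- function(trace, asym = 0.001, smooth = 4, iterations = 10,
                         threshold = 0.02) {
  y <- if (inherits(trace, "mz_trace")) trace$values else as.numeric(trace)
  m <- length(y)
  if (m < 10L) stop("trace too short for baseline estimation (need >= 10)")
  lam <- 10^smooth
  D <- Matrix::bandSparse(m - 2L, m,
                          k = 0:2,
                          diagonals = list(rep(1, m - 2L), rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  DtD <- lam * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(iterations)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w_new <- ifelse(y > z, asym, 1 - asym)
    changed <- mean(w_new != w)
    w <- w_new
    if (it > 1L && changed < threshold) break
  }
  z
}

#' Subtract the asymmetric least squares baseline from a trace
#'
#' Convenience wrapper: [als_baseline()] is estimated and subtracted,
#' returning the detrended trace.
#'
#' @inheritParams als_baseline
#' @param ... further settings passed to [als_baseline()].
#' @return The detrended trace (same type as the input).
#' @export
subtract_baseline <- function(trace, ...) {
  base <- als_baseline(trace, ...)
  if (inherits(trace, "mz_trace")) {
    trace$values <- trace$values - base
    trace
  } else {
    as.numeric(trace) - base
  }
}

# Centered moving average with edge shrinkage (window truncated at the ends).
moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window == 1L) return(x)
  k <- rep(1, window)
  num <- stats::filter(x, k, sides = 2)
  den <- stats::filter(rep(1, length(x)), k, sides = 2)
  out <- as.numeric(num / den)
  # stats::filter leaves NAs where the window does not fit; shrink it there
  half <- window %/% 2
  n <- length(x)
  for (i in which(is.na(out))) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Indices that are maxima of their (2*half+1)-point neighbourhood; ties are
# broken toward the earlier frame by requiring strict inequality on the left.
local_maxima <- function(x, half) {
  n <- length(x)
  ok <- rep(TRUE, n)
  for (d in seq_len(half)) {
    left <- c(rep(-Inf, d), x[1:(n - d)])
    right <- c(x[(d + 1):n], rep(-Inf, d))
    ok <- ok & (x > left) & (x >= right)
  }
  which(ok)
}

# Robust noise scale of a trace from first differences (spikes are sparse, so
# differences are noise-dominated).
noise_sigma <- function(x) stats::mad(diff(x)) / sqrt(2)

#' Detect calcium transients in a detrended trace
#'
#' Two-stage peak finder built around the standard settings for these
#' recordings. Stage 1 locates regions of activity on a heavily smoothed
#' copy of the trace (moving average over `smooth_window` frames): candidate
#' peaks are local maxima within a `local_points`-point window that exceed
#' both `height_frac` of the smoothed trace maximum and a noise floor of
#' `noise_mult` smoothed-noise standard deviations. Stage 2 resolves the
#' individual transients inside each candidate region on a lightly smoothed
#' copy (window `local_points`), because the stage-1 smoothing window is
#' wider than a single transient and would otherwise fuse closely spaced
#' spikes. Peak time, amplitude and FWHM are finally measured on the
#' unsmoothed detrended trace, the FWHM by linear interpolation at
#' half-height. Heights are measured from the trace's noise floor (lower
#' quartile plus 0.6745 robust noise SD), which is insensitive both to a
#' baseline-subtraction offset and to the decay tails of frequent
#' transients.
#'
#' @param detrended an `mz_trace` (baseline-subtracted), or a numeric vector
#'   with `frame_interval` giving the frame spacing in seconds.
#' @param smooth_window stage-1 moving-average window (frames).
#' @param local_points width of the local-maximum test window (frames); also
#'   the stage-2 smoothing window.
#' @param height_frac minimum peak height as a fraction of the trace
#'   maximum.
#' @param noise_mult noise floor in units of the robust noise SD, applied on
#'   the matching smoothing scale at both stages.
#' @param frame_interval frame spacing (s), used when `detrended` is a bare
#'   vector.
#' @return A data.frame of spike calls: `peak_time` (s), `frame` (0-based),
#'   `amplitude` (baseline-subtracted height) and `fwhm` (s; `NA` when a
#'   half-height crossing falls outside the recording).
#' @export
detect_spikes <- function(detrended, smooth_window = 20, local_points = 5,
                          height_frac = 0.10, noise_mult = 4,
                          frame_interval = 3) {
  if (inherits(detrended, "mz_trace")) {
    y <- detrended$values
    times <- detrended$times
  } else {
    y <- as.numeric(detrended)
    times <- (seq_along(y) - 1) * frame_interval
  }
  n <- length(y)
  empty <- data.frame(peak_time = numeric(), frame = integer(),
                      amplitude = numeric(), fwhm = numeric())
  if (n < smooth_window) return(empty)
  # zero reference: the noise floor, not the median -- decay tails of
  # frequent transients occupy enough frames to bias the median upward.
  sigma <- noise_sigma(y)
  centre <- unname(stats::quantile(y, 0.25)) + 0.6745 * sigma
  y0 <- y - centre
  half_loc <- max(1L, as.integer(local_points) %/% 2L)

  s_heavy <- moving_average(y0, smooth_window)
  if (max(s_heavy) <= 0) return(empty)
  thr1 <- max(height_frac * max(s_heavy),
              noise_mult * sigma / sqrt(smooth_window))
  cand <- local_maxima(s_heavy, half_loc)
  cand <- cand[s_heavy[cand] >= thr1 & s_heavy[cand] > 0]
  if (!length(cand)) return(empty)

  # candidate regions: contiguous half-height support on the smoothed trace,
  # padded by half the smoothing window; overlapping regions are merged
  regions <- lapply(cand, function(i) {
    hh <- s_heavy[i] / 2
    lo <- i
    while (lo > 1L && s_heavy[lo - 1L] >= hh) lo <- lo - 1L
    hi <- i
    while (hi < n && s_heavy[hi + 1L] >= hh) hi <- hi + 1L
    c(max(1L, lo - smooth_window %/% 2), min(n, hi + smooth_window %/% 2))
  })
  regions <- regions[order(vapply(regions, `[`, numeric(1), 1))]
  merged <- list(regions[[1]])
  for (r in regions[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] <= last[2]) merged[[length(merged)]] <- c(last[1], max(last[2], r[2]))
    else merged[[length(merged) + 1L]] <- r
  }

  s_light <- moving_average(y0, local_points)
  peaks <- integer()
  for (r in merged) {
    idx <- r[1]:r[2]
    sub <- local_maxima(s_light[idx], half_loc) + r[1] - 1L
    if (!length(sub)) next
    reg_max <- max(s_light[idx])
    thr2 <- max(0.4 * reg_max,
                height_frac * max(s_light),
                (noise_mult - 0.5) * sigma / sqrt(local_points))
    sub <- sub[s_light[sub] >= thr2]
    if (!length(sub)) next
    # a secondary sub-peak must be separated from stronger ones by a real
    # valley, otherwise it is a fluctuation on the tail of the same transient
    sub <- sub[order(s_light[sub], decreasing = TRUE)]
    kept <- sub[1]
    for (s in sub[-1]) {
      seps <- vapply(kept, function(k) {
        between <- s_light[min(k, s):max(k, s)]
        min(between) < 0.75 * min(s_light[k], s_light[s])
      }, logical(1))
      if (all(seps)) kept <- c(kept, s)
    }
    peaks <- c(peaks, kept)
  }
  if (!length(peaks)) return(empty)

  # refine each call on the unsmoothed trace
  refined <- vapply(as.integer(peaks), function(i) {
    lo <- max(1L, i - half_loc)
    hi <- min(n, i + half_loc)
    lo + which.max(y0[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # de-duplicate refined peaks closer than the local window
  if (length(refined) > 1L) {
    keep <- rep(TRUE, length(refined))
    for (j in 2:length(refined)) {
      if (refined[j] - refined[j - 1L] < local_points) {
        drop <- if (y0[refined[j]] >= y0[refined[j - 1L]]) j - 1L else j
        keep[drop] <- FALSE
      }
    }
    refined <- refined[keep]
  }

  amp <- y0[refined]
  fwhm <- vapply(seq_along(refined), function(j)
    fwhm_at(y0, refined[j], times), numeric(1))
  data.frame(peak_time = times[refined], frame = refined - 1L,
             amplitude = amp, fwhm = fwhm)
}

# FWHM of the transient peaking at index i, by linear interpolation of the
# half-height crossings on the unsmoothed trace. A single sample dipping
# below half height does not terminate the walk (noise robustness); the
# crossing is confirmed by the next sample outward.
fwhm_at <- function(y, i, times) {
  hh <- y[i] / 2
  n <- length(y)
  l <- i
  while (l > 1L && (y[l - 1L] > hh || (l > 2L && y[l - 2L] > hh))) l <- l - 1L
  r <- i
  while (r < n && (y[r + 1L] > hh || (r < n - 1L && y[r + 2L] > hh))) r <- r + 1L
  if (l == 1L && y[1L] > hh) return(NA_real_)
  if (r == n && y[n] > hh) return(NA_real_)
  while (l < i && y[l] <= hh) l <- l + 1L   # step back inside after a dip
  while (r > i && y[r] <= hh) r <- r - 1L
  t_left <- if (l == i && y[i] == hh) times[i] else {
    f <- (y[l] - hh) / (y[l] - y[l - 1L])
    times[l] - f * (times[l] - times[l - 1L])
  }
  t_right <- {
    f <- (y[r] - hh) / (y[r] - y[r + 1L])
    times[r] + f * (times[r + 1L] - times[r])
  }
  t_right - t_left
}

#' Summary statistics of a spike train
#'
#' @param spikes a data.frame of calls from [detect_spikes()].
#' @param duration recording duration (s).
#' @return A data.frame row: `frequency` (mHz, `1000 * n / duration`),
#'   `mean_amplitude` (`NA` when no spikes), `mean_fwhm` (s), `n_spikes`,
#'   `duration` (s).
#' @export
#' @examples
#' trace_stats(data.frame(peak_time = c(10, 200, 400), frame = c(3, 66, 133),
#'                        amplitude = c(40, 55, 47), fwhm = c(15, 14, 16)),
#'             duration = 600)  # frequency 5 mHz
trace_stats <- function(spikes, duration) {
  if (duration <= 0) stop("duration must be > 0")
  n <- nrow(spikes)
  data.frame(frequency = 1000 * n / duration,
             mean_amplitude = if (n) mean(spikes$amplitude) else NA_real_,
             mean_fwhm = if (n) mean(spikes$fwhm, na.rm = TRUE) else NA_real_,
             n_spikes = n,
             duration = duration)
}
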