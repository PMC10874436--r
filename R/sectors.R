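#' Label marginal-zone sectors on an image
#'
#' Builds an integer mask dividing an annulus arc into `n_sectors` sectors of
#' equal arc length, numbered 1..n starting from `theta_start` (by
#' convention the cut edge, so sector 1 is s1, nearest the edge). Pixels
#' outside the annulus arc are 0.
#'
#' Pixel coordinates follow the image convention: x = column, y = row,
#' origin at the top-left; angles are measured anticlockwise from the
#' positive x axis after flipping y.
#'
#' @param nrow,ncol image dimensions (pixels).
#' @param centre numeric length-2, annulus centre `(x, y)` in pixels.
#' @param r_inner,r_outer annulus radii (pixels).
#' @param theta_start start angle of the arc (degrees).
#' @param theta_span angular span of the arc (degrees, anticlockwise).
#' @param n_sectors number of equal sectors.
#' @return Integer matrix `nrow` x `ncol` with values 0..`n_sectors`.
#' @export
annulus_sector_mask <- function(nrow, ncol, centre, r_inner, r_outer,
                                theta_start = 0, theta_span = 180,
                                n_sectors = 4) {
  stopifnot(r_outer > r_inner, r_inner >= 0, n_sectors >= 1, theta_span > 0)
  x <- matrix(rep(seq_len(ncol), each = nrow), nrow, ncol) - centre[1]
  y <- centre[2] - matrix(rep(seq_len(nrow), ncol), nrow, ncol)  # y-flip
  r <- sqrt(x^2 + y^2)
  theta <- (atan2(y, x) * 180 / pi) %% 360
  rel <- (theta - theta_start) %% 360
  inside <- r >= r_inner & r <= r_outer & rel < theta_span
  sector <- 1L + pmin(n_sectors - 1L, floor(rel / (theta_span / n_sectors)))
  mask <- matrix(0L, nrow, ncol)
  mask[inside] <- as.integer(sector[inside])
  mask
}

#' Sector histogram analysis of a temporal-average image
#'
#' For each sector of the marginal-zone mask, histograms the pixel
#' intensities of the temporal-average image, fits a log-normal curve to the
#' histogram by nonlinear least squares, and reports the count of pixels
#' above the intensity threshold together with the fitted peak centre (the
#' mode of the log-normal). Comparing the per-sector above-threshold counts
#' and peak centres across time quantifies the spatial gradient of calcium
#' activity along the marginal zone.
#'
#' @param avg_image numeric matrix, the temporal-average image.
#' @param mz_mask integer matrix from [annulus_sector_mask()] (values
#'   0..`n_sectors`), same dimensions as the image.
#' @param n_sectors number of sectors expected in the mask.
#' @param threshold intensity threshold; pixels strictly above it are
#'   counted.
#' @param binwidth histogram bin width (intensity units).
#' @return A data.frame with one row per sector: `sector`, `n_pixels`,
#'   `above_threshold_count`, `meanlog`, `sdlog`, `scale` (fitted curve
#'   parameters), `peak_centre` (mode, `exp(meanlog - sdlog^2)`), `fit_ok`;
#'   histograms are attached as the `"histograms"` attribute (list of
#'   data.frames `mid`, `count`). Sectors where the fit fails report
#'   `fit_ok = FALSE` with `NA` parameters.
#' @export
sector_histogram <- function(avg_image, mz_mask, n_sectors = 4,
                             threshold = 6, binwidth = 1) {
  if (!all(dim(avg_image) == dim(mz_mask)))
    stop("image and mask dimensions differ")
  hists <- vector("list", n_sectors)
  rows <- vector("list", n_sectors)
  for (s in seq_len(n_sectors)) {
    px <- avg_image[mz_mask == s]
    if (!length(px)) stop("sector ", s, " is empty")
    brk <- seq(floor(min(px) / binwidth) * binwidth,
               ceiling(max(px) / binwidth) * binwidth + binwidth,
               by = binwidth)
    h <- graphics::hist(px, breaks = brk, plot = FALSE)
    fit <- fit_lognormal_hist(h$mids, h$counts, px, binwidth)
    hists[[s]] <- data.frame(mid = h$mids, count = h$counts)
    rows[[s]] <- data.frame(sector = s, n_pixels = length(px),
                            above_threshold_count = sum(px > threshold),
                            meanlog = fit["meanlog"], sdlog = fit["sdlog"],
                            scale = fit["scale"],
                            peak_centre = exp(fit["meanlog"] - fit["sdlog"]^2),
                            fit_ok = is.finite(fit["meanlog"]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "histograms") <- hists
  out
}

# Least-squares log-normal curve fit to histogram counts; moment-based
# starting values from the positive pixels.
fit_lognormal_hist <- function(mids, counts, px, binwidth) {
  pos <- px[px > 0]
  bad <- c(meanlog = NA_real_, sdlog = NA_real_, scale = NA_real_)
  if (length(pos) < 10) return(bad)
  df <- data.frame(x = mids[mids > 0], y = counts[mids > 0])
  if (sum(df$y > 0) < 4) return(bad)   # too few occupied bins to fit a curve
  start <- list(meanlog = mean(log(pos)),
                sdlog = max(stats::sd(log(pos)), 1e-3),
                scale = length(px) * binwidth)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ scale * stats::dlnorm(x, meanlog, sdlog),
                      data = df, start = start,
                      lower = c(-Inf, 1e-4, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad)
  co <- stats::coef(fit)
  c(meanlog = unname(co["meanlog"]), sdlog = abs(unname(co["sdlog"])),
    scale = unname(co["scale"]))
}
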