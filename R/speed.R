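#' Minimum transmission speed along the marginal zone
#'
#' Worked-example arithmetic for long-range positional signalling: an
#' embryonic disc of the given diameter (in cell lengths) has a marginal-zone
#' half-circumference of \eqn{\pi d / 2} cell lengths; a signal that must
#' traverse that arc within `traverse_h` hours needs a speed of at least
#' half-circumference / (60 * traverse_h) cells per minute.
#'
#' The conventional presentation of this estimate rounds the
#' half-circumference to the nearest `round_span_to` cell lengths before
#' dividing (pi * 240 / 2 = 376.99 is quoted as ~380, giving
#' 380 / 300 = 1.27 cells/min); both the exact and the rounded chain are
#' returned.
#'
#' @param diameter_cells disc diameter in cell lengths.
#' @param traverse_h available traversal time (h).
#' @param round_span_to granularity (cell lengths) for the rounded
#'   presentation of the half-circumference; use `NULL` to skip rounding.
#' @return A list with `half_circumference_cells` (exact),
#'   `half_circumference_rounded`, `min_speed_cells_per_min` (from the
#'   rounded span) and `min_speed_exact` (from the exact span).
#' @export
#' @examples
#' mz_transit_speed(240, 5)
mz_transit_speed <- function(diameter_cells = 240, traverse_h = 5,
                             round_span_to = 10) {
  stopifnot(diameter_cells > 0, traverse_h > 0)
  half <- pi * diameter_cells / 2
  half_r <- if (is.null(round_span_to)) half else
    round(half / round_span_to) * round_span_to
  list(half_circumference_cells = half,
       half_circumference_rounded = half_r,
       min_speed_cells_per_min = half_r / (60 * traverse_h),
       min_speed_exact = half / (60 * traverse_h))
}
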