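#' Model parameters for the marginal-zone ring
#'
#' Constructs and validates the parameter set of the three-variable ring
#' model: per-cell BMP4 concentration \eqn{B_i}, calcium activity \eqn{C_i}
#' and cVG1/GDF3 concentration \eqn{V_i}, with a latched binary streak
#' identity \eqn{A_i}. Concentrations are in arbitrary units, time in hours,
#' space in cell lengths.
#'
#' The defaults are the package's reference parameter set, calibrated so that
#' (a) the initial anterior-posterior BMP4 gradient keeps \eqn{B > \beta_V}
#' anteriorly and \eqn{B < \beta_V} posteriorly, and (b) the two scenario
#' behaviours hold: an intact ring commits a single posterior streak arc, and
#' an obliquely cut anterior half resolves transient bilateral cVG1 induction
#' into a single streak on the posterior-leaning edge. Users reproducing runs
#' of the originally published model should override these with the values
#' from its public repository.
#'
#' @param k_B BMP4 production rate (conc/h), gated by calcium activity.
#' @param alpha calcium-activity threshold for BMP4 production (activity
#'   units); "very low" so that any transmitted activity sustains BMP4.
#' @param gamma0 basal BMP4 decay rate (1/h).
#' @param gamma_C calcium-dependent BMP4 decay coefficient (per activity unit
#'   per hour).
#' @param gamma_V cVG1-dependent BMP4 decay coefficient (per conc per hour).
#' @param k_C calcium-activity production rate in committed (streak) cells
#'   (activity/h).
#' @param D calcium transmission coefficient between neighbouring cells
#'   (cell-length^2/h).
#' @param dx cell spacing (cell lengths).
#' @param lambda calcium-activity decay rate (1/h).
#' @param k_V cVG1 production rate (conc/h), active where BMP4 is below
#'   `beta_V`.
#' @param mu cVG1 decay rate (1/h).
#' @param beta_C BMP4 threshold for irreversible streak commitment (conc).
#' @param beta_V BMP4 threshold for cVG1 induction (conc); must exceed
#'   `beta_C`.
#' @param n_cells number of cells on the ring.
#' @param dt forward-Euler step (h). Must satisfy the explicit-scheme
#'   stability bound `dt <= dx^2 / (2 * D)`.
#' @param production_mode `"heaviside"` uses the step-function production
#'   terms (with the convention H(0) = 1); `"hill"` replaces both production
#'   switches by Hill functions of coefficient `hill_n`.
#' @param hill_n Hill coefficient for `production_mode = "hill"`.
#'
#' @return An object of class `mz_params` (a validated named list).
#' @seealso [scenario_config()], [simulate_ring()]
#' @export
#' @examples
#' p <- mz_params()
#' p$beta_V > p$beta_C
mz_params <- function(k_B = 2,
                      alpha = 0.001,
                      gamma0 = 0.4,
                      gamma_C = 2,
                      gamma_V = 0.5,
                      k_C = 100,
                      D = 8000,
                      dx = 1,
                      lambda = 6,
                      k_V = 2,
                      mu = 2,
                      beta_C = 1,
                      beta_V = 1.4,
                      n_cells = 100,
                      dt = 5e-5,
                      production_mode = c("heaviside", "hill"),
                      hill_n = 4) {
  production_mode <- match.arg(production_mode)
  p <- list(k_B = k_B, alpha = alpha, gamma0 = gamma0, gamma_C = gamma_C,
            gamma_V = gamma_V, k_C = k_C, D = D, dx = dx, lambda = lambda,
            k_V = k_V, mu = mu, beta_C = beta_C, beta_V = beta_V,
            n_cells = as.integer(n_cells), dt = dt,
            production_mode = production_mode, hill_n = hill_n)
  validate_params(p)
  class(p) <- "mz_params"
  p
}

#' The reference parameter set
#'
#' Returns [mz_params()] with all defaults, optionally overriding fields.
#'
#' @param ... overrides passed on to [mz_params()].
#' @return An `mz_params` object.
#' @export
reference_params <- function(...) mz_params(...)

validate_params <- function(p) {
  rates <- c("k_B", "alpha", "gamma0", "gamma_C", "gamma_V", "k_C", "D",
             "lambda", "k_V", "mu", "beta_C", "beta_V")
  for (nm in rates) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter '", nm, "' must be a single finite non-negative number",
           call. = FALSE)
  }
  if (!is.numeric(p$dx) || p$dx <= 0) stop("dx must be > 0", call. = FALSE)
  if (!is.numeric(p$dt) || p$dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (p$beta_V <= p$beta_C)
    stop("threshold ordering violated: beta_V > beta_C is required ",
         "(cVG1 induction must precede streak commitment as BMP4 falls)",
         call. = FALSE)
  if (p$n_cells < 3L)
    stop("n_cells must be at least 3", call. = FALSE)
  if (p$D > 0 && p$dt > p$dx^2 / (2 * p$D))
    stop(sprintf(paste0("explicit-scheme stability violated: dt = %g exceeds ",
                        "dx^2/(2*D) = %g"), p$dt, p$dx^2 / (2 * p$D)),
         call. = FALSE)
  if (p$production_mode == "hill" && (!is.numeric(p$hill_n) || p$hill_n <= 0))
    stop("hill_n must be > 0", call. = FALSE)
  invisible(p)
}

#' Scenario configuration for ring simulations
#'
#' Describes a simulation run: an intact ring, or an anterior half obtained
#' by removing an arc of cells through the posterior pole. Time is measured
#' from the cut: the pre-cut (intact) phase runs over negative times and the
#' cut defines t = 0.
#'
#' The cut arc runs from `cut_left_index` through the posterior pole (the
#' seam between the last and first cell) to `cut_right_index`, inclusive.
#' A nonzero `obliquity_offset` shifts the whole removed arc by that many
#' cells towards lower indices, modelling a slightly oblique cut with the
#' right side leaning posteriorly: the right edge cell of the remaining
#' segment then sits closer to the posterior pole and carries less BMP4 than
#' the left edge cell, which seeds the left/right competition.
#'
#' @param scenario `"intact"` or `"anterior_half"`.
#' @param pre_cut_duration duration of the intact phase (h).
#' @param post_cut_duration duration of the post-cut phase (h); ignored for
#'   the intact scenario.
#' @param cut_left_index,cut_right_index first and last removed cell
#'   (0-based, inclusive arc through the posterior pole) before the obliquity
#'   shift is applied.
#' @param obliquity_offset integer shift of the removed arc (cells). Positive
#'   values lean the right side posteriorly. An `anterior_half` run with
#'   offset 0 is perfectly symmetric and will not resolve to a single side;
#'   it is allowed (it is the control for mirror-symmetry checks) but raises
#'   a warning from [simulate_ring()].
#' @param record_interval time between recorded snapshots (h).
#' @return An object of class `mz_scenario`.
#' @export
scenario_config <- function(scenario = c("intact", "anterior_half"),
                            pre_cut_duration = 3,
                            post_cut_duration = 6,
                            cut_left_index = 90,
                            cut_right_index = 9,
                            obliquity_offset = 2,
                            record_interval = 0.02) {
  scenario <- match.arg(scenario)
  if (pre_cut_duration <= 0) stop("pre_cut_duration must be > 0")
  if (scenario == "anterior_half" && post_cut_duration <= 0)
    stop("post_cut_duration must be > 0 for the anterior_half scenario")
  if (record_interval <= 0) stop("record_interval must be > 0")
  cfg <- list(scenario = scenario,
              pre_cut_duration = pre_cut_duration,
              post_cut_duration = post_cut_duration,
              cut_left_index = as.integer(cut_left_index),
              cut_right_index = as.integer(cut_right_index),
              obliquity_offset = as.integer(obliquity_offset),
              record_interval = record_interval)
  class(cfg) <- "mz_scenario"
  cfg
}

# Removed cell ids (0-based) for a scenario, with the obliquity shift applied.
cut_arc_ids <- function(config, n_cells) {
  l <- (config$cut_left_index - config$obliquity_offset) %% n_cells
  r <- (config$cut_right_index - config$obliquity_offset) %% n_cells
  if (l <= r) l:r else c(l:(n_cells - 1L), 0L:r)
}
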