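#' Initial state of the intact marginal-zone ring
#'
#' Builds the pre-streak initial condition: a shallow linear BMP4 gradient,
#' highest at the anterior pole and lowest at the posterior pole, with zero
#' cVG1, zero calcium activity and no committed cells. The posterior pole
#' lies on the seam between the last and first cell, the anterior pole
#' diametrically opposite, so the two cells flanking each pole share the
#' anchor values: B = 1.1 on cells 0 and n-1, B = 2.2 on the two mid-ring
#' cells (49 and 50 for the default 100-cell ring). In between, B is linear
#' in the arc distance from the posterior pole, measured between cell
#' centres.
#'
#' @param params an [mz_params()] object.
#' @param b_posterior,b_anterior BMP4 anchor values at the posterior and
#'   anterior poles (conc).
#' @return An object of class `mz_ring_state`: a list with simulation time
#'   `t` (h), numeric vectors `B`, `C`, `V`, integer latch `A`, `topology`
#'   (`"periodic"` or `"segment"`), 0-based `cell_ids`, and a
#'   clamped-negative counter `clamp_count`.
#' @export
#' @examples
#' s <- init_intact_state(mz_params())
#' s$B[c(1, 100)]   # cells 0 and 99: 1.1
#' s$B[c(50, 51)]   # cells 49 and 50: 2.2
init_intact_state <- function(params, b_posterior = 1.1, b_anterior = 2.2) {
  validate_params(params)
  n <- params$n_cells
  i <- 0:(n - 1L)
  d <- pmin(i, n - 1L - i)             # arc distance to the nearer of cells 0, n-1
  d_max <- max(d)
  B <- b_posterior + (b_anterior - b_posterior) * d / d_max
  state <- list(t = 0, B = B, C = numeric(n), V = numeric(n),
                A = integer(n), topology = "periodic",
                cell_ids = i, clamp_count = 0L)
  class(state) <- "mz_ring_state"
  state
}

# Production switches. In heaviside mode the boundary belongs to the "on"
# branch: H(x) = 1 for x >= 0. In hill mode the switches are smooth with the
# configured coefficient; the decreasing switch is K^n / (K^n + x^n).
switch_up <- function(x, threshold, params) {
  if (params$production_mode == "heaviside") {
    as.numeric(x >= threshold)
  } else if (threshold <= 0) {
    rep(1, length(x))                  # degenerate half-saturation: always on
  } else {
    h <- params$hill_n
    x^h / (threshold^h + x^h)
  }
}

switch_down <- function(x, threshold, params) {
  if (params$production_mode == "heaviside") {
    as.numeric(x <= threshold)
  } else {
    h <- params$hill_n
    threshold^h / (threshold^h + x^h)
  }
}

# Discrete Laplacian of C under the state's topology: periodic wraps around;
# on a segment the missing neighbour mirrors the edge cell (no-flux), so no
# calcium crosses the wound.
ring_laplacian <- function(C, topology) {
  n <- length(C)
  if (topology == "periodic") {
    Cm <- C[c(n, 1:(n - 1L))]
    Cp <- C[c(2:n, 1L)]
  } else {
    Cm <- C[c(1L, 1:(n - 1L))]
    Cp <- C[c(2:n, n)]
  }
  Cp + Cm - 2 * C
}

#' Per-cell rate of change of BMP4
#'
#' \eqn{dB_i/dt = k_B P(C_i) - (\gamma_0 + \gamma_C C_i + \gamma_V V_i) B_i},
#' where the production switch P is the Heaviside step \eqn{H(C_i - \alpha)}
#' (1 where \eqn{C_i - \alpha \ge 0}) or the increasing Hill function in hill
#' mode. Calcium activity above the very low threshold `alpha` sustains BMP4
#' production, while both calcium activity and cVG1 accelerate its decay.
#'
#' @param state an `mz_ring_state`.
#' @param params an `mz_params`.
#' @return Numeric vector of per-cell rates (conc/h).
#' @export
dB_dt <- function(state, params) {
  stopifnot(length(state$B) == length(state$C),
            length(state$B) == length(state$V))
  prod <- params$k_B * switch_up(state$C, params$alpha, params)
  prod - (params$gamma0 + params$gamma_C * state$C +
            params$gamma_V * state$V) * state$B
}

#' Per-cell rate of change of calcium activity
#'
#' \eqn{dC_i/dt = k_C A_i + D/\Delta x^2 (C_{i+1} + C_{i-1} - 2 C_i) -
#' \lambda C_i}: committed (streak) cells are calcium sources, activity is
#' transmitted to neighbours through gap junctions (discrete diffusion), and
#' decays linearly. On a periodic ring the transmission term conserves total
#' activity; on a cut segment the edges are no-flux.
#'
#' @inheritParams dB_dt
#' @return Numeric vector of per-cell rates (activity/h).
#' @export
dC_dt <- function(state, params) {
  params$k_C * state$A +
    (params$D / params$dx^2) * ring_laplacian(state$C, state$topology) -
    params$lambda * state$C
}

#' Per-cell rate of change of cVG1
#'
#' \eqn{dV_i/dt = k_V Q(B_i) - \mu V_i}, where the production switch Q is the
#' decreasing step \eqn{H(\beta_V - B_i)} (1 where \eqn{\beta_V - B_i \ge 0})
#' or the decreasing Hill function in hill mode: cVG1 is induced wherever
#' BMP4 has dropped below the first threshold `beta_V`.
#'
#' @inheritParams dB_dt
#' @return Numeric vector of per-cell rates (conc/h).
#' @export
dV_dt <- function(state, params) {
  params$k_V * switch_down(state$B, params$beta_V, params) -
    params$mu * state$V
}

#' Update the streak-identity latch
#'
#' Sets \eqn{A_i = 1} wherever \eqn{B_i \le \beta_C} (the boundary included).
#' The latch is irreversible: once a cell has committed it stays committed
#' even if BMP4 later rises above the threshold.
#'
#' @inheritParams dB_dt
#' @return The state with the latch updated.
#' @export
update_latch <- function(state, params) {
  state$A <- as.integer(state$A | (state$B <= params$beta_C))
  state
}

#' Advance the ring state by one forward-Euler step
#'
#' Updates B, C and V by forward Euler with step `params$dt`, clamps any
#' negative values produced by discretisation error to zero (counted in
#' `state$clamp_count`), increments `t`, and then updates the streak latch
#' from the new BMP4 field. Aborts with diagnostics if the state becomes
#' non-finite (instability).
#'
#' @inheritParams dB_dt
#' @return The advanced `mz_ring_state`.
#' @export
euler_step <- function(state, params) {
  B <- state$B + params$dt * dB_dt(state, params)
  C <- state$C + params$dt * dC_dt(state, params)
  V <- state$V + params$dt * dV_dt(state, params)
  neg <- sum(B < 0) + sum(C < 0) + sum(V < 0)
  if (neg > 0L) {
    B[B < 0] <- 0
    C[C < 0] <- 0
    V[V < 0] <- 0
    state$clamp_count <- state$clamp_count + neg
  }
  if (!all(is.finite(B)) || !all(is.finite(C)) || !all(is.finite(V)))
    stop(sprintf(paste0("non-finite state at t = %.6f h (first bad cell: B %s,",
                        " C %s, V %s); reduce dt or D"),
                 state$t + params$dt,
                 which(!is.finite(B))[1], which(!is.finite(C))[1],
                 which(!is.finite(V))[1]),
         call. = FALSE)
  state$B <- B
  state$C <- C
  state$V <- V
  state$t <- state$t + params$dt
  update_latch(state, params)
}

#' Remove the posterior arc, leaving an anterior half segment
#'
#' Deletes the cells of the configured cut arc (which must contain every
#' committed cell), turning the ring into an open segment with no-flux
#' (mirror) boundary conditions at the two wound edges. With a positive
#' obliquity offset the removed arc is rotated so that the right edge of the
#' remaining segment lies closer to the posterior pole, hence carries less
#' BMP4 at cut time than the left edge. The cut defines t = 0.
#'
#' @param state an `mz_ring_state` on a periodic ring.
#' @param config an [scenario_config()] object.
#' @return The cut `mz_ring_state` (topology `"segment"`); `cell_ids` keeps
#'   the original ring indices, ordered from the right edge to the left edge.
#' @export
apply_anterior_half_cut <- function(state, config) {
  if (state$topology != "periodic")
    stop("state is already a segment", call. = FALSE)
  n <- length(state$B)
  removed <- cut_arc_ids(config, n)
  committed <- state$cell_ids[state$A == 1L]
  if (!all(committed %in% removed))
    stop("cut arc must contain every cell with streak identity; cells ",
         paste(setdiff(committed, removed), collapse = ", "),
         " are committed but retained", call. = FALSE)
  keep <- !(state$cell_ids %in% removed)
  # order retained cells along the segment from the right edge to the left
  r_edge <- (config$cut_right_index - config$obliquity_offset) %% n
  ids <- state$cell_ids[keep]
  ord <- order((ids - r_edge) %% n)
  idx <- which(keep)[ord]
  state$B <- state$B[idx]
  state$C <- state$C[idx]
  state$V <- state$V[idx]
  state$A <- state$A[idx]
  state$cell_ids <- state$cell_ids[idx]
  state$topology <- "segment"
  state$t <- 0
  state
}

#' Simulate an intact or anterior-half scenario
#'
#' Runs the pre-cut (intact) phase from t = -`pre_cut_duration` to the cut at
#' t = 0, and, for the `anterior_half` scenario, applies the oblique cut and
#' continues to t = `post_cut_duration`. Snapshots are recorded every
#' `record_interval` hours and per-cell first-commitment times are collected.
#' The run is fully deterministic.
#'
#' @param config an [scenario_config()] object.
#' @param params an [mz_params()] object.
#' @param init optional initial state (defaults to [init_intact_state()]).
#' @return An object of class `mz_sim_record`: a list with
#'   \describe{
#'     \item{pre, post}{phase records, each with `times` (h) and snapshot
#'       matrices `B`, `C`, `V`, `A` (rows = snapshots, columns = cells) plus
#'       the 0-based `cell_ids` labelling the columns; `post` is `NULL` for
#'       the intact scenario.}
#'     \item{events}{data.frame `cell_id`, `time_h` of first commitment.}
#'     \item{final}{the final `mz_ring_state`.}
#'     \item{streak_segments}{[detect_streak_segments()] of the final state.}
#'   }
#' @export
simulate_ring <- function(config, params, init = NULL) {
  validate_params(params)
  if (config$scenario == "anterior_half" && config$obliquity_offset == 0L)
    warning("anterior_half scenario with obliquity_offset = 0 is perfectly ",
            "symmetric and will not resolve to a single side")
  state <- if (is.null(init)) init_intact_state(params) else init
  state$t <- -config$pre_cut_duration
  events <- new.env(parent = emptyenv())
  events$time <- rep(NA_real_, params$n_cells)
  note_commits <- function(state) {
    id1 <- state$cell_ids + 1L
    newly <- id1[state$A == 1L & is.na(events$time[id1])]
    if (length(newly)) events$time[newly] <- state$t
  }
  note_commits(state)

  pre <- run_phase(state, params, config$pre_cut_duration,
                   config$record_interval, note_commits)
  state <- pre$state

  post <- NULL
  if (config$scenario == "anterior_half") {
    state <- apply_anterior_half_cut(state, config)
    post <- run_phase(state, params, config$post_cut_duration,
                      config$record_interval, note_commits)
    state <- post$state
  }

  committed <- which(!is.na(events$time))
  rec <- list(pre = pre$record, post = post$record,
              events = data.frame(cell_id = committed - 1L,
                                  time_h = events$time[committed]),
              final = state,
              params = params, config = config)
  class(rec) <- "mz_sim_record"
  rec$streak_segments <- detect_streak_segments(rec)
  rec
}

# Advance `state` by `duration` hours, snapshotting every `record_interval`.
run_phase <- function(state, params, duration, record_interval, note_commits) {
  n_steps <- max(1L, round(duration / params$dt))
  every <- max(1L, round(record_interval / params$dt))
  n_snap <- floor(n_steps / every) + 1L
  n <- length(state$B)
  times <- numeric(n_snap)
  Bm <- matrix(NA_real_, n_snap, n)
  Cm <- matrix(NA_real_, n_snap, n)
  Vm <- matrix(NA_real_, n_snap, n)
  Am <- matrix(NA_integer_, n_snap, n)
  snap <- function(k, s) {
    times[k] <<- s$t
    Bm[k, ] <<- s$B; Cm[k, ] <<- s$C; Vm[k, ] <<- s$V; Am[k, ] <<- s$A
  }
  snap(1L, state)
  k <- 1L
  for (step in seq_len(n_steps)) {
    state <- euler_step(state, params)
    note_commits(state)
    if (step %% every == 0L) {
      k <- k + 1L
      snap(k, state)
    }
  }
  record <- list(times = times[1:k], B = Bm[1:k, , drop = FALSE],
                 C = Cm[1:k, , drop = FALSE], V = Vm[1:k, , drop = FALSE],
                 A = Am[1:k, , drop = FALSE], cell_ids = state$cell_ids,
                 topology = state$topology)
  list(state = state, record = record)
}

#' Contiguous streak arcs in the final state
#'
#' Finds maximal contiguous runs of committed cells (A = 1) in the final
#' snapshot, wrapping around the index seam on a periodic ring. Each arc is
#' reported with its span in cells and the earliest commitment time among its
#' members.
#'
#' @param record an `mz_sim_record` (or an `mz_ring_state`; then onset times
#'   are `NA`).
#' @return A data.frame with columns `start_id`, `end_id` (0-based original
#'   cell ids, inclusive), `span` (cells) and `onset_h`; zero rows if no cell
#'   committed.
#' @export
detect_streak_segments <- function(record) {
  if (inherits(record, "mz_sim_record")) {
    state <- record$final
    events <- record$events
  } else {
    state <- record
    events <- data.frame(cell_id = integer(), time_h = numeric())
  }
  A <- state$A
  n <- length(A)
  empty <- data.frame(start_id = integer(), end_id = integer(),
                      span = integer(), onset_h = numeric())
  if (!any(A == 1L)) return(empty)
  if (all(A == 1L)) {
    onset <- if (nrow(events)) min(events$time_h) else NA_real_
    return(data.frame(start_id = state$cell_ids[1], end_id = state$cell_ids[n],
                      span = n, onset_h = onset))
  }
  # rotate a periodic ring so position 1 is uncommitted: runs cannot straddle
  # the seam after rotation
  rot <- 0L
  if (state$topology == "periodic" && A[1] == 1L) {
    rot <- which(A == 0L)[1] - 1L
    A <- c(A[(rot + 1L):n], A[1:rot])
  }
  ids <- state$cell_ids
  if (rot > 0L) ids <- c(ids[(rot + 1L):n], ids[1:rot])
  r <- rle(A)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values == 1L
  out <- data.frame(start_id = ids[starts[ok]], end_id = ids[ends[ok]],
                    span = r$lengths[ok])
  out$onset_h <- vapply(seq_len(nrow(out)), function(j) {
    members <- arc_member_ids(out$start_id[j], out$end_id[j], ids)
    tt <- events$time_h[events$cell_id %in% members]
    if (length(tt)) min(tt) else NA_real_
  }, numeric(1))
  out
}

# Original cell ids belonging to an arc from start_id to end_id along the
# stored cell order.
arc_member_ids <- function(start_id, end_id, ids) {
  i <- match(start_id, ids)
  j <- match(end_id, ids)
  if (i <= j) ids[i:j] else c(ids[i:length(ids)], ids[1:j])
}

#' @export
print.mz_sim_record <- function(x, ...) {
  cat("Marginal-zone ring simulation (", x$config$scenario, " scenario)\n",
      sep = "")
  cat("  cells:", x$params$n_cells,
      "| mode:", x$params$production_mode,
      "| dt:", x$params$dt, "h\n")
  cat("  phases: pre-cut", format(-x$pre$times[1], digits = 4), "h",
      if (!is.null(x$post))
        paste("; post-cut", format(max(x$post$times), digits = 4), "h"), "\n")
  cat("  committed cells:", nrow(x$events),
      "| clamped negatives:", x$final$clamp_count, "\n")
  if (nrow(x$streak_segments)) {
    cat("  streak arcs:\n")
    print(x$streak_segments, row.names = FALSE)
  } else cat("  streak arcs: none\n")
  invisible(x)
}
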