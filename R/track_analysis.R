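#' Link firing events into intercellular calcium tracks
#'
#' Reconstructs tracks from a table of firing events by linear-assignment
#' linking: events in consecutive frames are matched by minimising summed
#' squared distance, with links longer than `max_link` forbidden
#' (unmatched events start or end a track); track fragments whose end and
#' start are at most `gap_distance` apart and at most `gap_frames` frames
#' apart are then merged by a second assignment round (gap closing), so a
#' one-frame dropout does not break a track. Optionally, a fragment that
#' starts within `split_distance` of the body of another track one frame
#' earlier is annotated as a branch splitting off that track.
#'
#' Non-link alternatives are priced at 1.05 times the largest accepted link
#' cost in the round, the standard linear-assignment tracking convention.
#'
#' @param events data.frame with columns `frame` (integer), `time_s`, `x_um`,
#'   `y_um` and optionally `intensity`.
#' @param max_link maximum frame-to-frame link distance (um).
#' @param gap_frames maximum frame gap bridged by gap closing (a gap of 2
#'   frames means one missing frame).
#' @param gap_distance maximum gap-closing distance (um).
#' @param splitting whether to annotate branch tracks.
#' @param split_distance maximum splitting distance (um).
#' @return An object of class `mz_tracks`: list with
#'   \describe{
#'     \item{events}{the input events with a `track_id` column (every event
#'       belongs to exactly one track; singletons included).}
#'     \item{summary}{per-track data.frame: `track_id`, `n_events`,
#'       `duration_s`, `start_x`, `start_y`, `end_x`, `end_y`, `angle_deg`,
#'       `quadrant`, and `split_from` (the track a branch splits off, or
#'       `NA`).}
#'   }
#' @export
link_events <- function(events, max_link = 90, gap_frames = 2,
                        gap_distance = 90, splitting = TRUE,
                        split_distance = 90) {
  req <- c("frame", "time_s", "x_um", "y_um")
  if (!all(req %in% names(events)))
    stop("events must have columns ", paste(req, collapse = ", "))
  events <- events[order(events$frame, events$x_um, events$y_um), ,
                   drop = FALSE]
  n_ev <- nrow(events)
  succ <- rep(NA_integer_, n_ev)       # successor event row within a track
  if (n_ev == 0L)
    return(structure(list(events = cbind(events, track_id = integer(0)),
                          summary = empty_track_summary()),
                     class = "mz_tracks"))

  frames <- sort(unique(events$frame))
  by_frame <- split(seq_len(n_ev), events$frame)
  # frame-to-frame linking
  for (fi in seq_len(length(frames) - 1L)) {
    if (frames[fi + 1L] - frames[fi] != 1L) next
    a <- by_frame[[as.character(frames[fi])]]
    b <- by_frame[[as.character(frames[fi + 1L])]]
    links <- lap_link(events[a, ], events[b, ], max_link)
    if (length(links)) succ[a[as.integer(names(links))]] <- b[links]
  }

  track_of <- assemble_tracks(succ)

  # gap closing between fragment ends and fragment starts
  starts <- tapply(seq_len(n_ev), track_of, function(ix) ix[1])
  ends <- tapply(seq_len(n_ev), track_of, function(ix) ix[length(ix)])
  repeat {
    e_idx <- as.integer(ends)
    s_idx <- as.integer(starts)
    gap <- outer(events$frame[s_idx], events$frame[e_idx], `-`)
    dx <- outer(events$x_um[s_idx], events$x_um[e_idx], `-`)
    dy <- outer(events$y_um[s_idx], events$y_um[e_idx], `-`)
    dist <- sqrt(dx^2 + dy^2)
    feasible <- gap >= 2 & gap <= gap_frames & dist <= gap_distance
    if (!any(feasible)) break
    cost <- ifelse(feasible, dist^2, Inf)
    links <- lap_pair(cost)            # links[start_fragment] = end_fragment
    if (!length(links)) break
    for (k in seq_len(nrow(links))) {
      succ[e_idx[links[k, 2L]]] <- s_idx[links[k, 1L]]
    }
    track_of <- assemble_tracks(succ)
    starts <- tapply(seq_len(n_ev), track_of, function(ix) ix[1])
    ends <- tapply(seq_len(n_ev), track_of, function(ix) ix[length(ix)])
    break                              # a single gap-closing round suffices
  }

  track_of <- assemble_tracks(succ)
  events$track_id <- track_of
  summ <- summarise_tracks(events)

  # splitting: a fragment starting next to the body of another track one
  # frame earlier is annotated as a branch of that track
  summ$split_from <- NA_integer_
  if (splitting && nrow(summ) > 1L) {
    for (tid in summ$track_id) {
      ix <- which(events$track_id == tid)
      first <- ix[1]
      f0 <- events$frame[first]
      donors <- which(events$frame == f0 - 1L & events$track_id != tid &
                        !is.na(succ))  # non-terminal events only
      if (!length(donors)) next
      d <- sqrt((events$x_um[donors] - events$x_um[first])^2 +
                  (events$y_um[donors] - events$y_um[first])^2)
      j <- which.min(d)
      if (d[j] <= split_distance)
        summ$split_from[summ$track_id == tid] <- events$track_id[donors[j]]
    }
  }
  structure(list(events = events, summary = summ), class = "mz_tracks")
}

# Assignment between two frames' events; returns named integer vector
# mapping row index in `a` (name) to row index in `b` (value).
lap_link <- function(a, b, max_link) {
  dx <- outer(a$x_um, b$x_um, `-`)
  dy <- outer(a$y_um, b$y_um, `-`)
  dist2 <- dx^2 + dy^2
  cost <- ifelse(dist2 <= max_link^2, dist2, Inf)
  out <- lap_pair(cost)
  if (!length(out)) return(integer())
  stats::setNames(out[, 2L], out[, 1L])
}

# Solve the rectangular link/no-link problem for a cost matrix with Inf for
# forbidden links, via the standard square augmented matrix with
# alternative (no-link) costs on the diagonals. Returns a 2-column matrix of
# accepted (row, col) pairs.
lap_pair <- function(cost) {
  n1 <- nrow(cost)
  n2 <- ncol(cost)
  finite <- cost[is.finite(cost)]
  if (!length(finite)) return(matrix(integer(), 0L, 2L))
  b <- 1.05 * max(finite)
  if (b == 0) b <- 1
  big <- Inf
  m <- matrix(big, n1 + n2, n1 + n2)
  m[1:n1, 1:n2] <- cost
  m[cbind(1:n1, n2 + 1:n1)] <- b
  m[cbind(n1 + 1:n2, 1:n2)] <- b
  m[n1 + 1:n2, n2 + 1:n1][t(is.finite(cost))] <- 0
  a <- solve_lap(m)
  rows <- 1:n1
  cols <- a[rows]
  keep <- cols <= n2
  keep[keep] <- is.finite(cost[cbind(rows[keep], cols[keep])])
  cbind(rows[keep], cols[keep])
}

# Follow successor pointers into track memberships (1, 2, ... in order of
# first event).
assemble_tracks <- function(succ) {
  n <- length(succ)
  has_pred <- rep(FALSE, n)
  has_pred[succ[!is.na(succ)]] <- TRUE
  track_of <- integer(n)
  tid <- 0L
  for (i in which(!has_pred)) {
    tid <- tid + 1L
    j <- i
    while (!is.na(j)) {
      track_of[j] <- tid
      j <- succ[j]
    }
  }
  track_of
}

empty_track_summary <- function() {
  data.frame(track_id = integer(), n_events = integer(),
             duration_s = numeric(), start_x = numeric(), start_y = numeric(),
             end_x = numeric(), end_y = numeric(), angle_deg = numeric(),
             quadrant = character(), split_from = integer())
}

summarise_tracks <- function(events) {
  ids <- sort(unique(events$track_id))
  rows <- lapply(ids, function(tid) {
    ix <- which(events$track_id == tid)
    ix <- ix[order(events$frame[ix])]
    first <- ix[1]
    last <- ix[length(ix)]
    ang <- track_angle(events$x_um[first], events$y_um[first],
                       events$x_um[last], events$y_um[last])
    data.frame(track_id = tid, n_events = length(ix),
               duration_s = events$time_s[last] - events$time_s[first],
               start_x = events$x_um[first], start_y = events$y_um[first],
               end_x = events$x_um[last], end_y = events$y_um[last],
               angle_deg = ang,
               quadrant = quadrant_of(ang))
  })
  do.call(rbind, rows)
}

#' Duration of a track
#'
#' Time between the first and last event of a track. Singleton tracks have
#' no duration and are excluded from duration statistics.
#'
#' @param track a row of the track summary, or a data.frame of a single
#'   track's events (columns `time_s`).
#' @return Duration in seconds.
#' @export
track_duration <- function(track) {
  if (!is.null(track$duration_s)) {
    if (any(track$n_events < 2L)) stop("singleton track has no duration")
    return(track$duration_s)
  }
  if (nrow(track) < 2L) stop("singleton track has no duration")
  max(track$time_s) - min(track$time_s)
}

track_angle <- function(x0, y0, x1, y1) {
  if (x0 == x1 && y0 == y1) return(NA_real_)
  a <- atan2(y1 - y0, x1 - x0) * 180 / pi
  a %% 360
}

#' Quadrant class of a track direction
#'
#' Maps a start-to-end displacement to one of four half-open angle classes:
#' Q1 = \[0, 90), Q2 = \[90, 180), Q3 = \[180, 270), Q4 = \[270, 360)
#' degrees, measured anticlockwise from the positive x axis. Zero
#' displacement is unclassified (`NA`).
#'
#' @param track a track summary row (uses `angle_deg`), or a numeric angle in
#'   degrees.
#' @return Character `"Q1"`..`"Q4"`, or `NA` for zero displacement.
#' @export
angle_class <- function(track) {
  ang <- if (is.numeric(track)) track else track$angle_deg
  quadrant_of(ang)
}

quadrant_of <- function(ang) {
  if (length(ang) > 1L) return(vapply(ang, quadrant_of, character(1)))
  if (is.na(ang)) return(NA_character_)
  paste0("Q", findInterval(ang %% 360, c(0, 90, 180, 270)))
}

#' Count active cells from firing events
#'
#' Operationalises the "number of active cells" measure: firing events are
#' clustered by position, merging events closer than one blob diameter, and
#' the clusters are counted per region. Cells at least one blob diameter
#' apart are therefore counted exactly.
#'
#' @param events data.frame with `x_um`, `y_um`.
#' @param regions character/factor vector assigning each event to exactly one
#'   region (same length as `nrow(events)`).
#' @param blob_diameter_um clustering radius (um), the estimated blob
#'   diameter of the spot detector.
#' @return Named integer vector of per-region active-cell counts.
#' @export
count_active_cells <- function(events, regions, blob_diameter_um = 13) {
  if (length(regions) != nrow(events))
    stop("regions must assign each event to exactly one region")
  if (anyNA(regions))
    stop("events with no region assignment: rows ",
         paste(which(is.na(regions)), collapse = ", "))
  vapply(split(seq_len(nrow(events)), regions), function(ix) {
    if (!length(ix)) return(0L)
    xy <- cbind(events$x_um[ix], events$y_um[ix])
    n_position_clusters(xy, blob_diameter_um)
  }, integer(1))
}

# Number of connected components of the "closer than d" graph
# (single-linkage clustering cut strictly below d).
n_position_clusters <- function(xy, d) {
  n <- nrow(xy)
  if (n == 1L) return(1L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  dm <- as.matrix(stats::dist(xy))
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (dm[i, j] < d) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' @export
print.mz_tracks <- function(x, ...) {
  multi <- x$summary$n_events >= 2L
  cat("Calcium tracks:", nrow(x$summary), "tracks (",
      sum(multi), "with >= 2 events ) from", nrow(x$events), "events\n")
  if (any(multi))
    cat("  mean duration:",
        round(mean(x$summary$duration_s[multi]), 2), "s\n")
  invisible(x)
}
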