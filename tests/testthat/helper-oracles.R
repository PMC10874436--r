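# Independent oracles used across test files.

# Exhaustive minimum-cost assignment by permutation enumeration (n <= 7).
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  best <- Inf
  best_p <- NULL
  rec <- function(p) {
    i <- length(p) + 1L
    if (i > n) {
      v <- sum(cost[cbind(seq_len(n), p)])
      if (v < best) {
        best <<- v
        best_p <<- p
      }
      return()
    }
    for (j in setdiff(seq_len(n), p)) rec(c(p, j))
  }
  rec(integer())
  list(cost = best, assignment = best_p)
}

# Run lengths of 1s in a binary vector with optional wrap-around, by direct
# enumeration (checks every position).
brute_force_runs <- function(A, periodic) {
  n <- length(A)
  if (!any(A == 1L)) return(integer())
  if (all(A == 1L)) return(n)
  spans <- integer()
  i <- 1L
  visited <- rep(FALSE, n)
  for (start in seq_len(n)) {
    prev <- if (start == 1L) {
      if (periodic) n else NA
    } else start - 1L
    is_run_start <- A[start] == 1L && (is.na(prev) || A[prev] == 0L)
    if (!is_run_start) next
    len <- 0L
    j <- start
    while (A[j] == 1L && len < n) {
      len <- len + 1L
      j <- if (j == n) {
        if (periodic) 1L else break
      } else j + 1L
    }
    spans <- c(spans, len)
  }
  spans
}

# A minimal mz_trace for detector tests.
mk_trace <- function(values, times = (seq_along(values) - 1) * 3) {
  structure(list(times = times, values = values, cell_id = NA, region = "unknown"),
            class = "mz_trace")
}

# Match detected spike times against truth within a tolerance; returns
# TP/FN/FP counts. Tolerance defaults to one generating FWHM.
match_spikes <- function(detected_times, true_times, tol = 15) {
  used <- rep(FALSE, length(detected_times))
  tp <- 0L
  for (t0 in true_times) {
    j <- which(!used & abs(detected_times - t0) <= tol)
    if (length(j)) {
      used[j[which.min(abs(detected_times[j] - t0))]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fn = length(true_times) - tp, fp = sum(!used))
}

# Canonical form of a track partition: sorted event-index sets.
partition_signature <- function(track_ids) {
  sets <- split(seq_along(track_ids), track_ids)
  unname(sort(vapply(sets, function(s) paste(sort(s), collapse = ","),
                     character(1))))
}
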