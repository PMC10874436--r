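#' Solve a linear assignment problem
#'
#' Minimum-cost perfect matching of the rows to the columns of a square cost
#' matrix, by the shortest-augmenting-path (Jonker-Volgenant) algorithm with
#' dual potentials. Forbidden assignments are encoded as `Inf` and replaced
#' internally by a large finite cost; the problem must remain feasible (a
#' perfect matching using only finite costs must exist).
#'
#' This is the optimisation core of the event-linking step; it is exposed so
#' that the linking can be tested against exhaustive enumeration.
#'
#' @param cost square numeric cost matrix; `Inf` forbids an assignment.
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`.
#' @export
solve_lap <- function(cost) {
  n <- nrow(cost)
  if (n != ncol(cost)) stop("cost matrix must be square")
  if (n == 0L) return(integer())
  finite <- cost[is.finite(cost)]
  big <- if (length(finite)) max(abs(finite)) * n + 1 else 1
  cm <- cost
  cm[!is.finite(cm)] <- big * 2
  # potentials u (rows), v (cols); col_of[j] = row matched to column j
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  col_of <- integer(n + 1L)            # 0 = free
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    col_of[1L] <- i
    j0 <- 1L                           # sentinel column (index 1 = "virtual")
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- col_of[j0]
      jr <- 2:(n + 1L)
      cur <- cm[i0, ] - u[i0] - v[jr]
      open <- jr[!used[jr]]
      val <- cur[open - 1L]
      better <- val < minv[open]
      if (any(better)) {
        minv[open[better]] <- val[better]
        way[open[better]] <- j0
      }
      k <- which.min(minv[open])
      j1 <- open[k]
      delta <- minv[j1]
      isu <- which(used)
      u[col_of[isu]] <- u[col_of[isu]] + delta
      v[isu] <- v[isu] - delta
      notu <- which(!used)
      minv[notu] <- minv[notu] - delta
      j0 <- j1
      if (col_of[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      col_of[j0] <- col_of[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  a <- integer(n)
  for (j in 2:(n + 1L)) a[col_of[j]] <- j - 1L
  a
}
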