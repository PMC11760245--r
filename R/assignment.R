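# Linear assignment (Hungarian algorithm, potentials formulation).
# Hand-rolled because no installed package offers a weighted rectangular
# assignment solver; the inner relaxation loop is vectorized over columns so
# the cost is O(n^2) vector operations for an n x m problem.

# Minimum-cost assignment of rows to columns; requires nrow(cost) <= ncol(cost).
# Returns, for each row, the assigned column index.
hungarian_min <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m, all(is.finite(cost)))
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L) # p[j + 1]: row matched to column j (0 = free)
  way <- integer(m + 1L)
  cols <- seq_len(m)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[cols + 1L])
      cur <- cost[i0, free] - u[i0 + 1L] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      used_j <- which(used)
      u[p[used_j] + 1L] <- u[p[used_j] + 1L] + delta
      v[used_j] <- v[used_j] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  matched <- which(p[-1L] > 0L)
  ans[p[matched + 1L]] <- matched
  ans
}

#' Maximum-score one-to-one assignment
#'
#' Solves the rectangular linear assignment problem maximizing the total
#' score; surplus rows/columns of the larger side stay unassigned. Ties are
#' resolved deterministically (the solver scans rows and columns in index
#' order, so equal-score optima resolve to the lowest indices).
#'
#' @param score A finite numeric score matrix.
#' @return An integer matrix with columns `row`, `col`, one matched pair per
#'   line, ordered by `row`.
#' @export
solve_assignment <- function(score) {
  score <- as.matrix(score)
  if (!all(is.finite(score))) stop("score matrix must be finite", call. = FALSE)
  n <- nrow(score)
  m <- ncol(score)
  if (n == 0L || m == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("row", "col"))))
  }
  transposed <- n > m
  s <- if (transposed) t(score) else score
  assign_col <- hungarian_min(max(s) - s)
  pairs <- cbind(row = seq_len(nrow(s)), col = assign_col)
  pairs <- pairs[pairs[, 2L] > 0L, , drop = FALSE]
  if (transposed) pairs <- cbind(row = pairs[, 2L], col = pairs[, 1L])
  pairs[order(pairs[, 1L]), , drop = FALSE]
}
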