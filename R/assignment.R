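# Exact minimum-cost one-to-one assignment (Hungarian algorithm with
# potentials, shortest-augmenting-path formulation).  Used to label marker
# blobs with anatomical sites; problem sizes are tiny (<= 29), so a plain R
# implementation is ample.

#' Solve a rectangular assignment problem exactly
#'
#' Minimizes the total cost of a one-to-one assignment of rows to columns
#' of `cost` (requires `nrow <= ncol`; pad with zero-cost dummy columns for
#' the square or transposed case).
#'
#' @param cost Numeric cost matrix with `nrow(cost) <= ncol(cost)`.
#' @return Integer vector `a` of length `nrow(cost)`: row `i` is assigned
#'   to column `a[i]`.
#' @export
#' @examples
#' cost <- matrix(c(4, 1, 3, 2, 0, 5, 3, 2, 2), 3, 3)
#' solve_assignment(cost)
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop_pk("cost matrix needs nrow <= ncol", "bad_assignment")
  u <- numeric(n + 1)       # row potentials (index shifted by 1; [1] virtual)
  v <- numeric(m + 1)       # column potentials (likewise)
  p <- integer(m + 1)       # p[j+1]: row currently matched to column j
  way <- integer(m + 1)
  cols <- seq_len(m)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- logical(m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      cur <- cost[i0, ] - u[i0 + 1] - v[cols + 1]
      free <- !used[cols + 1]
      upd <- free & cur < minv
      minv[upd] <- cur[upd]
      way[cols[upd] + 1] <- j0
      jfree <- cols[free]
      j1 <- jfree[which.min(minv[jfree])]
      delta <- minv[j1]
      usedj <- which(used) - 1L            # column indices incl. virtual 0
      u[p[usedj + 1] + 1] <- u[p[usedj + 1] + 1] + delta
      v[usedj + 1] <- v[usedj + 1] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in cols) if (p[j + 1] > 0L) ans[p[j + 1]] <- j
  ans
}
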