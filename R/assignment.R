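## Dense linear assignment via the potentials form of the Hungarian
## algorithm (shortest augmenting paths). Problem sizes here are tens of
## rows per frame, so a plain R implementation is ample.

#' Solve a linear assignment problem
#'
#' Minimum-cost one-to-one assignment of rows to columns of a finite cost
#' matrix. Requires nrow(cost) <= ncol(cost); every row is assigned.
#'
#' @param cost numeric matrix of finite costs (use large values, not Inf,
#'   for undesirable pairs).
#' @return Integer vector: for each row, the assigned column index.
#' @examples
#' solveAssignment(matrix(c(4, 1, 3, 2, 0, 5, 3, 2, 2), 3, 3))
#' @export
solveAssignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L) return(integer(0))
  .stopIfNot(n <= m, "cost matrix needs nrow <= ncol")
  .stopIfNot(all(is.finite(cost)), "costs must be finite")
  INF <- Inf
  ## 1-based with a virtual column 0 stored at index 1 (columns j -> j + 1)
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)   # column -> assigned row (0 = free)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
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
  colOf <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) colOf[p[j + 1L]] <- j
  colOf
}
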