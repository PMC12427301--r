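# Linear assignment by the Hungarian algorithm with dual potentials
# (shortest augmenting paths, O(n^3)). Infeasible edges are encoded as
# ASSIGN_BIG; callers must check the returned assignment for BIG edges.
# Returned duals (u, v) satisfy c[i, j] - u[i] - v[j] >= 0 with equality
# on matched edges, which is what pair_karyotypes() uses to enumerate the
# full set of optimal matchings (tight-edge subgraph).

ASSIGN_BIG <- 1e9

solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, n >= 1L)
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1L)   # column potentials; slot 1 is the sentinel column
  p <- integer(n + 1L)   # p[j + 1]: row matched to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])
      cur <- cost[i0, free_j] - u[i0] - v[free_j + 1L]
      upd <- cur < minv[free_j]
      if (any(upd)) {
        minv[free_j[upd]] <- cur[upd]
        way[free_j[upd] + 1L] <- j0
      }
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      on <- which(used)
      u[p[on]] <- u[p[on]] + delta
      v[on] <- v[on] - delta
      minv[free_j] <- minv[free_j] - delta
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
  row_to_col <- integer(n)
  row_to_col[p[-1L]] <- seq_len(n)
  list(assignment = row_to_col,
       cost = sum(cost[cbind(seq_len(n), row_to_col)]),
       u = u, v = v[-1L])
}
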