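# Linear assignment solver: Hungarian algorithm with dual potentials and
# shortest augmenting paths, O(n^3). Written here because frame-to-frame
# linking needs capped partial matchings and no assignment solver is among
# the package's dependencies. Validated in the test suite against
# brute-force enumeration on random instances.

# cost: finite square matrix (large finite values mark forbidden pairs).
# Returns an integer vector `a` with a[i] = column assigned to row i.
lap_solve <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) return(integer(0))
  stopifnot(all(is.finite(cost)))
  V <- n + 1L  # index of the virtual root column
  u <- numeric(n)
  v <- numeric(V)
  p <- integer(V)    # p[j] = row matched to column j, 0 if free
  way <- integer(V)  # way[j] = previous column on the alternating path
  for (i in seq_len(n)) {
    p[V] <- i
    j0 <- V
    minv <- rep(Inf, n)
    used <- logical(V)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free_j <- which(!used[seq_len(n)])
      cur <- cost[i0, free_j] - u[i0] - v[free_j]
      upd <- cur < minv[free_j]
      if (any(upd)) {
        minv[free_j[upd]] <- cur[upd]
        way[free_j[upd]] <- j0
      }
      j1 <- free_j[which.min(minv[free_j])]
      delta <- minv[j1]
      used_idx <- which(used)
      u[p[used_idx]] <- u[p[used_idx]] + delta
      v[used_idx] <- v[used_idx] - delta
      minv[free_j] <- minv[free_j] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    while (j0 != V) {
      j1 <- way[j0]
      p[j0] <- if (j1 == V) i else p[j1]
      j0 <- j1
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) assignment[p[j]] <- j
  assignment
}
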