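# Independent oracles used across test files.

# Exact Voronoi adjacency oracle, independent of the empty-circumcircle
# implementation: sites i and j share a Voronoi ridge iff on their
# perpendicular bisector q(t) = midpoint + t * u there is a segment of
# positive length where q is at least as close to i (and j) as to every
# other site. Each other site k contributes one linear inequality in t,
# so adjacency reduces to a 1-D interval intersection.
bisector_voronoi_adjacency <- function(pos, tol = 1e-9) {
  n <- nrow(pos)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m <- (pos[i, ] + pos[j, ]) / 2
    d <- pos[j, ] - pos[i, ]
    u <- c(-d[2], d[1]) / sqrt(sum(d^2))
    lo <- -Inf; hi <- Inf
    for (k in seq_len(n)) {
      if (k == i || k == j) next
      a <- 2 * sum(m * (pos[k, ] - pos[i, ])) +
        sum(pos[i, ]^2) - sum(pos[k, ]^2)
      b <- 2 * sum(u * (pos[k, ] - pos[i, ]))
      if (abs(b) < 1e-12) {
        if (a > 0) { lo <- Inf; break }   # infeasible for all t
      } else if (b > 0) hi <- min(hi, -a / b) else lo <- max(lo, -a / b)
    }
    adj[i, j] <- adj[j, i] <- (hi - lo) > tol
  }
  adj
}

# brute-force nearest-neighbor oracle
brute_nn <- function(pos) {
  n <- nrow(pos)
  vapply(seq_len(n), function(i) {
    d <- sqrt((pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2)
    d[i] <- Inf
    which.min(d)
  }, integer(1))
}

# fraction of positive / negative radial-projection bins in map halves
half_plane_fractions <- function(map) {
  rp <- radial_projection(map)
  nb <- length(map$centers)
  cy <- t(matrix(map$centers, nb, nb))
  up <- !is.na(rp) & cy > 0
  lo <- !is.na(rp) & cy < 0
  list(upper_pos = mean(rp[up] > 0), n_upper = sum(up),
       lower_pos = mean(rp[lo] > 0), n_lower = sum(lo),
       all_pos = mean(rp[!is.na(rp)] > 0))
}
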