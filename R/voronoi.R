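#' Voronoi adjacency of a configuration
#'
#' Individuals are Voronoi neighbors when their Voronoi cells share an edge
#' (equivalently, when they are joined by a Delaunay edge) -- a standard
#' proxy for visual interaction networks in animal groups. For fewer than
#' three individuals every pair is adjacent; duplicate or fully collinear
#' configurations are rejected as degenerate. Exact cocircular ties (e.g. a
#' perfect square) are broken deterministically.
#'
#' @param positions N x 2 numeric matrix of positions (cm), N >= 2.
#' @return A `neighbor_graph` object: list with `adjacency` (N x N symmetric
#'   logical), `nearest` (integer vector, index of each individual's nearest
#'   neighbor over all others), and `pairs` (M x 2 integer matrix of
#'   adjacent pairs, i < j).
#' @export
#' @examples
#' pos <- cbind(c(0, 4, 1), c(0, 0, 3))
#' voronoi_adjacency(pos)$pairs  # a triangle: all three pairs
voronoi_adjacency <- function(positions) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) stop("need at least 2 individuals")
  if (!all(is.finite(positions))) stop("non-finite positions")
  adj <- .delaunay_edges_cpp(positions[, 1], positions[, 2])
  d2 <- as.matrix(stats::dist(positions))^2
  diag(d2) <- Inf
  nearest <- apply(d2, 1, which.min)
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  structure(list(adjacency = adj, nearest = as.integer(nearest),
                 pairs = unname(idx[order(idx[, 1], idx[, 2]), , drop = FALSE])),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("<neighbor_graph>", nrow(x$adjacency), "individuals,",
      nrow(x$pairs), "Voronoi edges\n")
  invisible(x)
}

#' Inverse-distance social weights
#'
#' Weights over an individual's interacting set: `w_j` proportional to
#' `1 / d_j`, normalized to sum to one (a weighted average, so a single
#' neighbor always has weight 1), or left unnormalized as a weighted sum.
#'
#' @param pos_i Focal position, length-2 numeric (cm).
#' @param pos_set Positions of the interacting set, M x 2 matrix (cm).
#' @param normalize Normalize weights to sum to one (default `TRUE`).
#' @return Numeric vector of M weights (length 0 for an empty set).
#' @export
#' @examples
#' social_weights(c(0, 0), rbind(c(2, 0), c(0, 4)))  # 2/3, 1/3
social_weights <- function(pos_i, pos_set, normalize = TRUE) {
  pos_set <- matrix(as.numeric(pos_set), ncol = 2)
  if (nrow(pos_set) == 0) return(numeric(0))
  d <- sqrt((pos_set[, 1] - pos_i[1])^2 + (pos_set[, 2] - pos_i[2])^2)
  if (any(d < 1e-12)) stop("zero distance in interacting set", call. = FALSE)
  w <- 1 / d
  if (normalize) w <- w / sum(w)
  w
}
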