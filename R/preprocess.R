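#' Fill short tracking gaps by spline interpolation
#'
#' Occlusions in tracked data leave runs of missing positions. Gaps of at
#' most `max_gap` frames are filled per individual and coordinate with a
#' cubic spline through the valid frames; longer gaps and gaps touching the
#' start or end of the recording stay `NA` and should be excluded
#' downstream.
#'
#' @param xy A frames x individuals numeric matrix of one coordinate, with
#'   `NA` for missing values (apply to x and y separately), or a list with
#'   `x` and `y` matrices (both are filled).
#' @param max_gap Longest gap filled, in frames.
#' @return Same shape as the input.
#' @export
interpolate_gaps <- function(xy, max_gap = 10) {
  if (is.list(xy) && !is.data.frame(xy))
    return(list(x = interpolate_gaps(xy$x, max_gap),
                y = interpolate_gaps(xy$y, max_gap)))
  m <- as.matrix(xy)
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (!anyNA(v)) next
    r <- rle(is.na(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    good <- which(!is.na(v))
    if (length(good) < 4) next
    for (k in which(r$values)) {
      if (starts[k] == 1 || ends[k] == length(v)) next  # boundary gap
      if (r$lengths[k] > max_gap) next
      at <- starts[k]:ends[k]
      m[at, j] <- spline(good, v[good], xout = at, method = "fmm")$y
    }
  }
  m
}

#' Perspective correction onto the tank plane
#'
#' Estimates the homography mapping the four imaged tank corners to a
#' physical square of side `side_cm` with corners `(0,0)`, `(side,0)`,
#' `(side,side)`, `(0,side)` (in that order), and applies it to the
#' tracked positions; output coordinates are cm in the tank plane.
#'
#' @param x,y Frames x individuals matrices (or vectors) of image
#'   coordinates.
#' @param corners 4 x 2 matrix of the imaged tank corners, ordered
#'   bottom-left, bottom-right, top-right, top-left; must form a convex
#'   quadrilateral.
#' @param side_cm Physical side length of the tank, cm.
#' @return List with matrices `x` and `y` in cm.
#' @export
project_to_plane <- function(x, y, corners, side_cm = 100) {
  corners <- as.matrix(corners)
  stopifnot(identical(dim(corners), c(4L, 2L)))
  target <- rbind(c(0, 0), c(side_cm, 0), c(side_cm, side_cm), c(0, side_cm))
  # convexity: all cross products of consecutive edges share a sign
  e <- rbind(diff(corners), corners[1, ] - corners[4, ])
  cr <- e[, 1] * e[c(2:4, 1), 2] - e[, 2] * e[c(2:4, 1), 1]
  if (any(cr == 0) || length(unique(sign(cr))) != 1)
    stop("corners must form a convex quadrilateral")
  H <- homography(corners, target)
  was_mat <- is.matrix(x)
  dm <- dim(as.matrix(x))
  u <- as.vector(x); v <- as.vector(y)
  den <- H[3, 1] * u + H[3, 2] * v + H[3, 3]
  X <- (H[1, 1] * u + H[1, 2] * v + H[1, 3]) / den
  Y <- (H[2, 1] * u + H[2, 2] * v + H[2, 3]) / den
  if (was_mat) { dim(X) <- dm; dim(Y) <- dm }
  list(x = X, y = Y)
}

# direct linear transform for 4 point correspondences (h33 fixed to 1)
homography <- function(src, dst) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    u <- src[i, 1]; v <- src[i, 2]; X <- dst[i, 1]; Y <- dst[i, 2]
    A[2 * i - 1, ] <- c(u, v, 1, 0, 0, 0, -u * X, -v * X)
    A[2 * i, ]     <- c(0, 0, 0, u, v, 1, -u * Y, -v * Y)
    b[2 * i - 1] <- X; b[2 * i] <- Y
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

#' Gaussian smoothing and differentiation of tracked positions
#'
#' Applies the kinematic convention used for experimental trajectories:
#' positions are smoothed with a Gaussian kernel of width `sigma` frames
#' truncated at `truncate * sigma`, and velocities and accelerations are
#' obtained by convolution with the first and second Gaussian-derivative
#' kernels (divided by dt and dt^2). The derivative kernels are normalized
#' to be exact on linear and quadratic trajectories respectively.
#' Boundaries use reflection padding; the first and last `truncate * sigma`
#' frames are flagged as boundary-affected in the `boundary` attribute of
#' the result.
#'
#' @param x,y Frames x individuals position matrices (cm), gap-free (see
#'   [interpolate_gaps()]).
#' @param dt Frame spacing, s.
#' @param sigma Kernel width in frames.
#' @param truncate Kernel support half-width in units of sigma.
#' @return A [school_traj()] with smoothed positions and
#'   Gaussian-derivative velocities and accelerations.
#' @export
smooth_and_differentiate <- function(x, y, dt, sigma = 2, truncate = 5) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(identical(dim(x), dim(y)), dt > 0, sigma > 0)
  h <- ceiling(truncate * sigma)
  if (nrow(x) < 2 * h + 2) stop("track shorter than the kernel support")
  k0 <- gaussian_kernel(sigma, 0, truncate)
  k1 <- gaussian_kernel(sigma, 1, truncate)
  k2 <- gaussian_kernel(sigma, 2, truncate)
  conv <- function(m, k) apply(m, 2, conv_reflect, k = k)
  tr <- school_traj(times = (seq_len(nrow(x)) - 1) * dt,
                    x = conv(x, k0), y = conv(y, k0),
                    vx = conv(x, k1) / dt, vy = conv(y, k1) / dt,
                    ax = conv(x, k2) / dt^2, ay = conv(y, k2) / dt^2,
                    source = "tracked")
  attr(tr, "boundary") <- c(seq_len(h), nrow(x) - h + seq_len(h))
  tr
}

#' Re-derive trajectory kinematics by the experimental convention
#'
#' Applies [smooth_and_differentiate()] to the positions of an existing
#' ensemble (typically a simulation) and drops the boundary-affected frames
#' at both ends, so simulated trajectories can be analyzed with exactly the
#' same kinematic estimator as experimental recordings.
#'
#' @param traj A [school_traj()].
#' @inheritParams smooth_and_differentiate
#' @return A [school_traj()] with Gaussian-derivative kinematics and
#'   `2 * ceiling(truncate * sigma)` fewer frames.
#' @export
tracked_kinematics <- function(traj, sigma = 2, truncate = 5) {
  stopifnot(inherits(traj, "school_traj"))
  sm <- smooth_and_differentiate(traj$x, traj$y, dt = traj$dt,
                                 sigma = sigma, truncate = truncate)
  h <- ceiling(truncate * sigma)
  keep <- (h + 1):(nrow(sm$x) - h)
  school_traj(sm$times[keep],
              sm$x[keep, , drop = FALSE], sm$y[keep, , drop = FALSE],
              sm$vx[keep, , drop = FALSE], sm$vy[keep, , drop = FALSE],
              sm$ax[keep, , drop = FALSE], sm$ay[keep, , drop = FALSE],
              params = traj$params, source = "tracked")
}

#' Gaussian and Gaussian-derivative kernels
#'
#' Discrete kernels on integer offsets `-h..h` with
#' `h = ceiling(truncate * sigma)`. Order 0 sums to one (exact on
#' constants and, by symmetry, on linear trends); order 1 is normalized so
#' that convolution recovers the slope of a linear sequence exactly (it
#' sums to zero); order 2 recovers the curvature of a quadratic exactly
#' and annihilates constants and linear trends. Estimates at frame t use
#' `sum_j k[j] x[t + j]`.
#'
#' @param sigma Width in frames.
#' @param order Derivative order: 0, 1 or 2.
#' @param truncate Support half-width in units of sigma.
#' @return Numeric kernel of length `2 h + 1`.
#' @export
gaussian_kernel <- function(sigma, order = 0, truncate = 5) {
  h <- ceiling(truncate * sigma)
  j <- seq(-h, h)
  g <- exp(-j^2 / (2 * sigma^2))
  switch(as.character(order),
    "0" = g / sum(g),
    "1" = {
      k <- j * g
      k / sum(j * k)        # sum(k * j) = 1 -> exact slope on linear data
    },
    "2" = {
      k <- (j^2 - sum(j^2 * g) / sum(g)) * g   # orthogonal to constants
      2 * k / sum(j^2 * k)  # sum(k * j^2) = 2 -> exact on quadratics
    },
    stop("order must be 0, 1 or 2"))
}

# correlation-style application of a symmetric-support kernel with
# reflection padding: out[t] = sum_j k[j] v[t + j], j in -h..h
# (stats::filter cross-correlates with the reversed coefficients)
conv_reflect <- function(v, k) {
  h <- (length(k) - 1) / 2
  n <- length(v)
  pad <- c(v[pmin((h:1) + 1, n)], v, v[pmax(n - seq_len(h), 1)])
  out <- stats::filter(pad, rev(k), sides = 2)
  as.numeric(out[(h + 1):(h + n)])
}
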