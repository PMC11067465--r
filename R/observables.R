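#' Polarization order parameter
#'
#' Modulus of the mean unit-velocity vector, `| mean_i vhat_i |`: 1 when
#' all individuals move in the same direction, near 0 for disordered
#' motion.
#'
#' @param v An N x 2 velocity matrix (one frame), or a [school_traj()]
#'   (one value per frame).
#' @return Scalar in `[0, 1]`, or a per-frame numeric vector.
#' @export
#' @examples
#' polarization(rbind(c(0, 1), c(1, 0), c(0, 1), c(1, 0)))  # sqrt(2)/2
polarization <- function(v) {
  if (inherits(v, "school_traj")) {
    s <- traj_speed(v)
    if (any(s < 1e-9)) stop("zero speed: heading undefined")
    return(sqrt(rowMeans(v$vx / s)^2 + rowMeans(v$vy / s)^2))
  }
  v <- as.matrix(v)
  s <- sqrt(rowSums(v^2))
  if (any(s < 1e-9)) stop("zero speed: heading undefined")
  sqrt(sum(colMeans(v / s)^2))
}

#' Mean nearest-neighbor distance
#'
#' Average over individuals of the distance to their own nearest neighbor,
#' a measure of group cohesion.
#'
#' @param pos An N x 2 position matrix (cm), N >= 2, or a [school_traj()]
#'   (one value per frame).
#' @return Scalar (cm), or a per-frame numeric vector.
#' @export
mean_nn_distance <- function(pos) {
  if (inherits(pos, "school_traj")) {
    nn <- traj_nn(pos)
    ri <- cbind(rep(seq_len(nrow(nn)), ncol(nn)), as.vector(nn))
    dx <- pos$x - matrix(pos$x[ri], nrow(nn))
    dy <- pos$y - matrix(pos$y[ri], nrow(nn))
    return(rowMeans(sqrt(dx^2 + dy^2)))
  }
  pos <- as.matrix(pos)
  if (nrow(pos) < 2) stop("need at least 2 individuals")
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Convex-hull area per individual
#'
#' Area of the smallest convex polygon containing all individuals, divided
#' by the number of individuals: the extension the group occupies per
#' capita. Collinear configurations have zero area and are flagged.
#'
#' @param pos An N x 2 position matrix (cm), N >= 3, or a [school_traj()].
#' @return Scalar (cm^2) with attribute `degenerate = TRUE` for collinear
#'   input, or a per-frame numeric vector for a trajectory.
#' @export
#' @examples
#' convex_hull_area_per_capita(rbind(c(0, 0), c(4, 0), c(0, 3)))  # 2
convex_hull_area_per_capita <- function(pos) {
  if (inherits(pos, "school_traj")) {
    return(vapply(seq_len(nrow(pos$x)), function(t)
      as.numeric(convex_hull_area_per_capita(cbind(pos$x[t, ], pos$y[t, ]))),
      numeric(1)))
  }
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (n < 3) stop("need at least 3 individuals")
  h <- grDevices::chull(pos)
  hx <- pos[h, 1]; hy <- pos[h, 2]
  # shoelace formula on the hull polygon
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  out <- area / n
  if (area < 1e-12) attr(out, "degenerate") <- TRUE
  out
}

#' Voronoi contact durations
#'
#' For every unordered pair of individuals, the lengths (s) of maximal runs
#' of consecutive frames during which the pair is Voronoi-adjacent. A
#' single-frame gap ends an episode (strict contiguity); a configurable gap
#' tolerance merges episodes separated by up to `gap_tolerance` frames.
#' Contact durations measure the persistence of the local neighborhood
#' structure.
#'
#' @param traj A [school_traj()] with at least 2 frames.
#' @param gap_tolerance Number of non-adjacent frames tolerated inside an
#'   episode (default 0, strict).
#' @return Numeric vector of episode durations, s (frame count times dt).
#' @export
voronoi_contact_durations <- function(traj, gap_tolerance = 0) {
  stopifnot(inherits(traj, "school_traj"), nrow(traj$x) >= 2)
  runs <- .contact_runs_cpp(traj$x, traj$y)
  if (gap_tolerance > 0) {
    # merging needs the per-pair episode sequence; recompute per pair in R
    runs <- merge_runs(traj, gap_tolerance)
  }
  runs * traj$dt
}

merge_runs <- function(traj, tol) {
  tn <- nrow(traj$x); n <- ncol(traj$x)
  adj <- array(FALSE, c(tn, n, n))
  for (t in seq_len(tn))
    adj[t, , ] <- .delaunay_edges_cpp(traj$x[t, ], traj$y[t, ])
  out <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- adj[, i, j]
    r <- rle(a)
    # close gaps of length <= tol between TRUE runs
    if (length(r$lengths) > 2) {
      inner <- 2:(length(r$lengths) - 1)
      gap <- !r$values[inner] & r$lengths[inner] <= tol
      r$values[inner][gap] <- TRUE
      a <- inverse.rle(r)
      r <- rle(a)
    }
    out <- c(out, r$lengths[r$values])
  }
  out
}

#' Signed turning rate
#'
#' Angular velocity of the heading, `omega = (vx ay - vy ax) / |v|^2`
#' (rad/s, positive counter-clockwise). Using the velocity-acceleration
#' cross product avoids 2-pi wrap artifacts of finite-differencing heading
#' angles.
#'
#' @param vel,acc Length-2 vectors, M x 2 matrices, or a [school_traj()]
#'   in `vel` (then `acc` is ignored and a frames x individuals matrix is
#'   returned).
#' @return Numeric: rad/s.
#' @export
turning_rate <- function(vel, acc = NULL) {
  if (inherits(vel, "school_traj")) {
    tr <- vel
    if (is.null(tr$ax)) stop("trajectory has no accelerations")
    s2 <- tr$vx^2 + tr$vy^2
    if (any(s2 < 1e-18)) stop("zero speed: turning rate undefined")
    return((tr$vx * tr$ay - tr$vy * tr$ax) / s2)
  }
  v <- rbind(vel); a <- rbind(acc)
  s2 <- rowSums(v^2)
  if (any(s2 < 1e-18)) stop("zero speed: turning rate undefined")
  unname(drop((v[, 1] * a[, 2] - v[, 2] * a[, 1]) / s2))
}

#' Binned probability density with Bernoulli error band
#'
#' Density per bin is the fraction of samples in the bin divided by the bin
#' width; the error band is the standard deviation of a Bernoulli variable
#' with that fraction, `sqrt(p (1 - p) / n)`, divided by the bin width.
#'
#' @param samples Numeric vector.
#' @param breaks Increasing vector of bin edges.
#' @return Data frame with `mid`, `density`, `band`, `count`; densities
#'   integrate to 1 over the binning when all samples fall inside it.
#' @export
pdf_with_error_band <- function(samples, breaks) {
  samples <- samples[is.finite(samples)]
  if (!length(samples)) stop("no samples")
  stopifnot(length(breaks) >= 2, all(diff(breaks) > 0))
  nb <- length(breaks) - 1
  ib <- findInterval(samples, breaks, rightmost.closed = TRUE)
  counts <- tabulate(ib[ib >= 1 & ib <= nb], nb)
  n <- length(samples)
  w <- diff(breaks)
  p <- counts / n
  data.frame(mid = (breaks[-1] + breaks[-(nb + 1)]) / 2,
             density = p / w,
             band = sqrt(p * (1 - p) / n) / w,
             count = counts)
}

#' Summary of group and individual observables
#'
#' Computes the observables used to compare models against each other and
#' against experimental data: per-frame polarization, mean
#' nearest-neighbor distance and convex-hull area per capita; Voronoi
#' contact durations; and per-sample speeds and turning rates.
#'
#' @param traj A [school_traj()] with accelerations.
#' @param contact_frames Optional cap on the number of frames used for the
#'   (more expensive) contact-duration scan; `NULL` uses all frames.
#' @return An object of class `school_observables`: list with `polarization`,
#'   `d_nn`, `hull_area_pc` (per-frame vectors), `contact_durations` (s),
#'   `speed` and `turning_rate` (frames x individuals matrices), and `dt`.
#' @export
observables_summary <- function(traj, contact_frames = NULL) {
  stopifnot(inherits(traj, "school_traj"))
  ctraj <- traj
  if (!is.null(contact_frames) && contact_frames < nrow(traj$x)) {
    keep <- seq_len(contact_frames)
    ctraj <- school_traj(traj$times[keep],
                         traj$x[keep, , drop = FALSE], traj$y[keep, , drop = FALSE],
                         traj$vx[keep, , drop = FALSE], traj$vy[keep, , drop = FALSE],
                         source = traj$source)
  }
  structure(list(
    polarization = polarization(traj),
    d_nn = mean_nn_distance(traj),
    hull_area_pc = if (ncol(traj$x) >= 3) convex_hull_area_per_capita(traj),
    contact_durations = voronoi_contact_durations(ctraj),
    speed = traj_speed(traj),
    turning_rate = if (!is.null(traj$ax)) turning_rate(traj),
    dt = traj$dt), class = "school_observables")
}

#' @export
print.school_observables <- function(x, ...) {
  cat("<school_observables>\n")
  cat(sprintf("  polarization: mean %.3f (sd %.3f)\n",
              mean(x$polarization), sd(x$polarization)))
  cat(sprintf("  d_NN: mean %.2f cm (sd %.2f)\n", mean(x$d_nn), sd(x$d_nn)))
  if (!is.null(x$hull_area_pc))
    cat(sprintf("  hull area per capita: mean %.1f cm^2\n",
                mean(x$hull_area_pc)))
  cat(sprintf("  contact durations: median %.2f s (n = %d)\n",
              median(x$contact_durations), length(x$contact_durations)))
  cat(sprintf("  speed: mean %.2f cm/s (sd %.2f)\n",
              mean(x$speed), sd(x$speed)))
  if (!is.null(x$turning_rate))
    cat(sprintf("  |turning rate|: mean %.2f rad/s\n",
                mean(abs(x$turning_rate))))
  invisible(x)
}
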