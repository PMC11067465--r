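#' Rotate a vector into the focal frame
#'
#' The focal frame of an individual has its y-axis along the individual's
#' direction of motion and its x-axis to the individual's right (the
#' heading rotated -90 degrees). Force maps are built in this frame.
#'
#' @param vec Length-2 numeric, or an M x 2 matrix of vectors.
#' @param heading Unit heading vector (length-2), or M x 2 matrix.
#' @return Rotated vector(s), same shape as `vec`.
#' @export
#' @examples
#' focal_frame(c(1, 0), c(1, 0))  # c(0, 1): ahead of an eastward mover
focal_frame <- function(vec, heading) {
  v <- rbind(vec); h <- rbind(heading)
  if (max(abs(rowSums(h^2) - 1)) > 1e-6)
    stop("heading must be unit norm", call. = FALSE)
  out <- cbind(v[, 1] * h[, 2] - v[, 2] * h[, 1],
               v[, 1] * h[, 1] + v[, 2] * h[, 2])
  if (is.matrix(vec)) out else drop(out)
}

# inverse rotation: focal-frame vector back to the lab frame
focal_to_lab <- function(vec, heading) {
  v <- rbind(vec); h <- rbind(heading)
  out <- cbind(v[, 1] * h[, 2] + v[, 2] * h[, 1],
               -v[, 1] * h[, 1] + v[, 2] * h[, 2])
  if (is.matrix(vec)) out else drop(out)
}

#' Conditional sample filters for force maps
#'
#' Builds a conjunctive predicate applied per (focal individual, frame)
#' sample when collecting force-map samples, mirroring the robustness
#' checks used on experimental data: ranges of nearest-neighbor distance,
#' wall distance (requires tank geometry; simulations are unbounded),
#' relative heading angle and focal speed, the approach/recede sign of
#' d(d_ij)/dt, and the neighbor faster/slower speed class.
#'
#' @param nn_dist Length-2 numeric range of distance to the neighbor, cm.
#' @param approach `"approaching"` (distance decreasing) or `"receding"`.
#' @param rel_heading Length-2 range of the angle between focal and
#'   neighbor headings, radians in `[0, pi]`.
#' @param focal_speed Length-2 range of focal speed, cm/s.
#' @param neighbor_speed `"faster"` (neighbor strictly faster than focal)
#'   or `"slower"`.
#' @param wall_dist Length-2 range of distance to the nearest tank wall,
#'   cm; requires `tank`.
#' @param tank Tank geometry for `wall_dist`: list with `side` (cm) and
#'   optionally `origin` (length-2, default `c(0, 0)`), describing a square
#'   tank with corners at `origin` and `origin + side`.
#' @return An object of class `sample_filter`.
#' @seealso [collect_samples()]
#' @export
sample_filter <- function(nn_dist = NULL, approach = NULL,
                          rel_heading = NULL, focal_speed = NULL,
                          neighbor_speed = NULL, wall_dist = NULL,
                          tank = NULL) {
  if (!is.null(approach))
    approach <- match.arg(approach, c("approaching", "receding"))
  if (!is.null(neighbor_speed))
    neighbor_speed <- match.arg(neighbor_speed, c("faster", "slower"))
  for (rng in list(nn_dist, rel_heading, focal_speed, wall_dist))
    if (!is.null(rng) && (length(rng) != 2 || rng[1] > rng[2]))
      stop("range filters must be length-2 increasing", call. = FALSE)
  if (!is.null(wall_dist) && is.null(tank))
    stop("'wall_dist' requires 'tank' geometry", call. = FALSE)
  structure(list(nn_dist = nn_dist, approach = approach,
                 rel_heading = rel_heading, focal_speed = focal_speed,
                 neighbor_speed = neighbor_speed, wall_dist = wall_dist,
                 tank = tank),
            class = "sample_filter")
}

#' Collect force-map samples from a trajectory
#'
#' For every focal individual and frame (passing the filter, if any), emits
#' one sample pairing a focal-frame coordinate with the focal-frame
#' acceleration response: the coordinate is the relative position
#' `x_i - x_NN` (kind `"position"`, attraction-repulsion map) or relative
#' velocity `v_i - v_NN` (kind `"velocity"`, alignment map) with the
#' nearest neighbor. With `neighbor = "voronoi"` one sample is emitted per
#' (focal, Voronoi neighbor) pair instead.
#'
#' @param traj A [school_traj()] with velocities and accelerations.
#' @param kind `"position"` or `"velocity"`.
#' @param neighbor `"nearest"` (default) or `"voronoi"`.
#' @param filter Optional [sample_filter()].
#' @return A data frame with focal-frame coordinate (`cx`, `cy`), response
#'   acceleration (`ax`, `ay`), and per-sample covariates (`frame`,
#'   `focal`, `neighbor`, `d_nn`, `approach_rate`, `rel_heading`,
#'   `focal_speed`, `neighbor_speed`).
#' @export
collect_samples <- function(traj, kind = c("position", "velocity"),
                            neighbor = c("nearest", "voronoi"),
                            filter = NULL) {
  kind <- match.arg(kind)
  neighbor <- match.arg(neighbor)
  stopifnot(inherits(traj, "school_traj"))
  if (is.null(traj$ax))
    stop("trajectory has no accelerations; force maps need full kinematics")
  tn <- nrow(traj$x); n <- ncol(traj$x)
  if (n < 2) stop("need at least 2 individuals")

  if (neighbor == "nearest") {
    nn <- traj_nn(traj)
    rows <- rep(seq_len(tn), n)
    focal <- rep(seq_len(n), each = tn)
    nbr <- as.vector(nn)
  } else {
    pairs_list <- vector("list", tn)
    for (t in seq_len(tn)) {
      adj <- .delaunay_edges_cpp(traj$x[t, ], traj$y[t, ])
      idx <- which(adj, arr.ind = TRUE)  # both directions
      pairs_list[[t]] <- cbind(t, idx)
    }
    prs <- do.call(rbind, pairs_list)
    rows <- prs[, 1]; focal <- prs[, 2]; nbr <- prs[, 3]
  }
  fi <- cbind(rows, focal); ni <- cbind(rows, nbr)

  sp_f <- sqrt(traj$vx[fi]^2 + traj$vy[fi]^2)
  if (any(sp_f < 1e-9)) stop("zero focal speed: heading undefined")
  hx <- traj$vx[fi] / sp_f; hy <- traj$vy[fi] / sp_f
  dx <- traj$x[fi] - traj$x[ni]; dy <- traj$y[fi] - traj$y[ni]
  dvx <- traj$vx[fi] - traj$vx[ni]; dvy <- traj$vy[fi] - traj$vy[ni]
  sp_n <- sqrt(traj$vx[ni]^2 + traj$vy[ni]^2)
  d <- sqrt(dx^2 + dy^2)

  if (kind == "position") { ux <- dx; uy <- dy } else { ux <- dvx; uy <- dvy }
  out <- data.frame(
    cx = ux * hy - uy * hx,
    cy = ux * hx + uy * hy,
    ax = traj$ax[fi] * hy - traj$ay[fi] * hx,
    ay = traj$ax[fi] * hx + traj$ay[fi] * hy,
    frame = rows, focal = focal, neighbor = nbr,
    d_nn = d,
    approach_rate = (dx * dvx + dy * dvy) / d,
    rel_heading = acos(pmin(1, pmax(-1,
      (traj$vx[fi] * traj$vx[ni] + traj$vy[fi] * traj$vy[ni]) / (sp_f * sp_n)))),
    focal_speed = sp_f, neighbor_speed = sp_n)

  if (!is.null(filter)) {
    stopifnot(inherits(filter, "sample_filter"))
    keep <- rep(TRUE, nrow(out))
    f <- filter
    if (!is.null(f$nn_dist))
      keep <- keep & out$d_nn >= f$nn_dist[1] & out$d_nn <= f$nn_dist[2]
    if (!is.null(f$approach))
      keep <- keep & if (f$approach == "approaching")
        out$approach_rate < 0 else out$approach_rate > 0
    if (!is.null(f$rel_heading))
      keep <- keep & out$rel_heading >= f$rel_heading[1] &
        out$rel_heading <= f$rel_heading[2]
    if (!is.null(f$focal_speed))
      keep <- keep & out$focal_speed >= f$focal_speed[1] &
        out$focal_speed <= f$focal_speed[2]
    if (!is.null(f$neighbor_speed))
      keep <- keep & if (f$neighbor_speed == "faster")
        out$neighbor_speed > out$focal_speed else
        out$neighbor_speed < out$focal_speed
    if (!is.null(f$wall_dist)) {
      org <- if (is.null(f$tank$origin)) c(0, 0) else f$tank$origin
      wx <- traj$x[fi] - org[1]; wy <- traj$y[fi] - org[2]
      wd <- pmin(wx, f$tank$side - wx, wy, f$tank$side - wy)
      keep <- keep & wd >= f$wall_dist[1] & wd <= f$wall_dist[2]
    }
    out <- out[keep, , drop = FALSE]
  }
  attr(out, "kind") <- kind
  out
}

#' Bin force-map samples into a force map
#'
#' Averages the sampled acceleration vectors on a uniform square grid
#' symmetric about the origin; bins with fewer than `min_count` samples
#' are masked (`NA`).
#'
#' @param samples Data frame from [collect_samples()] (columns `cx`, `cy`,
#'   `ax`, `ay`).
#' @param range Half-width of the grid (same units as the coordinate).
#' @param bins Number of bins per axis.
#' @param min_count Minimum samples per bin for the mean to be reported.
#' @return A `force_map` object: list with `kind`, `breaks`, `centers`,
#'   `fx`, `fy` (bins x bins matrices of mean acceleration, `[ix, iy]`
#'   indexing, `NA` where masked), `counts`, `min_count`, `n_samples`.
#' @export
bin_map <- function(samples, range = 15, bins = 30, min_count = 50) {
  stopifnot(range > 0, bins >= 1)
  breaks <- seq(-range, range, length.out = bins + 1)
  ix <- findInterval(samples$cx, breaks, rightmost.closed = TRUE)
  iy <- findInterval(samples$cy, breaks, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= bins & iy >= 1 & iy <= bins
  idx <- ix[ok] + bins * (iy[ok] - 1L)
  counts <- matrix(tabulate(idx, bins * bins), bins, bins)
  sum_ax <- matrix(0, bins, bins); sum_ay <- matrix(0, bins, bins)
  if (any(ok)) {
    sx <- rowsum(samples$ax[ok], idx)
    sy <- rowsum(samples$ay[ok], idx)
    at <- as.integer(rownames(sx))
    sum_ax[at] <- sx; sum_ay[at] <- sy
  }
  fx <- sum_ax / counts; fy <- sum_ay / counts
  mask <- counts < max(min_count, 1)
  fx[mask] <- NA_real_; fy[mask] <- NA_real_
  structure(list(kind = attr(samples, "kind", exact = TRUE),
                 breaks = breaks,
                 centers = (breaks[-1] + breaks[-(bins + 1)]) / 2,
                 fx = fx, fy = fy, counts = counts,
                 min_count = min_count, n_samples = nrow(samples)),
            class = "force_map")
}

#' @export
print.force_map <- function(x, ...) {
  cat(sprintf("<force_map> kind: %s, %d x %d bins over [%+g, %+g], %d samples, %d populated bins (min_count = %d)\n",
              if (is.null(x$kind)) "?" else x$kind,
              length(x$centers), length(x$centers),
              x$breaks[1], x$breaks[length(x$breaks)], x$n_samples,
              sum(!is.na(x$fx)), x$min_count))
  invisible(x)
}

#' Build a force map from a trajectory
#'
#' Convenience wrapper: [collect_samples()] then [bin_map()]. The default
#' grids are +-20 cm for the relative-position (attraction-repulsion) map
#' and +-15 cm/s for the relative-velocity (alignment) map.
#'
#' @inheritParams collect_samples
#' @inheritParams bin_map
#' @param range Grid half-width; defaults to 20 (cm) for `"position"` and
#'   15 (cm/s) for `"velocity"`.
#' @return A `force_map`.
#' @export
force_map <- function(traj, kind = c("position", "velocity"),
                      neighbor = c("nearest", "voronoi"), filter = NULL,
                      range = NULL, bins = 30, min_count = 50) {
  kind <- match.arg(kind)
  if (is.null(range)) range <- if (kind == "position") 20 else 15
  s <- collect_samples(traj, kind, neighbor, filter)
  bin_map(s, range = range, bins = bins, min_count = min_count)
}

#' Radial projection of a force map
#'
#' Per-bin dot product of the mean acceleration with the unit vector from
#' the origin to the bin center. Negative values point inward (attraction
#' in the relative-position map, alignment in the relative-velocity map);
#' positive values point outward (repulsion, antialignment).
#'
#' @param map A `force_map`.
#' @return bins x bins numeric matrix (`NA` where the map is masked or the
#'   bin center sits at the origin).
#' @export
radial_projection <- function(map) {
  stopifnot(inherits(map, "force_map"))
  cx <- outer(map$centers, rep(1, length(map$centers)))
  cy <- t(cx)
  r <- sqrt(cx^2 + cy^2)
  proj <- (map$fx * cx + map$fy * cy) / r
  proj[r < 1e-12] <- NA_real_
  proj
}

#' Angularly averaged radial force profile
#'
#' Bins force-map samples by the modulus of their coordinate and averages
#' the radial component of the acceleration, giving a one-dimensional
#' profile of the inward/outward force versus distance (or speed
#' difference). For the relative-position map of an
#' attraction-repulsion interaction, the profile crosses zero from
#' outward (repulsion) to inward (attraction) at the equilibrium distance;
#' [profile_zero_crossing()] locates that crossing by linear
#' interpolation between adjacent populated bins.
#'
#' @inheritParams collect_samples
#' @param r_max Profile range (coordinate modulus).
#' @param bins Number of radial bins.
#' @param min_count Minimum samples per bin.
#' @return A data frame with `r` (bin center), `radial` (mean radial
#'   acceleration component, `NA` if under-populated) and `count`.
#' @export
radial_force_profile <- function(traj, kind = c("position", "velocity"),
                                 neighbor = c("nearest", "voronoi"),
                                 filter = NULL, r_max = 20, bins = 40,
                                 min_count = 50) {
  kind <- match.arg(kind)
  s <- collect_samples(traj, kind, neighbor, filter)
  r <- sqrt(s$cx^2 + s$cy^2)
  proj <- (s$ax * s$cx + s$ay * s$cy) / r
  breaks <- seq(0, r_max, length.out = bins + 1)
  ib <- findInterval(r, breaks, rightmost.closed = TRUE)
  ok <- ib >= 1 & ib <= bins & r > 1e-12
  counts <- tabulate(ib[ok], bins)
  sums <- numeric(bins)
  agg <- rowsum(proj[ok], ib[ok])
  sums[as.integer(rownames(agg))] <- agg
  radial <- sums / counts
  radial[counts < max(min_count, 1)] <- NA_real_
  data.frame(r = (breaks[-1] + breaks[-(bins + 1)]) / 2,
             radial = radial, count = counts)
}

#' @rdname radial_force_profile
#' @param profile A profile data frame from `radial_force_profile()`.
#' @return `profile_zero_crossing()`: the interpolated location of the
#'   first outward-to-inward sign change (`NA` if none).
#' @export
profile_zero_crossing <- function(profile) {
  v <- profile[!is.na(profile$radial), ]
  if (nrow(v) < 2) return(NA_real_)
  for (i in seq_len(nrow(v) - 1)) {
    if (v$radial[i] > 0 && v$radial[i + 1] <= 0) {
      r1 <- v$r[i]; r2 <- v$r[i + 1]
      f1 <- v$radial[i]; f2 <- v$radial[i + 1]
      return(r1 + f1 * (r2 - r1) / (f1 - f2))
    }
  }
  NA_real_
}

#' Tabulated force field with smoothing and bilinear interpolation
#'
#' `smooth_and_interpolate_field()` turns a binned force map into a
#' continuous vector field: masked bins are first filled from their nearest
#' valid neighbors (so smoothing never bleeds mask sentinels), each
#' component is then smoothed with a Gaussian filter of width `sigma_bins`
#' bins, and the result is exposed through bilinear interpolation with the
#' boundary value clamped outside the grid. Such a field drives the
#' `"antialign"` model variant. `as_force_field()` wraps explicit component
#' matrices (e.g. an analytic field) in the same container, and
#' `field_eval()` evaluates a field at arbitrary points.
#'
#' @param map A `force_map`.
#' @param sigma_bins Gaussian smoothing width, in bins.
#' @return A `force_field` object.
#' @export
smooth_and_interpolate_field <- function(map, sigma_bins = 2) {
  stopifnot(inherits(map, "force_map"))
  if (all(is.na(map$fx))) stop("fully masked map: no field to build")
  fx <- fill_masked(map$fx); fy <- fill_masked(map$fy)
  if (sigma_bins > 0) {
    fx <- gauss_smooth2d(fx, sigma_bins)
    fy <- gauss_smooth2d(fy, sigma_bins)
  }
  nb <- length(map$centers)
  as_force_field(fx, fy,
                 xmin = map$breaks[1], xmax = map$breaks[nb + 1],
                 ymin = map$breaks[1], ymax = map$breaks[nb + 1])
}

#' @rdname smooth_and_interpolate_field
#' @param fx,fy nx x ny matrices of the field components on cell centers.
#' @param xmin,xmax,ymin,ymax Grid extent.
#' @export
as_force_field <- function(fx, fy, xmin, xmax, ymin, ymax) {
  fx <- as.matrix(fx); fy <- as.matrix(fy)
  stopifnot(identical(dim(fx), dim(fy)), xmax > xmin, ymax > ymin,
            all(is.finite(fx)), all(is.finite(fy)))
  structure(list(fx = fx, fy = fy, nx = nrow(fx), ny = ncol(fx),
                 xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = "force_field")
}

#' @rdname smooth_and_interpolate_field
#' @param field A `force_field`.
#' @param qx,qy Query coordinates (vectors).
#' @return `field_eval()`: list with numeric vectors `fx`, `fy`.
#' @export
field_eval <- function(field, qx, qy) {
  stopifnot(inherits(field, "force_field"))
  nx <- field$nx; ny <- field$ny
  hx <- (field$xmax - field$xmin) / nx
  hy <- (field$ymax - field$ymin) / ny
  gx <- pmin(pmax((qx - field$xmin) / hx - 0.5, 0), nx - 1)
  gy <- pmin(pmax((qy - field$ymin) / hy - 0.5, 0), ny - 1)
  i0 <- pmin(floor(gx), max(nx - 2, 0)) ; j0 <- pmin(floor(gy), max(ny - 2, 0))
  tx <- pmin(pmax(gx - i0, 0), 1); ty <- pmin(pmax(gy - j0, 0), 1)
  i1 <- pmin(i0 + 1, nx - 1); j1 <- pmin(j0 + 1, ny - 1)
  at <- function(m, i, j) m[cbind(i + 1, j + 1)]
  bil <- function(m)
    (1 - tx) * (1 - ty) * at(m, i0, j0) + tx * (1 - ty) * at(m, i1, j0) +
    (1 - tx) * ty * at(m, i0, j1) + tx * ty * at(m, i1, j1)
  list(fx = bil(field$fx), fy = bil(field$fy))
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf("<force_field> %d x %d grid over [%g, %g] x [%g, %g]\n",
              x$nx, x$ny, x$xmin, x$xmax, x$ymin, x$ymax))
  invisible(x)
}

# iterative nearest-valid fill: NA cells take the mean of their valid
# 4-neighbors until none remain
fill_masked <- function(m) {
  while (anyNA(m)) {
    na <- which(is.na(m), arr.ind = TRUE)
    filled <- m
    progressed <- FALSE
    for (k in seq_len(nrow(na))) {
      i <- na[k, 1]; j <- na[k, 2]
      nb <- c(if (i > 1) m[i - 1, j], if (i < nrow(m)) m[i + 1, j],
              if (j > 1) m[i, j - 1], if (j < ncol(m)) m[i, j + 1])
      nb <- nb[!is.na(nb)]
      if (length(nb)) { filled[i, j] <- mean(nb); progressed <- TRUE }
    }
    if (!progressed) stop("cannot fill masked bins")
    m <- filled
  }
  m
}

# separable Gaussian smoothing on a grid, reflected at the boundary
gauss_smooth2d <- function(m, sigma, truncate = 5) {
  h <- max(1L, ceiling(truncate * sigma))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k <- k / sum(k)
  sm1 <- function(v) {
    n <- length(v)
    pad <- c(v[pmin(h:1, n)], v, v[pmax(n - (1:h) + 1, 1)])
    as.numeric(stats::filter(pad, k, sides = 2))[(h + 1):(h + n)]
  }
  m2 <- apply(m, 2, sm1)
  t(apply(m2, 1, sm1))
}

#' Quiver plot of a force map
#'
#' Displays the per-bin modulus of the mean acceleration as a color image
#' with arrows for the vector components, in the focal frame (y-axis along
#' the focal individual's motion).
#'
#' @param x A `force_map`.
#' @param arrow_scale Multiplier from force units to plot units.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.force_map <- function(x, arrow_scale = NULL, ...) {
  mod <- sqrt(x$fx^2 + x$fy^2)
  image(x$centers, x$centers, mod, col = hcl.colors(64, "viridis"),
        xlab = if (identical(x$kind, "velocity"))
          "relative vx (cm/s)" else "relative x (cm)",
        ylab = if (identical(x$kind, "velocity"))
          "relative vy (cm/s)" else "relative y (cm)", ...)
  ok <- which(!is.na(x$fx), arr.ind = TRUE)
  if (nrow(ok)) {
    if (is.null(arrow_scale)) {
      step <- diff(x$centers[1:2])
      arrow_scale <- 0.8 * step / max(mod, na.rm = TRUE)
    }
    x0 <- x$centers[ok[, 1]]; y0 <- x$centers[ok[, 2]]
    arrows(x0, y0, x0 + arrow_scale * x$fx[ok], y0 + arrow_scale * x$fy[ok],
           length = 0.03, col = "white")
  }
  invisible(x)
}
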