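#' Deterministic trajectory fixtures
#'
#' Small analytic trajectory ensembles used across examples and tests.
#'
#' `fixture_copy_lag()` builds a leader-follower pair: individual 1 steers
#' through smooth heading and speed modulations, individual 2 reproduces
#' individual 1's velocity exactly `lag_frames` later (a known, exact
#' information flow -- the follower's orientation correlation with the
#' leader peaks at delay `-lag_frames * dt`, the leader's at
#' `+lag_frames * dt`).
#'
#' `fixture_circle()` is a single individual on uniform circular motion
#' (radius `radius`, speed `speed`): its turning rate is `speed / radius`
#' everywhere.
#'
#' `fixture_lattice()` is a rigid square lattice translating with a common
#' velocity: perfectly polarized, constant neighbor structure.
#'
#' `fixture_line_school()` is a set of individuals moving with an
#' identical, constant velocity from staggered positions: zero
#' accelerations, polarization 1.
#'
#' @param n_frames Number of frames.
#' @param dt Frame spacing, s.
#' @param lag_frames Lag of the follower, frames.
#' @param speed,radius Speed (cm/s) and radius (cm).
#' @param n,spacing Lattice/school size and spacing (cm).
#' @param heading Heading angle, rad.
#' @return A [school_traj()].
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
fixture_copy_lag <- function(n_frames = 2000, lag_frames = 10, dt = 0.02,
                             speed = 11) {
  stopifnot(lag_frames >= 1, n_frames > 3 * lag_frames)
  total <- n_frames + lag_frames
  tt <- (seq_len(total) - 1) * dt
  # aperiodic smooth steering so the velocity autocorrelation has a single
  # global maximum at zero lag
  theta <- 0.9 * sin(2 * pi * tt / 7.3) + 0.5 * sin(2 * pi * tt / 2.9 + 1)
  sp <- speed + 2.5 * sin(2 * pi * tt / 4.1) + 1.2 * sin(2 * pi * tt / 1.7 + 2)
  vx_l <- sp * cos(theta); vy_l <- sp * sin(theta)
  x_l <- cumsum(vx_l) * dt; y_l <- cumsum(vy_l) * dt
  keep_l <- (lag_frames + 1):total       # leader, aligned time axis
  keep_f <- seq_len(total - lag_frames)  # follower = leader delayed
  x <- cbind(x_l[keep_l], x_l[keep_f] + 3)
  y <- cbind(y_l[keep_l], y_l[keep_f] + 3)
  vx <- cbind(vx_l[keep_l], vx_l[keep_f])
  vy <- cbind(vy_l[keep_l], vy_l[keep_f])
  ax <- apply(vx, 2, central_diff, dt = dt)
  ay <- apply(vy, 2, central_diff, dt = dt)
  school_traj((seq_len(n_frames) - 1) * dt, x, y, vx, vy, ax, ay,
              source = "fixture")
}

#' @rdname fixtures
#' @export
fixture_circle <- function(n_frames = 500, dt = 0.02, radius = 10,
                           speed = 11) {
  w <- speed / radius
  tt <- (seq_len(n_frames) - 1) * dt
  school_traj(tt,
              x = cbind(radius * cos(w * tt)),
              y = cbind(radius * sin(w * tt)),
              vx = cbind(-speed * sin(w * tt)),
              vy = cbind(speed * cos(w * tt)),
              ax = cbind(-speed * w * cos(w * tt)),
              ay = cbind(-speed * w * sin(w * tt)),
              source = "fixture")
}

#' @rdname fixtures
#' @export
fixture_lattice <- function(n = 16, spacing = 5, n_frames = 100, dt = 0.02,
                            speed = 11, heading = pi / 4) {
  side <- ceiling(sqrt(n))
  gx <- spacing * (rep(seq_len(side), side)[seq_len(n)] - 1)
  gy <- spacing * (rep(seq_len(side), each = side)[seq_len(n)] - 1)
  tt <- (seq_len(n_frames) - 1) * dt
  vx <- speed * cos(heading); vy <- speed * sin(heading)
  school_traj(tt,
              x = outer(tt, rep(vx, n)) + matrix(gx, n_frames, n, TRUE),
              y = outer(tt, rep(vy, n)) + matrix(gy, n_frames, n, TRUE),
              vx = matrix(vx, n_frames, n), vy = matrix(vy, n_frames, n),
              ax = matrix(0, n_frames, n), ay = matrix(0, n_frames, n),
              source = "fixture")
}

#' @rdname fixtures
#' @export
fixture_line_school <- function(n = 5, spacing = 6, n_frames = 200,
                                dt = 0.02, speed = 11) {
  tt <- (seq_len(n_frames) - 1) * dt
  # staggered ranks so the configuration is never collinear
  gx <- spacing * seq_len(n)
  gy <- 2 * ((seq_len(n) %% 2) - 0.5) * spacing / 3
  school_traj(tt,
              x = matrix(gx, n_frames, n, TRUE),
              y = outer(tt, rep(speed, n)) + matrix(gy, n_frames, n, TRUE),
              vx = matrix(0, n_frames, n),
              vy = matrix(speed, n_frames, n),
              ax = matrix(0, n_frames, n), ay = matrix(0, n_frames, n),
              source = "fixture")
}

# central differences with one-sided ends
central_diff <- function(v, dt) {
  n <- length(v)
  c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1]) / dt
}
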