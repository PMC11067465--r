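#' Trajectory ensemble container
#'
#' A `school_traj` holds the kinematics of N identified individuals on a
#' uniform time grid: per-frame positions, velocities and accelerations as
#' `n_frames x N` matrices. Ensembles are produced by the simulator
#' ([simulate_school()]), by the experimental-style preprocessing pipeline
#' ([smooth_and_differentiate()]), or by the fixture generators; the two
#' kinematic conventions (integrator-recorded vs Gaussian-derivative) are
#' never mixed within one ensemble.
#'
#' @param times Frame times, s (uniform spacing).
#' @param x,y,vx,vy,ax,ay `n_frames x N` numeric matrices (cm, cm/s,
#'   cm/s^2).
#' @param params Optional [school_params()] the ensemble was generated
#'   with.
#' @param source Character tag: `"simulated"`, `"tracked"` or `"fixture"`.
#' @return An object of class `school_traj`.
#' @export
school_traj <- function(times, x, y, vx, vy, ax = NULL, ay = NULL,
                        params = NULL, source = "fixture") {
  x <- as.matrix(x); y <- as.matrix(y)
  vx <- as.matrix(vx); vy <- as.matrix(vy)
  tn <- length(times)
  stopifnot(nrow(x) == tn, identical(dim(x), dim(y)),
            identical(dim(x), dim(vx)), identical(dim(x), dim(vy)))
  if (tn >= 2) {
    dts <- diff(times)
    if (max(abs(dts - dts[1])) > 1e-9 * max(dts[1], 1))
      stop("frame times must be uniformly spaced")
    dt <- dts[1]
  } else dt <- NA_real_
  if (!is.null(ax)) {
    ax <- as.matrix(ax); ay <- as.matrix(ay)
    stopifnot(identical(dim(x), dim(ax)), identical(dim(x), dim(ay)))
  }
  structure(list(times = as.numeric(times), x = x, y = y, vx = vx, vy = vy,
                 ax = ax, ay = ay, dt = dt, params = params,
                 source = source),
            class = "school_traj")
}

#' @export
print.school_traj <- function(x, ...) {
  cat(sprintf("<school_traj> %d individuals x %d frames (dt = %g s, %.1f s), source: %s\n",
              ncol(x$x), nrow(x$x), x$dt, nrow(x$x) * x$dt, x$source))
  if (is.null(x$ax)) cat("  accelerations: absent\n")
  invisible(x)
}

#' @export
dim.school_traj <- function(x) dim(x$x)

#' @export
as.data.frame.school_traj <- function(x, ...) {
  tn <- nrow(x$x); n <- ncol(x$x)
  out <- data.frame(
    frame = rep(seq_len(tn) - 1L, n),
    id = rep(seq_len(n), each = tn),
    x_cm = as.vector(x$x), y_cm = as.vector(x$y),
    vx = as.vector(x$vx), vy = as.vector(x$vy))
  if (!is.null(x$ax)) {
    out$ax <- as.vector(x$ax)
    out$ay <- as.vector(x$ay)
  }
  out
}

#' Simulate a school of interacting self-propelled individuals
#'
#' Integrates the stochastic equations of motion with the Euler-Maruyama
#' scheme (semi-implicit ordering: velocities are updated from forces at
#' the current state, positions advance with the new velocity). Each
#' individual feels social forces -- attraction-repulsion and alignment,
#' averaged over its Voronoi neighbors with inverse-distance weights --
#' plus friction-propulsion toward the preferred speed and active noise
#' along and perpendicular to its heading. The interacting set is
#' controlled by `params$variant`; see [school_params()]. The simulation
#' plane is unbounded. Recorded accelerations are the deterministic force
#' plus the realized noise increment divided by dt, i.e. the acceleration a
#' tracking pipeline would measure from the trajectory.
#'
#' @param params A [school_params()] object.
#' @param n_frames Number of frames kept, after the transient.
#' @param n_transient Number of initial frames discarded as transient.
#' @param init Optional initial state: list with numeric vectors `x`, `y`,
#'   `vx`, `vy` of length `n_individuals`. By default positions are drawn
#'   uniformly in a disc sized so the mean nearest-neighbor distance is
#'   close to `d0`, with speeds `v0` and uniformly random headings.
#' @param seed Optional integer; if given, `set.seed(seed)` is called so
#'   the run is reproducible.
#' @return A [school_traj()] with `n_frames` frames.
#' @export
#' @examples
#' p <- school_params(n_individuals = 10)
#' tr <- simulate_school(p, n_frames = 200, n_transient = 50, seed = 1)
#' mean(polarization(tr))
simulate_school <- function(params, n_frames = 150000, n_transient = 1000,
                            init = NULL, seed = NULL) {
  stopifnot(inherits(params, "school_params"))
  if (n_transient < 0 || n_frames <= 0)
    stop("need n_frames > 0 and n_transient >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- default_init(params)
  n <- params$n_individuals
  stopifnot(length(init$x) == n, length(init$y) == n,
            length(init$vx) == n, length(init$vy) == n)
  res <- .simulate_cpp(init$x, init$y, init$vx, init$vy,
                       params_for_cpp(params),
                       as.integer(n_frames), as.integer(n_transient))
  school_traj(times = (seq_len(n_frames) - 1) * params$dt,
              x = res$x, y = res$y, vx = res$vx, vy = res$vy,
              ax = res$ax, ay = res$ay,
              params = params, source = "simulated")
}

# Positions uniform in a disc whose radius targets a mean nearest-neighbor
# distance of d0 (mean NN distance of a Poisson process of density rho is
# 0.5 / sqrt(rho)); speeds v0, headings uniform.
default_init <- function(params) {
  n <- params$n_individuals
  R <- max(2 * params$d0 * sqrt(n / pi), params$d0)
  r <- R * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  phi <- runif(n, 0, 2 * pi)
  list(x = r * cos(th), y = r * sin(th),
       vx = params$v0 * cos(phi), vy = params$v0 * sin(phi))
}

#' Write and read trajectory ensembles as columnar text
#'
#' The columnar format has header `frame, id, x_cm, y_cm, vx, vy[, ax, ay]`
#' and one row per individual and frame; a leading comment line records the
#' frame spacing (`# dt <seconds>`). Values are written with 12 significant
#' digits, so a round trip is lossless for practical purposes.
#'
#' @param traj A [school_traj()].
#' @param path File path.
#' @param dt Frame spacing in seconds; only needed when the file lacks the
#'   `# dt` comment line.
#' @return `read_trajectory()` returns a `school_traj`;
#'   `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "school_traj"))
  df <- as.data.frame(traj)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt %.12g", traj$dt), con)
  writeLines(paste(names(df), collapse = ","), con)
  num <- vapply(df, function(col)
    formatC(col, format = "g", digits = 12), character(nrow(df)))
  writeLines(apply(num, 1, paste, collapse = ","), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, dt = NULL) {
  first <- readLines(path, n = 1)
  if (grepl("^#\\s*dt\\s", first))
    dt <- as.numeric(sub("^#\\s*dt\\s+", "", first))
  if (is.null(dt) || !is.finite(dt))
    stop("frame spacing unknown: file has no '# dt' line and 'dt' not given")
  df <- read.table(path, header = TRUE, sep = ",", comment.char = "#")
  need <- c("frame", "id", "x_cm", "y_cm", "vx", "vy")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns ", paste(need, collapse = ", "))
  ids <- sort(unique(df$id))
  frames <- sort(unique(df$frame))
  tn <- length(frames); n <- length(ids)
  if (nrow(df) != tn * n)
    stop("trajectory file is not a complete frame x id grid")
  df <- df[order(df$id, df$frame), ]
  m <- function(col) matrix(df[[col]], nrow = tn, ncol = n)
  has_acc <- all(c("ax", "ay") %in% names(df))
  school_traj(times = (frames - frames[1]) * dt,
              x = m("x_cm"), y = m("y_cm"), vx = m("vx"), vy = m("vy"),
              ax = if (has_acc) m("ax"), ay = if (has_acc) m("ay"),
              source = "tracked")
}

# nearest-neighbor index matrix (frames x individuals), computed once
traj_nn <- function(traj) .nn_indices_cpp(traj$x, traj$y)

# speeds matrix
traj_speed <- function(traj) sqrt(traj$vx^2 + traj$vy^2)
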