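#' Surrogate self-delay force map
#'
#' Builds an alignment-style force map for pseudo-pairs with known
#' information flow: the "neighbor" of focal individual i at time t is the
#' same individual at time t + tau. For positive tau the present individual
#' follows its own future heading (a follower within the pseudo-pair), and
#' the map shows pure alignment (inward radial component); for negative
#' tau the present individual leads, and the map shows pure antialignment.
#' These surrogate maps give ground truth for interpreting
#' alignment/antialignment signatures as leader-follower relationships.
#'
#' @param traj A [school_traj()] with velocities and accelerations.
#' @param tau Signed delay, s; must be a nonzero integer multiple of the
#'   frame spacing (no interpolation is performed).
#' @param range,bins,min_count Binning as in [bin_map()].
#' @return A `force_map` (kind `"velocity"`) of the pseudo-pair relative
#'   velocity `v_i(t) - v_i(t + tau)` in the focal frame of i at t.
#' @export
surrogate_self_delay_map <- function(traj, tau = 0.2, range = 15,
                                     bins = 30, min_count = 50) {
  stopifnot(inherits(traj, "school_traj"))
  if (is.null(traj$ax)) stop("trajectory has no accelerations")
  k <- tau / traj$dt
  if (abs(k - round(k)) > 1e-6)
    stop("tau must be an integer multiple of the frame spacing")
  k <- as.integer(round(k))
  if (k == 0) stop("tau must be nonzero (self minus self is identically zero)")
  tn <- nrow(traj$x)
  if (abs(k) >= tn) stop("trajectory shorter than the requested delay")
  t_now <- if (k > 0) seq_len(tn - k) else seq(1 - k, tn)
  t_del <- t_now + k
  sp <- sqrt(traj$vx[t_now, , drop = FALSE]^2 + traj$vy[t_now, , drop = FALSE]^2)
  if (any(sp < 1e-9)) stop("zero focal speed: heading undefined")
  hx <- traj$vx[t_now, , drop = FALSE] / sp
  hy <- traj$vy[t_now, , drop = FALSE] / sp
  dvx <- traj$vx[t_now, , drop = FALSE] - traj$vx[t_del, , drop = FALSE]
  dvy <- traj$vy[t_now, , drop = FALSE] - traj$vy[t_del, , drop = FALSE]
  ax <- traj$ax[t_now, , drop = FALSE]; ay <- traj$ay[t_now, , drop = FALSE]
  s <- data.frame(cx = as.vector(dvx * hy - dvy * hx),
                  cy = as.vector(dvx * hx + dvy * hy),
                  ax = as.vector(ax * hy - ay * hx),
                  ay = as.vector(ax * hx + ay * hy))
  attr(s, "kind") <- "velocity"
  bin_map(s, range = range, bins = bins, min_count = min_count)
}

#' Per-sample state labels for leadership analysis
#'
#' Classifies a (focal, frame) sample by the focal individual's state
#' relative to its nearest neighbor: `"faster"`/`"slower"` compare speeds
#' (strict inequalities; equal speeds match neither), `"frontal"`/`"rear"`
#' test the sign of the neighbor-relative position along the focal
#' heading, and `"all"` is always true.
#'
#' @param traj A [school_traj()].
#' @param frame,focal Frame and individual indices (vectors of equal
#'   length, or one of them scalar).
#' @param label One of `"all"`, `"faster"`, `"slower"`, `"frontal"`,
#'   `"rear"`.
#' @return Logical vector.
#' @export
state_filter <- function(traj, frame, focal,
                         label = c("all", "faster", "slower",
                                   "frontal", "rear")) {
  label <- match.arg(label)
  n <- max(length(frame), length(focal))
  frame <- rep_len(frame, n); focal <- rep_len(focal, n)
  if (label == "all") return(rep(TRUE, n))
  nn <- traj_nn(traj)
  fi <- cbind(frame, focal)
  ni <- cbind(frame, nn[fi])
  sp_f <- sqrt(traj$vx[fi]^2 + traj$vy[fi]^2)
  sp_n <- sqrt(traj$vx[ni]^2 + traj$vy[ni]^2)
  switch(label,
    faster = sp_f > sp_n,
    slower = sp_f < sp_n,
    frontal = (traj$x[fi] - traj$x[ni]) * traj$vx[fi] +
      (traj$y[fi] - traj$y[ni]) * traj$vy[fi] > 0,
    rear = (traj$x[fi] - traj$x[ni]) * traj$vx[fi] +
      (traj$y[fi] - traj$y[ni]) * traj$vy[fi] < 0)
}

#' Time-delayed orientation and speed correlations
#'
#' For each signed delay tau on a uniform grid, pools all (focal, frame)
#' samples passing the state filter at the reference time t and pairs the
#' focal individual with its time-t nearest neighbor evaluated at t + tau
#' (the neighbor identity is fixed at t and tracked, not re-evaluated).
#' Orientation correlation is the mean heading dot product
#' `vhat_i(t) . vhat_NN(t + tau)`; speed correlation is the Pearson
#' coefficient of the pooled speeds. In the presence of leadership, a
#' follower needs time to copy its leader, so the curve of a leader state
#' peaks at positive delay and that of a follower state at negative delay.
#' Edge frames where t + tau leaves the recording are dropped.
#'
#' @param traj A [school_traj()].
#' @param tau_max Largest |tau|, s.
#' @param tau_step Delay grid spacing, s; must be a positive integer
#'   multiple of the frame spacing (default one frame).
#' @param label State filter label, see [state_filter()].
#' @param focal Optional subset of individuals to use as focal.
#' @return A `delayed_corr` data frame with columns `label`, `tau`,
#'   `orient` (mean heading dot product), `speed_r` (Pearson r of speeds)
#'   and `n` (pooled sample count).
#' @export
delayed_correlations <- function(traj, tau_max = 2, tau_step = NULL,
                                 label = "all", focal = NULL) {
  stopifnot(inherits(traj, "school_traj"))
  tn <- nrow(traj$x); n <- ncol(traj$x)
  if (is.null(tau_step)) tau_step <- traj$dt
  kstep <- tau_step / traj$dt
  if (kstep < 1 - 1e-9 || abs(kstep - round(kstep)) > 1e-6)
    stop("tau_step must be a positive integer multiple of the frame spacing")
  kstep <- as.integer(round(kstep))
  kmax <- as.integer(floor(tau_max / traj$dt / kstep)) * kstep
  if (kmax >= tn) stop("trajectory shorter than tau_max")
  ks <- seq(-kmax, kmax, by = kstep)

  nn <- traj_nn(traj)
  sp <- traj_speed(traj)
  if (any(sp < 1e-9)) stop("zero speed: heading undefined")
  ux <- traj$vx / sp; uy <- traj$vy / sp
  if (is.null(focal)) focal <- seq_len(n)

  frame_all <- rep(seq_len(tn), length(focal))
  focal_all <- rep(focal, each = tn)
  keep <- state_filter(traj, frame_all, focal_all, label)
  frame_all <- frame_all[keep]; focal_all <- focal_all[keep]
  nbr_all <- nn[cbind(frame_all, focal_all)]

  res <- lapply(ks, function(k) {
    ok <- frame_all + k >= 1 & frame_all + k <= tn
    ft <- frame_all[ok]; fo <- focal_all[ok]; nb <- nbr_all[ok]
    if (!length(ft))
      return(data.frame(label = label, tau = k * traj$dt, orient = NA_real_,
                        speed_r = NA_real_, n = 0L))
    fi <- cbind(ft, fo); di <- cbind(ft + k, nb)
    orient <- mean(ux[fi] * ux[di] + uy[fi] * uy[di])
    sr <- if (length(ft) >= 3 && sd(sp[fi]) > 0 && sd(sp[di]) > 0)
      cor(sp[fi], sp[di]) else NA_real_
    data.frame(label = label, tau = k * traj$dt, orient = orient,
               speed_r = sr, n = length(ft))
  })
  out <- do.call(rbind, res)
  class(out) <- c("delayed_corr", "data.frame")
  out
}

#' @rdname delayed_correlations
#' @param curve A `delayed_corr` data frame.
#' @param what `"orient"` or `"speed_r"`.
#' @return `peak_delay()`: list with `tau` (delay of the curve maximum) and
#'   `value`.
#' @export
peak_delay <- function(curve, what = c("orient", "speed_r")) {
  what <- match.arg(what)
  v <- curve[[what]]
  i <- which.max(v)
  list(tau = curve$tau[i], value = v[i])
}

#' Leadership report across state filters
#'
#' Computes delayed-correlation curves for a set of state labels on a
#' common delay grid and tabulates the location and height of each curve's
#' maximum, for both the orientation and the speed correlation. On data
#' with speed-mediated leadership, the `"faster"` curve peaks at positive
#' delay (faster individuals lead) and the `"slower"` curve at negative
#' delay (slower individuals follow).
#'
#' @inheritParams delayed_correlations
#' @param labels State labels to compare.
#' @return A `leadership_report`: list with `curves` (stacked
#'   `delayed_corr` rows) and `peaks` (one row per label: `orient_tau`,
#'   `orient_max`, `speed_tau`, `speed_max`).
#' @export
leadership_report <- function(traj, tau_max = 2, tau_step = NULL,
                              labels = c("all", "faster", "slower",
                                         "frontal", "rear"),
                              focal = NULL) {
  curves <- do.call(rbind, lapply(labels, function(lb)
    delayed_correlations(traj, tau_max, tau_step, lb, focal)))
  peaks <- do.call(rbind, lapply(labels, function(lb) {
    cv <- curves[curves$label == lb & !is.na(curves$orient), ]
    po <- peak_delay(cv, "orient")
    ps <- peak_delay(cv[!is.na(cv$speed_r), ], "speed_r")
    data.frame(label = lb, orient_tau = po$tau, orient_max = po$value,
               speed_tau = ps$tau, speed_max = ps$value)
  }))
  structure(list(curves = curves, peaks = peaks),
            class = "leadership_report")
}

#' @export
print.leadership_report <- function(x, ...) {
  cat("<leadership_report> curve maxima by state filter:\n")
  print(x$peaks, row.names = FALSE, digits = 3)
  invisible(x)
}
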