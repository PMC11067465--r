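#' Pairwise attraction-repulsion force
#'
#' Linear restoring force toward the equilibrium distance `d0`:
#' `F = -k (d_ij - d0) (x_i - x_j) / d_ij`, with `k = k_rep` for
#' `d_ij <= d0` and `k = k_att` for `d_ij > d0`. The force pushes the focal
#' individual away from a too-close neighbor and pulls it toward a distant
#' one; it vanishes at `d_ij = d0`.
#'
#' @param pos_i,pos_j Positions of the focal individual and the neighbor,
#'   numeric length-2 vectors (cm).
#' @param params A [school_params()] object.
#' @return Acceleration on the focal individual, length-2 numeric (cm/s^2).
#' @export
#' @examples
#' p <- school_params()
#' attraction_repulsion_force(c(0, 0), c(p$d0 + 1, 0), p)  # attraction
attraction_repulsion_force <- function(pos_i, pos_j, params) {
  dvec <- pos_i - pos_j
  d <- sqrt(sum(dvec^2))
  if (d < 1e-12)
    stop("degenerate pair: coincident positions", call. = FALSE)
  k <- if (d <= params$d0) params$k_rep else params$k_att
  -k * (d - params$d0) * dvec / d
}

#' Pairwise alignment force
#'
#' `F = -mu (v_i - v_j)`: a linear restoring force driving the focal
#' velocity (speed and heading) toward the neighbor's.
#'
#' @param vel_i,vel_j Velocities of focal individual and neighbor, length-2
#'   numeric (cm/s).
#' @inheritParams attraction_repulsion_force
#' @return Acceleration on the focal individual, length-2 numeric (cm/s^2).
#' @export
alignment_force <- function(vel_i, vel_j, params) {
  -params$mu * (vel_i - vel_j)
}

#' Friction-propulsion force
#'
#' `F = -((|v_i| - v0) / tau_v) * vhat_i`: self-propulsion that relaxes the
#' speed toward the preferred speed `v0` on the timescale `tau_v`, acting
#' along the heading.
#'
#' @inheritParams alignment_force
#' @return Acceleration, length-2 numeric (cm/s^2).
#' @export
friction_propulsion_force <- function(vel_i, params) {
  s <- sqrt(sum(vel_i^2))
  if (s < 1e-9)
    stop("degenerate state: zero speed, heading undefined", call. = FALSE)
  if (!is.finite(params$tau_v)) return(c(0, 0))
  -((s - params$v0) / params$tau_v) * vel_i / s
}

#' Active-noise force
#'
#' Draws one realization `sigma_v xi_v vhat + sigma_phi xi_phi phihat` with
#' independent standard Gaussian `xi`, where `phihat` is the heading rotated
#' +90 degrees. This is the instantaneous noise amplitude; the integrator
#' applies the Euler-Maruyama `sqrt(dt)` scaling (sigma carries units
#' cm s^-3/2).
#'
#' @inheritParams alignment_force
#' @return Length-2 numeric.
#' @export
noise_force <- function(vel_i, params) {
  s <- sqrt(sum(vel_i^2))
  if (s < 1e-9)
    stop("degenerate state: zero speed, heading undefined", call. = FALSE)
  vhat <- vel_i / s
  phihat <- c(-vhat[2], vhat[1])
  xi <- rnorm(2)
  params$sigma_v * xi[1] * vhat + params$sigma_phi * xi[2] * phihat
}

#' Persistent-random-force register
#'
#' State machine for the `"persistent"` model variant. An inactive
#' individual activates with probability `pr_rate * dt` per step, drawing a
#' uniformly random direction and holding it for `pr_duration` seconds with
#' amplitude `pr_amplitude`; while active, its social interactions are off.
#' `new_persistent_register()` builds the inactive register,
#' `step_persistent_register()` advances it one time step, and
#' `persistent_random_force()` reads the force it currently exerts.
#'
#' @param register A register as returned by `new_persistent_register()` or
#'   `step_persistent_register()`.
#' @param params A [school_params()] object with `variant = "persistent"`.
#' @return `persistent_random_force()`: length-2 numeric (cm/s^2);
#'   `step_persistent_register()`: the updated register.
#' @export
new_persistent_register <- function() {
  list(active = FALSE, direction = c(0, 0), remaining = 0)
}

#' @rdname new_persistent_register
#' @export
step_persistent_register <- function(register, params) {
  stopifnot(identical(params$variant, "persistent"))
  if (register$active && register$remaining <= 0) register$active <- FALSE
  if (!register$active && runif(1) < params$pr_rate * params$dt) {
    th <- runif(1, 0, 2 * pi)
    register$active <- TRUE
    register$direction <- c(cos(th), sin(th))
    register$remaining <- params$pr_duration
  }
  if (register$active) register$remaining <- register$remaining - params$dt
  register
}

#' @rdname new_persistent_register
#' @export
persistent_random_force <- function(register, params) {
  if (!register$active) return(c(0, 0))
  params$pr_amplitude * register$direction
}

#' Per-individual force breakdown
#'
#' Composes the deterministic forces acting on every individual for one
#' configuration, using the interaction rule of `params$variant`:
#' Voronoi adjacency, inverse-distance weights over the interacting set
#' (normalized to a weighted average by default), pairwise
#' attraction-repulsion plus alignment, and the individual
#' friction-propulsion term. Noise is excluded (it is a stochastic
#' increment, not a mean force). This is a plain-R reference composition;
#' the simulator's C++ step is checked against it in the test suite.
#'
#' @param positions,velocities N x 2 numeric matrices (cm, cm/s).
#' @param params A [school_params()] object.
#' @param registers For the `"persistent"` variant, a list of N registers
#'   (see [new_persistent_register()]); individuals with an active register
#'   feel the persistent force instead of social forces.
#' @return A `force_breakdown` object: list of N x 2 matrices
#'   `attraction_repulsion`, `alignment`, `friction_propulsion`,
#'   `persistent`, and `total` (their elementwise sum), cm/s^2.
#' @export
force_breakdown <- function(positions, velocities, params, registers = NULL) {
  n <- nrow(positions)
  stopifnot(ncol(positions) == 2, identical(dim(positions), dim(velocities)))
  zero <- matrix(0, n, 2)
  out <- list(attraction_repulsion = zero, alignment = zero,
              friction_propulsion = zero, persistent = zero)
  speeds <- sqrt(rowSums(velocities^2))
  graph <- if (n >= 2) voronoi_adjacency(positions) else NULL

  for (i in seq_len(n)) {
    if (params$variant == "persistent" && !is.null(registers) &&
        isTRUE(registers[[i]]$active)) {
      out$persistent[i, ] <- persistent_random_force(registers[[i]], params)
    } else if (n >= 2) {
      set <- interacting_set(i, graph, speeds, params, positions)
      if (length(set)) {
        w <- social_weights(positions[i, ], positions[set, , drop = FALSE],
                            normalize = params$weight_norm != "none")
        if (params$variant == "nearest") w <- 1  # single neighbor, weight 1
        else if (params$weight_norm == "voronoi") {
          nbrs <- which(graph$adjacency[i, ])
          dall <- sqrt(rowSums((positions[nbrs, , drop = FALSE] -
                        rep(positions[i, ], each = length(nbrs)))^2))
          dset <- sqrt(rowSums((positions[set, , drop = FALSE] -
                        rep(positions[i, ], each = length(set)))^2))
          w <- (1 / dset) / sum(1 / dall)
        }
        for (m in seq_along(set)) {
          j <- set[m]
          out$attraction_repulsion[i, ] <- out$attraction_repulsion[i, ] +
            w[m] * attraction_repulsion_force(positions[i, ], positions[j, ], params)
          if (params$variant != "antialign")
            out$alignment[i, ] <- out$alignment[i, ] +
              w[m] * alignment_force(velocities[i, ], velocities[j, ], params)
        }
      }
      if (params$variant == "antialign") {
        nn <- graph$nearest[i]
        h <- velocities[i, ] / speeds[i]
        dv_focal <- focal_frame(velocities[i, ] - velocities[nn, ], h)
        f_focal <- field_eval(params$field, dv_focal[1], dv_focal[2])
        out$alignment[i, ] <- focal_to_lab(c(f_focal$fx, f_focal$fy), h)
      }
    }
    out$friction_propulsion[i, ] <-
      friction_propulsion_force(velocities[i, ], params)
  }
  out$total <- out$attraction_repulsion + out$alignment +
    out$friction_propulsion + out$persistent
  structure(out, class = "force_breakdown")
}

# indices of the neighbors individual i responds to under the variant rule
interacting_set <- function(i, graph, speeds, params, positions) {
  nbrs <- which(graph$adjacency[i, ])
  switch(params$variant,
    standard = ,
    antialign = ,
    persistent = nbrs,
    selective = nbrs[speeds[nbrs] > speeds[i]],
    nearest = graph$nearest[i]
  )
}
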