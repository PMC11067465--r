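#' Model parameters for the schooling simulator
#'
#' Builds a validated parameter set for the two-dimensional schooling model.
#' The defaults are the reference parameter set used throughout the package:
#' a repulsive spring constant `k_rep = 12.5` s^-2 and attractive constant
#' `k_att = 5` s^-2 acting about an equilibrium distance `d0 = 5.8` cm, an
#' alignment constant `mu = 1.5` s^-1, a preferred speed `v0 = 11` cm/s
#' relaxed on a timescale `tau_v = 1.6` s, and active-noise amplitudes
#' `sigma_v = 6.4` and `sigma_phi = 2.6` cm s^-3/2 along and perpendicular
#' to the heading. All forces are accelerations (unit mass).
#'
#' @param k_rep Repulsive spring constant, s^-2. Acts for inter-individual
#'   distances at or below `d0`.
#' @param k_att Attractive spring constant, s^-2. Acts above `d0`.
#' @param d0 Equilibrium distance between neighbors, cm.
#' @param mu Alignment constant, s^-1.
#' @param v0 Preferred speed, cm/s.
#' @param tau_v Speed relaxation time, s. `Inf` disables the
#'   friction-propulsion force.
#' @param sigma_v,sigma_phi Noise amplitudes along and perpendicular to the
#'   heading, cm s^-3/2 (the sqrt(dt) factor of the Euler-Maruyama scheme is
#'   applied by the integrator).
#' @param dt Integration step, s.
#' @param n_individuals Number of individuals (at least 1; a single
#'   individual feels only its individual forces).
#' @param variant Interaction rule: `"standard"` (all Voronoi neighbors),
#'   `"selective"` (only Voronoi neighbors moving strictly faster than the
#'   focal individual), `"antialign"` (pairwise alignment replaced by a
#'   tabulated force field evaluated at the relative velocity with the
#'   nearest neighbor, see [smooth_and_interpolate_field()]),
#'   `"persistent"` (standard interactions interrupted by a persistent
#'   random force, see below), or `"nearest"` (interaction with the nearest
#'   neighbor only, a testing aid).
#' @param weight_norm How inverse-distance weights are normalized:
#'   `"set"` (default) divides by the sum of `1/d` over the interacting set
#'   (a weighted average whose weights always sum to one), `"voronoi"`
#'   divides by the sum over all Voronoi neighbors (so ignoring a neighbor
#'   genuinely reduces total social input), `"none"` uses the raw `1/d`
#'   weighted sum. The readings coincide for the standard variant up to the
#'   local value of `sum(1/d)`; they differ for the selective variant.
#' @param pr_rate,pr_amplitude,pr_duration Persistent-random-force
#'   parameters: activation probability rate r (s^-1), force amplitude A
#'   (cm/s^2) and persistence time (s). Required (no defaults) for the
#'   `"persistent"` variant; while the force is active the individual's
#'   social interactions are switched off.
#' @param field A `force_field` object (from
#'   [smooth_and_interpolate_field()] or [as_force_field()]); required for
#'   the `"antialign"` variant.
#'
#' @return An object of class `school_params`.
#' @seealso [simulate_school()], [read_params()]
#' @export
#' @examples
#' p <- school_params()
#' p$d0
#' school_params(variant = "selective", n_individuals = 20)
school_params <- function(k_rep = 12.5, k_att = 5, d0 = 5.8, mu = 1.5,
                          v0 = 11, tau_v = 1.6, sigma_v = 6.4,
                          sigma_phi = 2.6, dt = 0.02, n_individuals = 39,
                          variant = c("standard", "selective", "antialign",
                                      "persistent", "nearest"),
                          weight_norm = c("set", "voronoi", "none"),
                          pr_rate = NULL, pr_amplitude = NULL,
                          pr_duration = NULL, field = NULL) {
  variant <- match.arg(variant)
  num1 <- function(v, nm, min = 0, strict = FALSE) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop(sprintf("'%s' must be a single number", nm), call. = FALSE)
    if (strict && v <= min)
      stop(sprintf("'%s' must be > %g", nm, min), call. = FALSE)
    if (!strict && v < min)
      stop(sprintf("'%s' must be >= %g", nm, min), call. = FALSE)
    as.numeric(v)
  }
  p <- list(
    k_rep = num1(k_rep, "k_rep"), k_att = num1(k_att, "k_att"),
    d0 = num1(d0, "d0", strict = TRUE), mu = num1(mu, "mu"),
    v0 = num1(v0, "v0"), tau_v = num1(tau_v, "tau_v", strict = TRUE),
    sigma_v = num1(sigma_v, "sigma_v"),
    sigma_phi = num1(sigma_phi, "sigma_phi"),
    dt = num1(dt, "dt", strict = TRUE),
    n_individuals = as.integer(num1(n_individuals, "n_individuals", 1)),
    variant = variant,
    weight_norm = match.arg(weight_norm)
  )
  if (variant == "persistent") {
    if (is.null(pr_rate) || is.null(pr_amplitude) || is.null(pr_duration))
      stop("the 'persistent' variant requires pr_rate, pr_amplitude and pr_duration",
           call. = FALSE)
    p$pr_rate <- num1(pr_rate, "pr_rate")
    p$pr_amplitude <- num1(pr_amplitude, "pr_amplitude")
    p$pr_duration <- num1(pr_duration, "pr_duration")
  }
  if (variant == "antialign") {
    if (is.null(field) || !inherits(field, "force_field"))
      stop("the 'antialign' variant requires a 'force_field' object", call. = FALSE)
    p$field <- field
  }
  structure(p, class = "school_params")
}

variant_code <- function(variant) {
  match(variant, c("standard", "selective", "antialign",
                   "persistent", "nearest")) - 1L
}

# parameter list in the form the C++ integrator expects
params_for_cpp <- function(p) {
  out <- list(k_rep = p$k_rep, k_att = p$k_att, d0 = p$d0, mu = p$mu,
              v0 = p$v0, tau_v = p$tau_v, sigma_v = p$sigma_v,
              sigma_phi = p$sigma_phi, dt = p$dt,
              variant_code = variant_code(p$variant),
              weight_mode = match(p$weight_norm,
                                  c("none", "set", "voronoi")) - 1L)
  if (p$variant == "persistent")
    out[c("pr_rate", "pr_amplitude", "pr_duration")] <-
      p[c("pr_rate", "pr_amplitude", "pr_duration")]
  if (p$variant == "antialign")
    out$field <- unclass(p$field)
  out
}

#' @export
print.school_params <- function(x, ...) {
  cat("<school_params> variant:", x$variant,
      sprintf("(N = %d, dt = %g s)\n", x$n_individuals, x$dt))
  cat(sprintf("  k_rep = %g s^-2, k_att = %g s^-2, d0 = %g cm\n",
              x$k_rep, x$k_att, x$d0))
  cat(sprintf("  mu = %g s^-1, v0 = %g cm/s, tau_v = %g s\n",
              x$mu, x$v0, x$tau_v))
  cat(sprintf("  sigma_v = %g, sigma_phi = %g cm s^-3/2, weight norm: %s\n",
              x$sigma_v, x$sigma_phi, x$weight_norm))
  if (x$variant == "persistent")
    cat(sprintf("  persistent force: r = %g s^-1, A = %g cm/s^2, duration = %g s\n",
                x$pr_rate, x$pr_amplitude, x$pr_duration))
  invisible(x)
}

#' Read and write model configurations
#'
#' Configurations are flat key-value YAML files using the parameter names of
#' [school_params()]; keys absent from the file keep their defaults. The
#' tabulated field of the `"antialign"` variant is not serialized and must
#' be supplied programmatically.
#'
#' @param path File path.
#' @param params A `school_params` object.
#' @return `read_params()` returns a `school_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must contain key-value pairs")
  known <- names(formals(school_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(school_params, cfg)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "school_params"))
  p <- unclass(params)
  p$field <- NULL
  yaml::write_yaml(p, path)
  invisible(path)
}
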