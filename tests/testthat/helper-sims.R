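# Shared simulation ensembles, built once per test run and cached.
# The large runs reproduce the study conditions: N = 39, the reference
# parameters, 30,000 frames kept after a 1,000-frame transient.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .sim_cache))
    assign(name, build(), envir = .sim_cache)
  get(name, envir = .sim_cache)
}

sim_standard_big <- function()
  cached("standard_big", function()
    simulate_school(school_params(), n_frames = 30000, n_transient = 1000,
                    seed = 101))

sim_selective_big <- function()
  cached("selective_big", function()
    simulate_school(school_params(variant = "selective"), n_frames = 30000,
                    n_transient = 1000, seed = 102))

sim_standard_big_tracked <- function()
  cached("standard_big_tracked", function()
    tracked_kinematics(sim_standard_big()))

sim_selective_big_tracked <- function()
  cached("selective_big_tracked", function()
    tracked_kinematics(sim_selective_big()))

sim_standard_small <- function()
  cached("standard_small", function()
    simulate_school(school_params(n_individuals = 12), n_frames = 4000,
                    n_transient = 500, seed = 7))
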