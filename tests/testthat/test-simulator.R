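test_that("free streaming: no forces, no noise leaves velocity unchanged", {
  p <- school_params(n_individuals = 1, sigma_v = 0, sigma_phi = 0,
                     tau_v = Inf)
  tr <- simulate_school(p, n_frames = 50, n_transient = 0,
                        init = list(x = 0, y = 0, vx = 3, vy = 4))
  expect_equal(tr$vx[, 1], rep(3, 50))
  expect_equal(tr$vy[, 1], rep(4, 50))
  expect_equal(tr$x[, 1], 3 * (0:49) * 0.02, tolerance = 1e-12)
  expect_equal(tr$ax[, 1], rep(0, 50))
})

test_that("single noiseless agent relaxes to v0 with time constant tau_v", {
  p <- school_params(n_individuals = 1, sigma_v = 0, sigma_phi = 0)
  tr <- simulate_school(p, n_frames = 1000, n_transient = 0,
                        init = list(x = 0, y = 0, vx = 12, vy = 0))
  sp <- sqrt(tr$vx[, 1]^2 + tr$vy[, 1]^2)
  # first explicit-Euler step: 12 - (12 - 11)/1.6 * dt
  expect_equal(sp[2], 12 - 0.625 * 0.02, tolerance = 1e-12)
  # monotone decay to the preferred speed
  expect_true(all(diff(sp) <= 1e-12))
  expect_equal(sp[1000], 11, tolerance = 1e-4)
  # log-linear fit of the excess speed gives the relaxation rate; the
  # discrete-time rate -log(1 - dt/tau)/dt is within 1% of 1/tau here
  tt <- tr$times[1:150]
  lam <- -coef(lm(log(sp[1:150] - 11) ~ tt))[[2]]
  expect_equal(lam, 1 / 1.6, tolerance = 0.01)
  # inverting the one-step contraction recovers tau exactly
  expect_equal(0.02 / (1 - exp(-lam * 0.02)), 1.6, tolerance = 1e-9)
})

test_that("pairwise alignment-only decay rate is twice the alignment constant", {
  p <- school_params(n_individuals = 2, k_rep = 0, k_att = 0, sigma_v = 0,
                     sigma_phi = 0, tau_v = Inf)
  tr <- simulate_school(p, n_frames = 100, n_transient = 0,
                        init = list(x = c(0, 3), y = c(0, 0),
                                    vx = c(10, 12), vy = c(2, -1)))
  dv <- sqrt((tr$vx[, 1] - tr$vx[, 2])^2 + (tr$vy[, 1] - tr$vy[, 2])^2)
  lam <- -coef(lm(log(dv) ~ tr$times))[[2]]
  # raw discrete log-slope is biased high by -log(1-2*mu*dt)/(2*mu*dt): ~3%
  expect_equal(lam, 2 * 1.5, tolerance = 0.04)
  # integrator-aware inversion is exact
  expect_equal((1 - exp(-lam * 0.02)) / (2 * 0.02), 1.5, tolerance = 1e-9)
})

test_that("attraction-repulsion pair oscillates about the equilibrium distance", {
  p <- school_params(n_individuals = 2, mu = 0, sigma_v = 0, sigma_phi = 0,
                     tau_v = Inf)
  eps <- 1e-6  # near-rest release; exactly zero speed has no heading
  tr <- simulate_school(p, n_frames = 400, n_transient = 0,
                        init = list(x = c(0, 9.8), y = c(0, 0),
                                    vx = c(0, 0), vy = c(eps, eps)))
  # initial acceleration magnitude per agent is k_att * |d - d0|
  expect_equal(abs(tr$ax[1, 1]), 5 * (9.8 - 5.8), tolerance = 1e-9)
  d <- abs(tr$x[, 2] - tr$x[, 1])
  # relative distance oscillates about d0: both sides are visited
  expect_true(min(d) < 5.8, max(d) > 5.8)
  expect_gt(sum(diff(sign(d - 5.8)) != 0), 2)
})

test_that("one integrator step reproduces the R force composition", {
  set.seed(21)
  n <- 9
  init <- list(x = runif(n, 0, 20), y = runif(n, 0, 20),
               vx = rnorm(n, 9, 2), vy = rnorm(n, 4, 2))
  for (variant in c("standard", "selective", "nearest")) {
    for (wn in c("set", "voronoi", "none")) {
      p <- school_params(n_individuals = n, variant = variant,
                         sigma_v = 0, sigma_phi = 0, weight_norm = wn)
      tr <- simulate_school(p, n_frames = 2, n_transient = 0, init = init)
      fb <- force_breakdown(cbind(init$x, init$y), cbind(init$vx, init$vy), p)
      expect_equal(tr$vx[2, ], init$vx + fb$total[, 1] * p$dt,
                   tolerance = 1e-12)
      expect_equal(tr$vy[2, ], init$vy + fb$total[, 2] * p$dt,
                   tolerance = 1e-12)
      # recorded accelerations are the deterministic forces (noise off)
      expect_equal(tr$ax[1, ], fb$total[, 1], tolerance = 1e-12)
    }
  }
})

test_that("selective rule: slower Voronoi neighbors contribute nothing", {
  set.seed(22)
  n <- 8
  pos <- cbind(runif(n, 0, 18), runif(n, 0, 18))
  vel <- cbind(rnorm(n, 8, 3), rnorm(n, 3, 3))
  p <- school_params(n_individuals = n, variant = "selective")
  fb <- force_breakdown(pos, vel, p)
  g <- voronoi_adjacency(pos)
  speeds <- sqrt(rowSums(vel^2))
  fastest <- which.max(speeds)
  # the locally fastest individual has zero social force
  expect_equal(fb$attraction_repulsion[fastest, ], c(0, 0))
  expect_equal(fb$alignment[fastest, ], c(0, 0))
  # an individual with exactly one faster Voronoi neighbor feels exactly
  # the pairwise force to that neighbor (single-neighbor weight 1)
  one_faster <- which(vapply(seq_len(n), function(i)
    sum(speeds[which(g$adjacency[i, ])] > speeds[i]) == 1, logical(1)))
  for (i in one_faster) {
    j <- which(g$adjacency[i, ] & speeds > speeds[i])
    expect_equal(fb$attraction_repulsion[i, ] + fb$alignment[i, ],
                 attraction_repulsion_force(pos[i, ], pos[j, ], p) +
                   alignment_force(vel[i, ], vel[j, ], p))
  }
})

test_that("simulation is reproducible under a fixed seed", {
  p <- school_params(n_individuals = 8)
  a <- simulate_school(p, n_frames = 300, n_transient = 50, seed = 33)
  b <- simulate_school(p, n_frames = 300, n_transient = 50, seed = 33)
  expect_identical(a$x, b$x)
  expect_identical(a$vy, b$vy)
  c <- simulate_school(p, n_frames = 300, n_transient = 50, seed = 34)
  expect_false(identical(a$x, c$x))
})

test_that("standard model orders; without alignment strong heading noise disorders", {
  tr <- sim_standard_small()
  expect_gt(mean(polarization(tr)), 0.8)
  # mu = 0 with large heading noise: polarization near the independent-
  # headings null, mean ~ sqrt(pi)/(2 sqrt(N))
  p0 <- school_params(n_individuals = 12, mu = 0, sigma_phi = 12)
  tr0 <- simulate_school(p0, n_frames = 3000, n_transient = 500, seed = 8)
  null_level <- sqrt(pi) / 2 / sqrt(12)
  expect_lt(mean(polarization(tr0)), 2.5 * null_level)
})

test_that("trajectory container validates shapes and time grid", {
  expect_error(school_traj(c(0, 0.02, 0.05), matrix(0, 3, 2),
                           matrix(0, 3, 2), matrix(1, 3, 2), matrix(1, 3, 2)),
               "uniformly spaced")
  expect_error(simulate_school(school_params(), n_frames = 0), "n_frames")
})
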