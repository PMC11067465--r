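test_that("kernels are normalized for exact low-order polynomial derivatives", {
  for (s in c(1, 2, 3.5)) {
    k0 <- gaussian_kernel(s, 0)
    k1 <- gaussian_kernel(s, 1)
    k2 <- gaussian_kernel(s, 2)
    h <- (length(k0) - 1) / 2
    j <- seq(-h, h)
    expect_equal(sum(k0), 1)
    expect_equal(sum(k1), 0)
    expect_equal(sum(k1 * j), 1)       # exact slope on linear sequences
    expect_equal(sum(k2), 0, tolerance = 1e-12)
    expect_equal(sum(k2 * j), 0, tolerance = 1e-12)
    expect_equal(sum(k2 * j^2), 2)     # exact curvature on quadratics
  }
})

test_that("Gaussian differentiation is exact on linear and quadratic tracks", {
  dt <- 0.02
  tn <- 200
  tt <- (seq_len(tn) - 1) * dt
  # constant velocity: velocity exact, acceleration zero in the interior
  x <- cbind(3 + 7 * tt); y <- cbind(-2 + 4 * tt)
  tr <- smooth_and_differentiate(x, y, dt)
  interior <- 15:(tn - 15)
  expect_equal(tr$vx[interior, 1], rep(7, length(interior)), tolerance = 1e-9)
  expect_equal(tr$vy[interior, 1], rep(4, length(interior)), tolerance = 1e-9)
  expect_equal(tr$ax[interior, 1], rep(0, length(interior)), tolerance = 1e-8)
  expect_equal(tr$x[interior, 1], x[interior, 1], tolerance = 1e-9)
  # quadratic track x = g t^2 / 2: acceleration g in the interior
  g <- 3.7
  x2 <- cbind(0.5 * g * tt^2)
  tr2 <- smooth_and_differentiate(x2, cbind(1 + 0 * tt + 2 * tt), dt)
  expect_equal(tr2$ax[interior, 1], rep(g, length(interior)), tolerance = 1e-7)
  expect_equal(tr2$vx[interior, 1], g * tt[interior], tolerance = 1e-7)
})

test_that("smoothing commutes with time shifts and rigid motions", {
  set.seed(7)
  dt <- 0.02
  tn <- 300
  x <- cbind(cumsum(rnorm(tn, 0.2, 0.05)))
  y <- cbind(cumsum(rnorm(tn, 0.1, 0.05)))
  tr <- smooth_and_differentiate(x, y, dt)
  # shift equivariance: smoothing a shifted copy shifts the output
  sh <- 20
  trs <- smooth_and_differentiate(x[(sh + 1):tn, , drop = FALSE],
                                  y[(sh + 1):tn, , drop = FALSE], dt)
  inter <- 15:(tn - sh - 15)
  expect_equal(trs$vx[inter, 1], tr$vx[inter + sh, 1], tolerance = 1e-10)
  # translation + rotation commute with the linear filter
  th <- 0.8; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xr <- x * R[1, 1] + y * R[1, 2] + 5
  yr <- x * R[2, 1] + y * R[2, 2] - 3
  trr <- smooth_and_differentiate(xr, yr, dt)
  expect_equal(trr$vx[, 1], tr$vx[, 1] * R[1, 1] + tr$vy[, 1] * R[1, 2],
               tolerance = 1e-10)
  expect_equal(trr$x[, 1], tr$x[, 1] * R[1, 1] + tr$y[, 1] * R[1, 2] + 5,
               tolerance = 1e-10)
})

test_that("gap interpolation fills short gaps only", {
  tt <- 0:99
  x <- cbind(2 * tt + 1)  # straight constant-velocity track
  x_gap <- x
  x_gap[50, 1] <- NA
  filled <- interpolate_gaps(x_gap, max_gap = 10)
  expect_equal(filled[50, 1], x[50, 1], tolerance = 1e-9)  # midpoint exact
  expect_equal(interpolate_gaps(x, max_gap = 10), x)       # no gaps: identity
  # longer than max_gap stays masked
  x_long <- x; x_long[40:55, 1] <- NA
  out <- interpolate_gaps(x_long, max_gap = 10)
  expect_true(all(is.na(out[40:55, 1])))
  # boundary gaps stay masked
  x_b <- x; x_b[1:3, 1] <- NA
  expect_true(all(is.na(interpolate_gaps(x_b, max_gap = 10)[1:3, 1])))
})

test_that("perspective projection maps corners exactly and keeps lines straight", {
  corners <- rbind(c(120, 80), c(2850, 110), c(2900, 2700), c(100, 2750))
  side <- 100
  out <- project_to_plane(corners[, 1], corners[, 2], corners, side)
  expect_equal(cbind(out$x, out$y),
               rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)),
               tolerance = 1e-8)
  # already-square corners: a pure scaling
  sq <- rbind(c(0, 0), c(500, 0), c(500, 500), c(0, 500))
  p <- project_to_plane(c(250, 100), c(250, 400), sq, 100)
  expect_equal(p$x, c(50, 20))
  expect_equal(p$y, c(50, 80))
  # projective maps keep collinear points collinear
  tpar <- seq(0, 1, 0.25)
  lx <- 120 + tpar * (2900 - 120); ly <- 80 + tpar * (2700 - 80)
  pl <- project_to_plane(lx, ly, corners, side)
  fit <- lm(pl$y ~ pl$x)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  expect_error(project_to_plane(1, 1, rbind(c(0, 0), c(1, 0), c(0.5, 0.1),
                                            c(0.4, 0.05)), 100), "convex")
})

test_that("trajectory text round trip is lossless to stated precision", {
  tr <- simulate_school(school_params(n_individuals = 5), n_frames = 40,
                        n_transient = 0, seed = 12)
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$dt, tr$dt)
  expect_equal(back$x, tr$x, tolerance = 1e-9)
  expect_equal(back$ay, tr$ay, tolerance = 1e-9)
  # dt is carried in the file header
  expect_match(readLines(path, n = 1), "^# dt")
  unlink(path)
})

test_that("config files round-trip through flat YAML", {
  p <- school_params(variant = "selective", n_individuals = 20, mu = 2)
  path <- tempfile(fileext = ".yml")
  write_params(p, path)
  q <- read_params(path)
  expect_equal(q, p)
  writeLines("nonsense_key: 1", path)
  expect_error(read_params(path), "unknown config keys")
  unlink(path)
})

test_that("tracked kinematics reproduce smooth motion measures", {
  circ <- fixture_circle(n_frames = 400, radius = 12, speed = 9)
  trk <- tracked_kinematics(school_traj(circ$times, circ$x, circ$y,
                                        circ$vx, circ$vy))
  w <- turning_rate(trk)
  expect_equal(mean(w), 9 / 12, tolerance = 0.01)
  expect_equal(nrow(trk$x), 400 - 2 * 10)
})
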