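test_that("focal frame maps the heading to +y and preserves norms", {
  expect_equal(focal_frame(c(0.3, -0.7), c(0, 1)), c(0.3, -0.7))
  expect_equal(focal_frame(c(1, 0), c(1, 0)), c(0, 1))
  set.seed(1)
  for (k in 1:10) {
    v <- runif(2, -5, 5)
    th <- runif(1, 0, 2 * pi)
    h <- c(cos(th), sin(th))
    r <- focal_frame(v, h)
    expect_equal(sqrt(sum(r^2)), sqrt(sum(v^2)))
    # heading itself lands on (0, |h|)
    expect_equal(focal_frame(h, h), c(0, 1))
    # round trip through the inverse rotation
    expect_equal(schoolforces:::focal_to_lab(r, h), v)
  }
  expect_error(focal_frame(c(1, 0), c(2, 0)), "unit")
})

test_that("collect_samples does the bookkeeping and filters partition", {
  tr <- sim_standard_small()
  s <- collect_samples(tr, "velocity")
  expect_equal(nrow(s), nrow(tr$x) * ncol(tr$x))
  sf <- collect_samples(tr, "velocity",
                        filter = sample_filter(neighbor_speed = "faster"))
  ss <- collect_samples(tr, "velocity",
                        filter = sample_filter(neighbor_speed = "slower"))
  expect_equal(nrow(sf) + nrow(ss), nrow(s))  # speed ties have measure zero
  # identical motion: all relative-velocity samples at the origin
  lat <- fixture_lattice(n = 4, n_frames = 20)
  sl <- collect_samples(lat, "velocity")
  expect_true(all(abs(sl$cx) < 1e-12 & abs(sl$cy) < 1e-12))
  # nn-distance filter bounds the covariate
  s2 <- collect_samples(tr, "position",
                        filter = sample_filter(nn_dist = c(3, 6)))
  expect_true(all(s2$d_nn >= 3 & s2$d_nn <= 6))
  # approach + recede partition (zero rate has measure zero)
  sa <- collect_samples(tr, "position",
                        filter = sample_filter(approach = "approaching"))
  sr <- collect_samples(tr, "position",
                        filter = sample_filter(approach = "receding"))
  expect_equal(nrow(sa) + nrow(sr), nrow(s))
})

test_that("bin_map averages vectors per bin and masks sparse bins", {
  # constant field: every unmasked bin holds the constant
  set.seed(3)
  s <- data.frame(cx = runif(4000, -10, 10), cy = runif(4000, -10, 10),
                  ax = 1.5, ay = -2)
  attr(s, "kind") <- "velocity"
  m <- bin_map(s, range = 10, bins = 8, min_count = 10)
  expect_true(all(abs(m$fx[!is.na(m$fx)] - 1.5) < 1e-12))
  expect_true(all(abs(m$fy[!is.na(m$fy)] + 2) < 1e-12))
  expect_equal(sum(m$counts), 4000)
  # min_count = Inf masks everything
  m0 <- bin_map(s, range = 10, bins = 8, min_count = Inf)
  expect_true(all(is.na(m0$fx)))
  # linear restoring field with noise is recovered within standard error
  mu <- 1.5
  n <- 60000
  s2 <- data.frame(cx = runif(n, -10, 10), cy = runif(n, -10, 10))
  s2$ax <- -mu * s2$cx + rnorm(n, 0, 2)
  s2$ay <- -mu * s2$cy + rnorm(n, 0, 2)
  attr(s2, "kind") <- "velocity"
  m2 <- bin_map(s2, range = 10, bins = 5, min_count = 100)
  cx <- matrix(m2$centers, 5, 5); cy <- t(cx)
  se <- 2 / sqrt(m2$counts) # per-bin standard error of the mean
  expect_true(all(abs(m2$fx - (-mu * cx)) < 5 * se + 0.3))
  expect_true(all(abs(m2$fy - (-mu * cy)) < 5 * se + 0.3))
})

test_that("radial projection has the documented sign convention", {
  # vectors pointing at the origin -> negative everywhere
  set.seed(4)
  s <- data.frame(cx = runif(3000, -8, 8), cy = runif(3000, -8, 8))
  s$ax <- -2 * s$cx; s$ay <- -2 * s$cy
  attr(s, "kind") <- "velocity"
  m <- bin_map(s, range = 8, bins = 6, min_count = 5)
  rp <- radial_projection(m)
  expect_true(all(rp[!is.na(rp)] < 0))
  # a = -mu dv projects to -mu |dv| at the bin center (piecewise-linear
  # field averaged over a symmetric bin: small discretization allowance)
  cx <- matrix(m$centers, 6, 6); cy <- t(cx)
  r <- sqrt(cx^2 + cy^2)
  expect_equal(rp[!is.na(rp)], (-2 * r)[!is.na(rp)], tolerance = 0.05)
  # rotating every sample by a right angle (which maps the bin grid onto
  # itself) permutes the bins but leaves the projections unchanged
  th <- pi / 2; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- as.matrix(s[, c("cx", "cy")]) %*% t(R)
  rota <- as.matrix(s[, c("ax", "ay")]) %*% t(R)
  s3 <- data.frame(cx = rot[, 1], cy = rot[, 2], ax = rota[, 1], ay = rota[, 2])
  attr(s3, "kind") <- "velocity"
  rp3 <- radial_projection(bin_map(s3, range = 8, bins = 6, min_count = 5))
  expect_equal(sort(as.vector(rp3)), sort(as.vector(rp)), tolerance = 1e-9)
})

test_that("radial profile zero crossing locates the spring equilibrium", {
  # synthetic spring-force samples: a = -k(r - d0) r_hat exactly
  set.seed(5)
  n <- 30000; d0 <- 5.8
  r <- runif(n, 1, 12); th <- runif(n, 0, 2 * pi)
  s <- data.frame(cx = r * cos(th), cy = r * sin(th))
  k <- ifelse(r <= d0, 12.5, 5)
  s$ax <- -k * (r - d0) * cos(th) + rnorm(n, 0, 1)
  s$ay <- -k * (r - d0) * sin(th) + rnorm(n, 0, 1)
  attr(s, "kind") <- "position"
  # profile computed straight from a data frame of samples is not part of
  # the API; wrap the samples in a minimal trajectory via bin-level check
  proj <- (s$ax * s$cx + s$ay * s$cy) / r
  br <- seq(0, 12, length.out = 25)
  ib <- findInterval(r, br, rightmost.closed = TRUE)
  prof <- data.frame(r = (br[-1] + br[-25]) / 2,
                     radial = tapply(proj, factor(ib, levels = 1:24), mean),
                     count = tabulate(ib, 24))
  expect_equal(profile_zero_crossing(prof), d0, tolerance = 0.2)
  # no crossing on a pure attraction profile
  prof2 <- data.frame(r = 1:10, radial = -(1:10), count = rep(100, 10))
  expect_true(is.na(profile_zero_crossing(prof2)))
})

test_that("field smoothing and interpolation behave on known fields", {
  nb <- 12
  br <- seq(-6, 6, length.out = nb + 1)
  ctr <- (br[-1] + br[-(nb + 1)]) / 2
  cx <- matrix(ctr, nb, nb); cy <- t(cx)
  # constant field: smoothing and interpolation are the identity
  fldc <- as_force_field(matrix(2, nb, nb), matrix(-1, nb, nb), -6, 6, -6, 6)
  ev <- field_eval(fldc, c(-5, 0, 2.3, 40), c(1, 0, -5.9, -40))
  expect_equal(ev$fx, rep(2, 4))
  expect_equal(ev$fy, rep(-1, 4))
  # linear field recovered in the interior after masked-fill + smoothing
  m <- list(kind = "velocity", breaks = br, centers = ctr,
            fx = -1.5 * cx, fy = -1.5 * cy,
            counts = matrix(100, nb, nb), min_count = 1, n_samples = 1)
  class(m) <- "force_map"
  m$fx[3, 4] <- NA; m$fy[3, 4] <- NA  # one masked bin, filled before smoothing
  fld <- smooth_and_interpolate_field(m, sigma_bins = 1)
  interior <- expand.grid(x = ctr[5:8], y = ctr[5:8])
  ev2 <- field_eval(fld, interior$x, interior$y)
  expect_equal(ev2$fx, -1.5 * interior$x, tolerance = 0.15)
  expect_equal(ev2$fy, -1.5 * interior$y, tolerance = 0.15)
  # outside the grid the boundary value is clamped (finite, no NA)
  evb <- field_eval(fld, 1000, 1000)
  expect_true(is.finite(evb$fx) && is.finite(evb$fy))
  # fully masked map cannot be turned into a field
  m$fx[] <- NA; m$fy[] <- NA
  expect_error(smooth_and_interpolate_field(m), "masked")
})

test_that("standard-model force maps recover attraction-repulsion and alignment", {
  tr <- sim_standard_small()
  prof <- radial_force_profile(tr, "position", r_max = 15, bins = 30,
                               min_count = 100)
  x0 <- profile_zero_crossing(prof)
  expect_equal(x0, 5.8, tolerance = 0.7)
  # alignment map: strongly inward overall (on a short run marginal bins
  # can flip by noise; the large-ensemble all-bins check is the
  # acceptance-level property)
  m <- force_map(tr, "velocity", min_count = 200)
  rp <- radial_projection(m)
  expect_gt(mean(rp[!is.na(rp)] < 0), 0.9)
  expect_lt(mean(rp, na.rm = TRUE), -1)
})
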