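test_that("metainference energy reproduces the printed expression", {
  flat <- make_toy_system("double_well_1d", a = 0)
  # no data: sum of force-field energies
  dw <- make_toy_system("double_well_1d")
  st <- replica_state(list(0.5, -2), kT = 2.48)
  expect_equal(metainference_energy(st, numeric(0), dw),
               dw$energy(0.5) + dw$energy(-2))
  # one replica, one datum, f = d: only the normalization terms remain
  st1 <- replica_state(list(1.0), sigma = 0.7, kT = 2.48, n_data = 1)
  expect_equal(metainference_energy(st1, 1.0, flat),
               2.48 * (0.5 * log(2 * pi * 0.7) + 0.5 * log(0.7)))
  # hand example: N=2, X={0,2}, d=1, sigma=1, kT=1 -> E = log(2 pi)
  st2 <- replica_state(list(0, 2), sigma = 1, kT = 1, n_data = 1)
  expect_equal(metainference_energy(st2, 1, flat), log(2 * pi))
  # sigma -> infinity: only normalization terms change the energy
  st_big <- replica_state(list(0.5, -2), sigma = 1e8, kT = 2.48, n_data = 1)
  expect_equal(metainference_energy(st_big, 99, dw) -
                 metainference_energy(st, numeric(0), dw),
               2 * 2.48 * (0.5 * log(2 * pi * 1e8) + 0.5 * log(1e8)),
               tolerance = 1e-6)
  expect_error(replica_state(list(0), sigma = -1), "positive")
})

test_that("sigma sampling drifts with the residuals and matches quadrature", {
  flat <- make_toy_system("double_well_1d", a = 0)
  set.seed(31)
  # huge residuals push sigma toward the upper bound
  st <- replica_state(list(0), sigma = 1, kT = 1, n_data = 1)
  for (i in 1:2500) st <- sample_sigma(st, 50, flat, bounds = c(0.01, 10),
                                       width = 0.5)
  expect_gt(st$sigma[1, 1], 5)
  # zero residuals: long-run mean matches the quadrature posterior of
  # the prior-likelihood balance, density prop. to sigma^-1.5
  st2 <- replica_state(list(0), sigma = 1, kT = 1, n_data = 1)
  vals <- numeric(15000)
  for (i in 1:15000) {
    st2 <- sample_sigma(st2, 0, flat, bounds = c(0.01, 10), width = 0.8)
    vals[i] <- st2$sigma[1, 1]
  }
  s <- seq(0.01, 10, length.out = 100000)
  dens <- s^-1.5
  expect_equal(mean(vals[5000:15000]), sum(s * dens) / sum(dens),
               tolerance = 0.15)
})

test_that("PB Gaussian deposition follows the well-tempered rule", {
  kt <- 2.48
  b <- pbmetad_bias(list(c(-2, 2), c(-2, 2)), sigmas = c(0.2, 0.2),
                    h0 = 0.5, gamma = 16, kT = kt)
  # first deposition on zero bias at symmetric points: height h0/2 each
  b1 <- deposit_gaussian(b, c(0.5, -0.5))
  peak1 <- max(b1$grids[[1]]$V)
  expect_equal(peak1, 0.25, tolerance = 1e-3)
  expect_equal(max(b1$grids[[2]]$V), peak1, tolerance = 1e-3)
  # gamma -> infinity: heights do not decay with accumulated bias
  binf <- pbmetad_bias(list(c(-2, 2)), sigmas = 0.2, h0 = 0.5,
                       gamma = 1e9, kT = kt)
  for (i in 1:50) binf <- deposit_gaussian(binf, 0)
  expect_equal(max(binf$grids[[1]]$V), 50 * 0.5, tolerance = 1e-3)
  # repeated deposition at one point saturates like the WT fixed point:
  # decayed height h0 exp(-V/((gamma-1)kT)) -> increments shrink
  bwt <- pbmetad_bias(list(c(-2, 2)), sigmas = 0.2, h0 = 0.5,
                      gamma = 4, kT = kt)
  peaks <- numeric(200)
  for (i in 1:200) {
    bwt <- deposit_gaussian(bwt, 0)
    peaks[i] <- max(bwt$grids[[1]]$V)
  }
  incr <- diff(peaks)
  expect_true(all(diff(incr) < 1e-8))
  expect_equal(incr[199] / incr[1],
               exp(-(peaks[199] - peaks[1]) / ((4 - 1) * kt)),
               tolerance = 1e-3)
  # out-of-grid CV deposits at the nearest edge with a warning
  expect_warning(deposit_gaussian(b, c(5, 0)), "nearest edge")
})

test_that("bias stays constant outside the stated interval", {
  b <- pbmetad_bias(list(c(-2.5, 2.5)), sigmas = 0.3,
                    intervals = list(c(-1, 1)), h0 = 0.5, gamma = 16)
  for (v in c(0.9, -0.95, 0.2)) b <- deposit_gaussian(b, v)
  g <- b$grids[[1]]
  outside_hi <- g$V[g$s > 1]
  outside_lo <- g$V[g$s < -1]
  expect_equal(max(outside_hi) - min(outside_hi), 0)
  expect_equal(max(outside_lo) - min(outside_lo), 0)
})

test_that("unbiased sampling reproduces the Boltzmann density", {
  sys <- make_toy_system("double_well_1d")
  run <- run_sampler(sys, config = list(steps = 60000L, seed = 3,
                                        step_size = 0.35,
                                        record_stride = 10L))
  q <- boltzmann_quadrature(sys, 2.48)
  cdf <- cumsum(q$density) * (q$grid[2] - q$grid[1])
  ks <- max(abs(stats::ecdf(run$trajectory$x1)(q$grid) - cdf))
  expect_lt(ks, 0.05)
  # determinism under a fixed seed
  run2 <- run_sampler(sys, config = list(steps = 500L, seed = 12))
  run3 <- run_sampler(sys, config = list(steps = 500L, seed = 12))
  expect_identical(run2$trajectory, run3$trajectory)
})

test_that("replica-averaged observable approaches the datum as N grows", {
  # the error parameter includes the standard error of the replica
  # mean, which shrinks as 1/sqrt(N); with that scaling the restrained
  # ensemble average converges onto the datum as replicas are added
  # (at fixed sigma the prior and restraint both scale with N and the
  # mean deviation provably has no N-trend)
  sys <- make_toy_system("double_well_1d")
  d <- 0.8  # offset from the symmetric prior mean of 0
  devs <- vapply(c(1L, 4L, 16L), function(N) {
    s0 <- 0.6 / sqrt(N)
    run <- run_sampler(sys, data = d, config = list(
      steps = 3000L * N, n_replicas = N, seed = 21, step_size = 0.8,
      sigma0 = s0, sigma_bounds = c(s0, s0 * 1.000001),
      record_stride = 10L))
    tr <- run$trajectory
    half <- tr[tr$step > max(tr$step) / 2, ]
    abs(mean(tapply(half$x1, half$step, mean)) - d)
  }, 0)
  expect_lt(devs[3], devs[1])
  expect_lt(devs[3], 0.1)
})

test_that("final-bias weights recover unbiased averages on the double well", {
  sys <- make_toy_system("double_well_1d")
  run <- run_sampler(sys, config = list(
    steps = 60000L, stride = 20L, seed = 7, step_size = 0.35,
    h0 = 0.5, gamma = 16, sigma_cv = 0.2, cv_grids = list(c(-2.5, 2.5)),
    intervals = list(c(-1.5, 1.5)), record_stride = 20L))
  tr <- run$trajectory
  keep <- tr$step > max(tr$step) / 2
  w <- final_weights(run$bias, tr$cv1[keep], 2.48)
  obs <- tr$x1[keep]^2
  est <- sum(w * obs)
  ref <- boltzmann_quadrature(sys, 2.48, function(x) x^2)$mean
  # effective-sample-size-based standard error
  ess <- 1 / sum(w^2)
  se <- sqrt(sum(w * (obs - est)^2) / ess)
  expect_lt(abs(est - ref), 3 * se + 0.02)
  # zero bias: uniform weights
  expect_equal(final_weights(NULL, 1:5), rep(0.2, 5))
})

test_that("convergence drift separates converged from unconverged runs", {
  sys <- make_toy_system("double_well_1d")
  cfg <- list(stride = 20L, seed = 7, step_size = 0.35, h0 = 0.5,
              gamma = 16, sigma_cv = 0.2, cv_grids = list(c(-2.5, 2.5)),
              intervals = list(c(-1.5, 1.5)), record_stride = 50L)
  long <- run_sampler(sys, config = c(cfg, list(steps = 60000L)))
  short <- run_sampler(sys, config = c(cfg, list(steps = 6000L)))
  g <- long$bias$grids[[1]]
  drift_long <- convergence_check(long$checkpoints, g$s, 16,
                                  interval = c(-1.5, 1.5))$max_drift
  drift_short <- convergence_check(short$checkpoints, g$s, 16,
                                   interval = c(-1.5, 1.5))$max_drift
  expect_lt(drift_long, drift_short)
  expect_error(convergence_check(long$checkpoints[1], g$s, 16), "2 checkpoints")
})

test_that("toy-system registry and reference free energies behave", {
  sys <- make_toy_system("double_well_1d")
  s <- seq(-1.5, 1.5, length.out = 101)
  F_ <- analytic_free_energy(sys, s)
  expect_equal(F_, rev(F_))  # symmetric well
  expect_equal(min(F_), 0)
  expect_error(make_toy_system("no_such_system"), "unknown")
  # quadrature partition function vs long-run MC occupancy ratio
  q <- boltzmann_quadrature(sys, 2.48)
  run <- run_sampler(sys, config = list(steps = 50000L, seed = 5,
                                        step_size = 0.35,
                                        record_stride = 5L))
  p_right_mc <- mean(run$trajectory$x1 > 0)
  dx <- q$grid[2] - q$grid[1]
  p_right_q <- sum(q$density[q$grid > 0]) * dx
  expect_equal(p_right_mc, p_right_q, tolerance = 0.05)
  asym <- make_toy_system("asym_double_well")
  Fa <- analytic_free_energy(asym, s)
  expect_gt(max(abs(Fa - rev(Fa))), 1)  # asymmetric by construction
  h2 <- make_toy_system("harmonic_2d")
  expect_equal(h2$dim, 2L)
  expect_equal(h2$energy(c(1, 1)), 10)
})
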