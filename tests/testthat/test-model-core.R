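test_that("enzyme partition follows the conservation law", {
  p <- kinetic_params(1, 1, 1, 100, sigma = 0.1, z_tot = 1, x_tot = 10)
  pools <- partition_enzyme(p, 0)
  expect_equal(pools[["x0"]], 10 / 1.1, tolerance = 1e-12)
  expect_equal(pools[["x1"]], 10 / 1.1 * 0.1, tolerance = 1e-12)

  # sigma = 0 disables the direct pool
  p0 <- kinetic_params(1, 1, 1, 100, sigma = 0, z_tot = 1, x_tot = 5)
  expect_equal(unname(partition_enzyme(p0, 2)), c(3, 0))

  # all enzyme in complex leaves nothing for the other pools
  expect_equal(unname(partition_enzyme(p, 10)), c(0, 0))

  # conservation at arbitrary x2
  for (x2 in c(0, 1.7, 10)) {
    pools <- partition_enzyme(p, x2)
    expect_equal(pools[["x0"]] + pools[["x1"]] + x2, p$x_tot,
                 tolerance = 1e-12)
  }

  expect_error(partition_enzyme(p, -0.5), "-0.5")
  expect_error(partition_enzyme(p, 11), "exceeds total Rabex-5")
})

test_that("time derivatives match the kinetic equations", {
  # no enzyme, no activity
  p_empty <- kinetic_params(2, 3, 4, 5, sigma = 0.5, z_tot = 1, x_tot = 0)
  expect_equal(unname(time_derivatives(p_empty, c(z = 0, x2 = 0))), c(0, 0))

  # production by the directly bound pool only
  p <- kinetic_params(1, 1, 1, 100, sigma = 0.1, z_tot = 1, x_tot = 10)
  d <- time_derivatives(p, c(z = 0, x2 = 0))
  expect_equal(d[["dz_dt"]], 10 * 0.1 / 1.1, tolerance = 1e-12)
  expect_equal(d[["dx2_dt"]], 0)

  # pure decay when no membrane-bound enzyme at all
  p_decay <- kinetic_params(1, 1, 0, 1, sigma = 0, z_tot = 1, x_tot = 5)
  d <- time_derivatives(p_decay, c(z = 0.4, x2 = 0))
  expect_equal(d[["dz_dt"]], -0.4, tolerance = 1e-12)
  expect_equal(d[["dx2_dt"]], 0)
})

test_that("parameter validation rejects malformed inputs", {
  expect_error(kinetic_params(-1, 1, 1, 1, 0, 1), "alpha")
  expect_error(kinetic_params(1, NA, 1, 1, 0, 1), "beta")
  expect_error(kinetic_params(1, 1, 1, 1, Inf, 1), "sigma")
})

test_that("simulation reproduces closed-form decay with no enzyme", {
  beta <- 0.7
  p <- kinetic_params(1, beta, 1, 10, sigma = 0.2, z_tot = 1, x_tot = 0)
  times <- seq(0, 10, by = 0.25)
  tr <- simulate_activation(p, init = c(z = 0.8, x2 = 0), times = times)
  expect_equal(tr$z_M, 0.8 * exp(-beta * times), tolerance = 1e-6)
})

test_that("trajectories conserve enzyme and stay in bounds", {
  set.seed(41)
  for (p in random_params(20)) {
    z0 <- stats::runif(1, 0, p$z_tot)
    tr <- simulate_activation(p, init = c(z = z0, x2 = 0),
                              times = seq(0, 5 / max(p$beta, 0.01),
                                          length.out = 30))
    expect_true(all(tr$z_M >= 0 & tr$z_M <= p$z_tot))
    expect_true(all(tr$x2_M >= 0 & tr$x2_M <= p$x_tot))
    expect_lt(max(abs(tr$x0_M + tr$x1_M + tr$x2_M - p$x_tot)),
              1e-11 + 1e-8 * p$x_tot)
  }
})

test_that("long-time simulation converges to a root of the vector field", {
  p <- kinetic_params(1, 1, 1, 100, sigma = 0.1, z_tot = 1, x_tot = 50)
  ss <- simulate_to_steady(p)
  d <- time_derivatives(p, ss)
  expect_lt(max(abs(d)), 1e-8)
  expect_equal(ss[["z"]], steady_state_general(p), tolerance = 1e-6)
})

test_that("direct-only simulation settles at the derived midpoint level", {
  p <- fig2_params(sigma = 0.1, z_tot = 10)
  p_mid <- kinetic_params(p$alpha, p$beta, 0, p$lam, p$sigma, p$z_tot,
                          x_tot = midpoint_direct(p))
  ss <- simulate_to_steady(p_mid, init = c(z = 0, x2 = 0))
  expect_equal(ss[["z"]], p$z_tot / 2, tolerance = 1e-6)
})

test_that("trajectory CSV round-trips through the declared header", {
  p <- kinetic_params(1, 1, 1, 100, 0.1, z_tot = 1, x_tot = 5)
  tr <- simulate_activation(p, times = seq(0, 2, by = 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("time_s", "z_M", "x2_M", "x0_M", "x1_M"))
  expect_equal(back$z_M, tr$z_M, tolerance = 1e-12)
})

test_that("parameter JSON round-trips with exact keys", {
  p <- kinetic_params(2e4, 0.2, 1e4, 9.375e-2, 0, 2.5e-5, 1e-6)
  path <- withr::local_tempfile(fileext = ".json")
  write_params(p, path)
  keys <- names(jsonlite::fromJSON(path))
  expect_identical(keys, c("alpha", "beta", "gamma", "lam", "sigma",
                           "z_tot", "x_tot"))
  expect_equal(read_params(path), p)
})
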