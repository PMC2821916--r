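test_that("direct-only steady state is the expected hyperbola", {
  expect_equal(steady_state_direct_only(
    kinetic_params(1, 1, 0, 1, 0.1, z_tot = 1, x_tot = 0)), 0)
  # x1 = 0.1 * 11 / 1.1 = 1 gives half-maximal activation
  expect_equal(steady_state_direct_only(
    kinetic_params(1, 1, 0, 1, 0.1, z_tot = 1, x_tot = 11)), 0.5,
    tolerance = 1e-12)
  # saturation limit
  expect_equal(steady_state_direct_only(
    kinetic_params(1, 1, 0, 1, 0.1, z_tot = 1, x_tot = 1e9)), 1,
    tolerance = 1e-6)
  # sigma = 0: no membrane enzyme, returns 0 (documented, not an error)
  expect_equal(steady_state_direct_only(
    kinetic_params(1, 1, 0, 1, 0, z_tot = 1, x_tot = 10)), 0)
})

test_that("direct midpoint formula beta(1+sigma)/(alpha sigma) holds", {
  expect_equal(midpoint_direct(kinetic_params(1, 1, 0, 1, 0.1, 1)), 11,
               tolerance = 1e-12)
  # all-membrane-bound limit
  expect_equal(midpoint_direct(kinetic_params(1, 1, 0, 1, 1e9, 1)), 1,
               tolerance = 1e-6)
  # linear in beta
  m1 <- midpoint_direct(kinetic_params(2, 1, 0, 1, 0.3, 1))
  m2 <- midpoint_direct(kinetic_params(2, 2, 0, 1, 0.3, 1))
  expect_equal(m2, 2 * m1, tolerance = 1e-12)
  # substitution check: the steady state at the midpoint is z_tot/2
  set.seed(11)
  for (p in random_params(10, gamma = 0)) {
    if (p$sigma == 0) p$sigma <- 0.5
    p$x_tot <- midpoint_direct(p)
    expect_equal(steady_state_direct_only(p), p$z_tot / 2,
                 tolerance = 1e-10)
  }
  expect_error(midpoint_direct(kinetic_params(1, 1, 0, 1, 0, 1)),
               "undefined")
})

test_that("indirect-only steady state has the clamped rational form", {
  expect_equal(steady_state_indirect_only(
    kinetic_params(1, 1, 1, 100, 0, z_tot = 200, x_tot = 1)), 50,
    tolerance = 1e-12)
  # exactly at threshold the branch crosses zero
  p <- kinetic_params(1, 1, 1, 100, 0, z_tot = 200)
  p_at_thr <- kinetic_params(1, 1, 1, 100, 0, 200,
                             x_tot = onset_threshold(p))
  expect_equal(steady_state_indirect_only(p_at_thr), 0, tolerance = 1e-12)
  # below threshold: clamped to the stable zero branch, and the ODE from a
  # small positive state decays there
  p_below <- kinetic_params(1, 1, 1, 100, 0, z_tot = 200, x_tot = 0.25)
  expect_equal(steady_state_indirect_only(p_below), 0)
  expect_lt(ode_steady_z(p_below), 1e-6)
})

test_that("onset threshold formula and its inverse-z_tot scaling hold", {
  expect_equal(onset_threshold(kinetic_params(1, 1, 1, 100, 0, 10)), 10,
               tolerance = 1e-12)
  expect_equal(onset_threshold(kinetic_params(1, 1, 1, 100, 0, 200)), 0.5,
               tolerance = 1e-12)
  p1 <- kinetic_params(2, 3, 0.5, 80, 0, 7)
  p2 <- kinetic_params(2, 3, 0.5, 80, 0, 14)
  expect_equal(onset_threshold(p1), 2 * onset_threshold(p2),
               tolerance = 1e-12)
  expect_error(onset_threshold(kinetic_params(1, 1, 1, 100, 0, 0)),
               "z_tot")
})

test_that("general steady state reduces to the pathway-specific forms", {
  set.seed(21)
  for (p in random_params(25, gamma = 0)) {
    expect_equal(steady_state_general(p), steady_state_direct_only(p),
                 tolerance = 1e-10)
  }
  for (p in random_params(25, sigma = 0)) {
    expect_equal(steady_state_general(p), steady_state_indirect_only(p),
                 tolerance = 1e-10)
  }
})

test_that("general steady state matches brute-force and ODE oracles", {
  p <- kinetic_params(1, 1, 1, 100, sigma = 0.1, z_tot = 10, x_tot = 20)
  z_closed <- steady_state_general(p)
  expect_equal(z_closed, brute_force_steady_z(p), tolerance = 1e-7)
  expect_equal(z_closed, ode_steady_z(p), tolerance = 1e-6)

  set.seed(31)
  for (p in random_params(30)) {
    expect_equal(steady_state_general(p), brute_force_steady_z(p),
                 tolerance = 1e-6)
  }
})

test_that("response curves are monotone, bounded and mode-consistent", {
  p <- fig2_params()
  grid <- 10^seq(-3, 5, length.out = 200)
  for (mode in c("direct_only", "indirect_only", "combined")) {
    rc <- response_curve(p, grid, mode)
    expect_true(all(diff(rc$z_M) >= -1e-12))
    expect_true(all(rc$z_M >= 0 & rc$z_M <= p$z_tot))
  }
  # indirect-only is exactly zero below the onset threshold
  rc_ind <- response_curve(p, grid, "indirect_only")
  thr <- onset_threshold(p)
  expect_true(all(rc_ind$z_M[rc_ind$x_tot_M < thr] == 0))
  expect_true(all(rc_ind$z_M[rc_ind$x_tot_M > thr * 1.01] > 0))
  # empty grid gives an empty curve
  expect_equal(nrow(response_curve(p, numeric(0), "combined")), 0L)
  expect_error(response_curve(p, c(2, 1), "combined"), "increasing")
})

test_that("Hill coefficient: 1 for the hyperbola, up to 2 for feedback", {
  grid <- 10^seq(-4, 8, length.out = 600)
  # direct pathway: Hill coefficient 1 regardless of constants
  set.seed(51)
  for (p in random_params(5, gamma = 0)) {
    if (p$sigma == 0) p$sigma <- 0.2
    rc <- response_curve(p, grid * midpoint_direct(p) / 10, "direct_only")
    expect_equal(hill_coefficient(rc), 1, tolerance = 0.01)
  }
  # indirect pathway: approaches 2 when lam/gamma >> z_tot ...
  p_hi <- kinetic_params(1, 1, 1, 1e4, 0, z_tot = 1)
  rc_hi <- response_curve(p_hi, 10^seq(2, 7, length.out = 500),
                          "indirect_only")
  expect_equal(hill_coefficient(rc_hi), 2, tolerance = 0.02)
  # ... and falls back to 1 when lam/gamma << z_tot
  p_lo <- kinetic_params(1, 1, 1, 1e-4, 0, z_tot = 1)
  rc_lo <- response_curve(p_lo, 10^seq(-6, 2, length.out = 500),
                          "indirect_only")
  expect_equal(hill_coefficient(rc_lo), 1, tolerance = 0.02)
  # numeric estimate agrees with the analytic 10-90% expression
  for (lg in 10^seq(-2, 2, by = 1)) {
    p <- kinetic_params(1, 1, 1, lg, 0, z_tot = 1)
    rc <- response_curve(p, 10^seq(-5, 7, length.out = 800),
                         "indirect_only")
    expect_equal(hill_coefficient(rc), analytic_hill_indirect(lg, 1),
                 tolerance = 0.01)
  }
  # a grid that does not span 10-90% is refused with advice
  rc_narrow <- response_curve(p_hi, 10^seq(2, 3, length.out = 50),
                              "indirect_only")
  expect_error(hill_coefficient(rc_narrow), "widen")
})

test_that("normalized-slope sensitivity tracks the Hill estimate", {
  p <- kinetic_params(1, 1, 1, 1e4, 0, z_tot = 1)
  rc <- response_curve(p, 10^seq(2, 7, length.out = 2000), "indirect_only")
  expect_equal(normalized_slope(rc), hill_coefficient(rc), tolerance = 0.1)
})

test_that("response-curve CSV/JSON sidecar records the derived quantities", {
  p <- fig2_params(sigma = 0, z_tot = 10)
  rc <- response_curve(p, 10^seq(-2, 4, length.out = 300), "indirect_only")
  path <- withr::local_tempfile(fileext = ".csv")
  write_response_curve(rc, path)
  side <- jsonlite::fromJSON(sub("\\.csv$", ".json", path))
  expect_equal(side$threshold_M, 10, tolerance = 1e-10)
  expect_equal(side$hill_coefficient, analytic_hill_indirect(100, 10),
               tolerance = 0.01)
  expect_identical(names(utils::read.csv(path)), c("x_tot_M", "z_M"))
})
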