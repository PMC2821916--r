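test_that("induction profile has the stated shape and landmarks", {
  prof <- induction_profile(3, 32, 2, 9)
  expect_equal(induction_timecourse(prof, 0), 3)
  expect_equal(induction_timecourse(prof, 2), (3 + 32) / 2,
               tolerance = 1e-12)
  # BHK-like: an order of magnitude above baseline by the plateau time
  expect_gte(induction_timecourse(prof, 7), 0.9 * 32)
  # inverse mapping
  expect_equal(induction_timecourse(prof, induction_crossing_time(prof, 20)),
               20, tolerance = 1e-9)
  expect_true(is.na(induction_crossing_time(prof, 40)))
  expect_error(induction_profile(10, 5, 1, 4), "baseline")
  expect_error(induction_profile(1, 10, 5, 6), "95%")
})

test_that("preset scenarios encode the intended study conditions", {
  nf <- rab5_scenario("nf73")
  # enzyme crosses the onset threshold (12 fg/cell) at 6 h
  thr_fg <- molar_to_fg_per_cell(onset_threshold(nf$params), 40, 80)
  expect_equal(thr_fg, 12, tolerance = 1e-9)
  expect_equal(induction_crossing_time(nf$profile, 12), 6,
               tolerance = 0.005)
  # BHK with GFP-Rab5 doubles total Rab5 relative to endogenous
  expect_equal(rab5_scenario("bhk_gfp_rab5")$params$z_tot,
               2 * rab5_scenario("bhk_endogenous")$params$z_tot)
  # BHK endogenous: the 32 fg/cell plateau stays below threshold
  be <- rab5_scenario("bhk_endogenous")
  expect_gt(molar_to_fg_per_cell(onset_threshold(be$params), 40, 80),
            be$profile$plateau)
})

test_that("identical seeds give identical datasets", {
  sc <- rab5_scenario("nf73")
  expect_identical(generate_dataset(sc, 7), generate_dataset(sc, 7))
  d1 <- generate_dataset(sc, 7)
  d2 <- generate_dataset(sc, 8)
  expect_false(identical(d1$activity, d2$activity))
})

test_that("below-threshold induction leaves the activity flat vs control", {
  ds <- generate_dataset(rab5_scenario("bhk_endogenous"), seed = 5)
  expect_true(all(ds$z_true_M == 0))
  pvals <- vapply(seq_along(ds$times_h), function(i) {
    stats::t.test(log(ds$activity[i, ]), log(ds$control[i, ]))$p.value
  }, numeric(1))
  expect_true(all(pvals > 0.01))
})

test_that("above-threshold induction rises where the threshold is crossed", {
  sc <- rab5_scenario("nf73")
  ds <- generate_dataset(sc, seed = 6)
  thr_fg <- molar_to_fg_per_cell(onset_threshold(sc$params), 40, 80)
  t_cross <- induction_crossing_time(sc$profile, thr_fg)
  expect_true(all(ds$z_true_M[ds$times_h <= t_cross - 0.01] == 0))
  expect_true(all(ds$z_true_M[ds$times_h >= t_cross + 1] > 0))
})

test_that("observation maps increase monotonically with activation", {
  sc <- rab5_scenario("nf73")
  ds <- generate_dataset(sc, seed = 9)
  ord <- order(ds$z_true_M)
  # expected (noise-free) signals are strictly increasing in z
  sc0 <- sc; sc0$noise$cv <- 0
  ds0 <- generate_dataset(sc0, seed = 1)
  expect_true(all(diff(ds0$activity[ord, 1]) >= 0))
  expect_true(all(diff(rowMeans(ds0$endosomes)[ord]) >= 0))
  # and the noisy endosome protocol keeps the trend between extremes
  expect_gt(mean(ds$endosomes[which.max(ds$z_true_M), ]),
            mean(ds$endosomes[which.min(ds$z_true_M), ]))
})

test_that("quasi-steady-state generation agrees with the full ODE", {
  # direct+indirect BHK scenario: induction over hours vs relaxation in
  # seconds, so the quasi-steady state should track within 5%
  sc <- rab5_scenario("bhk_gfp_rab5")
  q <- generate_dataset(sc, 1, mode = "qss")$z_true_M
  o <- generate_dataset(sc, 1, mode = "ode")$z_true_M
  expect_lt(max(abs(o - q) / pmax(q, 1e-3 * sc$params$z_tot)), 0.05)
  # indirect-only scenario: agreement once activation is appreciable
  scn <- rab5_scenario("nf73")
  qn <- generate_dataset(scn, 1, mode = "qss")$z_true_M
  on <- generate_dataset(scn, 1, mode = "ode")$z_true_M
  idx <- qn > 0.01 * scn$params$z_tot
  expect_true(any(idx))
  expect_lt(max(abs(on[idx] - qn[idx]) / qn[idx]), 0.05)
})

test_that("dataset bundle round-trips through CSV + manifest", {
  sc <- rab5_scenario("nf73")
  ds <- generate_dataset(sc, seed = 3)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_setequal(list.files(dir),
                  c("timecourse.csv", "endosomes.csv", "manifest.json"))
  back <- read_dataset(dir)
  expect_equal(back$activity, ds$activity, tolerance = 1e-12)
  expect_equal(back$enzyme_fg, ds$enzyme_fg, tolerance = 1e-12)
  expect_equal(back$endosomes, ds$endosomes, tolerance = 1e-12)
  expect_equal(back$scenario$params, sc$params)
  expect_equal(back$seed, ds$seed)
})
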