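test_that("interval release implements the literal mass-fraction formula", {
  # single interval: 0.0546 mg/g x 5 g / (0.078 x 10 mg)
  rs <- release_series(1, 0.0546, 2, 2, vessel_mass_g = 5,
                       omega_lys = 0.078, sample_mass_mg = 10)
  res <- interval_release(rs, "as_printed")
  expect_equal(res$interval_fractions, 0.35, tolerance = 1e-12)
  # all-zero concentrations give all-zero fractions
  rs0 <- release_series(c(1, 2, 4), rep(0, 3), rep(2, 3), rep(2, 3),
                        5, 0.078, 10)
  expect_equal(interval_release(rs0)$interval_fractions, rep(0, 3))
})

test_that("the two bookkeeping modes agree when nothing is withdrawn and release is stepwise", {
  # all release happens before the first sampling; later samples see only
  # the undisturbed residual, so the corrected increments vanish
  rs <- release_series(c(1, 2), c(0.05, 0.05), c(0, 0), c(0, 0), 5, 0.078, 10)
  printed <- interval_release(rs, "as_printed")
  corrected <- interval_release(rs, "carryover_corrected")
  expect_equal(printed$interval_fractions[1], corrected$interval_fractions[1])
  expect_equal(corrected$interval_fractions[2], 0)
  # single interval: identical by construction
  rs1 <- release_series(1, 0.0546, 2, 2, 5, 0.078, 10)
  expect_equal(interval_release(rs1, "as_printed")$interval_fractions,
               interval_release(rs1, "carryover_corrected")$interval_fractions)
})

test_that("carryover-corrected cumulative release converges to the generator plateau", {
  rs <- gen_release_series(plateau_frac = 0.703, rate_h = 0.25)
  res <- interval_release(rs, "carryover_corrected")
  final <- utils::tail(res$cumulative_fractions, 1)
  expect_equal(final, 0.703, tolerance = 0.001)
  # cumulative is nondecreasing and matches the running sum exactly
  expect_true(all(diff(res$cumulative_fractions) >= -1e-15))
  expect_equal(res$cumulative_fractions,
               cumulative_release(res$interval_fractions))
})

test_that("cumulative release is the exact running sum", {
  expect_equal(cumulative_release(c(0.1, 0.2, 0.05)), c(0.1, 0.3, 0.35))
  expect_equal(cumulative_release(rep(0, 4)), rep(0, 4))
  # permuting intervals changes the path, not the total
  f <- c(0.05, 0.2, 0.1)
  expect_equal(utils::tail(cumulative_release(f), 1),
               utils::tail(cumulative_release(rev(f)), 1))
})

test_that("zero release rate and instantaneous release behave as limits", {
  rs0 <- gen_release_series(0.7, 0)
  expect_true(all(rs0$schedule$conc_mg_g == 0))
  rs_inf <- gen_release_series(1.0, 1e6)
  res <- interval_release(rs_inf, "carryover_corrected")
  expect_equal(res$interval_fractions[1], 1, tolerance = 1e-6)
})

test_that("silica percent dissolved scales linearly against theoretical Si", {
  # dose 30 mg/L of SiO2 -> 14.02 mg/L theoretical Si
  expect_equal(si_percent_dissolved(30 * 28.08 / 60.08, 30), 100)
  expect_equal(si_percent_dissolved(0, 30), 0)
  expect_equal(si_percent_dissolved(7, 30), 2 * si_percent_dissolved(3.5, 30))
  expect_error(si_percent_dissolved(5, 0), "dose")
  # the printed-molar-mass override is available
  expect_equal(si_percent_dissolved(30 * 28.08 / 80.08, 30,
                                    si_mass_fraction = 28.08 / 80.08), 100)
})

test_that("dissolution fixture calibrated to ~93% at 24 h recovers T50 near 6.2 h", {
  ds <- gen_dissolution_series(plateau_pct = 100, rate_h = 0.111)
  pct <- si_percent_dissolved(ds$si_mg_L, 30)
  p24 <- pct[ds$time_h == 24]
  expect_equal(p24, 93, tolerance = 0.01)
  t50 <- t50_interpolate(ds$time_h, pct)
  expect_gt(t50, 4); expect_lt(t50, 8)
})

test_that("T50 interpolation is exact on linear data and unit-consistent", {
  expect_equal(t50_interpolate(c(0, 8), c(0, 100)), 4.0)
  t <- c(1, 2, 4, 6, 8)
  expect_equal(t50_interpolate(t, 8.065 * t), 50 / 8.065, tolerance = 1e-12)
  # rescaling time to minutes and window accordingly rescales T50
  expect_equal(t50_interpolate(t * 60, 8.065 * t, window = c(0, 480)),
               60 * 50 / 8.065, tolerance = 1e-9)
  expect_error(t50_interpolate(t, rep(10, 5)), "no dissolution trend")
  expect_error(t50_interpolate(c(1), c(10)), ">= 2")
})

test_that("activity ratio is the plain percentage of the reference", {
  expect_equal(activity_ratio(5, 5), 100)
  expect_equal(activity_ratio(0.92 * 3, 3), 92)
  expect_equal(activity_ratio(0.70 * 3, 3), 70)
  expect_error(activity_ratio(1, 0), "reference")
})

test_that("viability normalization is linear between blank and untreated", {
  expect_equal(normalize_viability(0.8, 0.8, 0.1), 100)
  expect_equal(normalize_viability(0.1, 0.8, 0.1), 0)
  expect_equal(normalize_viability(0.45, 0.8, 0.1), 50)
  expect_error(normalize_viability(0.5, 0.1, 0.2), "exceed")
})

test_that("4PL fit recovers noiseless parameters exactly", {
  dr <- gen_dose_response(upper = 100, lower = 0, inflection = 0.5, hill = 2)
  fit <- fit_4pl(dr$conc, dr$response)
  expect_equal(fit$upper, 100, tolerance = 1e-6)
  expect_equal(fit$lower, 0, tolerance = 1e-5)
  expect_equal(fit$inflection, 0.5, tolerance = 1e-6)
  expect_equal(fit$hill, 2, tolerance = 1e-5)
  expect_false(fit$ic50_beyond_range)
})

test_that("noisy 4PL recovery lies within 2 SE of the truth", {
  dr <- gen_dose_response(100, 0, 0.5, 2, noise_sd = 0.05, seed = 3)
  fit <- fit_4pl(dr$conc, dr$response)
  expect_lt(abs(fit$inflection - 0.5), 2 * fit$se[["cc"]])
})

test_that("flat viability across the tested range flags the IC50 as beyond range", {
  dr <- gen_dose_response(upper = 100, lower = 100, inflection = 0.5, hill = 2,
                          conc = 1 / 2^(7:0))
  fit <- fit_4pl(dr$conc, dr$response)
  expect_true(fit$ic50_beyond_range)
  expect_error(fit_4pl(c(0.1, 0.2, 0.4), c(100, 90, 50)), ">= 5")
})

test_that("release CSV reader round-trips a generated schedule", {
  rs <- gen_release_series(0.7, 0.25)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rs$schedule, path, row.names = FALSE)
  back <- read_release_series(path, vessel_mass_g = 5, omega_lys = 0.078,
                              sample_mass_mg = 10)
  expect_equal(back$schedule$conc_mg_g, rs$schedule$conc_mg_g,
               tolerance = 1e-10)
})
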