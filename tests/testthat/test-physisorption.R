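test_that("BET regression recovers the closed-form forward model exactly", {
  iso <- gen_bet_isotherm(v_m = 71.68, C = 100)
  res <- bet_surface_area(iso, fit_range = c(0.05, 0.30))
  # 71.68 cm3 STP/g x 4.3525 m2 g-1 per cm3 STP g-1
  expect_equal(res$surface_area_m2_g, 71.68 * 4.3525, tolerance = 1e-8)
  expect_equal(res$monolayer_capacity_cm3_g, 71.68, tolerance = 1e-6)
  expect_equal(res$bet_constant_C, 100, tolerance = 1e-6)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
})

test_that("BET round-trip holds across monolayer capacities and C values", {
  for (vm in c(10, 71.68, 300)) {
    for (C in c(30, 100, 400)) {
      iso <- gen_bet_isotherm(vm, C)
      res <- bet_surface_area(iso)
      expect_equal(res$monolayer_capacity_cm3_g, vm, tolerance = 1e-6)
      expect_equal(res$bet_constant_C, C, tolerance = 1e-6)
    }
  }
})

test_that("BET surface area is linear in the adsorbed quantity", {
  iso <- gen_bet_isotherm(50, 80)
  iso2 <- sorption_isotherm(iso$p_rel, 2 * iso$q_cm3stp_g, iso$branch)
  expect_equal(bet_surface_area(iso2)$surface_area_m2_g,
               2 * bet_surface_area(iso)$surface_area_m2_g, tolerance = 1e-10)
})

test_that("degenerate isotherms are rejected by the BET fit", {
  flat <- sorption_isotherm(seq(0.05, 0.3, by = 0.05),
                            rep(0, 6), rep("ads", 6))
  expect_error(bet_surface_area(flat), "insufficient")
  few <- sorption_isotherm(c(0.1, 0.2), c(10, 12), rep("ads", 2))
  expect_error(bet_surface_area(few), "insufficient")
})

test_that("total pore volume applies the gas-to-liquid conversion at the plateau", {
  iso <- sorption_isotherm(c(0.1, 0.5, 0.99), c(100, 300, 452.5), rep("ads", 3))
  expect_equal(total_pore_volume(iso), 452.5 * 0.0015468, tolerance = 1e-12)
  trunc <- sorption_isotherm(c(0.1, 0.5, 0.95), c(100, 300, 450), rep("ads", 3))
  expect_error(total_pore_volume(trunc), "does not reach")
  zero <- sorption_isotherm(c(0.1, 0.99), c(0, 0), rep("ads", 2))
  expect_equal(total_pore_volume(zero), 0)
})

test_that("BJH round-trips a forward-generated isotherm", {
  iso <- gen_isotherm(median_A = 80, gsd_g = 1.25, total_volume_cm3_g = 0.70)
  psd <- bjh_distribution(iso, branch = "des")
  expect_equal(psd_total_volume(psd), 0.70, tolerance = 0.05)
  expect_equal(psd_mode(psd), 80, tolerance = 0.10)
  # single-point total volume includes the film term, so it bounds BJH
  expect_gte(total_pore_volume(iso) * 1.0001, psd_total_volume(psd))
})

test_that("nonporous film-only isotherm yields negligible BJH volume", {
  porous <- gen_isotherm(80, 1.25, 0.70)
  film_only <- gen_isotherm(80, 1.25, 0, external_area_m2_g = 300)
  v_ref <- psd_total_volume(bjh_distribution(porous))
  v_film <- psd_total_volume(bjh_distribution(film_only))
  expect_lt(v_film, 0.02 * v_ref)
})

test_that("average pore diameter is the volume-weighted mean or 4V/A", {
  single <- pore_size_distribution(80, 0.5)
  expect_equal(as.numeric(average_pore_diameter(single, "volume_weighted")), 80)
  expect_equal(as.numeric(average_pore_diameter(single, "four_v_over_a")), 80)
  two <- pore_size_distribution(c(60, 100), c(0.25, 0.75))
  expect_equal(as.numeric(average_pore_diameter(two)), 90)
  sym <- pore_size_distribution(c(60, 80, 100), c(0.2, 0.5, 0.2))
  expect_equal(as.numeric(average_pore_diameter(sym)), 80)
  empty <- pore_size_distribution(c(60, 80), c(0, 0))
  expect_error(average_pore_diameter(empty), "empty distribution")
})

test_that("pore-metric reductions are the standard relative differences", {
  ref <- pore_metrics(312, 0.70, 80.5)
  lys <- pore_metrics(108, 0.25, 73.5)
  washed <- pore_metrics(171, 0.40, 78.5)
  d1 <- pore_metrics_delta(ref, lys)
  expect_equal(d1$surface_area_reduction_pct, 100 * (312 - 108) / 312)
  d2 <- pore_metrics_delta(ref, washed)
  expect_equal(d2$surface_area_reduction_pct, 100 * (312 - 171) / 312)
  expect_equal(d2$pore_volume_reduction_pct, 100 * (0.70 - 0.40) / 0.70)
  same <- pore_metrics_delta(ref, ref)
  expect_equal(same$surface_area_reduction_pct, 0)
  expect_false(same$increase_flagged)
  # an increase is allowed but flagged
  up <- pore_metrics_delta(ref, pore_metrics(400, 0.8, 85))
  expect_true(up$increase_flagged)
})

test_that("isotherm validation enforces branch monotonicity and hysteresis direction", {
  expect_error(sorption_isotherm(c(0.2, 0.1), c(10, 20), c("ads", "ads")),
               "strictly increasing")
  expect_error(sorption_isotherm(c(0.1, 0.2), c(10, 20), c("des", "des")),
               "strictly decreasing")
  expect_error(sorption_isotherm(c(0.5, 1.2), c(10, 20), c("ads", "ads")),
               "strictly in")
  # desorption below adsorption violates hysteresis direction
  expect_error(
    sorption_isotherm(c(0.2, 0.5, 0.8, 0.8, 0.5, 0.2),
                      c(10, 20, 30, 28, 15, 8),
                      rep(c("ads", "des"), each = 3)),
    "hysteresis|falls below")
})

test_that("isotherm CSV reader round-trips", {
  iso <- gen_isotherm(80, 1.25, 0.70, n_pressure = 20)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(iso)[c("branch", "p_rel", "q_cm3stp_g")],
                   path, row.names = FALSE)
  back <- read_isotherm(path)
  expect_equal(back$q_cm3stp_g, iso$q_cm3stp_g, tolerance = 1e-12)
})
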