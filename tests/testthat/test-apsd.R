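test_that("stage cut-offs scale with flow by the calibration power law", {
  cuts64 <- suppressWarnings(scale_cutoffs(64))
  expect_equal(cuts64[["stage3"]], 2.82 * (60 / 64)^0.5, tolerance = 1e-12)
  expect_equal(scale_cutoffs(60), stats::setNames(ngi_stage_table$cutoff_60lpm_um,
                                                  ngi_stage_table$stage))
  tab0 <- ngi_stage_table
  tab0$flow_exponent <- rep(1e-9, 7)
  expect_equal(unname(scale_cutoffs(45, tab0)), tab0$cutoff_60lpm_um,
               tolerance = 1e-6)
  expect_error(scale_cutoffs(0), "positive")
  expect_warning(scale_cutoffs(20), "calibrated")
})

test_that("cumulative undersize counts mass below each cut-off", {
  m <- c(stage3 = 100, stage4 = 100)
  run <- impactor_run(m, flow_lpm = 60)
  u <- cumulative_undersize(run)
  cuts <- scale_cutoffs(60)
  # at the stage3 cut-off, only the stage4 mass is finer: 50%
  expect_equal(u$undersize_pct[u$diameter_um == cuts[["stage3"]]], 50)
  # at the largest cut-off, everything except stage-1 mass is finer
  expect_equal(u$undersize_pct[u$diameter_um == cuts[["stage1"]]], 100)
  # all mass on the finest location
  run2 <- impactor_run(c(moc = 50, stage7 = 1e-9), flow_lpm = 60)
  u2 <- cumulative_undersize(run2)
  expect_true(all(u2$undersize_pct > 99.99))
  expect_error(cumulative_undersize(impactor_run(c(device = 10), 60)),
               "zero impactor-sized")
})

test_that("MMAD is the diameter at 50% undersize", {
  # construct a table crossing 50% exactly at 3.0 um
  u <- data.frame(diameter_um = c(1.5, 3.0, 6.0),
                  undersize_pct = c(20, 50, 80))
  expect_equal(mmad_gsd(u)$mmad_um, 3.0, tolerance = 1e-12)
})

test_that("probit interpolation recovers analytic log-normal tables to < 2%", {
  for (mmad in c(1, 2, 3.5, 5)) {
    for (gsd in c(1.3, 1.8, 2.5)) {
      run <- gen_impactor_run(mmad, gsd, flow_lpm = 64)
      res <- mmad_gsd(cumulative_undersize(run))
      expect_equal(res$mmad_um, mmad, tolerance = 0.02)
      expect_equal(res$gsd, gsd, tolerance = 0.02)
    }
  }
})

test_that("a perfectly log-normal table is collinear in probit vs ln diameter", {
  run <- gen_impactor_run(2.0, 1.8, flow_lpm = 64)
  res <- mmad_gsd(cumulative_undersize(run), method = "regression")
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
})

test_that("full reduction reproduces generator truth and conserves dose", {
  run <- gen_impactor_run(2.0, 1.8, total_dose_ug = 10000,
                          device_retention_frac = 0.05,
                          extrathoracic_frac = 0.10, flow_lpm = 64)
  res <- apsd_reduce(run)
  expect_equal(res$mmad_um, 2.0, tolerance = 0.02)
  expect_equal(res$gsd, 1.8, tolerance = 0.02)
  # conservation: emitted + device = total recovered, exactly
  expect_equal(res$emitted_dose_ug + run$masses_ug[["device"]],
               sum(run$masses_ug))
  expect_equal(res$device_retention_pct + res$delivered_dose_pct, 100)
  # FPF against the analytic log-normal undersize at 5 um
  sized <- sum(run$masses_ug[c(paste0("stage", 1:7), "moc")])
  fpf_true <- 100 * stats::pnorm(log(5 / 2.0) / log(1.8)) *
    sized / res$emitted_dose_ug
  expect_equal(res$fpf_pct, fpf_true, tolerance = 0.02)
})

test_that("FPF is monotone in the cut diameter and scale invariant", {
  run <- gen_impactor_run(2.0, 1.8, flow_lpm = 64)
  cuts <- c(1, 2, 5, 8)
  fpf <- vapply(cuts, function(d) apsd_reduce(run, fpf_diameter_um = d)$fpf_pct,
                numeric(1))
  expect_true(all(diff(fpf) > 0))
  run2 <- run
  run2$masses_ug <- run$masses_ug * 7
  res1 <- apsd_reduce(run)
  res2 <- apsd_reduce(run2)
  expect_equal(res2$fpf_pct, res1$fpf_pct, tolerance = 1e-12)
  expect_equal(res2$mmad_um, res1$mmad_um, tolerance = 1e-12)
  expect_equal(res2$gsd, res1$gsd, tolerance = 1e-12)
})

test_that("all mass in the device is an error; doubling dose doubles masses", {
  expect_error(apsd_reduce(impactor_run(c(device = 100, stage3 = 0), 60)),
               "emitted dose is zero|zero impactor")
  r1 <- gen_impactor_run(2, 1.8, total_dose_ug = 1000, flow_lpm = 64)
  r2 <- gen_impactor_run(2, 1.8, total_dose_ug = 2000, flow_lpm = 64)
  expect_equal(r2$masses_ug, 2 * r1$masses_ug, tolerance = 1e-12)
  # no retention and no extrathoracic loss -> emitted equals loaded
  r3 <- gen_impactor_run(2, 1.8, total_dose_ug = 1000,
                         device_retention_frac = 0, extrathoracic_frac = 0,
                         flow_lpm = 64)
  expect_equal(apsd_reduce(r3)$emitted_dose_ug, 1000)
})

test_that("NGI CSV reader and mass-balance flag work", {
  run <- gen_impactor_run(2, 1.8, total_dose_ug = 1000, flow_lpm = 64)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(location = names(run$masses_ug),
                              mass_ug = unname(run$masses_ug)),
                   path, row.names = FALSE)
  back <- read_impactor_run(path, flow_lpm = 64, total_loaded_dose_ug = 1000)
  expect_true(back$balance_ok)
  expect_equal(back$masses_ug, run$masses_ug)
  bad <- read_impactor_run(path, flow_lpm = 64, total_loaded_dose_ug = 5000)
  expect_false(bad$balance_ok)
  expect_error(apsd_reduce(bad), "mass balance")
  expect_s3_class(apsd_reduce(bad, override_balance = TRUE), "apsd_result")
})
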