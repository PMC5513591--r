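test_that("noiseless bundles report the ground truth medians", {
  cfg <- study_config(n_dams = c(NP = 3, LP = 3), measurement_cv = 0,
                      rate_cv = 0, dam_mass_cv = 0, pup_mass_cv = 0,
                      wsw_noise_sd = 0, baseline_ppm = 0, seed = 2)
  s <- generate_study(cfg)
  rep1 <- run_experiment1(s)
  mf <- rep1$group_summary[rep1$group_summary$endpoint == "milk_flow_gph", ]
  for (g in c("NP", "LP"))
    expect_equal(mf$median[mf$group == g],
                 median(s$truth$milk_flow_gph[s$truth$group == g]),
                 tolerance = 1e-6)
  rep2 <- run_experiment2(s$wsw)
  expect_equal(rep2$table$mean_gph,
               rep(tapply(s$truth$milk_flow_gph, s$truth$group, mean)[
                 rep2$table$group], 1),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("the low-protein group shows lower milk flow across seeds", {
  lower <- vapply(1:8, function(seed) {
    s <- generate_study(study_config(seed = seed))
    r <- run_experiment1(s)
    mf <- r$group_summary[r$group_summary$endpoint == "milk_flow_gph", ]
    mf$median[mf$group == "LP"] < mf$median[mf$group == "NP"]
  }, logical(1))
  expect_gte(mean(lower), 7 / 8)
})

test_that("a single-group study skips the comparison with a notice", {
  s <- generate_study(study_config(n_dams = c(NP = 3), seed = 4))
  expect_message(r <- run_experiment1(s), "skipped")
  expect_null(r$tests)
  expect_identical(nrow(r$per_dam), 3L)
})

test_that("weight-suckle-weight report is per group and day, with nd cells", {
  s <- generate_study(study_config(seed = 6))
  wsw <- s$wsw[!(s$wsw$group == "NP" & s$wsw$pnd == 11), ]  # NP day 11 missing
  r <- run_experiment2(wsw)
  cell <- r$table[r$table$group == "NP" & r$table$pnd == 11, ]
  expect_true(is.na(cell$mean_gph))
  expect_identical(cell$n, 0)
  expect_output(print(r), "nd")
  # day 11 cannot be tested, later days can
  expect_true(is.na(r$tests$p_value[r$tests$pnd == 11]))
  expect_false(any(is.na(r$tests$p_value[r$tests$pnd > 11])))

  # a day with a single litter in one group gets a mean but no test
  wsw2 <- s$wsw[!(s$wsw$group == "NP" & s$wsw$pnd == 12 &
                    s$wsw$litter_id != "NP1"), ]
  r2 <- run_experiment2(wsw2)
  expect_true(is.na(r2$tests$p_value[r2$tests$pnd == 12]))
  expect_false(is.na(r2$table$mean_gph[r2$table$group == "NP" &
                                         r2$table$pnd == 12]))
})

test_that("method comparison measures the tracer-over-WSW percent gap", {
  # one group so every dam shares the flow the loss rate is calibrated to
  cfg <- study_config(n_dams = c(NP = 3), measurement_cv = 0,
                      rate_cv = 0, dam_mass_cv = 0, pup_mass_cv = 0,
                      wsw_noise_sd = 0, baseline_ppm = 0, seed = 10)
  s <- generate_study(cfg)
  # inject the loss rate that produces a 24% overestimation exactly
  q <- 0.24
  s$wsw <- inject_suckling_losses(s$wsw,
                                  s$truth$milk_flow_gph[1] * q / (1 + q))
  rep1 <- suppressMessages(run_experiment1(s))
  cmp <- compare_methods(rep1, run_experiment2(s$wsw), pnd = 13)
  expect_equal(cmp$mean_percent_diff, 24, tolerance = 0.05)
  expect_identical(nrow(cmp$by_cell), 1L)
})

test_that("reports serialise to CSV and JSON", {
  s <- generate_study(study_config(n_dams = c(NP = 3, LP = 3), seed = 13))
  r <- run_experiment1(s)
  dir <- file.path(tempdir(), "exp1-report")
  write_experiment1_report(r, dir)
  expect_true(all(file.exists(file.path(dir,
    c("per_dam.csv", "summary.csv", "report.json")))))
  j <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(j$tests$milk_flow_p, r$tests$milk_flow$p.value,
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
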