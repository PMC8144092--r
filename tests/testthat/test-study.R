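# miniature configurations keep these orchestration tests fast; the
# scaled-down scientific experiments live in test-acceptance.R
tiny_solver <- function() solver_spec(fast = TRUE, n_prepace_beats = 10L)

test_that("study pipeline is fully deterministic under config + seed", {
  cfg <- study_config(scenario = "circadian_hr_ions",
                      pop_spec = population_spec(n_subjects = 2),
                      hours = c(8, 20), solver = tiny_solver(), seed = 7)
  r1 <- run_smetana_study(cfg)
  r2 <- run_smetana_study(cfg)
  expect_identical(r1$measurements, r2$measurements)
  expect_identical(r1$subject_stats, r2$subject_stats)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study_outputs(r1, d1)
  write_study_outputs(r2, d2)
  for (f in c("measurements.csv", "subject_stats.csv", "population.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_true(file.exists(file.path(d1, "manifest.json")))
})

test_that("frozen scenario leaves no within-subject QT or QTc variation", {
  cfg <- study_config(scenario = "no_circadian",
                      pop_spec = population_spec(n_subjects = 1),
                      hours = c(0, 9, 15), solver = tiny_solver(), seed = 3)
  res <- run_smetana_study(cfg)
  expect_equal(res$subject_stats$qt_sd_ms, 0)
  expect_equal(res$subject_stats$qtc_sd_ms, 0)
  # degenerate RR falls back to QTc = QT
  expect_equal(res$measurements$qtc_ms, res$measurements$qt_ms)
})

test_that("same-seed same-scenario comparison reports zero differences", {
  cfg <- study_config(pop_spec = population_spec(n_subjects = 1),
                      hours = c(7, 19), solver = tiny_solver(), seed = 5)
  cmp <- run_scenario_comparison(cfg, "circadian_hr_only", "circadian_hr_only")
  expect_true(all(cmp$comparison$per_subject$mean_qtc_diff_ms == 0))
  expect_true(all(cmp$comparison$per_subject$max_qtc_diff_ms == 0))
})

test_that("trial runner produces matched series and Tmax summaries", {
  cfg <- study_config(pop_spec = population_spec(n_subjects = 2),
                      solver = tiny_solver(),
                      doses_mg = 2,
                      pk = pk_spec(sample_times_h = c(0.5, 1, 2)),
                      correction = "study_specific", seed = 13)
  res <- run_tolterodine_study(cfg)
  expect_s3_class(res, "trial_result")
  # one baseline and one drug row per subject-time
  expect_equal(nrow(res$series), 2 * 2 * 3)
  expect_equal(nrow(res$tmax_table), 1)
  expect_equal(res$tmax_table$n_valid, 2)
  # hERG block cannot shorten QT: deltas non-negative
  expect_true(all(res$deltas$delta_qtc_ms > -0.5))
  # drug-arm concentrations are positive and dose-tagged
  drug <- res$series[res$series$arm == "drug", ]
  expect_true(all(drug$conc_ng_per_mL > 0))
  expect_true(all(drug$dose_mg == 2))
})

test_that("configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "scenario: circadian_hr_only",
    "correction: study_specific",
    "doses_mg: [2, 4]",
    "seed: 99",
    "population:",
    "  n_subjects: 12",
    "  prop_female: 0.5",
    "pk:",
    "  dose_mg: 2",
    "  ka_per_h: 3",
    "solver:",
    "  fast: true"
  ), path)
  cfg <- load_study_config(path)
  expect_s3_class(cfg, "study_config")
  expect_equal(cfg$scenario, "circadian_hr_only")
  expect_equal(cfg$pop_spec$n_subjects, 12L)
  expect_equal(cfg$doses_mg, c(2, 4))
  expect_true(cfg$solver$fast)
  expect_equal(cfg$seed, 99L)
})
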