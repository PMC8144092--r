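test_that("RR regression reproduces hand-evaluated values and orderings", {
  # independent inline evaluation of the regression for a 30-y male
  lp_noon <- 7.163 + 0.0961 - 0.0243 * 30 + 0.00027 * 900 - 0.0664 - 0.0608
  lp_midnight <- 7.163 + 0.0961 - 0.0243 * 30 + 0.00027 * 900 + 0.0664 + 0.0608
  expect_equal(mean_rr("male", 30, 12), exp(lp_noon), tolerance = 1e-12)
  expect_equal(mean_rr("male", 30, 0), exp(lp_midnight), tolerance = 1e-12)
  # night RR longer than day RR; male RR longer than female RR at matched age
  expect_gt(mean_rr("male", 30, 0), mean_rr("male", 30, 12))
  expect_gt(mean_rr("male", 30, 3), mean_rr("female", 30, 3))
  # magnitudes land in the physiological range
  expect_equal(mean_rr("male", 30, 12), 769.6, tolerance = 1e-3)
  expect_equal(mean_rr("male", 30, 0), 992.6, tolerance = 1e-3)
})

test_that("RR regression validates inputs", {
  expect_error(mean_rr("male", -5, 12), "non-negative")
  expect_warning(mean_rr("male", 10, 12), "range")
  expect_error(mean_rr("male", 30, 25), "hour")
  expect_error(mean_rr("boy", 30, 12), "sex")
})

test_that("all circadian models are 24-h periodic", {
  expect_equal(mean_rr("male", 30, 0), mean_rr("male", 30, 24),
               tolerance = 1e-13)
  expect_equal(mean_rr("female", 44, 0), mean_rr("female", 44, 24),
               tolerance = 1e-13)
  for (ion in c("K", "Na", "Ca"))
    expect_equal(ion_concentration(ion, "male", 0),
                 ion_concentration(ion, "male", 24), tolerance = 1e-13)
})

test_that("cosinor ion models have the printed means, amplitudes, phases", {
  # 24-h trapezoid average equals the sex mean (cosine integrates out)
  hrs <- seq(0, 24, length.out = 2881)
  for (ion in c("K", "Na")) {
    for (sex in c("male", "female")) {
      v <- vapply(hrs, function(h) ion_concentration(ion, sex, h), numeric(1))
      avg <- (sum(v) - (v[1] + v[length(v)]) / 2) / (length(v) - 1)
      p <- circadian_ion_params(ion)
      expected <- if (sex == "male") p$mean_male else p$mean_female
      expect_lt(abs(avg - expected), 1e-9)
      # peak-to-trough equals twice the amplitude
      expect_equal(max(v) - min(v), 2 * p$amplitude, tolerance = 1e-5)
    }
  }
  # peak at the acrophase
  expect_equal(ion_concentration("K", "female", 10 + 7 / 60), 4.088 + 0.18)
  expect_equal(ion_concentration("Na", "male", 13 + 8 / 60), 140.096 + 1.1)
})

test_that("calcium model is flat at the sex mean", {
  for (h in c(0, 5.5, 13.13, 23)) {
    expect_identical(ion_concentration("Ca", "female", h), 2.313)
    expect_identical(ion_concentration("Ca", "male", h), 2.418)
  }
  expect_equal(ion_concentration("Ca", "female", 4, subject_offset = 0.1), 2.413)
})

test_that("unknown ion and invalid hour are rejected", {
  expect_error(ion_concentration("Mg", "male", 4), "unknown ion")
  expect_error(ion_concentration("K", "male", -1), "hour")
})

test_that("circadian_profile assembles deterministic per-hour states", {
  subj <- list(sex = "female", age = 25, rr_offset = 1.05,
               ion_offsets = c(K = 0.2, Na = -1, Ca = 0.05))
  p1 <- circadian_profile(subj, hours = 0:23)
  p2 <- circadian_profile(subj, hours = 0:23)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 24)
  # rr follows a single 24-h sinusoidal period: one max, one min in the cycle
  expect_equal(p1$rr_ms, 1.05 * mean_rr("female", 25, 0:23))
  expect_equal(p1$k_mM[1],
               ion_concentration("K", "female", 0, subject_offset = 0.2))
  # disabling circadian freezes everything at the hour-0 baseline
  p0 <- circadian_profile(subj, hours = 0:23, circadian = FALSE)
  expect_true(all(p0$rr_ms == p0$rr_ms[1]))
  expect_true(all(p0$k_mM == p0$k_mM[1]))
  expect_equal(p0$rr_ms[1], p1$rr_ms[1])
  # freezing only the ions keeps RR diurnal and ions at the subject mesor
  pi <- circadian_profile(subj, hours = 0:23, ions_circadian = FALSE)
  expect_equal(pi$rr_ms, p1$rr_ms)
  expect_true(all(pi$k_mM == 4.088 + 0.2))
})

test_that("hourly profile CSV writer produces one row per subject-hour", {
  pop <- generate_population(population_spec(n_subjects = 3, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_circadian_csv(pop, path, hours = c(0, 12))
  tab <- read.csv(path)
  expect_equal(nrow(tab), 6)
  expect_named(tab, c("subject_id", "hour", "rr_ms", "k_mM", "na_mM", "ca_mM"))
  expect_equal(tab$rr_ms, out$rr_ms)
})
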