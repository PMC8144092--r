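test_that("QTc has the RR = 1 s fixed point and the Fridericia value", {
  for (n in c(0.068, 1 / 3, 0.5, 1))
    expect_identical(qtc(400, 1, n), 400)
  expect_equal(qtc(400, 0.8, 1 / 3), 400 / 0.8^(1 / 3))
  expect_equal(qtc(400, 0.8, 1 / 3), 430.9, tolerance = 1e-4)
  expect_error(qtc(400, 0, 1 / 3), "positive")
})

test_that("exponent fitting exactly recovers a noise-free power law", {
  rr <- seq(0.6, 1.2, by = 0.05)
  qt <- 400 * rr^0.33
  fit <- fit_qtc_exponent(qt, rr, scope = "pooled")
  expect_s3_class(fit, "qtc_fit")
  expect_equal(coef(fit), 0.33, tolerance = 1e-9)
  # corrected values are flat in RR
  qtci <- predict(fit, qt, rr)
  expect_lt(max(qtci) - min(qtci), 1e-9)
})

test_that("exponent fitting is unbiased under Gaussian noise", {
  set.seed(31)
  n_true <- 0.25
  est <- replicate(400, {
    rr <- runif(24, 0.7, 1.1)
    qt <- 380 * rr^n_true * exp(rnorm(24, 0, 0.01))
    coef(fit_qtc_exponent(qt, rr, scope = "pooled"))
  })
  expect_lt(abs(mean(est) - n_true), 3 * sd(est) / sqrt(length(est)) + 0.005)
})

test_that("individual fits decorrelate QTc from RR per subject", {
  set.seed(12)
  sid <- rep(1:6, each = 24)
  nexp <- runif(6, 0.1, 0.5)
  rr <- runif(length(sid), 0.7, 1.1)
  qt <- 390 * rr^nexp[sid] * exp(rnorm(length(sid), 0, 0.004))
  fit <- fit_qtc_exponent(qt, rr, subject_id = sid, scope = "individual")
  qtci <- predict(fit, qt, rr, subject_id = sid)
  for (i in 1:6) {
    r <- cor(qtci[sid == i], rr[sid == i])
    expect_lt(abs(r), 0.05)
  }
})

test_that("pooled fit on homogeneous subjects equals the individual fit", {
  rr <- rep(seq(0.7, 1.1, by = 0.1), 2)
  sid <- rep(1:2, each = 5)
  qt <- 400 * rr^0.3
  pooled <- fit_qtc_exponent(qt, rr, scope = "pooled")
  indiv <- fit_qtc_exponent(qt, rr, subject_id = sid, scope = "individual")
  expect_equal(unname(coef(indiv)), rep(coef(pooled), 2), tolerance = 1e-9)
})

test_that("degenerate fits are rejected", {
  expect_error(fit_qtc_exponent(c(400, 410, 420), rep(1, 3)), "degenerate")
  expect_error(fit_qtc_exponent(c(400, 410), c(0.9, 1.0)), "at least 3")
})

test_that("delta QTc is a time-matched within-subject difference", {
  ser <- expand.grid(subject_id = 1:3, time = c(0, 1, 2), arm = c("baseline", "drug"),
                     stringsAsFactors = FALSE)
  ser$qtc_ms <- 400 + as.numeric(ser$subject_id)
  # null drug: drug arm identical to baseline
  d0 <- delta_qtc(ser)
  expect_true(all(d0$delta_qtc_ms == 0))
  expect_equal(nrow(d0), 9)
  # constant shift moves every delta by exactly that amount
  ser2 <- ser
  ser2$qtc_ms[ser2$arm == "drug"] <- ser2$qtc_ms[ser2$arm == "drug"] + 5
  expect_true(all(delta_qtc(ser2)$delta_qtc_ms == 5))
  # unmatched time points are dropped and counted
  ser3 <- ser[!(ser$arm == "baseline" & ser$time == 2), ]
  d3 <- delta_qtc(ser3)
  expect_equal(nrow(d3), 6)
  expect_equal(attr(d3, "n_unmatched"), 3)
})

test_that("trial summary follows the mean + 1.96 SE convention", {
  s <- summarize_trial(c(0, 0, 0, 0))
  expect_equal(s$mean_ms, 0)
  expect_equal(s$se_ms, 0)
  expect_equal(s$ci95_upper_ms, 0)
  x <- c(2, 4, 6, 8)
  s2 <- summarize_trial(x)
  expect_equal(s2$mean_ms, 5)
  expect_equal(s2$se_ms, sd(x) / 2)
  expect_equal(s2$ci95_upper_ms, 5 + 1.96 * sd(x) / 2)
  # permutation invariance
  expect_identical(summarize_trial(x), summarize_trial(rev(x)))
  expect_error(summarize_trial(3), "at least 2")
})
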