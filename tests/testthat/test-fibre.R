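# shared small fibre run (prepaced, two beats) reused across assertions
fibre_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pre <- lapply(c(endo = "endo", mid = "mid", epi = "epi"), function(ct)
        prepace_single_cell(tt06_params(ct), cl_ms = 1000, n_beats = 15,
                            dt_ms = 0.02))
      spec <- fibre_spec(n_cells = 50, dt_ms = 0.02, cl_ms = 1000, n_beats = 2)
      fib <- build_fibre(spec)
      cache <<- list(fib = fib, pre = pre,
                     trace = simulate_fibre(fib, pre, sample_ms = 0.5,
                                            v_sample_ms = 1))
    }
    cache
  }
})

test_that("largest-remainder apportionment reproduces the 50:30:20 layout", {
  prop <- c(endo = 0.5, mid = 0.3, epi = 0.2)
  expect_equal(circaqt:::.apportion(165, prop), c(83L, 49L, 33L))
  expect_equal(circaqt:::.apportion(10, prop), c(5L, 3L, 2L))
  expect_equal(circaqt:::.apportion(100, prop), c(50L, 30L, 20L))
  fib <- build_fibre(fibre_spec(n_cells = 165))
  expect_equal(unname(fib$counts), c(83L, 49L, 33L))
  expect_identical(fib$cell_type[1], "endo")
  expect_identical(fib$cell_type[165], "epi")
  expect_identical(rle(fib$cell_type)$values, c("endo", "mid", "epi"))
})

test_that("invalid fibre specs are refused", {
  expect_error(fibre_spec(proportions = c(endo = 0.6, mid = 0.3, epi = 0.2)),
               "sum to 1")
  expect_error(fibre_spec(n_cells = 10), ">= 20")
  expect_error(fibre_spec(dx_cm = 0.001, dt_ms = 0.01), "unstable")
})

test_that("spatially uniform potential gives an identically zero pseudo-ECG", {
  V <- matrix(c(-85, 20, -40), nrow = 3, ncol = 50)
  expect_true(all(compute_pseudoecg(V, 0.01, -2) == 0))
})

test_that("electrode placement is validated and side flip reverses polarity", {
  fx <- fibre_fixture()
  tr <- fx$trace
  expect_error(compute_pseudoecg(tr$v_mV, 0.01, 0.25), "on the fibre")
  phi_left <- compute_pseudoecg(tr$v_mV, 0.01, -2)
  phi_right <- compute_pseudoecg(tr$v_mV, 0.01, 0.5 + 2)
  # QRS deflection of the last beat flips sign with the electrode side
  qrs <- tr$v_time_ms >= 1000 & tr$v_time_ms <= 1060
  i <- which.max(abs(phi_left[qrs]))
  expect_true(sign(phi_left[qrs][i]) != sign(phi_right[qrs][i]))
})

test_that("activation spreads monotonically away from the pacing site", {
  fx <- fibre_fixture()
  tr <- fx$trace
  vt <- tr$v_time_ms
  sel <- vt >= 1000
  act <- apply(tr$v_mV[sel, ], 2, function(v) vt[sel][which(v > 0)[1]])
  expect_true(all(is.finite(act)))
  # paced at the epicardial (last) end: activation times decrease with index
  expect_true(all(diff(act) <= 0 + 1e-9 | diff(act) == 0))
  expect_lt(act[50], act[1])
})

test_that("the default transmural layout yields a measurable positive T wave", {
  fx <- fibre_fixture()
  m <- measure_qt(fx$trace)
  expect_false(m$flag)
  expect_gt(m$qt_ms, 250)
  expect_lt(m$qt_ms, 450)
  expect_lt(m$qt_ms, m$rr_ms)
  expect_gt(m$t_end_ms, m$t_peak_ms)
  # T wave deflection is positive at its peak
  base <- median(fx$trace$phi[fx$trace$time_ms >= 970 & fx$trace$time_ms < 1000])
  tpk <- fx$trace$phi[fx$trace$time_ms == m$t_peak_ms]
  expect_gt(tpk - base, 0)
})

test_that("identical fibre runs are bit-identical", {
  fx <- fibre_fixture()
  tr2 <- simulate_fibre(fx$fib, fx$pre, sample_ms = 0.5, v_sample_ms = 1)
  expect_identical(fx$trace$phi, tr2$phi)
  expect_identical(fx$trace$states, tr2$states)
})

test_that("tangent method recovers an analytically constructed QT", {
  # Gaussian QRS at t = 0 and Gaussian T peaking at 250 ms with sd 25 ms:
  # the tangent at the steepest descent (t = 275) crosses baseline at 300 ms
  t <- seq(-50, 500, by = 0.5)
  phi <- 5 * exp(-t^2 / (2 * 9)) + 1 * exp(-(t - 250)^2 / (2 * 625))
  m <- measure_qt(list(time_ms = t, phi = phi), stim_times = 0)
  expect_false(m$flag)
  expect_equal(m$qt_ms, 300, tolerance = 2)
})

test_that("a flat T wave is flagged rather than measured", {
  t <- seq(-50, 500, by = 0.5)
  phi <- 5 * exp(-t^2 / (2 * 9)) # QRS only
  m <- measure_qt(list(time_ms = t, phi = phi), stim_times = 0)
  expect_true(m$flag)
  expect_true(is.na(m$qt_ms))
})

test_that("fibre QT lengthens at slower pacing", {
  qt_at <- function(cl) {
    pre <- lapply(c(endo = "endo", mid = "mid", epi = "epi"), function(ct)
      prepace_single_cell(tt06_params(ct), cl_ms = cl, n_beats = 60,
                          dt_ms = 0.02))
    spec <- fibre_spec(n_cells = 50, dt_ms = 0.02, cl_ms = cl, n_beats = 2)
    measure_qt(simulate_fibre(build_fibre(spec), pre))$qt_ms
  }
  expect_gt(qt_at(1200), qt_at(700))
})
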