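test_that("published resting state is near equilibrium", {
  y <- tt06_initial_state()
  for (ct in c("endo", "mid", "epi")) {
    dy <- tt06_rhs(y, tt06_params(ct))
    expect_lt(abs(dy[["V"]]), 0.05)
  }
  # holding without stimulus for 1 ms leaves the state essentially unchanged
  out <- tt06_pace(y, tt06_params("epi"), cl_ms = 1, n_beats = 1, dt_ms = 0.01,
                   stim_amp = 0, stim_dur = 0)
  expect_lt(abs(out$state[["V"]] - y[["V"]]), 2e-3)
  gates <- c("m", "h", "j", "d", "f", "f2", "fCass", "r", "s", "xr1", "xr2", "xs")
  expect_lt(max(abs(out$state[gates] - y[gates])), 2e-3)
})

test_that("with every current blocked the membrane is inert", {
  zero <- c(INa = 0, ICaL = 0, Ito = 0, IKr = 0, IKs = 0, IK1 = 0,
            INaCa = 0, INaK = 0, IpCa = 0, IpK = 0, IbNa = 0, IbCa = 0)
  p <- tt06_params("epi", block_scales = zero)
  y <- tt06_initial_state()
  for (v in c(-120, -60, 0, 40)) {
    y[["V"]] <- v
    expect_identical(tt06_rhs(y, p)[["V"]], 0)
  }
})

test_that("derivatives match the independent reference at random states", {
  set.seed(19)
  for (i in 1:10) {
    y <- tt06_random_state()
    ct <- sample(c("endo", "mid", "epi"), 1)
    a <- tt06_rhs(y, tt06_params(ct))
    b <- tt06_ref_rhs(0, y, tt06_ref_constants(ct))[[1]]
    expect_lt(max(abs(a - b) / pmax(abs(b), 1e-6)), 1e-6)
  }
})

test_that("a paced beat matches the reference trajectory and APD90", {
  skip_if_not_installed("deSolve")
  times <- seq(0, 450, by = 0.5)
  ref <- tt06_ref_beat(times, "epi")
  # fine-step Rush-Larsen solution against the adaptive reference
  fine <- tt06_pace(tt06_initial_state(), tt06_params("epi"), cl_ms = 1000,
                    n_beats = 1, dt_ms = 5e-4, stim_amp = -52, stim_dur = 1,
                    sample_ms = 0.5, record_all = TRUE)
  vfine <- fine$v_mV[fine$time_ms <= 450 + 1e-9]
  expect_lt(max(abs(vfine - ref[, "V"])), 1)
  # default-step APD90 within 5 ms of the reference
  std <- tt06_pace(tt06_initial_state(), tt06_params("epi"), cl_ms = 1000,
                   n_beats = 1, dt_ms = 0.01, record_all = TRUE)
  apd_ref <- apd90(ref[, 1], ref[, "V"])
  expect_lt(abs(apd90(std$time_ms, std$v_mV) - apd_ref), 5)
})

test_that("halving the time step barely changes APD90", {
  y <- tt06_initial_state()
  p <- tt06_params("epi")
  apd90_of <- function(dt) {
    o <- tt06_pace(y, p, cl_ms = 1000, n_beats = 1, dt_ms = dt)
    apd90(o$time_ms, o$v_mV)
  }
  expect_lt(abs(apd90_of(0.01) - apd90_of(0.005)), 0.5)
})

test_that("pre-pacing reaches a quasi-steady state", {
  p <- tt06_params("epi")
  s40 <- prepace_single_cell(p, cl_ms = 1000, n_beats = 40, dt_ms = 0.02)
  s41 <- prepace_single_cell(p, cl_ms = 1000, n_beats = 41, dt_ms = 0.02)
  apd <- function(st) {
    o <- tt06_pace(st, p, cl_ms = 1000, n_beats = 1, dt_ms = 0.02)
    apd90(o$time_ms, o$v_mV)
  }
  expect_lt(abs(apd(s40) - apd(s41)), 0.5)
})

apd_at <- function(cl, ko = 5.4, ikr = 1, n_pre = 40) {
  p <- tt06_params("epi", block_scales = c(IKr = ikr), ko_mM = ko)
  st <- prepace_single_cell(p, cl_ms = cl, n_beats = n_pre, dt_ms = 0.02)
  o <- tt06_pace(st, p, cl_ms = cl, n_beats = 1, dt_ms = 0.02)
  list(apd = apd90(o$time_ms, o$v_mV), state = o$state)
}

test_that("APD90 responds in the physiological directions", {
  # rate adaptation: slower pacing lengthens APD over CL 600-1200 ms
  apds <- vapply(c(600, 900, 1200), function(cl) apd_at(cl, n_pre = 120)$apd,
                 numeric(1))
  expect_true(all(diff(apds) > 0))
  # night-time (long RR) APD exceeds daytime APD
  expect_gt(apd_at(993, n_pre = 120)$apd, apd_at(770, n_pre = 120)$apd)
  # hypokalemia prolongs the action potential
  expect_gt(apd_at(1000, ko = 4.0)$apd, apd_at(1000, ko = 5.4)$apd)
  # IKr block prolongs the action potential, monotonically
  blocked <- vapply(c(1, 0.8, 0.6), function(s) apd_at(1000, ikr = s)$apd,
                    numeric(1))
  expect_true(all(diff(blocked) > 0))
})

test_that("gates stay in [0,1] and concentrations positive through pacing", {
  res <- apd_at(800, ko = 4.0, ikr = 0.6)
  st <- res$state
  gates <- c("m", "h", "j", "d", "f", "f2", "fCass", "r", "s", "xr1", "xr2", "xs")
  expect_true(all(st[gates] >= 0 & st[gates] <= 1))
  expect_true(all(st[c("Nai", "Ki", "Cai", "Cass", "Casr")] > 0))
})

test_that("invalid states and steps are rejected with the variable named", {
  y <- tt06_initial_state()
  y[["Cai"]] <- NaN
  expect_error(tt06_rhs(y, tt06_params("epi")), "Cai")
  expect_error(tt06_pace(tt06_initial_state(), tt06_params("epi"), dt_ms = 0.05),
               "dt")
})
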