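# Independent reference transcription of the ten Tusscher-Panfilov 2006
# human ventricular myocyte equations, written for deSolve and kept separate
# from the package's compiled implementation so the two can be compared.
# States are addressed by name; all units as in the original publication
# (mV, ms, mM, uA/uF).

tt06_ref_constants <- function(cell_type = "epi") {
  ct <- match.arg(cell_type, c("endo", "mid", "epi"))
  list(
    R = 8314.472, T = 310, F = 96485.3415,
    Cm = 0.185, Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468,
    Ko = 5.4, Nao = 140, Cao = 2,
    GNa = 14.838, GK1 = 5.405, GKr = 0.153,
    Gto = if (ct == "endo") 0.073 else 0.294,
    GKs = if (ct == "mid") 0.098 else 0.392,
    GCaL = 3.98e-5, GbNa = 0.00029, GbCa = 0.000592,
    GpCa = 0.1238, KpCa = 0.0005, GpK = 0.0146,
    PNaK = 2.724, KmK = 1, KmNa = 40,
    kNaCa = 1000, KmNai = 87.5, KmCa = 1.38, ksat = 0.1,
    alpha_ncx = 2.5, gamma_ncx = 0.35, pKNa = 0.03,
    Vmaxup = 0.006375, Kup = 0.00025, Vrel = 0.102, Vleak = 0.00036,
    Vxfer = 0.0038, k1p = 0.15, k2p = 0.045, k3 = 0.06, k4 = 0.005,
    EC = 1.5, maxsr = 2.5, minsr = 1,
    Bufc = 0.2, Kbufc = 0.001, Bufsr = 10, Kbufsr = 0.3,
    Bufss = 0.4, Kbufss = 0.00025,
    cell_type = ct
  )
}

# y: named vector with the package's state names
tt06_ref_rhs <- function(t, y, parms, stim = 0) {
  cc <- parms
  V <- y[["V"]]
  RTF <- cc$R * cc$T / cc$F

  EK <- RTF * log(cc$Ko / y[["Ki"]])
  ENa <- RTF * log(cc$Nao / y[["Nai"]])
  EKs <- RTF * log((cc$Ko + cc$pKNa * cc$Nao) / (y[["Ki"]] + cc$pKNa * y[["Nai"]]))
  ECa <- RTF / 2 * log(cc$Cao / y[["Cai"]])

  INa <- cc$GNa * y[["m"]]^3 * y[["h"]] * y[["j"]] * (V - ENa)

  x <- 2 * (V - 15) * cc$F / (cc$R * cc$T)
  drive <- if (abs(x) < 1e-7) (0.25 * y[["Cass"]] - cc$Cao) else
    x * (0.25 * y[["Cass"]] * exp(x) - cc$Cao) / (exp(x) - 1)
  ICaL <- cc$GCaL * y[["d"]] * y[["f"]] * y[["f2"]] * y[["fCass"]] * 2 * cc$F * drive

  Ito <- cc$Gto * y[["r"]] * y[["s"]] * (V - EK)
  IKr <- cc$GKr * sqrt(cc$Ko / 5.4) * y[["xr1"]] * y[["xr2"]] * (V - EK)
  IKs <- cc$GKs * y[["xs"]]^2 * (V - EKs)

  aK1 <- 0.1 / (1 + exp(0.06 * (V - EK - 200)))
  bK1 <- (3 * exp(0.0002 * (V - EK + 100)) + exp(0.1 * (V - EK - 10))) /
    (1 + exp(-0.5 * (V - EK)))
  IK1 <- cc$GK1 * sqrt(cc$Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK)

  INaCa <- cc$kNaCa *
    (exp(cc$gamma_ncx * V / RTF) * y[["Nai"]]^3 * cc$Cao -
       exp((cc$gamma_ncx - 1) * V / RTF) * cc$Nao^3 * y[["Cai"]] * cc$alpha_ncx) /
    ((cc$KmNai^3 + cc$Nao^3) * (cc$KmCa + cc$Cao) *
       (1 + cc$ksat * exp((cc$gamma_ncx - 1) * V / RTF)))

  INaK <- cc$PNaK * cc$Ko * y[["Nai"]] /
    ((cc$Ko + cc$KmK) * (y[["Nai"]] + cc$KmNa) *
       (1 + 0.1245 * exp(-0.1 * V / RTF) + 0.0353 * exp(-V / RTF)))

  IpCa <- cc$GpCa * y[["Cai"]] / (y[["Cai"]] + cc$KpCa)
  IpK <- cc$GpK * (V - EK) / (1 + exp((25 - V) / 5.98))
  IbNa <- cc$GbNa * (V - ENa)
  IbCa <- cc$GbCa * (V - ECa)

  Itot <- INa + ICaL + Ito + IKr + IKs + IK1 + INaCa + INaK + IpCa + IpK + IbNa + IbCa

  # gate kinetics
  m_inf <- 1 / (1 + exp((-56.86 - V) / 9.03))^2
  tau_m <- (1 / (1 + exp((-60 - V) / 5))) *
    (0.1 / (1 + exp((V + 35) / 5)) + 0.1 / (1 + exp((V - 50) / 200)))
  h_inf <- 1 / (1 + exp((V + 71.55) / 7.43))^2
  if (V < -40) {
    ah <- 0.057 * exp(-(V + 80) / 6.8)
    bh <- 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V)
  } else {
    ah <- 0
    bh <- 0.77 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
  }
  tau_h <- 1 / (ah + bh)
  j_inf <- h_inf
  if (V < -40) {
    aj <- (-25428 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) * (V + 37.78) /
      (1 + exp(0.311 * (V + 79.23)))
    bj <- 0.02424 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
  } else {
    aj <- 0
    bj <- 0.6 * exp(0.057 * V) / (1 + exp(-0.1 * (V + 32)))
  }
  tau_j <- 1 / (aj + bj)
  d_inf <- 1 / (1 + exp((-8 - V) / 7.5))
  tau_d <- (1.4 / (1 + exp((-35 - V) / 13)) + 0.25) * (1.4 / (1 + exp((V + 5) / 5))) +
    1 / (1 + exp((50 - V) / 20))
  f_inf <- 1 / (1 + exp((V + 20) / 7))
  tau_f <- 1102.5 * exp(-(V + 27)^2 / 225) + 200 / (1 + exp((13 - V) / 10)) +
    180 / (1 + exp((V + 30) / 10)) + 20
  f2_inf <- 0.67 / (1 + exp((V + 35) / 7)) + 0.33
  tau_f2 <- 562 * exp(-(V + 27)^2 / 240) + 31 / (1 + exp((25 - V) / 10)) +
    80 / (1 + exp((V + 30) / 10))
  fCass_inf <- 0.6 / (1 + (y[["Cass"]] / 0.05)^2) + 0.4
  tau_fCass <- 80 / (1 + (y[["Cass"]] / 0.05)^2) + 2
  r_inf <- 1 / (1 + exp((20 - V) / 6))
  tau_r <- 9.5 * exp(-(V + 40)^2 / 1800) + 0.8
  if (cc$cell_type == "endo") {
    s_inf <- 1 / (1 + exp((V + 28) / 5))
    tau_s <- 1000 * exp(-(V + 67)^2 / 1000) + 8
  } else {
    s_inf <- 1 / (1 + exp((V + 20) / 5))
    tau_s <- 85 * exp(-(V + 45)^2 / 320) + 5 / (1 + exp((V - 20) / 5)) + 3
  }
  xr1_inf <- 1 / (1 + exp((-26 - V) / 7))
  tau_xr1 <- (450 / (1 + exp((-45 - V) / 10))) * (6 / (1 + exp((V + 30) / 11.5)))
  xr2_inf <- 1 / (1 + exp((V + 88) / 24))
  tau_xr2 <- (3 / (1 + exp((-60 - V) / 20))) * (1.12 / (1 + exp((V - 60) / 20)))
  xs_inf <- 1 / (1 + exp((-5 - V) / 14))
  tau_xs <- (1400 / sqrt(1 + exp((5 - V) / 6))) * (1 / (1 + exp((V - 35) / 15))) + 80

  # calcium subsystem
  kcasr <- cc$maxsr - (cc$maxsr - cc$minsr) / (1 + (cc$EC / y[["Casr"]])^2)
  k1 <- cc$k1p / kcasr
  k2 <- cc$k2p * kcasr
  O <- k1 * y[["Cass"]]^2 * y[["Rq"]] / (cc$k3 + k1 * y[["Cass"]]^2)
  dRq <- -k2 * y[["Cass"]] * y[["Rq"]] + cc$k4 * (1 - y[["Rq"]])
  Irel <- cc$Vrel * O * (y[["Casr"]] - y[["Cass"]])
  Iup <- cc$Vmaxup / (1 + cc$Kup^2 / y[["Cai"]]^2)
  Ileak <- cc$Vleak * (y[["Casr"]] - y[["Cai"]])
  Ixfer <- cc$Vxfer * (y[["Cass"]] - y[["Cai"]])

  bcai <- 1 / (1 + cc$Bufc * cc$Kbufc / (y[["Cai"]] + cc$Kbufc)^2)
  bcsr <- 1 / (1 + cc$Bufsr * cc$Kbufsr / (y[["Casr"]] + cc$Kbufsr)^2)
  bcss <- 1 / (1 + cc$Bufss * cc$Kbufss / (y[["Cass"]] + cc$Kbufss)^2)

  dy <- c(
    V = -(Itot + stim),
    m = (m_inf - y[["m"]]) / tau_m,
    h = (h_inf - y[["h"]]) / tau_h,
    j = (j_inf - y[["j"]]) / tau_j,
    d = (d_inf - y[["d"]]) / tau_d,
    f = (f_inf - y[["f"]]) / tau_f,
    f2 = (f2_inf - y[["f2"]]) / tau_f2,
    fCass = (fCass_inf - y[["fCass"]]) / tau_fCass,
    r = (r_inf - y[["r"]]) / tau_r,
    s = (s_inf - y[["s"]]) / tau_s,
    xr1 = (xr1_inf - y[["xr1"]]) / tau_xr1,
    xr2 = (xr2_inf - y[["xr2"]]) / tau_xr2,
    xs = (xs_inf - y[["xs"]]) / tau_xs,
    Rq = dRq,
    Nai = -(INa + IbNa + 3 * INaK + 3 * INaCa) * cc$Cm / (cc$Vc * cc$F),
    Ki = -(IK1 + Ito + IKr + IKs - 2 * INaK + IpK + stim) * cc$Cm / (cc$Vc * cc$F),
    Cai = bcai * ((Ileak - Iup) * cc$Vsr / cc$Vc + Ixfer -
                    (IbCa + IpCa - 2 * INaCa) * cc$Cm / (2 * cc$Vc * cc$F)),
    Cass = bcss * (-ICaL * cc$Cm / (2 * cc$Vss * cc$F) + Irel * cc$Vsr / cc$Vss -
                     Ixfer * cc$Vc / cc$Vss),
    Casr = bcsr * (Iup - Irel - Ileak)
  )
  list(dy)
}

# integrate one paced beat with deSolve (stimulus -52 uA/uF for the first
# 1 ms), returning V on the requested time grid
tt06_ref_beat <- function(times, cell_type = "epi", y0 = tt06_initial_state(),
                          stim_amp = -52, stim_dur = 1) {
  cc <- tt06_ref_constants(cell_type)
  f_stim <- function(t, y, parms) tt06_ref_rhs(t, y, parms, stim = stim_amp)
  f_free <- function(t, y, parms) tt06_ref_rhs(t, y, parms, stim = 0)
  t1 <- times[times <= stim_dur]
  if (!length(t1) || max(t1) < stim_dur) t1 <- c(t1, stim_dur)
  o1 <- deSolve::lsoda(y0, t1, f_stim, cc, rtol = 1e-8, atol = 1e-8)
  y_mid <- o1[nrow(o1), -1]
  t2 <- c(stim_dur, times[times > stim_dur])
  o2 <- deSolve::lsoda(y_mid, t2, f_free, cc, rtol = 1e-8, atol = 1e-8)
  out <- rbind(o1[o1[, 1] %in% times, , drop = FALSE],
               o2[-1, , drop = FALSE][o2[-1, 1] %in% times, , drop = FALSE])
  out
}

# random but physiologically plausible state for derivative comparisons
tt06_random_state <- function() {
  st <- c(V = stats::runif(1, -90, 40),
          m = stats::runif(1), h = stats::runif(1), j = stats::runif(1),
          d = stats::runif(1), f = stats::runif(1), f2 = stats::runif(1),
          fCass = stats::runif(1), r = stats::runif(1), s = stats::runif(1),
          xr1 = stats::runif(1), xr2 = stats::runif(1), xs = stats::runif(1),
          Rq = stats::runif(1),
          Nai = stats::runif(1, 5, 15), Ki = stats::runif(1, 120, 145),
          Cai = stats::runif(1, 5e-5, 1e-3), Cass = stats::runif(1, 1e-4, 1e-2),
          Casr = stats::runif(1, 1, 5))
  st
}
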