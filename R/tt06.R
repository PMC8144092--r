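#' @useDynLib circaqt, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# order of the state vector shared with the compiled core
.tt06_state_names <- c("V", "m", "h", "j", "d", "f", "f2", "fCass", "r", "s",
                       "xr1", "xr2", "xs", "Rq", "Nai", "Ki", "Cai", "Cass", "Casr")

.tt06_param_names <- c("s_variant", "GNa", "GCaL", "Gto", "GKr", "GKs", "GK1",
                       "GpCa", "GpK", "GbNa", "GbCa", "PNaK", "kNaCa",
                       "Ko", "Nao", "Cao")

#' TT06 cell parameters
#'
#' Build the parameter vector for the ten Tusscher--Panfilov 2006 human
#' ventricular myocyte model. Transmural cell types differ only in the
#' transient-outward conductance `Gto`, the slow delayed-rectifier
#' conductance `GKs` and the kinetics of the `s` inactivation gate.
#' Extracellular ion concentrations enter the Nernst/GHK terms and are the
#' mechanistic route by which circadian plasma electrolytes move the QT
#' interval. Pore-block scale factors multiply the corresponding maximal
#' conductance (or pump/exchanger rate).
#'
#' @param cell_type one of `"endo"`, `"mid"`, `"epi"`.
#' @param block_scales named numeric vector of multiplicative scale factors in
#'   \[0, 1\]; recognised names are `INa`, `ICaL`, `Ito`, `IKr`, `IKs`, `IK1`,
#'   `INaCa`, `INaK`, `IpCa`, `IpK`, `IbNa`, `IbCa`. Unnamed currents are left
#'   untouched (scale 1).
#' @param ko_mM,nao_mM,cao_mM extracellular K+, Na+ and Ca2+ concentrations
#'   (mM). Defaults are the TT06 publication values.
#' @return named numeric vector of model parameters.
#' @export
tt06_params <- function(cell_type = c("epi", "endo", "mid"),
                        block_scales = NULL,
                        ko_mM = 5.4, nao_mM = 140, cao_mM = 2.0) {
  cell_type <- match.arg(cell_type)
  stopifnot(ko_mM > 0, nao_mM > 0, cao_mM > 0)
  p <- c(
    s_variant = if (cell_type == "endo") 0 else 1,
    GNa = 14.838,
    GCaL = 3.98e-5,
    Gto = if (cell_type == "endo") 0.073 else 0.294,
    GKr = 0.153,
    GKs = if (cell_type == "mid") 0.098 else 0.392,
    GK1 = 5.405,
    GpCa = 0.1238,
    GpK = 0.0146,
    GbNa = 0.00029,
    GbCa = 0.000592,
    PNaK = 2.724,
    kNaCa = 1000,
    Ko = ko_mM,
    Nao = nao_mM,
    Cao = cao_mM
  )
  if (!is.null(block_scales)) {
    if (is.null(names(block_scales)) || any(!nzchar(names(block_scales))))
      stop("block_scales must be a named vector")
    map <- c(INa = "GNa", ICaL = "GCaL", Ito = "Gto", IKr = "GKr", IKs = "GKs",
             IK1 = "GK1", INaCa = "kNaCa", INaK = "PNaK", IpCa = "GpCa",
             IpK = "GpK", IbNa = "GbNa", IbCa = "GbCa")
    unknown <- setdiff(names(block_scales), names(map))
    if (length(unknown))
      stop("unknown current id(s) in block_scales: ", paste(unknown, collapse = ", "))
    if (any(block_scales < 0))
      stop("block_scales must be non-negative")
    for (cur in names(block_scales))
      p[map[[cur]]] <- p[map[[cur]]] * block_scales[[cur]]
  }
  p
}

#' TT06 initial state
#'
#' Published paced steady-state initial conditions of the TT06 model
#' (epicardial variant at a cycle length of 1000 ms). All cell types are
#' started from this state and pre-paced to their own steady state before
#' use (see [prepace_single_cell()]).
#'
#' @return named numeric state vector (19 variables).
#' @export
tt06_initial_state <- function() {
  c(V = -85.23, m = 0.00172, h = 0.7444, j = 0.7045,
    d = 3.373e-5, f = 0.7888, f2 = 0.9755, fCass = 0.9953,
    r = 2.42e-8, s = 0.999998, xr1 = 0.00621, xr2 = 0.4712, xs = 0.0095,
    Rq = 0.9073, Nai = 8.604, Ki = 136.89,
    Cai = 0.000126, Cass = 0.00036, Casr = 3.64)
}

.check_state <- function(state) {
  if (length(state) != 19L) stop("state must have 19 elements")
  if (any(!is.finite(state))) {
    bad <- .tt06_state_names[which(!is.finite(state))[1]]
    stop("non-finite state variable '", bad, "'")
  }
  invisible(state)
}

#' TT06 right-hand side
#'
#' Time derivatives of all 19 state variables, evaluated exactly (no lookup
#' tables). Gate derivatives are `(inf - y)/tau`.
#'
#' @param state numeric state vector (see [tt06_initial_state()]).
#' @param params parameter vector from [tt06_params()].
#' @param stimulus stimulus current (uA/uF; depolarising stimuli are negative).
#' @return named numeric vector of derivatives (per ms).
#' @export
tt06_rhs <- function(state, params, stimulus = 0) {
  .check_state(state)
  dy <- .tt06_rhs_cpp(as.numeric(state), as.numeric(params), stimulus)
  names(dy) <- .tt06_state_names
  dy
}

#' Paced single-cell simulation
#'
#' Integrate one TT06 cell under regular pacing with Rush--Larsen updates for
#' the Hodgkin--Huxley gates and forward Euler for voltage, concentrations and
#' the release gate. Stimuli of `stim_amp` uA/uF and `stim_dur` ms are applied
#' at t = 0, `cl_ms`, 2*`cl_ms`, ...
#'
#' @param state initial state vector.
#' @param params parameter vector from [tt06_params()].
#' @param cl_ms pacing cycle length (ms).
#' @param n_beats number of paced beats to simulate.
#' @param dt_ms time step (ms, at most 0.02).
#' @param stim_amp,stim_dur stimulus amplitude (uA/uF) and duration (ms).
#' @param sample_ms sampling interval of the recorded trace (ms).
#' @param record_all record the whole run (`TRUE`) or only the final beat.
#' @param use_lut use voltage lookup tables for the gate kinetics (fast); set
#'   `FALSE` for a plain forward-Euler reference path.
#' @return list with the final `state`, sampled `time_ms`, `v_mV`, `cai_mM`.
#' @export
tt06_pace <- function(state, params, cl_ms = 1000, n_beats = 1, dt_ms = 0.01,
                      stim_amp = -52, stim_dur = 1, sample_ms = 0.1,
                      record_all = FALSE, use_lut = TRUE) {
  .check_state(state)
  out <- .tt06_pace_cpp(as.numeric(state), as.numeric(params), cl_ms,
                        as.integer(n_beats), dt_ms, stim_amp, stim_dur,
                        sample_ms, record_all, use_lut)
  names(out$state) <- .tt06_state_names
  out
}

#' Single-cell steady-state initialisation
#'
#' Pre-pace a single cell for `n_beats` beats at the given cycle length so
#' that fibre simulations can start from a (quasi) steady state and need only
#' a few beats themselves.
#'
#' @inheritParams tt06_pace
#' @param state optional starting state (defaults to [tt06_initial_state()]).
#' @return the state vector after `n_beats` paced beats.
#' @export
prepace_single_cell <- function(params, cl_ms = 1000, n_beats = 100,
                                dt_ms = 0.01, state = tt06_initial_state(),
                                stim_amp = -52, stim_dur = 1) {
  if (n_beats < 1) stop("n_beats must be >= 1")
  out <- tt06_pace(state, params, cl_ms = cl_ms, n_beats = n_beats,
                   dt_ms = dt_ms, stim_amp = stim_amp, stim_dur = stim_dur,
                   sample_ms = cl_ms) # no trace needed
  out$state
}

#' Action potential duration at 90% repolarisation
#'
#' APD90 from a sampled membrane-potential trace of one (or more) beats:
#' time from the maximum-upstroke-velocity point to 90% repolarisation of the
#' last action potential.
#'
#' @param time_ms,v_mV sampled trace.
#' @return APD90 in ms (NA if no action potential is detected).
#' @export
apd90 <- function(time_ms, v_mV) {
  stopifnot(length(time_ms) == length(v_mV))
  dv <- diff(v_mV) / diff(time_ms)
  iup <- which.max(dv)
  if (!length(iup) || max(dv) < 5) return(NA_real_)
  t_up <- time_ms[iup]
  v_rest <- v_mV[1]
  v_peak <- max(v_mV[time_ms >= t_up])
  v90 <- v_peak - 0.9 * (v_peak - v_rest)
  after <- which(time_ms > t_up)
  below <- after[v_mV[after] <= v90]
  # first crossing after the peak (skip upstroke samples still below v90)
  ipk <- after[which.max(v_mV[after])]
  below <- below[below > ipk]
  if (!length(below)) return(NA_real_)
  i2 <- below[1]; i1 <- i2 - 1L
  # linear interpolation of the crossing time
  w <- (v90 - v_mV[i1]) / (v_mV[i2] - v_mV[i1])
  t_cross <- time_ms[i1] + w * (time_ms[i2] - time_ms[i1])
  t_cross - t_up
}
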