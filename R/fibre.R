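#' Fibre specification
#'
#' Geometry, discretisation and protocol of the heterogeneous 1D monodomain
#' fibre: contiguous endocardial, mid-myocardial and epicardial segments in
#' 50:30:20 proportions, explicit operator-split solver, pacing at one end,
#' and a unipolar pseudo-ECG electrode on the fibre axis beyond the non-paced
#' end. The default space step of 0.01 cm with D = 0.0016 cm^2/ms and
#' dt = 0.01 ms gives an explicit-scheme stability factor D*dt/dx^2 = 0.16.
#'
#' @param n_cells number of nodes (>= 20); the default 165 corresponds to a
#'   1.65 cm fibre at dx = 0.01 cm.
#' @param proportions endo:mid:epi proportions (must sum to 1).
#' @param dx_cm space step (cm).
#' @param dt_ms time step (ms).
#' @param diffusion_cm2_per_ms diffusion coefficient (cm^2/ms).
#' @param pacing_site `"epi_end"` (default, the epicardial end of the strand)
#'   or `"endo_end"`.
#' @param cl_ms pacing cycle length (ms).
#' @param n_beats number of fibre beats; the last one is measured.
#' @param total_time_ms optional total simulated time (defaults to
#'   `n_beats * cl_ms`).
#' @param electrode_distance_cm distance of the electrode beyond the
#'   non-paced end (cm).
#' @param stim_amp,stim_dur stimulus amplitude (uA/uF) and duration (ms),
#'   applied to the 3 nodes at the pacing site.
#' @param n_stim_nodes number of stimulated nodes.
#' @return object of class `fibre_spec`.
#' @export
fibre_spec <- function(n_cells = 165,
                       proportions = c(endo = 0.5, mid = 0.3, epi = 0.2),
                       dx_cm = 0.01, dt_ms = 0.01,
                       diffusion_cm2_per_ms = 0.0016,
                       pacing_site = c("epi_end", "endo_end"),
                       cl_ms = 1000, n_beats = 3, total_time_ms = NULL,
                       electrode_distance_cm = 2,
                       stim_amp = -52, stim_dur = 2, n_stim_nodes = 10) {
  pacing_site <- match.arg(pacing_site)
  if (n_cells < 20) stop("n_cells must be >= 20")
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (dt_ms > 0.02 + 1e-12) stop("dt_ms must be <= 0.02 ms")
  cfl <- diffusion_cm2_per_ms * dt_ms / dx_cm^2
  if (cfl >= 0.5)
    stop(sprintf("explicit scheme unstable: D*dt/dx^2 = %.3f >= 0.5 (D = %g, dt = %g, dx = %g)",
                 cfl, diffusion_cm2_per_ms, dt_ms, dx_cm))
  if (is.null(total_time_ms)) total_time_ms <- n_beats * cl_ms
  structure(list(n_cells = as.integer(n_cells), proportions = proportions,
                 dx_cm = dx_cm, dt_ms = dt_ms,
                 diffusion_cm2_per_ms = diffusion_cm2_per_ms,
                 pacing_site = pacing_site, cl_ms = cl_ms,
                 n_beats = n_beats, total_time_ms = total_time_ms,
                 electrode_distance_cm = electrode_distance_cm,
                 stim_amp = stim_amp, stim_dur = stim_dur,
                 n_stim_nodes = as.integer(n_stim_nodes)),
            class = "fibre_spec")
}

# largest-remainder apportionment with ties broken by descending proportion
.apportion <- function(n, proportions) {
  quota <- n * proportions
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    rem <- quota - counts
    ord <- order(-rem, -proportions)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

#' Build the heterogeneous fibre layout
#'
#' Contiguous segments ordered endocardium -> mid-myocardium -> epicardium,
#' with node counts by largest-remainder rounding of the proportions.
#'
#' @param spec a [fibre_spec()].
#' @param cell_params_by_type named list of parameter vectors (from
#'   [tt06_params()]) for `endo`, `mid` and `epi`.
#' @return list with `cell_type` (character per node), `counts`, `params`
#'   (parameter matrix, one column per node) and the spec.
#' @export
build_fibre <- function(spec, cell_params_by_type = NULL) {
  stopifnot(inherits(spec, "fibre_spec"))
  if (is.null(cell_params_by_type))
    cell_params_by_type <- list(endo = tt06_params("endo"),
                                mid = tt06_params("mid"),
                                epi = tt06_params("epi"))
  stopifnot(all(c("endo", "mid", "epi") %in% names(cell_params_by_type)))
  counts <- .apportion(spec$n_cells, spec$proportions[c("endo", "mid", "epi")])
  names(counts) <- c("endo", "mid", "epi")
  cell_type <- rep(c("endo", "mid", "epi"), counts)
  params <- vapply(cell_type, function(ct) as.numeric(cell_params_by_type[[ct]]),
                   numeric(16))
  list(cell_type = cell_type, counts = counts, params = params, spec = spec)
}

#' Simulate the fibre and its pseudo-ECG
#'
#' Operator-split explicit integration of the monodomain cable: a reaction
#' step per node (Rush--Larsen gates, forward-Euler voltage/concentrations)
#' followed by explicit diffusion of the membrane potential with no-flux
#' boundaries. The unipolar pseudo-ECG is accumulated on the fly at full
#' spatial resolution.
#'
#' @param fibre layout from [build_fibre()].
#' @param init_states either a single state vector applied to every node, or
#'   a named list of per-cell-type state vectors (recommended: pre-paced
#'   states from [prepace_single_cell()]), or a 19 x n matrix.
#' @param sample_ms pseudo-ECG sampling interval (ms).
#' @param v_sample_ms when > 0, also record the membrane-potential field
#'   every `v_sample_ms` ms.
#' @return list of class `pseudoecg_trace` with `time_ms`, `phi`,
#'   `stim_times`, final `states`, and optionally `v_time_ms`/`v_mV`.
#' @export
simulate_fibre <- function(fibre, init_states = tt06_initial_state(),
                           sample_ms = 0.5, v_sample_ms = 0) {
  spec <- fibre$spec
  n <- spec$n_cells
  if (is.matrix(init_states)) {
    stopifnot(nrow(init_states) == 19, ncol(init_states) == n)
    smat <- init_states
  } else if (is.list(init_states)) {
    stopifnot(all(fibre$cell_type %in% names(init_states)))
    smat <- vapply(fibre$cell_type, function(ct) as.numeric(init_states[[ct]]),
                   numeric(19))
  } else {
    smat <- matrix(as.numeric(init_states), nrow = 19, ncol = n)
  }
  pace_first <- spec$pacing_site == "endo_end"
  electrode_x <- if (pace_first) n * spec$dx_cm + spec$electrode_distance_cm
                 else -spec$electrode_distance_cm
  out <- .tt06_fibre_cpp(smat, fibre$params,
                         spec$diffusion_cm2_per_ms, spec$dx_cm, spec$dt_ms,
                         spec$cl_ms, spec$total_time_ms,
                         pace_first, spec$n_stim_nodes,
                         spec$stim_amp, spec$stim_dur,
                         sample_ms, electrode_x, v_sample_ms)
  out$electrode_x_cm <- electrode_x
  out$spec <- spec
  class(out) <- "pseudoecg_trace"
  out
}

#' Unipolar pseudo-ECG from a membrane-potential field
#'
#' Extracellular potential at a point electrode on the fibre axis:
#' `phi(x*) = -sum_i dV_i * d(1/r)_i / dx` over node interfaces, with
#' r = |x - x*| and node i centred at `(i - 1/2) dx`. Arbitrary units;
#' a spatially uniform field gives phi identically zero.
#'
#' @param v_mV matrix of membrane potentials, one row per time sample and one
#'   column per node.
#' @param dx_cm space step (cm).
#' @param electrode_x_cm electrode position on the fibre axis (cm); must lie
#'   outside the fibre `[0, n*dx]`.
#' @return numeric vector of phi, one value per row of `v_mV`.
#' @export
compute_pseudoecg <- function(v_mV, dx_cm, electrode_x_cm) {
  v_mV <- as.matrix(v_mV)
  n <- ncol(v_mV)
  x <- (seq_len(n) - 0.5) * dx_cm
  if (electrode_x_cm > -1e-9 && electrode_x_cm < n * dx_cm + 1e-9)
    stop("electrode lies on the fibre")
  invr <- 1 / abs(x - electrode_x_cm)
  dinvr <- diff(invr)
  dv <- v_mV[, -1, drop = FALSE] - v_mV[, -n, drop = FALSE]
  as.numeric(-(dv %*% dinvr) / dx_cm)
}

#' Measure the QT interval of the last complete beat
#'
#' Q onset is the stimulus time; T end is found by the tangent method: the
#' point of steepest return of the T wave towards the isoelectric baseline,
#' extrapolated linearly to its baseline crossing. The isoelectric level is
#' the median pseudo-ECG value over the 30 ms preceding the measured beat's
#' stimulus. Beats with a flat T wave (T amplitude below `min_t_frac` of the
#' QRS amplitude) or without a tangent crossing are flagged.
#'
#' @param trace a `pseudoecg_trace` from [simulate_fibre()], or any list with
#'   `time_ms` and `phi`.
#' @param stim_times stimulus times (ms); defaults to `trace$stim_times`.
#' @param qrs_skip_ms window after the stimulus excluded from the T-wave
#'   search (contains the QRS complex).
#' @param min_t_frac minimum T amplitude as a fraction of QRS amplitude.
#' @return list with `qt_ms`, `rr_ms`, `q_onset_ms`, `t_end_ms`, `t_peak_ms`
#'   and a logical `flag` (TRUE = unreliable measurement).
#' @export
measure_qt <- function(trace, stim_times = NULL, qrs_skip_ms = 120,
                       min_t_frac = 0.01) {
  t <- trace$time_ms
  phi <- trace$phi
  if (is.null(stim_times)) stim_times <- trace$stim_times
  if (is.null(stim_times) || !length(stim_times))
    stop("stimulus times are required to anchor Q onset")
  stim_times <- sort(stim_times)
  t_end_trace <- t[length(t)]
  # last stimulus with a complete repolarisation window after it
  rr <- if (length(stim_times) > 1) diff(stim_times)[length(stim_times) - 1]
        else t_end_trace - stim_times[1]
  q_on <- stim_times[length(stim_times)]
  if (t_end_trace - q_on < qrs_skip_ms + 80 && length(stim_times) > 1) {
    q_on <- stim_times[length(stim_times) - 1]
  }
  win_end <- min(t_end_trace, q_on + rr - 10)

  flagged <- function(reason) list(qt_ms = NA_real_, rr_ms = rr,
                                   q_onset_ms = q_on, t_end_ms = NA_real_,
                                   t_peak_ms = NA_real_, flag = TRUE,
                                   reason = reason)

  base_idx <- t >= q_on - 30 & t < q_on
  baseline <- if (any(base_idx)) stats::median(phi[base_idx]) else 0
  qrs_idx <- t >= q_on & t < q_on + qrs_skip_ms
  qrs_amp <- max(abs(phi[qrs_idx] - baseline))
  tw <- which(t >= q_on + qrs_skip_ms & t <= win_end)
  if (length(tw) < 5) return(flagged("window too short"))
  dev <- phi[tw] - baseline
  ipk <- tw[which.max(abs(dev))]
  t_amp <- phi[ipk] - baseline
  if (abs(t_amp) < min_t_frac * qrs_amp) return(flagged("flat T wave"))
  # descending limb: from the T peak until the signal is back near baseline
  after <- which(t > t[ipk] & t <= win_end)
  if (length(after) < 3) return(flagged("no descending limb"))
  near0 <- after[abs(phi[after] - baseline) <= 0.05 * abs(t_amp)]
  limb_end <- if (length(near0)) near0[1] else after[length(after)]
  limb <- after[after <= limb_end]
  if (length(limb) < 3) return(flagged("no descending limb"))
  slopes <- diff(phi[limb]) / diff(t[limb])
  # slope must head back towards baseline
  want <- if (t_amp > 0) slopes < 0 else slopes > 0
  if (!any(want)) return(flagged("no return to baseline"))
  imax <- which(abs(slopes) == max(abs(slopes[want])) & want)[1]
  i_t <- limb[imax]
  slope <- slopes[imax]
  t_end <- t[i_t] + (baseline - phi[i_t]) / slope
  if (!is.finite(t_end) || t_end <= t[ipk] || t_end > win_end + 50)
    return(flagged("tangent crossing out of range"))
  list(qt_ms = t_end - q_on, rr_ms = rr, q_onset_ms = q_on, t_end_ms = t_end,
       t_peak_ms = t[ipk], flag = FALSE, reason = NA_character_)
}
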