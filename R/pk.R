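#' Synthetic pharmacokinetic specification
#'
#' One-compartment, first-order-absorption generator of unbound tolterodine
#' concentration-time profiles under twice-daily oral dosing. CYP2D6
#' polymorphism is represented by a Bernoulli extensive/poor-metaboliser
#' (EM/PM) phenotype with phenotype-specific clearance; between-subject
#' variability is lognormal on clearance. Concentrations are linear in dose.
#'
#' @param dose_mg dose per administration (mg).
#' @param interval_h dosing interval (h; 12 = BID).
#' @param n_days days of dosing (profiles are sampled after the morning dose
#'   of the last day; the default reaches steady state by day 4).
#' @param ka_per_h first-order absorption rate constant (1/h).
#' @param cl_em_L_per_h,cl_pm_L_per_h apparent clearance of extensive and poor
#'   metabolisers (L/h).
#' @param pm_fraction probability of the PM phenotype.
#' @param v_L apparent volume of distribution (L).
#' @param fu unbound fraction in plasma.
#' @param cl_cv between-subject CV of clearance (lognormal).
#' @param sample_times_h sampling times after the last morning dose (h);
#'   the default grid is pre-dose plus 0.5, 1, 2, 4, 6 and 12 h.
#' @param seed integer seed.
#' @return object of class `pk_spec`.
#' @export
pk_spec <- function(dose_mg = 2, interval_h = 12, n_days = 4,
                    ka_per_h = 3, cl_em_L_per_h = 30, cl_pm_L_per_h = 6,
                    pm_fraction = 0.07, v_L = 100, fu = 0.037,
                    cl_cv = 0.30,
                    sample_times_h = c(0, 0.5, 1, 2, 4, 6, 12),
                    seed = 1L) {
  stopifnot(dose_mg >= 0, interval_h > 0, n_days >= 1,
            ka_per_h > 0, cl_em_L_per_h > 0, cl_pm_L_per_h > 0,
            v_L > 0, fu > 0, fu <= 1, cl_cv >= 0)
  if (pm_fraction < 0 || pm_fraction > 1) stop("pm_fraction must lie in [0, 1]")
  structure(list(dose_mg = dose_mg, interval_h = interval_h, n_days = n_days,
                 ka_per_h = ka_per_h, cl_em_L_per_h = cl_em_L_per_h,
                 cl_pm_L_per_h = cl_pm_L_per_h, pm_fraction = pm_fraction,
                 v_L = v_L, fu = fu, cl_cv = cl_cv,
                 sample_times_h = sample_times_h, seed = as.integer(seed)),
            class = "pk_spec")
}

# total plasma concentration (ng/mL) by superposition of one-compartment
# first-order-absorption doses given at `dose_times_h`
.conc_1cpt <- function(t_h, dose_mg, dose_times_h, ka, cl, v) {
  k <- cl / v
  conc <- numeric(length(t_h))
  coef <- dose_mg * ka / (v * (ka - k)) # mg/L = ug/mL
  for (td in dose_times_h) {
    dtau <- t_h - td
    on <- dtau > 0
    conc[on] <- conc[on] + coef * (exp(-k * dtau[on]) - exp(-ka * dtau[on]))
  }
  conc * 1000 # ug/mL -> ng/mL
}

#' Generate synthetic unbound PK profiles
#'
#' One profile per subject: phenotype drawn Bernoulli(`pm_fraction`),
#' clearance lognormal around the phenotype mean, multiple BID dosing to the
#' morning dose of day `n_days`, sampled at `sample_times_h` after that dose.
#' Unbound concentration = total x `fu`. Deterministic given the spec seed and
#' the subject ids (per-subject counter-derived seeds).
#'
#' @param spec a [pk_spec()].
#' @param subjects list of subjects (only `id` is used).
#' @return list of profiles, each with `subject_id`, `phenotype`, `times_h`
#'   (time after the last morning dose), `conc_ng_per_mL` (unbound) and the
#'   realised `cl_L_per_h`.
#' @export
generate_pk <- function(spec = pk_spec(), subjects) {
  stopifnot(inherits(spec, "pk_spec"))
  n_doses <- 2 * (spec$n_days - 1) + 1 # through the morning dose of the last day
  dose_times <- spec$interval_h * (seq_len(n_doses) - 1)
  t_ref <- dose_times[n_doses] # last morning dose
  lapply(subjects, function(s) {
    child <- .child_seed(spec$seed, s$id, stream = 17L)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(child)
    pm <- stats::runif(1) < spec$pm_fraction
    cl_mean <- if (pm) spec$cl_pm_L_per_h else spec$cl_em_L_per_h
    cl <- cl_mean * .lnorm_from_cv(1, spec$cl_cv)
    tot <- .conc_1cpt(t_ref + spec$sample_times_h, spec$dose_mg, dose_times,
                      spec$ka_per_h, cl, spec$v_L)
    list(subject_id = s$id,
         phenotype = if (pm) "PM" else "EM",
         times_h = spec$sample_times_h,
         conc_ng_per_mL = tot * spec$fu,
         cl_L_per_h = cl)
  })
}

#' Write PK profiles to CSV
#'
#' Long format with columns `subject_id`, `time_h`, `conc_ng_per_mL`,
#' `phenotype` (unbound concentrations).
#'
#' @param profiles list of profiles from [generate_pk()].
#' @param path output CSV path.
#' @return the written data.frame, invisibly.
#' @export
write_pk_csv <- function(profiles, path) {
  out <- do.call(rbind, lapply(profiles, function(p)
    data.frame(subject_id = p$subject_id, time_h = p$times_h,
               conc_ng_per_mL = p$conc_ng_per_mL, phenotype = p$phenotype)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Load PK profiles from CSV
#'
#' Expects columns `subject_id`, `time_h`, `conc_ng_per_mL` (unbound, ng/mL)
#' and optionally `phenotype`. Times must be strictly increasing within each
#' subject. When `subjects` is supplied, profile ids must match the
#' population exactly.
#'
#' @param path CSV path.
#' @param subjects optional population to validate ids against.
#' @return list of profiles as in [generate_pk()].
#' @export
load_pk_csv <- function(path, subjects = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty PK file: ", path)
  need <- c("subject_id", "time_h", "conc_ng_per_mL")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  profiles <- lapply(split(tab, tab$subject_id), function(d) {
    d <- d[order(seq_len(nrow(d))), ]
    if (any(diff(d$time_h) <= 0))
      stop("non-monotone times for subject ", d$subject_id[1])
    if (any(d$conc_ng_per_mL < 0))
      stop("negative concentration for subject ", d$subject_id[1])
    list(subject_id = d$subject_id[1],
         phenotype = if ("phenotype" %in% names(d)) d$phenotype[1] else NA_character_,
         times_h = d$time_h, conc_ng_per_mL = d$conc_ng_per_mL,
         cl_L_per_h = NA_real_)
  })
  profiles <- unname(profiles[order(as.numeric(names(profiles)))])
  if (!is.null(subjects)) {
    pop_ids <- vapply(subjects, function(s) s$id, numeric(1))
    pk_ids <- vapply(profiles, function(p) p$subject_id, numeric(1))
    orphans <- setdiff(pk_ids, pop_ids)
    missing <- setdiff(pop_ids, pk_ids)
    if (length(orphans) || length(missing))
      stop("PK/population id mismatch; orphan profile ids: ",
           paste(orphans, collapse = ", "), "; subjects without profiles: ",
           paste(missing, collapse = ", "))
  }
  profiles
}
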