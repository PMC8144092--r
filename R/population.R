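#' Virtual population specification
#'
#' Settings of the virtual-population generator: size, sex split, age range
#' and the magnitudes of subject-level random effects. Ages are drawn
#' uniformly over \[`age_min`, `age_max`\]. Subject-level variability:
#' a lognormal multiplicative RR offset (`rr_cv`), additive normal ion
#' offsets (`ion_sd`, mM) and lognormal conductance scale factors
#' (`conductance_cv`) on GKr/GKs/Gto/GCaL.
#'
#' @param n_subjects number of subjects.
#' @param prop_female proportion of females in \[0, 1\].
#' @param age_min,age_max age bounds (years).
#' @param rr_cv coefficient of variation of the multiplicative RR offset.
#' @param ion_sd named numeric vector of SDs (mM) for the K/Na/Ca offsets.
#' @param conductance_cv CV of the lognormal conductance scale factors.
#' @param seed integer seed for the population.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 53, prop_female = 0.53,
                            age_min = 18, age_max = 49,
                            rr_cv = 0.08,
                            ion_sd = c(K = 0.35, Na = 2.0, Ca = 0.10),
                            conductance_cv = 0.15,
                            seed = 1L) {
  if (n_subjects <= 0) stop("n_subjects must be positive")
  if (prop_female < 0 || prop_female > 1) stop("prop_female must lie in [0, 1]")
  if (age_min >= age_max) stop("age_min must be smaller than age_max")
  stopifnot(rr_cv >= 0, conductance_cv >= 0, all(ion_sd >= 0),
            all(c("K", "Na", "Ca") %in% names(ion_sd)))
  structure(list(n_subjects = as.integer(n_subjects), prop_female = prop_female,
                 age_min = age_min, age_max = age_max, rr_cv = rr_cv,
                 ion_sd = ion_sd, conductance_cv = conductance_cv,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# counter-based child seed: adding subjects never reshuffles existing ones
.child_seed <- function(master, index, stream = 0L) {
  (as.integer(master) + 1000003L * as.integer(index) + 7919L * as.integer(stream)) %% 2147483647L
}

.lnorm_from_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog) # mean 1
}

#' Generate a virtual population
#'
#' Draws `n_subjects` virtual subjects: `round(n * prop_female)` females, ages
#' uniform over the configured range, and subject-level random effects (RR
#' offset, ion baseline offsets, conductance scale factors). Each subject
#' carries its own child seed derived from the population seed by a counter
#' scheme, so runs are exactly reproducible and extending the population
#' leaves existing subjects unchanged.
#'
#' @param spec a [population_spec()].
#' @return list of subjects; each subject is a list with `id`, `sex`, `age`,
#'   `rr_offset`, `ion_offsets`, `conductance_scales`, `fibre_length_cm`,
#'   `rng_seed`.
#' @export
generate_population <- function(spec = population_spec()) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_subjects
  # interleaved deterministic sex sequence: subject i is female when the
  # rounded cumulative female quota increases at i. The first round(n * p)
  # subjects of any larger population are identical, so extending a
  # population never reshuffles existing subjects.
  quota <- round(seq_len(n) * spec$prop_female)
  sexes <- ifelse(diff(c(0, quota)) > 0, "female", "male")
  subjects <- lapply(seq_len(n), function(i) {
    child <- .child_seed(spec$seed, i)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(child)
    age <- stats::runif(1, spec$age_min, spec$age_max)
    rr_offset <- .lnorm_from_cv(1, spec$rr_cv)
    ion_offsets <- c(
      K = stats::rnorm(1, 0, spec$ion_sd[["K"]]),
      Na = stats::rnorm(1, 0, spec$ion_sd[["Na"]]),
      Ca = stats::rnorm(1, 0, spec$ion_sd[["Ca"]])
    )
    gsc <- .lnorm_from_cv(4, spec$conductance_cv)
    names(gsc) <- c("IKr", "IKs", "Ito", "ICaL")
    subj <- list(id = i, sex = sexes[i], age = age,
                 rr_offset = rr_offset, ion_offsets = ion_offsets,
                 conductance_scales = gsc,
                 fibre_length_cm = NA_real_, rng_seed = child)
    assign_geometry(subj)
  })
  subjects
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Assign fibre geometry to a subject
#'
#' Deterministic fibre length from a configurable sex table; the shipped
#' default is 1.65 cm for everyone (a 165-node fibre at dx = 0.01 cm). The
#' length must be an integer multiple of the space step.
#'
#' @param subject a subject list with at least `sex`.
#' @param length_table named numeric vector `c(male = ..., female = ...)` of
#'   fibre lengths in cm.
#' @param dx_cm space step used to check that the length maps to an integer
#'   cell count.
#' @return the subject with `fibre_length_cm` filled in.
#' @export
assign_geometry <- function(subject, length_table = c(male = 1.65, female = 1.65),
                            dx_cm = 0.01) {
  stopifnot(subject$sex %in% names(length_table))
  len <- unname(length_table[[subject$sex]])
  ncell <- len / dx_cm
  if (abs(ncell - round(ncell)) > 1e-8)
    stop("fibre length ", len, " cm is not an integer multiple of dx = ", dx_cm, " cm")
  subject$fibre_length_cm <- len
  subject
}

#' Serialize a population to a data.frame / CSV
#'
#' One row per subject with all offsets, scale factors and seeds, so any run
#' is exactly reconstructable.
#'
#' @param population list of subjects.
#' @param path optional CSV path; when given the table is written there.
#' @return data.frame (invisibly when `path` is given).
#' @export
population_table <- function(population, path = NULL) {
  out <- do.call(rbind, lapply(population, function(s) {
    data.frame(id = s$id, sex = s$sex, age = s$age, rr_offset = s$rr_offset,
               k_offset = s$ion_offsets[["K"]], na_offset = s$ion_offsets[["Na"]],
               ca_offset = s$ion_offsets[["Ca"]],
               gkr_scale = s$conductance_scales[["IKr"]],
               gks_scale = s$conductance_scales[["IKs"]],
               gto_scale = s$conductance_scales[["Ito"]],
               gcal_scale = s$conductance_scales[["ICaL"]],
               fibre_length_cm = s$fibre_length_cm, rng_seed = s$rng_seed)
  }))
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
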