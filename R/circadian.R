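#' Circadian RR-interval regression coefficients
#'
#' Coefficients of the multivariate regression of log RR (RR in ms, natural
#' log) on sex, age and clock time: intercept, sex effect (1 = male,
#' 0 = female), linear and quadratic age effects, 24-h sine/cosine terms and
#' their sex interactions.
#'
#' @return named numeric vector of the eight coefficients.
#' @export
circadian_rr_params <- function() {
  c(intercept = 7.163, sex_coef = 0.0961, age_coef = -0.0243,
    age2_coef = 0.00027, sin_coef = 0.1055, cos_coef = 0.0664,
    sin_sex_coef = -0.0155, cos_sex_coef = 0.0608)
}

#' Cosinor parameters of the plasma-electrolyte circadian models
#'
#' Sex-specific 24-h mean (MESOR), amplitude and acrophase (clock time of the
#' peak, decimal hours) of plasma potassium, sodium and calcium. Calcium
#' carries no circadian term (amplitude 0): the model returns the sex mean.
#'
#' @param ion one of `"K"`, `"Na"`, `"Ca"`.
#' @return list with `ion_id`, `mean_female`, `mean_male` (mM), `amplitude`
#'   (mM) and `acrophase` (decimal clock hours).
#' @export
circadian_ion_params <- function(ion = c("K", "Na", "Ca")) {
  ion <- match.arg(ion)
  switch(ion,
    K = list(ion_id = "K", mean_female = 4.088, mean_male = 4.213,
             amplitude = 0.18, acrophase = 10 + 7 / 60),
    Na = list(ion_id = "Na", mean_female = 138.169, mean_male = 140.096,
              amplitude = 1.1, acrophase = 13 + 8 / 60),
    Ca = list(ion_id = "Ca", mean_female = 2.313, mean_male = 2.418,
              amplitude = 0, acrophase = 0)
  )
}

.check_sex <- function(sex) {
  if (!is.character(sex) || !sex %in% c("male", "female"))
    stop("sex must be \"male\" or \"female\"")
  sex
}

#' Mean RR interval at a clock hour
#'
#' Evaluates the circadian RR regression: `exp()` of a linear predictor in
#' sex (1 = male, 0 = female), age, age squared and 24-h sine/cosine terms
#' with sex interactions. RR is returned in ms.
#'
#' @param sex `"male"` or `"female"`.
#' @param age age in years (warns outside 18--100, errors when negative).
#' @param hour clock time in decimal hours, 0--24.
#' @param params coefficient vector, see [circadian_rr_params()].
#' @return RR interval in ms.
#' @export
mean_rr <- function(sex, age, hour, params = circadian_rr_params()) {
  .check_sex(sex)
  if (any(age < 0)) stop("age must be non-negative")
  if (any(age < 18) || any(age > 100))
    warning("age outside the 18-100 y range the regression was built for")
  if (any(hour < 0) || any(hour > 24)) stop("hour must lie in [0, 24]")
  s <- as.numeric(sex == "male")
  w <- 2 * pi / 24 * hour
  lp <- params[["intercept"]] +
    params[["sex_coef"]] * s +
    params[["age_coef"]] * age +
    params[["age2_coef"]] * age^2 +
    params[["sin_coef"]] * sin(w) +
    params[["cos_coef"]] * cos(w) +
    params[["sin_sex_coef"]] * sin(w) * s +
    params[["cos_sex_coef"]] * cos(w) * s
  unname(exp(lp))
}

#' Plasma ion concentration at a clock hour
#'
#' Cosinor evaluation: sex mean + subject offset +
#' amplitude * cos(2*pi/24 * (hour - acrophase)). Calcium has amplitude 0 and
#' therefore no diurnal variation.
#'
#' @param ion `"K"`, `"Na"` or `"Ca"`.
#' @param sex `"male"` or `"female"`.
#' @param hour clock time in decimal hours, 0--24.
#' @param params cosinor parameter list, see [circadian_ion_params()].
#' @param subject_offset additive subject-level offset (mM).
#' @return concentration in mM.
#' @export
ion_concentration <- function(ion, sex, hour, params = circadian_ion_params(ion),
                              subject_offset = 0) {
  if (!ion %in% c("K", "Na", "Ca")) stop("unknown ion id: ", ion)
  .check_sex(sex)
  if (any(hour < 0) || any(hour > 24)) stop("hour must lie in [0, 24]")
  m <- if (sex == "male") params$mean_male else params$mean_female
  m + subject_offset + params$amplitude * cos(2 * pi / 24 * (hour - params$acrophase))
}

#' Hourly circadian state profile for one subject
#'
#' Assembles the RR and electrolyte circadian models into per-hour states for
#' a subject. The subject's multiplicative RR offset and additive ion offsets
#' (mM) are applied. With `circadian = FALSE` every requested hour returns the
#' hour-0 values (constant-model degenerate case); `ions_circadian = FALSE`
#' freezes only the electrolytes at their subject-specific 24-h mean while RR
#' keeps its diurnal course.
#'
#' @param subject a subject from [generate_population()] (or any list with
#'   `sex`, `age`, `rr_offset`, `ion_offsets`).
#' @param hours numeric vector of clock hours.
#' @param circadian master switch for all diurnal variation.
#' @param ions_circadian switch for the electrolyte cosinor terms only.
#' @return data.frame with columns `hour`, `rr_ms`, `k_mM`, `na_mM`, `ca_mM`.
#' @export
circadian_profile <- function(subject, hours = 0:23, circadian = TRUE,
                              ions_circadian = TRUE) {
  stopifnot(!is.null(subject$sex), !is.null(subject$age))
  rr_off <- if (is.null(subject$rr_offset)) 1 else subject$rr_offset
  ioff <- subject$ion_offsets
  if (is.null(ioff)) ioff <- c(K = 0, Na = 0, Ca = 0)
  eval_hours <- if (circadian) hours else rep(0, length(hours))
  rr <- rr_off * mean_rr(subject$sex, subject$age, eval_hours)
  one_ion <- function(ion) {
    if (circadian && ions_circadian) {
      vapply(eval_hours, function(h)
        ion_concentration(ion, subject$sex, h, subject_offset = ioff[[ion]]),
        numeric(1))
    } else {
      p <- circadian_ion_params(ion)
      m <- if (subject$sex == "male") p$mean_male else p$mean_female
      rep(m + ioff[[ion]], length(hours))
    }
  }
  out <- data.frame(hour = hours, rr_ms = rr,
                    k_mM = one_ion("K"), na_mM = one_ion("Na"),
                    ca_mM = one_ion("Ca"))
  stopifnot(all(out$rr_ms > 0), all(out$k_mM > 0), all(out$na_mM > 0),
            all(out$ca_mM > 0))
  out
}

#' Write hourly circadian profiles to CSV
#'
#' One row per subject-hour with columns `subject_id`, `hour`, `rr_ms`,
#' `k_mM`, `na_mM`, `ca_mM`.
#'
#' @param population list of subjects from [generate_population()].
#' @param path output CSV path.
#' @param hours clock hours to evaluate.
#' @param ... passed to [circadian_profile()].
#' @return the written data.frame, invisibly.
#' @export
write_circadian_csv <- function(population, path, hours = 0:23, ...) {
  rows <- lapply(population, function(s) {
    prof <- circadian_profile(s, hours = hours, ...)
    cbind(subject_id = s$id, prof)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
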