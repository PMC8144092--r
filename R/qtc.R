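#' Heart-rate corrected QT
#'
#' `QTc = QT / RR^n` with RR in seconds, so that QTc(RR = 1 s) = QT for any
#' exponent. Fixed exponents: Fridericia n = 1/3, Bazett n = 1/2; fitted
#' exponents come from [fit_qtc_exponent()].
#'
#' @param qt_ms QT interval (ms).
#' @param rr_s RR interval (seconds), positive.
#' @param n correction exponent.
#' @return corrected QT in ms.
#' @export
qtc <- function(qt_ms, rr_s, n = 1 / 3) {
  if (any(rr_s <= 0)) stop("rr_s must be positive")
  qt_ms / rr_s^n
}

#' Fit a QT correction exponent
#'
#' Ordinary least squares of log(QT) on log(RR) (RR in seconds): the slope is
#' the correction exponent n. `scope = "individual"` fits one exponent per
#' subject (QTcI); `scope = "pooled"` fits a single study-specific exponent
#' (QTcS) on all rows.
#'
#' @param qt_ms QT intervals (ms).
#' @param rr_s RR intervals (seconds).
#' @param subject_id subject labels; required for `scope = "individual"`.
#' @param scope `"individual"` or `"pooled"`.
#' @return object of class `qtc_fit` with the kind, scope and exponent(s).
#' @export
fit_qtc_exponent <- function(qt_ms, rr_s, subject_id = NULL,
                             scope = c("pooled", "individual")) {
  scope <- match.arg(scope)
  stopifnot(length(qt_ms) == length(rr_s), all(rr_s > 0), all(qt_ms > 0))
  fit_one <- function(qt, rr) {
    if (length(qt) < 3) stop("need at least 3 points to fit an exponent")
    if (diff(range(rr)) < 1e-12) stop("degenerate fit: RR is constant")
    stats::coef(stats::lm(log(qt) ~ log(rr)))
  }
  if (scope == "pooled") {
    cf <- fit_one(qt_ms, rr_s)
    out <- list(kind = "study_specific", scope = scope,
                exponent = unname(cf[2]), intercept = unname(cf[1]))
  } else {
    if (is.null(subject_id)) stop("subject_id is required for individual fits")
    sp <- split(seq_along(qt_ms), subject_id)
    fits <- lapply(sp, function(idx) fit_one(qt_ms[idx], rr_s[idx]))
    out <- list(kind = "individual", scope = scope,
                exponent = vapply(fits, function(cf) unname(cf[2]), numeric(1)),
                intercept = vapply(fits, function(cf) unname(cf[1]), numeric(1)))
  }
  structure(out, class = "qtc_fit")
}

#' @export
print.qtc_fit <- function(x, ...) {
  cat("QT correction exponent fit (", x$kind, ")\n", sep = "")
  if (x$scope == "pooled") {
    cat(sprintf("  n = %.4f\n", x$exponent))
  } else {
    cat(sprintf("  %d subjects; n: median %.4f, range [%.4f, %.4f]\n",
                length(x$exponent), stats::median(x$exponent),
                min(x$exponent), max(x$exponent)))
  }
  invisible(x)
}

#' @export
coef.qtc_fit <- function(object, ...) object$exponent

#' Apply a fitted correction
#'
#' @param object a `qtc_fit`.
#' @param qt_ms,rr_s intervals to correct.
#' @param subject_id subject labels (individual fits only).
#' @param ... unused.
#' @return corrected QT in ms.
#' @export
predict.qtc_fit <- function(object, qt_ms, rr_s, subject_id = NULL, ...) {
  if (object$scope == "pooled") {
    qtc(qt_ms, rr_s, object$exponent)
  } else {
    if (is.null(subject_id)) stop("subject_id is required for individual fits")
    n <- object$exponent[as.character(subject_id)]
    if (anyNA(n)) stop("unknown subject id(s) in prediction")
    qtc(qt_ms, rr_s, unname(n))
  }
}

#' Time-matched change in QTc from baseline
#'
#' Pairs drug-arm and baseline rows of the same subject at the same protocol
#' time and returns their QTc difference. Because the baseline is the
#' drug-free situation, this time-matched difference plays the role of the
#' placebo-adjusted change from baseline in a thorough-QT analysis. Unmatched
#' time points are dropped with a count in the `n_unmatched` attribute.
#'
#' @param series data.frame with columns `subject_id`, `time`, `arm`
#'   (`"baseline"` or `"drug"`) and `qtc_ms`.
#' @return data.frame with `subject_id`, `time`, `delta_qtc_ms`.
#' @export
delta_qtc <- function(series) {
  need <- c("subject_id", "time", "arm", "qtc_ms")
  miss <- setdiff(need, names(series))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  base <- series[series$arm == "baseline", ]
  drug <- series[series$arm == "drug", ]
  m <- merge(drug[, c("subject_id", "time", "qtc_ms")],
             base[, c("subject_id", "time", "qtc_ms")],
             by = c("subject_id", "time"), suffixes = c("_drug", "_base"))
  n_unmatched <- (nrow(drug) - nrow(m)) + (nrow(base) - nrow(m))
  out <- data.frame(subject_id = m$subject_id, time = m$time,
                    delta_qtc_ms = m$qtc_ms_drug - m$qtc_ms_base)
  out <- out[order(out$subject_id, out$time), ]
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Trial summary of QTc changes
#'
#' Mean, standard error (SD/sqrt(n)) and the upper limit of the two-sided 95%
#' confidence interval (mean + 1.96 SE) of per-subject QTc changes.
#'
#' @param deltas numeric vector of per-subject changes (ms).
#' @return list with `mean_ms`, `se_ms`, `ci95_upper_ms`, `n_valid`.
#' @export
summarize_trial <- function(deltas) {
  deltas <- deltas[is.finite(deltas)]
  n <- length(deltas)
  if (n < 2) stop("need at least 2 valid values to summarise")
  m <- mean(deltas)
  se <- stats::sd(deltas) / sqrt(n)
  list(mean_ms = m, se_ms = se, ci95_upper_ms = m + 1.96 * se, n_valid = n)
}
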