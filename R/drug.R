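#' Channel affinity
#'
#' IC50 (uM) and Hill coefficient of a drug against one cardiac ion current.
#'
#' @param current_id one of `"IKr"`, `"IKs"`, `"INa"`, `"ICaL"`.
#' @param ic50_uM half-maximal inhibitory concentration (uM, unbound).
#' @param hill_coef Hill coefficient.
#' @return list of class `channel_affinity`.
#' @export
channel_affinity <- function(current_id, ic50_uM, hill_coef = 1) {
  if (!current_id %in% c("IKr", "IKs", "INa", "ICaL"))
    stop("unknown current id: ", current_id)
  if (ic50_uM <= 0) stop("ic50_uM must be positive")
  if (hill_coef <= 0) stop("hill_coef must be positive")
  structure(list(current_id = current_id, ic50_uM = ic50_uM,
                 hill_coef = hill_coef),
            class = "channel_affinity")
}

#' Tolterodine channel affinities
#'
#' In-vitro inhibitory potencies of tolterodine against the four main cardiac
#' ion currents (HEK/CHO patch-clamp data): IKr IC50 0.0096 uM (Hill 1.09),
#' IKs 79.43 uM, INa 19.12 uM, ICaL 25.12 uM (Hill 1 each). No temperature
#' correction is applied to the room-temperature values.
#'
#' @return list of [channel_affinity()] objects.
#' @export
tolterodine_affinities <- function() {
  list(channel_affinity("IKr", 0.0096, 1.09),
       channel_affinity("IKs", 79.43, 1),
       channel_affinity("INa", 19.12, 1),
       channel_affinity("ICaL", 25.12, 1))
}

#' Fractional channel inhibition (Hill equation)
#'
#' `conc^h / (ic50^h + conc^h)`: 0 at zero concentration, 0.5 at the IC50.
#'
#' @param conc_uM unbound drug concentration (uM), non-negative.
#' @param affinity a [channel_affinity()].
#' @return inhibited fraction in \[0, 1\].
#' @export
fractional_inhibition <- function(conc_uM, affinity) {
  stopifnot(inherits(affinity, "channel_affinity"))
  if (any(conc_uM < 0)) stop("concentration must be non-negative")
  ch <- conc_uM^affinity$hill_coef
  ch / (affinity$ic50_uM^affinity$hill_coef + ch)
}

#' Concentration at a given inhibited fraction
#'
#' Closed-form inverse of the Hill equation:
#' `ic50 * (f / (1 - f))^(1/h)`. At `f = 0.5` this recovers the IC50.
#'
#' @param fraction inhibited fraction in (0, 1).
#' @param affinity a [channel_affinity()].
#' @return concentration in uM.
#' @export
inhibition_to_conc <- function(fraction, affinity) {
  stopifnot(inherits(affinity, "channel_affinity"))
  if (any(fraction <= 0) || any(fraction >= 1))
    stop("fraction must lie strictly inside (0, 1)")
  affinity$ic50_uM * (fraction / (1 - fraction))^(1 / affinity$hill_coef)
}

#' Simple pore-block conductance scaling
#'
#' Static scale factor per current: `1 - inhibition` at the given unbound
#' concentration. Currents without a listed affinity are untouched. No
#' state-dependent or trapping kinetics are modelled.
#'
#' @param conc_uM unbound drug concentration (uM).
#' @param affinities list of [channel_affinity()] objects, one per current.
#' @return named numeric vector of conductance scale factors in \[0, 1\].
#' @export
block_profile <- function(conc_uM, affinities = tolterodine_affinities()) {
  ids <- vapply(affinities, function(a) a$current_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate current id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  scales <- vapply(affinities, function(a) 1 - fractional_inhibition(conc_uM, a),
                   numeric(1))
  names(scales) <- ids
  scales
}

#' Convert ng/mL to uM
#'
#' @param x concentration in ng/mL.
#' @param mw molecular weight in g/mol (default: tolterodine, 325.49).
#' @return concentration in uM.
#' @export
ngml_to_uM <- function(x, mw = 325.49) {
  stopifnot(mw > 0)
  x / mw
}

#' Load channel affinities from a CSV table
#'
#' Columns: `current_id`, `ic50_uM`, `hill_coef` (an optional `source` column
#' is carried along but unused).
#'
#' @param path CSV path.
#' @return list of [channel_affinity()] objects.
#' @export
load_affinities_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("current_id", "ic50_uM", "hill_coef")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i)
    channel_affinity(tab$current_id[i], tab$ic50_uM[i], tab$hill_coef[i]))
}
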