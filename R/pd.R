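#' Classify battery items for process dissociation
#'
#' Process dissociation uses only the proscriptive-norm dilemmas:
#' those whose action benefits exceed its costs pit the utilitarian and
#' deontological principles against each other (incongruent), those whose
#' costs exceed the benefits align them (congruent). Prescriptive items are
#' excluded.
#'
#' @param battery a `cni_battery` (or data.frame accepted by
#'   [validate_battery()]).
#' @return factor with levels `congruent`, `incongruent`, `excluded`, one
#'   entry per item.
#' @export
pd_congruence <- function(battery) {
  battery <- validate_battery(battery)
  out <- ifelse(battery$norm != "proscriptive", "excluded",
                ifelse(battery$consequences == "benefits_exceed_costs",
                       "incongruent", "congruent"))
  factor(out, levels = c("congruent", "incongruent", "excluded"))
}

#' Process-dissociation parameters from unacceptability proportions
#'
#' Decomposes a participant's proportions of "unacceptable" judgments on
#' congruent and incongruent proscriptive dilemmas into a utilitarian
#' inclination `U = p_unacc_congruent - p_unacc_incongruent` and a
#' deontological inclination `D = p_unacc_incongruent / (1 - U)`. When
#' `U == 1` (all incongruent actions accepted, all congruent rejected) `D`
#' is undefined and returned as `NA`.
#'
#' @param p_unacc_cong,p_unacc_incong proportions in \[0, 1\].
#' @return named vector `c(U=, D=)`; `D` is `NA` when undefined.
#' @examples
#' pd_parameters(0.7, 0.4)   # U = 0.3, D = 4/7
#' @export
pd_parameters <- function(p_unacc_cong, p_unacc_incong) {
  stopifnot_prob(p_unacc_cong, "p_unacc_cong")
  stopifnot_prob(p_unacc_incong, "p_unacc_incong")
  U <- p_unacc_cong - p_unacc_incong
  D <- ifelse(U < 1, p_unacc_incong / (1 - U), NA_real_)
  c(U = unname(U), D = unname(D))
}

#' Per-participant process-dissociation scores
#'
#' Computes, for every participant with at least one congruent and one
#' incongruent response, the unacceptability proportions (1 - mean response,
#' since responses code action acceptance), the U and D parameters, and
#' their standardized versions `U_z`, `D_z` (mean 0, sample-SD 1 over the
#' participants with defined values). Participants with undefined `D`
#' (`U == 1`) keep their `U` but are dropped from the `D` standardization
#' pool; out-of-range `D` values from noisy proportions are retained, not
#' clipped, as the downstream regressions expect unbiased inputs.
#'
#' @param data a `cni_data` object.
#' @return data.frame of class `pd_scores`: `participant_id`,
#'   `p_unacc_cong`, `p_unacc_incong`, `U`, `D`, `U_z`, `D_z`,
#'   `d_defined`.
#' @export
pd_scores <- function(data) {
  stopifnot(inherits(data, "cni_data"))
  cong <- pd_congruence(data$battery)
  cls <- cong[match(data$responses$item_id, data$battery$item_id)]
  r <- data$responses[cls != "excluded", ]
  cls <- cls[cls != "excluded"]
  ids <- data$participants$participant_id
  fp <- factor(r$participant_id, levels = ids)
  mean_by <- function(keep) {
    s <- tapply(r$response[keep], fp[keep], mean)
    as.vector(s[ids])
  }
  p_cong <- 1 - mean_by(cls == "congruent")
  p_incong <- 1 - mean_by(cls == "incongruent")
  usable <- is.finite(p_cong) & is.finite(p_incong)
  if (any(!usable))
    warning(sprintf("%d participant(s) without both congruent and incongruent responses were excluded",
                    sum(!usable)))
  out <- data.frame(participant_id = ids[usable],
                    p_unacc_cong = p_cong[usable],
                    p_unacc_incong = p_incong[usable],
                    stringsAsFactors = FALSE)
  out$U <- out$p_unacc_cong - out$p_unacc_incong
  out$d_defined <- out$U < 1
  out$D <- ifelse(out$d_defined, out$p_unacc_incong / (1 - out$U), NA_real_)
  out$U_z <- zscore(out$U)
  out$D_z <- NA_real_
  out$D_z[out$d_defined] <- zscore(out$D[out$d_defined])
  class(out) <- c("pd_scores", "data.frame")
  out
}
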