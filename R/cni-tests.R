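#' Test a CNI parameter against a reference value
#'
#' Nested likelihood-ratio test: refits the model with the parameter fixed at
#' the reference value (in every group) and reports
#' `deltaG2 = G2(constrained) - G2(unconstrained)` on 1 df per constrained
#' group. Typical uses are testing C or N against 0 (no sensitivity) and I
#' against its neutral point 0.5 (no action/inaction asymmetry).
#'
#' @param data a `cni_counts` table, `cni_data`, or an unconstrained
#'   `cni_fit` (its counts are reused).
#' @param parameter one of `"C"`, `"N"`, `"I"`.
#' @param reference value in \[0, 1\] to test against.
#' @param ... passed to [cni_fit()].
#' @return object of class `cni_test`: list with `statistic`, `df`,
#'   `p.value`, and the two fits.
#' @export
cni_test_reference <- function(data, parameter = c("C", "N", "I"), reference,
                               ...) {
  parameter <- match.arg(parameter)
  if (reference < 0 || reference > 1) mc_stop("reference must lie in [0, 1]")
  if (inherits(data, "cni_fit")) {
    free <- data
    counts <- data$counts
  } else {
    counts <- data
    free <- cni_fit(counts, ...)
  }
  constrained <- cni_fit(counts, fixed = stats::setNames(reference, parameter),
                         equal = free$equal, ...)
  df <- constrained$df - free$df
  stat <- max(0, constrained$G2 - free$G2)
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 parameter = parameter, reference = reference,
                 free = free, constrained = constrained,
                 label = sprintf("%s = %g", parameter, reference)),
            class = "cni_test")
}

#' Test equality of a CNI parameter between two groups
#'
#' Nested likelihood-ratio test comparing the two-group fit with all
#' parameters free against the fit with one parameter constrained equal
#' across groups; `deltaG2` on 1 df.
#'
#' @param data a `cni_counts` table with exactly two groups (or a `cni_data`
#'   plus `group`).
#' @param parameter one of `"C"`, `"N"`, `"I"`.
#' @param group passed to [cni_counts()] when `data` is a `cni_data`.
#' @param ... passed to [cni_fit()].
#' @return object of class `cni_test`.
#' @export
cni_test_equality <- function(data, parameter = c("C", "N", "I"),
                              group = NULL, ...) {
  parameter <- match.arg(parameter)
  counts <- if (inherits(data, "cni_data")) cni_counts(data, group) else data
  if (length(unique(counts$group)) != 2L)
    mc_stop("group-equality test requires exactly two groups")
  free <- cni_fit(counts, ...)
  constrained <- cni_fit(counts, equal = parameter, ...)
  stat <- max(0, constrained$G2 - free$G2)
  df <- constrained$df - free$df
  structure(list(statistic = stat, df = df,
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 parameter = parameter, reference = NULL,
                 free = free, constrained = constrained,
                 label = sprintf("%s equal across groups", parameter)),
            class = "cni_test")
}

#' @export
print.cni_test <- function(x, ...) {
  cat(sprintf("CNI likelihood-ratio test: %s\n", x$label))
  cat(sprintf("deltaG2(%d) = %.3f, p = %s\n", x$df, x$statistic,
              format.pval(x$p.value, digits = 3)))
  invisible(x)
}
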