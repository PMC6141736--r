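#' @keywords internal
"_PACKAGE"

# Canonical cell order used everywhere in the package. A single fixed order
# (proscriptive/benefits>costs, proscriptive/benefits<costs,
#  prescriptive/benefits>costs, prescriptive/benefits<costs)
# prevents silent cell-permutation bugs between the generator, the count
# aggregator and the likelihood.
.cni_cells <- data.frame(
  cell = 1:4,
  norm = c("proscriptive", "proscriptive", "prescriptive", "prescriptive"),
  consequences = c("benefits_exceed_costs", "costs_exceed_benefits",
                   "benefits_exceed_costs", "costs_exceed_benefits"),
  stringsAsFactors = FALSE
)

.norm_levels <- c("proscriptive", "prescriptive")
.cons_levels <- c("benefits_exceed_costs", "costs_exceed_benefits")

#' @noRd
cell_index <- function(norm, consequences) {
  ifelse(norm == "proscriptive",
         ifelse(consequences == "benefits_exceed_costs", 1L, 2L),
         ifelse(consequences == "benefits_exceed_costs", 3L, 4L))
}

cell_label <- function(cell) {
  paste0(.cni_cells$norm[cell], "/", .cni_cells$consequences[cell])
}

# Typed validation errors: every malformed input raises a condition with
# class "moralcni_validation_error", never a partial dataset.
mc_stop <- function(msg, class = "moralcni_validation_error") {
  stop(errorCondition(msg, class = c(class, "moralcni_error", "error", "condition")))
}

stopifnot_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    mc_stop(sprintf("'%s' must lie in [0, 1]", name))
  invisible(x)
}

# sample z-scores with sample (n-1) SD; ties the PD and regression modules
# to a single standardization convention
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) mc_stop("cannot standardize a constant column")
  (x - mean(x)) / s
}
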