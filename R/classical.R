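#' Traditional moral-choice scores
#'
#' Counts each participant's action ("yes") judgments on the six incongruent
#' items (proscriptive norm, benefits exceed costs) — the only form the
#' traditional dilemma approach scores. The score runs 0-6 with neutral
#' reference point 3; higher values mean more utilitarian choices.
#'
#' @param data a `cni_data` object.
#' @return data.frame with `participant_id`, `score` (0-6), `n_items`, and
#'   `complete` (answered all six incongruent items).
#' @export
choice_scores <- function(data) {
  stopifnot(inherits(data, "cni_data"))
  cong <- pd_congruence(data$battery)
  inc_items <- data$battery$item_id[cong == "incongruent"]
  r <- data$responses[data$responses$item_id %in% inc_items, ]
  ids <- data$participants$participant_id
  fp <- factor(r$participant_id, levels = ids)
  score <- tapply(r$response, fp, sum, default = NA_integer_)
  n <- tapply(r$response, fp, length, default = 0L)
  out <- data.frame(participant_id = ids,
                    score = as.integer(score[ids]),
                    n_items = as.integer(n[ids]),
                    stringsAsFactors = FALSE)
  out$complete <- out$n_items == length(inc_items)
  if (any(!out$complete))
    warning(sprintf("%d participant(s) with missing incongruent items flagged",
                    sum(!out$complete)))
  out
}

#' One-sample t-test with Cohen's d
#'
#' Classical one-sample t against a reference value, with the standardized
#' effect size `d = |mean - mu| / sd`.
#'
#' @param values numeric vector, `n >= 2`, non-constant.
#' @param mu reference value.
#' @return list with `t`, `df`, `p.value`, `mean`, `sd`, `cohen_d`.
#' @export
one_sample_t <- function(values, mu = 0) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) mc_stop("one_sample_t needs at least two values")
  s <- stats::sd(values)
  if (s == 0) mc_stop("one_sample_t: zero variance")
  tt <- stats::t.test(values, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean = mean(values), sd = s,
       cohen_d = abs(mean(values) - mu) / s)
}

#' Pearson correlation with two-tailed p-value
#'
#' @param x,y equal-length numeric vectors (`n >= 3`), non-constant.
#' @return list with `r`, `n`, `df`, `p.value`.
#' @export
pearson_r <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) mc_stop("pearson_r needs at least three complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    mc_stop("pearson_r: degenerate variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), n = length(x),
       df = unname(ct$parameter), p.value = ct$p.value)
}

#' Hierarchical (blockwise) multiple regression with standardized betas
#'
#' Fits ordinary least squares on cumulative predictor blocks and reports
#' standardized coefficients, R-squared, the R-squared change over the
#' previous block, and the F test of that change
#' (`F = (deltaR2/q) / ((1 - R2_full)/(n - k - 1))`). The outcome and all
#' predictors — including 0/1 dummies — are z-scored before fitting, which
#' matches the "Beta" column convention of common statistics packages.
#'
#' @param df data.frame holding outcome and predictors.
#' @param outcome name of the outcome column.
#' @param blocks list of character vectors; block k is added to blocks
#'   1..k-1.
#' @return object of class `hier_reg`: per-block list with `beta`, `r2`,
#'   `delta_r2`, `f_change`, `df1`, `df2`, `p_change`; plus `n`.
#' @export
hierarchical_regression <- function(df, outcome, blocks) {
  vars <- c(outcome, unique(unlist(blocks)))
  if (!all(vars %in% names(df)))
    mc_stop(paste("missing columns:", paste(setdiff(vars, names(df)), collapse = ", ")))
  d <- df[stats::complete.cases(df[, vars]), vars, drop = FALSE]
  n <- nrow(d)
  k_total <- length(unique(unlist(blocks)))
  if (n <= k_total + 1L) mc_stop("too few observations for the predictor count")
  z <- as.data.frame(lapply(d, zscore))
  r2_prev <- 0
  out <- vector("list", length(blocks))
  cum <- character(0)
  for (b in seq_along(blocks)) {
    cum <- unique(c(cum, blocks[[b]]))
    X <- as.matrix(z[, cum, drop = FALSE])
    if (qr(cbind(1, X))$rank < ncol(X) + 1L)
      mc_stop(paste("rank-deficient design in block", b, "- collinear columns among:",
                    paste(cum, collapse = ", ")))
    fit <- stats::lm(z[[outcome]] ~ X)
    r2 <- summary(fit)$r.squared
    q <- length(blocks[[b]])
    df2 <- n - length(cum) - 1L
    dr2 <- r2 - r2_prev
    f <- (dr2 / q) / ((1 - r2) / df2)
    out[[b]] <- list(predictors = cum,
                     beta = stats::setNames(stats::coef(fit)[-1], cum),
                     r2 = r2, delta_r2 = dr2,
                     f_change = f, df1 = q, df2 = df2,
                     p_change = stats::pf(f, q, df2, lower.tail = FALSE))
    r2_prev <- r2
  }
  structure(list(blocks = out, outcome = outcome, n = n), class = "hier_reg")
}

.sig_mark <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ifelse(p < 0.10, "#", "")))
}

#' @export
print.hier_reg <- function(x, digits = 3, ...) {
  cat(sprintf("Hierarchical regression of %s (n = %d)\n", x$outcome, x$n))
  for (b in seq_along(x$blocks)) {
    bl <- x$blocks[[b]]
    cat(sprintf("Block %d: %s\n", b, paste(bl$predictors, collapse = " + ")))
    for (v in names(bl$beta))
      cat(sprintf("  beta[%s] = %.*f\n", v, digits, bl$beta[[v]]))
    cat(sprintf("  R2 = %.*f, deltaR2 = %.*f%s (F(%d, %d) = %.*f, p = %.3g)\n",
                digits, bl$r2, digits, bl$delta_r2, .sig_mark(bl$p_change),
                bl$df1, bl$df2, digits, bl$f_change, bl$p_change))
  }
  invisible(x)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of totals)` with
#' sample variances.
#'
#' @param item_matrix numeric matrix, participants in rows, items in
#'   columns; at least 2 of each.
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (nrow(m) < 2L || ncol(m) < 2L)
    mc_stop("cronbach_alpha needs at least 2 participants and 2 items")
  k <- ncol(m)
  vt <- stats::var(rowSums(m))
  if (vt == 0) mc_stop("cronbach_alpha: zero total-score variance")
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / vt)
}

#' Median split of a continuous score
#'
#' Dichotomizes scores at the sample median: strictly above the median goes
#' to the `high` group, at or below to the `low` group (with integer scores
#' the at-median ties make the low group the larger one). The tie rule is
#' configurable.
#'
#' @param scores numeric vector; if named, names are carried through.
#' @param ties_high if `TRUE`, at-median values go to the high group
#'   instead.
#' @return object of class `median_split`: `median`, `assignment` (factor
#'   `low`/`high`), `sizes`, `means`, `sds`.
#' @export
median_split <- function(scores, ties_high = FALSE) {
  if (length(scores) < 2L) mc_stop("median_split needs at least two scores")
  if (length(unique(scores)) == 1L) mc_stop("median split degenerate: all values identical")
  med <- stats::median(scores)
  high <- if (ties_high) scores >= med else scores > med
  assignment <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  names(assignment) <- names(scores)
  structure(list(median = med, assignment = assignment,
                 sizes = table(assignment),
                 means = tapply(scores, assignment, mean),
                 sds = tapply(scores, assignment, stats::sd)),
            class = "median_split")
}

#' @export
print.median_split <- function(x, ...) {
  cat(sprintf("Median split at %g\n", x$median))
  for (g in c("high", "low"))
    cat(sprintf("  %s: n = %d, M = %.2f, SD = %.2f\n", g, x$sizes[[g]],
                x$means[[g]], x$sds[[g]]))
  invisible(x)
}
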