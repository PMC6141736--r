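#' @export
print.cni_fit <- function(x, digits = 3, ...) {
  G <- nrow(x$coefficients)
  cat("CNI model fit (maximum likelihood, pooled counts)\n")
  if (length(x$fixed))
    cat("  fixed:", paste(names(x$fixed), "=", format(x$fixed), collapse = ", "), "\n")
  if (length(x$equal))
    cat("  equal across groups:", paste(x$equal, collapse = ", "), "\n")
  for (gi in seq_len(G)) {
    if (G > 1 || x$groups[gi] != "all") cat("Group:", x$groups[gi], "\n")
    est <- x$coefficients[gi, ]
    lo <- x$ci[gi, , 1]; hi <- x$ci[gi, , 2]
    for (j in 1:3)
      cat(sprintf("  %s = %.*f  [%.*f, %.*f]%s\n", c("C", "N", "I")[j],
                  digits, est[j], digits, lo[j], digits, hi[j],
                  if (isTRUE(x$boundary[gi, j])) " (boundary)" else ""))
  }
  cat(sprintf("G2(%d) = %.3f, p = %s\n", x$df, x$G2,
              if (is.na(x$p.value)) "NA" else format.pval(x$p.value, digits = 3)))
  invisible(x)
}

#' @export
summary.cni_fit <- function(object, ...) {
  G <- nrow(object$coefficients)
  tab <- do.call(rbind, lapply(seq_len(G), function(gi) {
    data.frame(group = object$groups[gi], parameter = c("C", "N", "I"),
               estimate = object$coefficients[gi, ],
               se = object$se[gi, ],
               ci_lower = object$ci[gi, , 1], ci_upper = object$ci[gi, , 2],
               boundary = object$boundary[gi, ], row.names = NULL)
  }))
  out <- list(parameters = tab, G2 = object$G2, df = object$df,
              p.value = object$p.value, logLik = object$logLik)
  class(out) <- "summary.cni_fit"
  out
}

#' @export
print.summary.cni_fit <- function(x, ...) {
  print(x$parameters, row.names = FALSE, digits = 4)
  cat(sprintf("G2(%d) = %.3f, p = %s; logLik = %.3f\n", x$df, x$G2,
              if (is.na(x$p.value)) "NA" else format.pval(x$p.value, digits = 3),
              x$logLik))
  invisible(x)
}

#' @export
coef.cni_fit <- function(object, ...) {
  co <- object$coefficients
  if (nrow(co) == 1L) co[1, ] else co
}

#' @export
logLik.cni_fit <- function(object, ...) {
  structure(object$logLik, df = object$layout$n_free, class = "logLik")
}

#' @export
vcov.cni_fit <- function(object, ...) object$vcov

#' Confidence intervals for CNI parameters
#'
#' Wald intervals (default) come from the observed information at the MLE.
#' Profile-likelihood intervals invert the likelihood-ratio test (the set of
#' values whose constrained refit raises G2 by less than the chi-square
#' quantile); they are slower but remain sensible near the boundary, and are
#' available for single-group fits.
#'
#' @param object a `cni_fit`.
#' @param parm parameters (among `"C"`, `"N"`, `"I"`); default all.
#' @param level confidence level.
#' @param type `"wald"` or `"profile"`.
#' @param ... unused.
#' @return matrix (or, for several groups, a long data.frame) of bounds.
#' @export
confint.cni_fit <- function(object, parm = c("C", "N", "I"), level = 0.95,
                            type = c("wald", "profile"), ...) {
  type <- match.arg(type)
  parm <- match.arg(parm, several.ok = TRUE)
  G <- nrow(object$coefficients)
  if (type == "wald") {
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- pmax(object$coefficients - z * object$se, 0)
    hi <- pmin(object$coefficients + z * object$se, 1)
    if (G == 1L) {
      out <- cbind(lower = lo[1, parm], upper = hi[1, parm])
      rownames(out) <- parm
      return(out)
    }
    return(do.call(rbind, lapply(seq_len(G), function(gi)
      data.frame(group = object$groups[gi], parameter = parm,
                 lower = lo[gi, parm], upper = hi[gi, parm], row.names = NULL))))
  }
  if (G > 1L) {
    message("profile intervals are implemented for single-group fits; returning Wald")
    return(confint.cni_fit(object, parm, level, type = "wald"))
  }
  crit <- stats::qchisq(level, 1)
  counts <- object$counts
  out <- t(vapply(parm, function(pn) {
    hat <- object$coefficients[1, pn]
    dev <- function(v) {
      f <- cni_fit(counts, fixed = stats::setNames(v, pn),
                   equal = object$equal, n_starts = 2)
      f$G2 - object$G2
    }
    bound <- function(lower) {
      ends <- if (lower) c(0, hat) else c(hat, 1)
      at_end <- dev(ends[if (lower) 1 else 2])
      if (at_end <= crit) return(ends[if (lower) 1 else 2])
      f <- function(v) dev(v) - crit
      stats::uniroot(f, interval = sort(ends), tol = 1e-5)$root
    }
    c(bound(TRUE), bound(FALSE))
  }, numeric(2)))
  colnames(out) <- c("lower", "upper")
  out
}

#' Expected cell probabilities or counts from a CNI fit
#'
#' @param object a `cni_fit`.
#' @param type `"prob"` for action probabilities per cell, `"counts"` for
#'   expected action counts given the observed cell totals.
#' @param ... unused.
#' @return groups-by-4 matrix in the canonical cell order.
#' @export
predict.cni_fit <- function(object, type = c("prob", "counts"), ...) {
  type <- match.arg(type)
  p <- cni_probabilities(object$coefficients[, 1], object$coefficients[, 2],
                         object$coefficients[, 3])
  if (is.null(dim(p))) p <- matrix(p, 1, dimnames = list(NULL, names(p)))
  rownames(p) <- object$groups
  if (type == "prob") p else p * (object$na + object$ni)
}

#' Parametric-bootstrap count tables from a CNI fit
#'
#' @param object a `cni_fit`.
#' @param nsim number of replicate count tables.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `cni_counts` tables drawn from the fitted binomials.
#' @export
simulate.cni_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$na + object$ni
  p <- predict(object, "prob")
  lapply(seq_len(nsim), function(i) {
    a <- matrix(stats::rbinom(length(n), as.vector(n), as.vector(p)), nrow(n))
    as_cni_counts(as.vector(t(a)), as.vector(t(n - a)),
                  group = rep(object$groups, each = 4))
  })
}

#' @export
residuals.cni_fit <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  n <- object$na + object$ni
  p <- predict(object, "prob")
  if (type == "pearson") {
    r <- (object$na - n * p) / sqrt(n * p * (1 - p))
  } else {
    xlx <- function(x, d) ifelse(x == 0, 0, x * log(x / d))
    dev <- 2 * (xlx(object$na, n * p) + xlx(object$ni, n * (1 - p)))
    r <- sign(object$na - n * p) * sqrt(pmax(dev, 0))
  }
  rownames(r) <- object$groups
  colnames(r) <- c("pro_bgc", "pro_bsc", "pre_bgc", "pre_bsc")
  r
}

#' Plot CNI parameter estimates with confidence intervals
#'
#' Dot-and-error-bar chart of the C, N and I estimates, one cluster of
#' points per parameter with groups side by side.
#'
#' @param x a `cni_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cni_fit <- function(x, ...) {
  G <- nrow(x$coefficients)
  off <- if (G == 1) 0 else seq(-0.15, 0.15, length.out = G)
  xs <- rep(1:3, each = G) + rep(off, 3)
  est <- as.vector(x$coefficients)   # column-major: C group1..G, N ..., I ...
  lo <- as.vector(x$ci[, , 1]); hi <- as.vector(x$ci[, , 2])
  graphics::plot(xs, est, xlim = c(0.5, 3.5), ylim = c(0, 1), xaxt = "n",
                 xlab = "parameter", ylab = "estimate",
                 pch = rep(seq_len(G), 3), ...)
  graphics::axis(1, at = 1:3, labels = c("C", "N", "I"))
  graphics::arrows(xs, lo, xs, hi, angle = 90, code = 3, length = 0.04)
  if (G > 1)
    graphics::legend("topright", legend = x$groups, pch = seq_len(G), bty = "n")
  invisible(x)
}

#' Likelihood-ratio comparison of nested CNI fits
#'
#' Computes the change in the G2 statistic between nested fits of the same
#' count data (e.g. a fit with a parameter fixed or equated across groups
#' versus the free fit), with the difference in degrees of freedom and a
#' chi-square p-value.
#'
#' @param object,... two or more `cni_fit` objects on the same counts.
#' @return data.frame of class `anova`.
#' @export
anova.cni_fit <- function(object, ...) {
  fits <- c(list(object), list(...))
  if (length(fits) < 2L) mc_stop("anova needs at least two cni_fit objects")
  ord <- order(vapply(fits, function(f) f$df, numeric(1)), decreasing = TRUE)
  fits <- fits[ord]
  G2 <- vapply(fits, function(f) f$G2, numeric(1))
  df <- vapply(fits, function(f) f$df, numeric(1))
  dG2 <- c(NA, -diff(G2))
  ddf <- c(NA, -diff(df))
  p <- ifelse(is.na(ddf) | ddf <= 0, NA, stats::pchisq(dG2, ddf, lower.tail = FALSE))
  out <- data.frame(G2 = G2, df = df, deltaG2 = dG2, delta_df = ddf,
                    `Pr(>Chi)` = p, check.names = FALSE)
  rownames(out) <- paste0("model", seq_along(fits))
  structure(out, class = c("anova", "data.frame"),
            heading = "Likelihood-ratio comparison of nested CNI fits")
}
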