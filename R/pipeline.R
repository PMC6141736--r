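#' Run the full moral-judgment analysis pipeline
#'
#' Executes, in order: stress-scale descriptives (with Cronbach's alpha when
#' item scores are present); traditional choice scores with a one-sample t
#' against the neutral point 3; the correlation matrix over age, gender,
#' stress, choice score and the standardized process-dissociation U and D;
#' hierarchical regressions (block 1: age + gender; block 2: + stress) for
#' the choice score, U and D; a median split of stress totals; the pooled
#' CNI fit with reference tests (C vs 0, N vs 0, I vs 0.5); and the
#' two-group CNI fit with equality tests for C, N and I. Every reported
#' statistic carries its df, CI and/or p-value.
#'
#' @param data a `cni_data` object.
#' @param neutral_point reference value of the choice-score t-test.
#' @param reference_tests named numeric vector of CNI reference tests.
#' @param verbose if `TRUE`, log one structured line per statistic to
#'   stderr.
#' @param ... passed to [cni_fit()].
#' @return object of class `cni_study` with components `pss`, `choice`,
#'   `correlations`, `regressions`, `split`, `cni`.
#' @export
run_study <- function(data, neutral_point = 3,
                      reference_tests = c(C = 0, N = 0, I = 0.5),
                      verbose = FALSE, ...) {
  stopifnot(inherits(data, "cni_data"))
  log1 <- function(name, value, df = NA, p = NA, group = NA) {
    if (verbose)
      message(sprintf("stat name=%s value=%.4f df=%s p=%s group=%s",
                      name, value, format(df), format(p), group))
  }
  part <- data$participants
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      mc_stop(sprintf("[%s] %s", label, conditionMessage(e)), class = class(e)[1]))
  }

  # -- stress scale ----------------------------------------------------------
  item_cols <- paste0("pss_", 1:10)
  pss <- stage("pss", {
    alpha <- if (all(item_cols %in% names(part)))
      cronbach_alpha(part[, item_cols]) else NA_real_
    list(mean = mean(part$pss_total), sd = stats::sd(part$pss_total),
         alpha = alpha)
  })
  log1("pss_mean", pss$mean); if (!is.na(pss$alpha)) log1("pss_alpha", pss$alpha)

  # -- traditional analyses --------------------------------------------------
  choice <- stage("choice", {
    sc <- choice_scores(data)
    tt <- one_sample_t(sc$score[sc$complete], mu = neutral_point)
    list(scores = sc, mean = tt$mean, sd = tt$sd, t = tt$t, df = tt$df,
         p.value = tt$p.value, cohen_d = tt$cohen_d,
         neutral_point = neutral_point)
  })
  log1("choice_t", choice$t, choice$df, choice$p.value)

  pd <- stage("pd", pd_scores(data))

  corr <- stage("correlations", {
    vars <- data.frame(age = part$age, gender = part$gender,
                       stress = part$pss_total,
                       choice = choice$scores$score[match(part$participant_id,
                                                          choice$scores$participant_id)])
    vars$U_z <- pd$U_z[match(part$participant_id, pd$participant_id)]
    vars$D_z <- pd$D_z[match(part$participant_id, pd$participant_id)]
    nm <- names(vars)
    rmat <- pmat <- matrix(NA_real_, length(nm), length(nm),
                           dimnames = list(nm, nm))
    diag(rmat) <- 1
    for (i in seq_along(nm)) for (j in seq_along(nm)) if (i < j) {
      ct <- pearson_r(vars[[i]], vars[[j]])
      rmat[i, j] <- rmat[j, i] <- ct$r
      pmat[i, j] <- pmat[j, i] <- ct$p.value
    }
    list(vars = vars, rmat = rmat, pmat = pmat)
  })
  vars <- corr$vars; rmat <- corr$rmat; pmat <- corr$pmat
  log1("r_stress_choice", rmat["stress", "choice"], p = pmat["stress", "choice"])

  regressions <- stage("regressions", {
    blocks <- list(c("age", "gender"), "stress")
    lapply(c(choice = "choice", U = "U_z", D = "D_z"), function(y)
      hierarchical_regression(vars, y, blocks))
  })

  # -- CNI analyses ----------------------------------------------------------
  split <- stage("median_split",
                 median_split(stats::setNames(part$pss_total, part$participant_id)))
  cni <- stage("cni", {
    pooled <- cni_fit(data, ...)
    refs <- lapply(names(reference_tests), function(pn)
      cni_test_reference(pooled, pn, reference_tests[[pn]], ...))
    names(refs) <- paste0(names(reference_tests), "_vs_", reference_tests)
    ga <- stats::setNames(as.character(split$assignment), names(split$assignment))
    counts2 <- cni_counts(data, group = ga)
    two <- cni_fit(counts2, ...)
    eqs <- lapply(c(C = "C", N = "N", I = "I"), function(pn)
      cni_test_equality(counts2, pn, ...))
    list(pooled = pooled, reference_tests = refs, groups = two,
         equality_tests = eqs)
  })
  log1("cni_G2", cni$pooled$G2, cni$pooled$df, cni$pooled$p.value)
  for (nm2 in names(cni$equality_tests))
    log1(paste0("dG2_", nm2), cni$equality_tests[[nm2]]$statistic, 1,
         cni$equality_tests[[nm2]]$p.value)

  structure(list(pss = pss, choice = choice, pd = pd,
                 correlations = list(r = rmat, p = pmat),
                 regressions = regressions, split = split, cni = cni,
                 n = nrow(part)),
            class = "cni_study")
}

#' @export
print.cni_study <- function(x, digits = 3, ...) {
  cat(sprintf("Moral-judgment study analysis (n = %d)\n", x$n))
  cat("\n-- Stress scale --\n")
  cat(sprintf("  PSS total: M = %.2f, SD = %.2f", x$pss$mean, x$pss$sd))
  if (!is.na(x$pss$alpha)) cat(sprintf(", Cronbach's alpha = %.2f", x$pss$alpha))
  cat("\n\n-- Traditional analyses --\n")
  cat(sprintf("  Choice score (0-6): M = %.2f, SD = %.2f; t(%d) = %.2f vs %g, p = %.3g, d = %.2f\n",
              x$choice$mean, x$choice$sd, x$choice$df, x$choice$t,
              x$choice$neutral_point, x$choice$p.value, x$choice$cohen_d))
  cat(sprintf("  r(stress, choice) = %.3f, p = %.3g\n",
              x$correlations$r["stress", "choice"],
              x$correlations$p["stress", "choice"]))
  cat("\n-- Process dissociation --\n")
  cat(sprintf("  U: M = %.2f, SD = %.2f;  D: M = %.2f, SD = %.2f (%d undefined D dropped)\n",
              mean(x$pd$U), stats::sd(x$pd$U),
              mean(x$pd$D, na.rm = TRUE), stats::sd(x$pd$D, na.rm = TRUE),
              sum(!x$pd$d_defined)))
  cat(sprintf("  r(stress, D) = %.3f, p = %.3g; r(stress, U) = %.3f, p = %.3g\n",
              x$correlations$r["stress", "D_z"], x$correlations$p["stress", "D_z"],
              x$correlations$r["stress", "U_z"], x$correlations$p["stress", "U_z"]))
  cat("\n-- Median split --\n  ")
  print(x$split)
  cat("\n-- CNI model --\n")
  print(x$cni$pooled, digits = digits)
  for (t in x$cni$reference_tests) print(t)
  cat("\nTwo-group fit:\n")
  print(x$cni$groups, digits = digits)
  for (t in x$cni$equality_tests) print(t)
  invisible(x)
}

# flatten a cni_study into plain lists for JSON serialization
.study_as_list <- function(x) {
  fit_list <- function(f) list(
    params = as.data.frame.table(f$coefficients, responseName = "estimate"),
    coef = apply(f$coefficients, 2, stats::setNames, f$groups, simplify = FALSE),
    C = unname(f$coefficients[, "C"]), N = unname(f$coefficients[, "N"]),
    I = unname(f$coefficients[, "I"]),
    se = f$se, ci_lower = f$ci[, , 1], ci_upper = f$ci[, , 2],
    G2 = f$G2, df = f$df, p = f$p.value, logLik = f$logLik)
  test_list <- function(t) list(statistic = t$statistic, df = t$df, p = t$p.value)
  reg_list <- function(r) lapply(r$blocks, function(b)
    list(beta = as.list(b$beta), r2 = b$r2, delta_r2 = b$delta_r2,
         f_change = b$f_change, df1 = b$df1, df2 = b$df2, p_change = b$p_change))
  list(
    n = x$n,
    pss = x$pss,
    choice = x$choice[c("mean", "sd", "t", "df", "p.value", "cohen_d", "neutral_point")],
    correlations = list(r = x$correlations$r, p = x$correlations$p),
    regressions = lapply(x$regressions, reg_list),
    median_split = list(median = x$split$median,
                        sizes = as.list(x$split$sizes),
                        means = as.list(x$split$means),
                        sds = as.list(x$split$sds)),
    cni = list(pooled = fit_list(x$cni$pooled),
               reference_tests = lapply(x$cni$reference_tests, test_list),
               groups = fit_list(x$cni$groups),
               equality_tests = lapply(x$cni$equality_tests, test_list)))
}

#' Write a machine- and human-readable analysis report
#'
#' Serializes the full set of estimates, statistics, dfs, p-values and CIs
#' of a [run_study()] result to JSON and writes a plain-text companion (the
#' printed report).
#'
#' @param results a `cni_study`.
#' @param path output JSON path; the text report goes to the same path with
#'   extension `.txt`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (is.null(results) || (is.list(results) && length(results) == 0))
    mc_stop("nothing to report")
  stopifnot(inherits(results, "cni_study"))
  lst <- .study_as_list(results)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  writeLines(utils::capture.output(print(results)), txt)
  invisible(path)
}

#' Parameter-recovery and calibration study
#'
#' For each condition (generating parameters x number of participants),
#' simulates model-true pooled count tables (6 responses per cell per
#' participant), refits the CNI model, and summarizes bias, RMSE, Wald-CI
#' coverage per parameter, and the rejection rate of the G2 fit test at the
#' given alpha.
#'
#' @param truth named vector `c(C=, N=, I=)` of generating parameters.
#' @param n_participants vector of sample sizes.
#' @param reps Monte-Carlo replicates per condition.
#' @param alpha test level for the fit-test rejection rate.
#' @param responses_per_cell trials each participant contributes per cell.
#' @param ... passed to [cni_fit()].
#' @return data.frame, one row per (n, parameter), with columns `bias`,
#'   `rmse`, `coverage`, plus the per-n `fit_reject` rate.
#' @export
run_recovery_study <- function(truth = c(C = 0.131, N = 0.145, I = 0.451),
                               n_participants = c(50, 200, 2000),
                               reps = 200, alpha = 0.05,
                               responses_per_cell = 6, ...) {
  p_true <- cni_probabilities(truth[["C"]], truth[["N"]], truth[["I"]])
  rows <- list()
  for (n in n_participants) {
    total <- n * responses_per_cell
    est <- matrix(NA_real_, reps, 3)
    cover <- matrix(NA, reps, 3)
    reject <- logical(reps)
    for (r in seq_len(reps)) {
      a <- stats::rbinom(4, total, p_true)
      fit <- cni_fit(as_cni_counts(a, total - a), ...)
      est[r, ] <- fit$coefficients[1, ]
      cover[r, ] <- truth >= fit$ci[1, , 1] & truth <= fit$ci[1, , 2]
      reject[r] <- is.finite(fit$p.value) && fit$p.value < alpha
    }
    for (j in 1:3)
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, parameter = c("C", "N", "I")[j], true = truth[[j]],
        bias = mean(est[, j]) - truth[[j]],
        rmse = sqrt(mean((est[, j] - truth[[j]])^2)),
        coverage = mean(cover[, j], na.rm = TRUE),
        fit_reject = mean(reject))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
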