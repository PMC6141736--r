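#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the generator with defaults that emulate the
#' chronic-stress moral-judgment study design the package analyses: 197
#' participants aged 18-22 (mean 19.49, SD 0.83), 34.5% male, 10-item
#' perceived-stress totals with mean 26.51 and SD 5.33 and item-level
#' reliability near alpha = 0.80, and CNI baselines at the pooled estimates
#' C = 0.131, N = 0.145, I = 0.451. The stress-to-parameter link acts on the
#' logit scale (`logit(P_i) = logit(P0) + beta_P * z_i + eps_i`), which keeps
#' every realized parameter inside (0, 1) for any effect size; the betas
#' default to 0 because no generative effect sizes are part of the study
#' description — values used in power experiments are illustrative choices.
#'
#' @param n_participants number of participants (>= 2).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param age_mean,age_sd,age_min,age_max integer-age rejection-sampling
#'   window (years).
#' @param prop_male probability of gender code 1.
#' @param pss_mean,pss_sd target moments of the stress totals.
#' @param pss_item_level if `TRUE`, draw 10 item scores from a one-factor
#'   model whose loading is solved so the expected Cronbach's alpha matches
#'   `target_alpha` and the expected total SD matches `pss_sd`; items are
#'   rounded and clipped to 0..4 and the total recomputed from them.
#' @param target_alpha desired item-level reliability in (0, 1).
#' @param C0,N0,I0 baseline CNI parameters in (0, 1), exclusive (the logit
#'   link is undefined at the boundary).
#' @param beta_C,beta_N,beta_I effect of standardized stress on the logit of
#'   each parameter.
#' @param between_subject_sd SD of logit-scale participant noise added to
#'   each parameter.
#' @return list of class `sim_control`.
#' @export
sim_control <- function(n_participants = 197, seed = NULL,
                        age_mean = 19.49, age_sd = 0.83,
                        age_min = 18, age_max = 22,
                        prop_male = 0.345,
                        pss_mean = 26.51, pss_sd = 5.33,
                        pss_item_level = FALSE, target_alpha = 0.80,
                        C0 = 0.131, N0 = 0.145, I0 = 0.451,
                        beta_C = 0, beta_N = 0, beta_I = 0,
                        between_subject_sd = 0) {
  cfg <- as.list(environment())
  if (cfg$n_participants < 2) mc_stop("n_participants must be >= 2")
  for (nm in c("prop_male", "target_alpha"))
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1) mc_stop(sprintf("'%s' must lie in (0, 1)", nm))
  for (nm in c("C0", "N0", "I0"))
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
      mc_stop(sprintf("baseline '%s' must lie strictly in (0, 1): logit undefined at 0/1", nm))
  for (nm in c("age_sd", "pss_sd", "between_subject_sd"))
    if (cfg[[nm]] < 0) mc_stop(sprintf("'%s' must be non-negative", nm))
  class(cfg) <- "sim_control"
  cfg
}

# rejection sampling of a rounded truncated normal on [lo, hi]
.rtruncnorm_int <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    draw <- round(stats::rnorm(2 * (n - length(out)) + 10, mean, sd))
    out <- c(out, as.integer(draw[draw >= lo & draw <= hi]))
  }
  out[seq_len(n)]
}

# One-factor PSS item model: solve loading and uniqueness so that the
# continuous-scale alpha and total SD hit their targets before
# discretization. With k items and mean inter-item correlation
# rbar = alpha / (k - alpha*(k-1)), the item variance v satisfies
# k^2*rbar*v + k*(1-rbar)*v = pss_sd^2; loading^2 = rbar*v.
.pss_item_pars <- function(pss_mean, pss_sd, target_alpha, k = 10) {
  rbar <- target_alpha / (k - target_alpha * (k - 1))
  v <- pss_sd^2 / (k^2 * rbar + k * (1 - rbar))
  list(mu = pss_mean / k, loading = sqrt(rbar * v), uniq = sqrt((1 - rbar) * v))
}

#' Generate synthetic participants
#'
#' Ages are rounded truncated normals on the configured window, gender is
#' Bernoulli, and stress totals are either rounded truncated normals on
#' 0..40 or (item level) sums of 10 one-factor item scores rounded and
#' clipped to 0..4.
#'
#' @param config a [sim_control()] list. The seed field is *not* consumed
#'   here; seed handling happens in [simulate_cni_study()].
#' @return list with `participants` (a `cni_participants`) and `stress_z`
#'   (sample z-scores of the totals, named by participant).
#' @export
simulate_participants <- function(config = sim_control()) {
  stopifnot(inherits(config, "sim_control"))
  n <- config$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  age <- .rtruncnorm_int(n, config$age_mean, config$age_sd,
                         config$age_min, config$age_max)
  gender <- stats::rbinom(n, 1, config$prop_male)
  if (config$pss_item_level) {
    pp <- .pss_item_pars(config$pss_mean, config$pss_sd, config$target_alpha)
    f <- stats::rnorm(n)
    items <- sapply(1:10, function(j)
      pmin(pmax(round(pp$mu + pp$loading * f + stats::rnorm(n, 0, pp$uniq)), 0), 4))
    colnames(items) <- paste0("pss_", 1:10)
    part <- data.frame(participant_id = ids, age = age, gender = gender,
                       items, pss_total = as.integer(rowSums(items)),
                       stringsAsFactors = FALSE)
  } else {
    total <- .rtruncnorm_int(n, config$pss_mean, config$pss_sd, 0, 40)
    part <- data.frame(participant_id = ids, age = age, gender = gender,
                       pss_total = total, stringsAsFactors = FALSE)
  }
  part <- validate_participants(part)
  z <- zscore(part$pss_total)
  names(z) <- ids
  list(participants = part, stress_z = z)
}

#' Realize per-participant CNI parameters from stress
#'
#' Applies the logit-scale link
#' `P_i = plogis(qlogis(P0) + beta_P * z_i + eps_i)` with
#' `eps_i ~ Normal(0, between_subject_sd)` independently for each of C, N
#' and I.
#'
#' @param stress_z numeric vector of standardized stress (named by
#'   participant id if available).
#' @param config a [sim_control()].
#' @return data.frame of class `cni_truth` with columns `participant_id`,
#'   `stress_z`, `C`, `N`, `I`.
#' @export
realize_parameters <- function(stress_z, config = sim_control()) {
  stopifnot(inherits(config, "sim_control"))
  n <- length(stress_z)
  one <- function(P0, beta) {
    stats::plogis(stats::qlogis(P0) + beta * stress_z +
                    stats::rnorm(n, 0, config$between_subject_sd))
  }
  ids <- names(stress_z)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n))
  out <- data.frame(participant_id = ids, stress_z = as.numeric(stress_z),
                    C = one(config$C0, config$beta_C),
                    N = one(config$N0, config$beta_N),
                    I = one(config$I0, config$beta_I),
                    stringsAsFactors = FALSE)
  class(out) <- c("cni_truth", "data.frame")
  out
}

#' Generate binary dilemma responses from realized CNI parameters
#'
#' Each response is an independent Bernoulli draw whose action probability
#' comes from the participant's (C, N, I) and the item's
#' norm-by-consequences cell via [cni_probabilities()].
#'
#' @param battery a `cni_battery`.
#' @param truth a `cni_truth` from [realize_parameters()].
#' @return long data.frame `participant_id`, `item_id`, `response`.
#' @export
simulate_responses <- function(battery, truth) {
  battery <- validate_battery(battery)
  stopifnot(inherits(truth, "cni_truth"))
  p_cell <- cni_probabilities(truth$C, truth$N, truth$I)
  if (is.null(dim(p_cell))) p_cell <- matrix(p_cell, 1)
  n <- nrow(truth); m <- nrow(battery)
  # participant-major, battery-order layout
  idx_p <- rep(seq_len(n), each = m)
  idx_i <- rep(seq_len(m), n)
  probs <- p_cell[cbind(idx_p, battery$cell[idx_i])]
  data.frame(participant_id = truth$participant_id[idx_p],
             item_id = battery$item_id[idx_i],
             response = stats::rbinom(n * m, 1, probs),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic study
#'
#' Runs the whole generator under one seed: participants and stress,
#' realized per-participant CNI parameters, and the full 24-item response
#' table; also records the high/low group each participant falls into under
#' a median split of the stress totals. Identical seeds give byte-identical
#' datasets.
#'
#' @param config a [sim_control()].
#' @param battery battery to administer (default [cni_battery()]).
#' @return list of class `cni_sim` with `data` (a `cni_data`), `truth`
#'   (`cni_truth` with the median-split `group` column) and `config`.
#' @export
simulate_cni_study <- function(config = sim_control(), battery = cni_battery()) {
  stopifnot(inherits(config, "sim_control"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pp <- simulate_participants(config)
  truth <- realize_parameters(pp$stress_z, config)
  responses <- simulate_responses(battery, truth)
  data <- cni_data(battery, pp$participants, responses)
  split <- median_split(stats::setNames(pp$participants$pss_total,
                                        pp$participants$participant_id))
  truth$group <- as.character(split$assignment[truth$participant_id])
  structure(list(data = data, truth = truth, config = config),
            class = "cni_sim")
}

#' Write a simulated study to CSV files
#'
#' Writes `battery.csv`, `participants.csv`, `responses.csv` and `truth.csv`
#' into a directory.
#'
#' @param sim a `cni_sim` from [simulate_cni_study()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cni_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_battery(sim$data$battery, file.path(dir, "battery.csv"))
  p <- sim$data$participants
  utils::write.csv(as.data.frame(p), file.path(dir, "participants.csv"),
                   row.names = FALSE, quote = FALSE)
  write_responses(sim$data, file.path(dir, "responses.csv"))
  utils::write.csv(as.data.frame(sim$truth), file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
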