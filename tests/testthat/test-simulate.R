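test_that("identical seeds give identical datasets; different seeds differ", {
  cfg <- sim_control(n_participants = 40, seed = 123, beta_I = 0.3,
                     between_subject_sd = 0.2)
  s1 <- simulate_cni_study(cfg)
  s2 <- simulate_cni_study(cfg)
  expect_identical(s1$data$responses, s2$data$responses)
  expect_identical(s1$data$participants, s2$data$participants)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cni_study(sim_control(n_participants = 40, seed = 124))
  expect_false(identical(s1$data$responses, s3$data$responses))
})

test_that("participant generation respects the configured ranges", {
  cfg <- sim_control(n_participants = 500, seed = 1)
  set.seed(cfg$seed)
  pp <- simulate_participants(cfg)
  p <- pp$participants
  expect_equal(length(unique(p$participant_id)), 500L)
  expect_true(all(p$age >= 18 & p$age <= 22 & p$age == round(p$age)))
  expect_true(all(p$gender %in% 0:1))
  expect_true(all(p$pss_total >= 0 & p$pss_total <= 40))
  expect_equal(mean(pp$stress_z), 0, tolerance = 1e-12)

  tiny <- sim_control(n_participants = 2, seed = 5)
  set.seed(5)
  expect_equal(length(unique(simulate_participants(tiny)$participants$participant_id)), 2L)
})

test_that("stress totals hit the target moments at large n", {
  cfg <- sim_control(n_participants = 10000, seed = 77)
  set.seed(cfg$seed)
  p <- simulate_participants(cfg)$participants
  expect_equal(mean(p$pss_total), 26.51, tolerance = 0.2)
  expect_equal(sd(p$pss_total), 5.33, tolerance = 0.2)
  expect_equal(mean(p$age), 19.49, tolerance = 0.1)
})

test_that("item-level stress scores reach the target reliability", {
  cfg <- sim_control(n_participants = 10000, seed = 88, pss_item_level = TRUE,
                     target_alpha = 0.80)
  set.seed(cfg$seed)
  p <- simulate_participants(cfg)$participants
  items <- as.matrix(p[, paste0("pss_", 1:10)])
  expect_true(all(items >= 0 & items <= 4))
  expect_equal(p$pss_total, as.integer(rowSums(items)))
  a <- cronbach_alpha(items)
  expect_gte(a, 0.75)
  expect_lte(a, 0.85)
})

test_that("the logit link realizes parameters exactly in the noiseless case", {
  cfg <- sim_control(I0 = 0.5, beta_I = 0, between_subject_sd = 0)
  tr <- realize_parameters(c(-1, 0, 2), cfg)
  expect_equal(tr$I, rep(0.5, 3))
  expect_equal(tr$C, rep(cfg$C0, 3))
  cfg2 <- sim_control(I0 = 0.5, beta_I = 0.4, between_subject_sd = 0)
  tr2 <- realize_parameters(c(0, 1), cfg2)
  expect_equal(tr2$I[1], 0.5)
  expect_equal(tr2$I[2], plogis(0.4))         # inverse-logit(0.4) ~ 0.5987
  expect_error(sim_control(I0 = 1), "logit undefined")
})

test_that("deterministic parameter archetypes force the response pattern", {
  b <- cni_battery()
  mk_truth <- function(C, N, I) {
    structure(data.frame(participant_id = "p1", stress_z = 0,
                         C = C, N = N, I = I),
              class = c("cni_truth", "data.frame"))
  }
  r <- simulate_responses(b, mk_truth(1, 0.5, 0.5))
  cells <- b$cell[match(r$item_id, b$item_id)]
  expect_true(all(r$response[cells %in% c(1, 3)] == 1))
  expect_true(all(r$response[cells %in% c(2, 4)] == 0))
  r0 <- simulate_responses(b, mk_truth(0, 0, 1))
  expect_true(all(r0$response == 0))
})

test_that("pooled cell proportions converge to the analytic probabilities", {
  cfg <- sim_control(n_participants = 5000, seed = 31, C0 = 0.2, N0 = 0.3,
                     I0 = 0.6)
  sim <- simulate_cni_study(cfg)
  cnt <- cni_counts(sim$data)
  prop <- cnt$n_action / (cnt$n_action + cnt$n_inaction)
  expect_equal(prop, c(0.424, 0.224, 0.664, 0.464), tolerance = 0.01)
})

test_that("simulation CSVs round-trip through the readers", {
  sim <- simulate_cni_study(sim_control(n_participants = 15, seed = 44))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  b <- read_battery(file.path(dir, "battery.csv"))
  p <- read_participants(file.path(dir, "participants.csv"))
  d <- read_responses(file.path(dir, "responses.csv"), b, p)
  expect_equal(d$responses, sim$data$responses)
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(truth$C, sim$truth$C, tolerance = 1e-12)
})
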