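test_that("category probabilities match branch enumeration and hand cases", {
  # consequences fully drive
  expect_equal(unname(cni_probabilities(1, 0.4, 0.7)), c(1, 0, 1, 0))
  # pure coin flip
  expect_equal(unname(cni_probabilities(0, 0, 0.5)), rep(0.5, 4))
  # worked example: sum the three action paths by hand
  expect_equal(unname(cni_probabilities(0.2, 0.3, 0.6)),
               c(0.424, 0.224, 0.664, 0.464))
  set.seed(101)
  for (i in 1:50) {
    th <- runif(3)
    p <- cni_probabilities(th[1], th[2], th[3])
    expect_equal(unname(p), oracle_probs(th[1], th[2], th[3]))
    expect_true(all(p >= 0 & p <= 1))
    # model structure: proscriptive cells differ by exactly C, and the
    # norm contrast is identical across consequence levels (the 1-df tie)
    expect_equal(unname(p[1] - p[2]), th[1])
    expect_equal(unname(p[3] - p[1]), unname(p[4] - p[2]))
  }
})

test_that("moment inversion solves the tree algebra", {
  expect_equal(unname(cni_invert(c(0.424, 0.224, 0.664, 0.464))),
               c(0.2, 0.3, 0.6), tolerance = 1e-12, ignore_attr = TRUE)
  cf <- cni_invert(c(0.5, 0.5, 0.5, 0.5))
  expect_equal(unname(cf[1:3]), c(0, 0, 0.5), ignore_attr = TRUE)
  expect_false(attr(cf, "flagged"))
  bd <- cni_invert(c(1, 0, 1, 0))
  expect_equal(unname(bd[["C"]]), 1)
  expect_true(is.na(bd[["N"]]) && is.na(bd[["I"]]))
  expect_true(attr(bd, "flagged"))
  set.seed(7)
  for (i in 1:25) {
    th <- runif(3, 0.05, 0.95)
    got <- cni_invert(cni_probabilities(th[1], th[2], th[3]))
    expect_equal(unname(got[1:3]), th, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("count aggregation pools by cell and group", {
  b <- cni_battery()
  p <- data.frame(participant_id = c("a", "b"), age = 20, gender = c(1, 0),
                  pss_total = c(10, 30))
  r <- expand.grid(participant_id = p$participant_id, item_id = b$item_id,
                   stringsAsFactors = FALSE)
  r$response <- 1L
  d <- cni_data(b, p, r)

  one <- cni_counts(cni_data(b, p[1, ], r[r$participant_id == "a", ]))
  expect_equal(one$n_action, rep(6L, 4))
  expect_equal(one$n_inaction, rep(0L, 4))

  both <- cni_counts(d)                      # identical participants double
  expect_equal(both$n_action, 2L * one$n_action)

  grp <- cni_counts(d, group = c(a = "low", b = "high"))
  expect_equal(sort(unique(grp$group)), c("high", "low"))
  expect_equal(grp$n_action[grp$group == "low"], one$n_action)
  expect_error(cni_counts(d, group = c(a = "x", b = NA)), "no group")
})

test_that("complete 197-participant data gives 1182 trials per cell", {
  sim <- simulate_cni_study(sim_control(n_participants = 197, seed = 2))
  cnt <- cni_counts(sim$data)
  expect_equal(cnt$n_action + cnt$n_inaction, rep(197L * 6L, 4))
})

test_that("ML fit recovers generating parameters from model-true counts", {
  p <- cni_probabilities(0.2, 0.3, 0.6)
  fit <- cni_fit(as_cni_counts(1000 * p, 1000 * (1 - p)), n_starts = 5)
  expect_equal(unname(coef(fit)), c(0.2, 0.3, 0.6), tolerance = 1e-4)
  expect_lt(fit$G2, 1e-6)
  expect_equal(fit$df, 1L)                   # 4 cells - 3 free parameters
  expect_true(fit$converged)
})

test_that("degrees of freedom follow the cells-minus-parameters rule", {
  p1 <- cni_probabilities(0.3, 0.2, 0.5)
  p2 <- cni_probabilities(0.25, 0.2, 0.6)
  cnt <- as_cni_counts(c(round(600 * p1), round(600 * p2)),
                       c(round(600 * (1 - p1)), round(600 * (1 - p2))),
                       group = rep(c("lo", "hi"), each = 4))
  free <- cni_fit(cnt, n_starts = 3)
  expect_equal(free$df, 2L)                  # 8 cells - 6 parameters
  eq <- cni_fit(cnt, equal = "I", n_starts = 3)
  expect_equal(eq$df, 3L)
  fx <- cni_fit(cnt, fixed = c(C = 0.3), n_starts = 3)
  expect_equal(fx$df, 4L)
})

test_that("fit refuses empty cells and out-of-range constraints", {
  expect_error(cni_fit(as_cni_counts(c(1, 1, 1, 1), c(1, -1, 1, 1))),
               "non-negative")
  cnt <- as_cni_counts(c(5, 5, 5, 0), c(5, 5, 5, 0))
  expect_error(cni_fit(cnt), "positive total",
               class = "moralcni_validation_error")
  cnt <- as_cni_counts(c(5, 5, 5, 5), c(5, 5, 5, 5))
  expect_error(cni_fit(cnt, fixed = c(C = 1.2)), "outside")
})

test_that("Wald intervals are centred on the estimate and ordered", {
  set.seed(42)
  p <- cni_probabilities(0.3, 0.25, 0.55)
  a <- rbinom(4, 800, p)
  fit <- cni_fit(as_cni_counts(a, 800 - a), n_starts = 3)
  ci <- confint(fit)
  expect_true(all(ci[, "lower"] < coef(fit) & coef(fit) < ci[, "upper"]))
  pr <- confint(fit, type = "profile")
  expect_true(all(pr[, "lower"] < coef(fit) & coef(fit) < pr[, "upper"]))
  # profile and Wald agree closely away from the boundary at this n
  expect_equal(unname(pr), unname(ci), tolerance = 0.02)
})

test_that("predict/simulate/residuals are coherent with the fit", {
  set.seed(9)
  p <- cni_probabilities(0.25, 0.3, 0.5)
  a <- rbinom(4, 500, p)
  fit <- cni_fit(as_cni_counts(a, 500 - a), n_starts = 3)
  pr <- predict(fit, "prob")
  expect_equal(dim(pr), c(1L, 4L))
  expect_equal(unname(predict(fit, "counts")[1, ]), unname(pr[1, ] * 500))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_s3_class(sims[[1]], "cni_counts")
  expect_equal(sims[[1]]$n_action + sims[[1]]$n_inaction, rep(500L, 4))
  r <- residuals(fit)
  expect_equal(dim(r), c(1L, 4L))
  expect_true(all(is.finite(r)))
})
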