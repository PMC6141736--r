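test_that("choice scores count action judgments on incongruent items", {
  b <- cni_battery()
  cls <- pd_congruence(b)
  p <- data.frame(participant_id = c("yes6", "no6", "mid"), age = 20,
                  gender = c(1, 0, 1), pss_total = c(20, 25, 30))
  resp_for <- function(id, pattern) {
    out <- integer(nrow(b))
    out[cls == "incongruent"] <- pattern
    data.frame(participant_id = id, item_id = b$item_id, response = out)
  }
  d <- cni_data(b, p, rbind(resp_for("yes6", rep(1L, 6)),
                            resp_for("no6", rep(0L, 6)),
                            resp_for("mid", c(1L, 1L, 0L, 1L, 0L, 0L))))
  s <- choice_scores(d)
  expect_equal(s$score[match(c("yes6", "no6", "mid"), s$participant_id)],
               c(6L, 0L, 3L))
  expect_true(all(s$complete))
})

test_that("one-sample t matches the hand formula", {
  centred <- one_sample_t(c(2, 3, 4), mu = 3)
  expect_equal(centred$t, 0)
  expect_equal(centred$cohen_d, 0)
  shifted <- one_sample_t(c(4, 5, 6), mu = 3)
  expect_equal(shifted$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(shifted$df, 2)
  expect_equal(shifted$cohen_d, 2)
  expect_error(one_sample_t(5, mu = 3), "at least two")
  expect_error(one_sample_t(c(3, 3, 3), mu = 0), "zero variance")
})

test_that("pearson_r matches hand computation and is symmetric", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  y <- c(1, 3, 2, 4)
  expect_equal(pearson_r(x, y)$r, 0.8)        # cov 4/3, sds sqrt(5/3)
  expect_equal(pearson_r(x, y)$r, pearson_r(y, x)$r)
  expect_equal(pearson_r(10 + 2 * x, y)$r, pearson_r(x, y)$r)
  expect_error(pearson_r(c(1, 2), c(1, 2)), "at least three")
  expect_error(pearson_r(c(1, 1, 1), y[1:3]), "degenerate")
})

test_that("hierarchical regression matches the normal-equations oracle", {
  # 6-row worked fixture; z-score by hand, solve (X'X)^-1 X'y directly
  df <- data.frame(y = c(2.1, 3.0, 4.2, 3.7, 5.1, 4.4),
                   a = c(1.0, 2.0, 1.5, 3.0, 2.5, 3.5),
                   b = c(0, 1, 0, 1, 1, 0),
                   s = c(10, 12, 9, 15, 18, 13))
  z <- function(v) (v - mean(v)) / sd(v)
  Z <- sapply(df, z)
  fit <- hierarchical_regression(df, "y", list(c("a", "b"), "s"))

  for (blk in 1:2) {
    preds <- fit$blocks[[blk]]$predictors
    X <- cbind(1, Z[, preds])
    beta_hat <- solve(crossprod(X), crossprod(X, Z[, "y"]))
    expect_equal(unname(fit$blocks[[blk]]$beta), unname(beta_hat[-1]),
                 tolerance = 1e-10)
    resid <- Z[, "y"] - X %*% beta_hat
    r2_hat <- 1 - sum(resid^2) / sum(Z[, "y"]^2)
    expect_equal(fit$blocks[[blk]]$r2, r2_hat, tolerance = 1e-10)
  }
  expect_equal(fit$blocks[[2]]$delta_r2,
               fit$blocks[[2]]$r2 - fit$blocks[[1]]$r2, tolerance = 1e-14)
})

test_that("regression degenerate cases behave", {
  df <- data.frame(y = c(1, 2, 3, 4, 5, 6), x = c(1, 2, 3, 4, 5, 6),
                   w = c(2, 4, 6, 8, 10, 12), n = c(0, 1, 0, 1, 1, 0))
  fit <- suppressWarnings(hierarchical_regression(df, "y", list("x", "n")))
  expect_equal(fit$blocks[[1]]$r2, 1, tolerance = 1e-12)
  expect_equal(fit$blocks[[2]]$delta_r2, 0, tolerance = 1e-10)
  expect_error(hierarchical_regression(df, "y", list(c("x", "w"))),
               "collinear")
  set.seed(4)
  big <- data.frame(y = rnorm(4000), x = rnorm(4000))
  expect_lt(hierarchical_regression(big, "y", list("x"))$blocks[[1]]$r2, 0.01)
})

test_that("Cronbach's alpha covers the limiting cases and a hand fixture", {
  x <- c(1, 4, 2, 5, 3, 5, 2, 1, 4, 3)
  expect_equal(cronbach_alpha(cbind(x, x)), 1)
  set.seed(12)
  noise <- matrix(rnorm(5000 * 10), ncol = 10)
  expect_lt(abs(cronbach_alpha(noise)), 0.05)
  m <- rbind(c(1, 2, 1), c(2, 3, 3), c(3, 3, 2))
  k <- 3
  alpha_hand <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
  expect_equal(cronbach_alpha(m), alpha_hand, tolerance = 1e-14)
  expect_error(cronbach_alpha(m[1, , drop = FALSE]), "at least 2")
})

test_that("median split partitions with at-median values going low", {
  sp <- median_split(c(a = 1, b = 2, c = 3, d = 4, e = 5))
  expect_equal(names(sp$assignment)[sp$assignment == "high"], c("d", "e"))
  expect_equal(unname(sp$sizes["low"]), 3L, ignore_attr = TRUE)
  sp2 <- median_split(c(1, 2))
  expect_equal(as.character(sp2$assignment), c("low", "high"))
  expect_error(median_split(c(3, 3, 3)), "degenerate")
  sp3 <- median_split(c(a = 1, b = 2, c = 2, d = 5), ties_high = TRUE)
  expect_equal(sum(sp3$assignment == "high"), 3L)

  set.seed(6)
  x <- sample(10:40, 51, replace = TRUE)
  sp4 <- median_split(x)
  expect_equal(sum(sp4$sizes), 51L, ignore_attr = TRUE)
  expect_gt(min(x[sp4$assignment == "high"]), max(x[sp4$assignment == "low"]) - 1e-9)
})
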