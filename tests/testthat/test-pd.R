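test_that("congruence classification follows the norm/consequence rule", {
  b <- cni_battery()
  cls <- pd_congruence(b)
  expect_equal(as.character(cls[b$norm == "proscriptive" &
                                b$consequences == "benefits_exceed_costs"]),
               rep("incongruent", 6))
  expect_equal(as.character(cls[b$norm == "proscriptive" &
                                b$consequences == "costs_exceed_benefits"]),
               rep("congruent", 6))
  expect_equal(as.character(cls[b$norm == "prescriptive"]), rep("excluded", 12))
})

test_that("PD parameter algebra matches hand computation", {
  expect_equal(pd_parameters(0.7, 0.4), c(U = 0.3, D = 0.4 / 0.7))
  expect_equal(pd_parameters(0.5, 0.5), c(U = 0, D = 0.5))
  bd <- pd_parameters(1, 0)
  expect_equal(bd[["U"]], 1)
  expect_true(is.na(bd[["D"]]))
  expect_error(pd_parameters(1.2, 0.5), "\\[0, 1\\]")
})

make_pd_data <- function(responses_by_participant) {
  b <- cni_battery()
  ids <- names(responses_by_participant)
  p <- data.frame(participant_id = ids, age = 20,
                  gender = rep(c(1, 0), length.out = length(ids)),
                  pss_total = seq(10, 30, length.out = length(ids)))
  r <- do.call(rbind, lapply(ids, function(id) {
    data.frame(participant_id = id, item_id = b$item_id,
               response = responses_by_participant[[id]](b))
  }))
  cni_data(b, p, r)
}

test_that("participant scoring handles the pure and mixed archetypes", {
  cong_items <- function(b) pd_congruence(b)
  d <- make_pd_data(list(
    deont = function(b) ifelse(b$norm == "proscriptive", 0L, 1L),
    util = function(b) ifelse(cong_items(b) == "incongruent", 1L, 0L),
    mixed = function(b) {
      cls <- cong_items(b)
      out <- integer(nrow(b))
      out[cls == "congruent"] <- c(1L, 1L, 0L, 0L, 0L, 0L)   # 2 of 6 yes
      out[cls == "incongruent"] <- c(1L, 1L, 1L, 1L, 0L, 0L) # 4 of 6 yes
      out
    }))
  s <- suppressWarnings(pd_scores(d))
  deont <- s[s$participant_id == "deont", ]
  expect_equal(deont$p_unacc_cong, 1)
  expect_equal(deont$p_unacc_incong, 1)
  expect_equal(deont$U, 0)
  expect_equal(deont$D, 1)

  util <- s[s$participant_id == "util", ]
  expect_equal(util$U, 1)
  expect_false(util$d_defined)
  expect_true(is.na(util$D))

  mixed <- s[s$participant_id == "mixed", ]
  expect_equal(mixed$p_unacc_cong, 4 / 6)
  expect_equal(mixed$p_unacc_incong, 2 / 6)
  expect_equal(mixed$U, 1 / 3)
  expect_equal(mixed$D, 0.5)
})

test_that("reconstruction identities and standardization hold on synthetic data", {
  sim <- simulate_cni_study(sim_control(n_participants = 150, seed = 8,
                                        between_subject_sd = 0.5))
  s <- pd_scores(sim$data)
  expect_equal(s$p_unacc_cong, s$U + (1 - s$U) * s$D, tolerance = 1e-12)
  expect_equal(s$p_unacc_incong, (1 - s$U) * s$D, tolerance = 1e-12)
  expect_equal(mean(s$U_z), 0, tolerance = 1e-12)
  expect_equal(sd(s$U_z), 1, tolerance = 1e-12)
  ok <- s$d_defined
  expect_equal(mean(s$D_z[ok]), 0, tolerance = 1e-12)
  expect_equal(sd(s$D_z[ok]), 1, tolerance = 1e-12)
})

test_that("mean U tracks the generating consequence sensitivity", {
  mean_u <- sapply(c(0.1, 0.4, 0.7), function(c0) {
    sim <- simulate_cni_study(sim_control(n_participants = 400, seed = 99,
                                          C0 = c0))
    mean(pd_scores(sim$data)$U)
  })
  expect_true(all(diff(mean_u) > 0))
})
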