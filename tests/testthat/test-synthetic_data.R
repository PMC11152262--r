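test_that("generation is deterministic in the seed", {
  cfg <- generator_config(n = 120, seed = 7)
  g1 <- generate_survey(cfg)
  g2 <- generate_survey(cfg)
  expect_identical(as.data.frame(g1$table), as.data.frame(g2$table))
  expect_identical(g1$truth$W, g2$truth$W)
  g3 <- generate_survey(generator_config(n = 120, seed = 8))
  expect_false(identical(as.data.frame(g1$table),
                         as.data.frame(g3$table)))
})

test_that("config invariants are enforced", {
  expect_error(generator_config(n = 0), "at least 1")
  expect_error(generator_config(noise_sd = 0), "positive")
  expect_error(generator_config(missing_learn = 400), "missing_learn")
  bad_eff <- rbind(default_effects(), astrology_sign = c(1, 1, 1))
  expect_error(generator_config(effects = bad_eff), "astrology_sign")
  m <- default_marginals(); m$health <- c(poor = 0.5, fair = 0.2)
  expect_error(generator_config(marginals = m), "sum to 1")
})

test_that("exactly the configured number of learning answers go missing", {
  tab <- generate_survey(generator_config(n = 150, seed = 2,
                                          missing_learn = 11))$table
  expect_equal(sum(is.na(tab$learn_elderly)), 11)
  expect_false(anyNA(tab$health))
})

test_that("null effects produce near-zero regression slopes", {
  cfg <- generator_config(n = 2000, seed = 10,
                          effects = default_effects() * 0,
                          item_noise_sd = 0.01, missing_learn = 0)
  gen <- generate_survey(cfg)
  scores <- score_table(gen$table)
  coded <- collapse_levels(gen$table, scores)
  regs <- fit_wellbeing_regressions(coded, scores)
  for (h in names(regs)) {
    # every slope statistically compatible with the true zero effect
    tstats <- (regs[[h]]$coefficients / regs[[h]]$se)[-1]
    expect_lt(max(abs(tstats)), 4.5)
  }
})

test_that("a planted learning effect is recovered by downstream regression", {
  est <- vapply(1:4, function(s) {
    gen <- generate_survey(generator_config(n = 5000, seed = s))
    scores <- score_table(gen$table)
    coded <- collapse_levels(gen$table, scores)
    des <- build_design(coded, scores)
    fit <- fit_ols_robust(des$X, des$Y[, "quality"])
    fit$coefficients[["learn_elderly"]]
  }, 0)
  expect_lt(abs(mean(est) - default_effects()["learn_elderly", "quality"]),
            0.01)
})

test_that("generated category frequencies match the configured marginals", {
  tab <- generate_survey(generator_config(n = 300, seed = 14,
                                          missing_learn = 0))$table
  mg <- default_marginals()
  for (field in c("health", "education", "work")) {
    p <- mg[[field]]
    obs <- table(factor(tab[[field]], levels = names(p)))
    # 4-sigma binomial band per category
    for (lv in names(p)) {
      se <- sqrt(300 * p[[lv]] * (1 - p[[lv]]))
      expect_lt(abs(obs[[lv]] - 300 * p[[lv]]), 4 * se + 1)
    }
  }
  # class-count distribution follows its marginal: exercise most frequent
  cls <- colSums(tab[class_flag_fields()])
  expect_equal(names(which.max(cls)), "class_exercise")
})

test_that("fixtures are deterministic and have their stated shapes", {
  t8 <- make_fixture("tiny8")
  expect_equal(nrow(t8), 8)
  expect_false(anyNA(t8))
  p300 <- make_fixture("paper_like_300")
  expect_equal(nrow(p300), 300)
  expect_equal(sum(is.na(p300$learn_elderly)), 8)
  expect_identical(as.data.frame(p300),
                   as.data.frame(make_fixture("paper_like_300")))
  ab <- make_fixture("allbest4")
  expect_equal(nrow(ab), 4)
  expect_true(all(ab$casp_01 == 4))
  expect_true(all(ab$who_01 == 1))   # WHO-5: low raw response is best
  expect_error(make_fixture("nope"), "unknown fixture")
})

test_that("item responses always respect their scale bounds", {
  tab <- generate_survey(generator_config(n = 200, seed = 19,
                                          item_noise_sd = 0.5))$table
  for (sc in default_scales()) {
    for (j in seq_along(sc$items)) {
      v <- tab[[sc$items[j]]]
      expect_true(all(v >= sc$m[j] & v <= sc$M[j]))
    }
  }
})
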