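test_that("generation is deterministic given the seed and validates its config", {
  cfg <- generator_config(n_population = 2000, seed = 99)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a, b)

  expect_error(generator_config(n_population = 0), "n_population")
  expect_error(generator_config(survey_fraction = 1.2), "survey_fraction")
  bad <- default_adjusters()
  bad$region$probs <- c(0.5, 0.5, 0.5, 0.5)
  expect_error(generator_config(adjusters = bad), "probs")
  expect_error(generator_config(hidden_severity_sd = -1), "hidden_severity_sd")
  expect_error(generator_config(mortality_rate = 2), "mortality_rate")
})

test_that("spending is non-negative with the configured point mass at zero", {
  cfg <- generator_config(n_population = 50000, seed = 4)
  pop <- generate_population(cfg)
  expect_true(all(pop$spending >= 0))
  p0 <- cfg$spending_noise$p_zero
  frac_zero <- mean(pop$spending < 1e-9)
  mc_se <- sqrt(p0 * (1 - p0) / nrow(pop))
  expect_lt(abs(frac_zero - p0), 3 * mc_se)
})

test_that("switching the latent component off forces zero residual signal", {
  cfg <- generator_config(n_population = 5000, seed = 12,
                          hidden_severity_sd = 0, group_undercompensation = 0)
  pop <- generate_population(cfg)
  expect_true(all(pop$true_group_effect == 0))
})

test_that("condition carriers outspend non-carriers by the closed-form gap", {
  conds <- data.frame(name = "cond_01", prevalence = 0.2, loading = 1.0,
                      morbidity_logit = 0, ever = FALSE)
  cfg <- generator_config(n_population = 200000, seed = 8,
                          conditions = conds, survey_fraction = 0.9,
                          nonresponse_beta = 0, response_intercept = 5)
  pop <- generate_population(cfg)
  resp <- pop[pop$survey_responded, ]
  carrier <- resp$cond_01 %in% TRUE
  gap <- mean(resp$spending[carrier]) - mean(resp$spending[!carrier])
  expected <- expected_condition_gap(cfg, 0.2, 1.0)
  mc_se <- sqrt(stats::var(resp$spending[carrier]) / sum(carrier) +
                  stats::var(resp$spending[!carrier]) / sum(!carrier))
  expect_gt(gap, 0)
  expect_lt(abs(gap - expected), 3 * mc_se)
})

test_that("survey response declines across latent-severity quintiles", {
  cfg <- generator_config(n_population = 100000, seed = 21,
                          nonresponse_beta = 0.4)
  pop <- generate_population(cfg)
  inv <- pop[pop$survey_invited, ]
  quintile <- cut(inv$latent_severity,
                  stats::quantile(inv$latent_severity, seq(0, 1, 0.2)),
                  include.lowest = TRUE, labels = FALSE)
  rate <- tapply(inv$survey_responded, quintile, mean)
  expect_true(all(diff(rate) < 0))
})

test_that("undercompensation flag shifts spending by delta/(1-q)", {
  # the flag is independent of adjusters and severity, so the raw spending
  # gap between flagged and unflagged equals delta/(1-q) in expectation
  cfg <- generator_config(n_population = 200000, seed = 3,
                          group_undercompensation = 500, uc_prevalence = 0.2,
                          survey_fraction = 0.9, nonresponse_beta = 0,
                          response_intercept = 5)
  pop <- generate_population(cfg)
  resp <- pop[pop$survey_responded, ]
  flagged <- resp$uc_flag %in% TRUE
  gap <- mean(resp$spending[flagged]) - mean(resp$spending[!flagged])
  mc_se <- sqrt(stats::var(resp$spending[flagged]) / sum(flagged) +
                  stats::var(resp$spending[!flagged]) / sum(!flagged))
  expect_lt(abs(gap - 500 / (1 - 0.2)), 3 * mc_se)
})

test_that("train/test split is seeded, disjoint and exhaustive", {
  survey <- data.frame(person_id = 1:10,
                       survey_responded = rep(TRUE, 10))
  sp <- split_train_test(survey, 0.7, seed = 5)
  expect_length(sp$train_ids, 7)
  expect_length(sp$test_ids, 3)
  expect_identical(sp, split_train_test(survey, 0.7, seed = 5))
  expect_setequal(c(sp$train_ids, sp$test_ids), 1:10)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)

  expect_error(split_train_test(survey[0, ], 0.7, 1), "no survey responders")
  expect_error(split_train_test(survey, 1.5, 1), "train_fraction")
})
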