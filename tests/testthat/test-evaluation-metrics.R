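test_that("subgroup mean profit/loss follows the weighted-mean identities", {
  rev <- data.frame(person_id = 1:2, profit = c(10, -10))
  r <- subgroup_profit_loss(rev, c(TRUE, TRUE), name = "toy")
  expect_equal(r$mean_result, 0)
  expect_false(r$significant)

  rev2 <- data.frame(person_id = 1:2, profit = c(100, -50))
  r2 <- subgroup_profit_loss(rev2, c(TRUE, TRUE), weights = c(1, 3))
  expect_equal(r2$mean_result, -12.5)
  expect_equal(r2$N_g, 4)

  expect_error(subgroup_profit_loss(rev, c(FALSE, FALSE), name = "ghost"),
               "empty subgroup `ghost`")
})

test_that("no-HRP whole-sample profit equals minus the mean residual", {
  sim <- small_pipeline_fixture()
  rev <- sim$scenarios$no_hrp$revenues
  r <- subgroup_profit_loss(rev, rep(TRUE, nrow(rev)), name = "all")
  ri <- match(rev$person_id, sim$residuals$person_id)
  expect_equal(r$mean_result, -mean(sim$residuals$residual_spending[ri]))
})

test_that("wmar evaluates its defining formula", {
  res <- data.frame(group = c("a", "b"), N_g = c(10, 30),
                    mean_result = c(-50, 10))
  expect_equal(wmar(res), 20)
  expect_equal(wmar(res, "a"), 50)
  res$mean_result <- c(0, 0)
  expect_equal(wmar(res), 0)
  expect_error(wmar(res, c("a", "zz")), "unknown subgroup")
})

test_that("wmar matches a brute-force person-level recomputation", {
  sim <- small_pipeline_fixture()
  groups <- default_subgroups(sim$test)
  wts <- sim$test$weight
  for (s in names(sim$scenarios)) {
    sg <- sim$scenarios[[s]]$subgroup_results
    for (set_name in names(sim$group_sets)) {
      got <- wmar(sg, sim$group_sets[[set_name]])
      want <- oracle_wmar(sim$scenarios[[s]]$revenues, groups, wts,
                          sim$group_sets[[set_name]])
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("power reduction reproduces the hand-computed two-person case", {
  persons <- data.frame(person_id = 1:2, spending = c(100, 100))
  residuals <- data.frame(person_id = 1:2, predicted_spending = c(40, 100),
                          residual_spending = c(60, 0))
  pool <- structure(list(
    member_ids = 1L, threshold = 50,
    compensation = c(`1` = 10), total_compensation = 10,
    flat_contribution = 10, n_complement = 1L,
    config = pool_config(0.5)), class = "pool_assignment")
  expect_equal(power_reduction(persons, residuals, pool), 0.5)
  expect_equal(power_reduction(persons, residuals, NULL), 0)

  # a member far below the threshold contributes nothing to the change
  deep <- pool
  deep$threshold <- 1e6
  deep$compensation <- c(`1` = 0)
  deep$total_compensation <- 0
  expect_equal(power_reduction(persons, residuals, deep), 0)
})

test_that("power reduction stays in [0,1], grows with pool size and matches brute force", {
  sim <- small_pipeline_fixture()
  pr <- vapply(sim$scenarios, function(s) s$power_reduction, numeric(1))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_true(all(diff(pr[setdiff(names(pr), "no_hrp")]) > 0))
  for (s in setdiff(names(sim$scenarios), "no_hrp")) {
    expect_equal(sim$scenarios[[s]]$power_reduction,
                 oracle_power(sim$test, sim$residuals, sim$scenarios[[s]]$pool),
                 tolerance = 1e-12)
  }
})

test_that("system-wide financing recomputation nets aggregate revenue to zero", {
  sim <- small_pipeline_fixture()
  pool <- sim$scenarios[[2]]$pool
  pr <- power_reduction(sim$test, sim$residuals, pool,
                        recompute_financing = TRUE)
  expect_equal(pr, 0, tolerance = 1e-12)
})

test_that("the incentive report has the trade-off structure", {
  sim <- small_pipeline_fixture()
  rep_ <- sim$report
  expect_equal(nrow(rep_), length(sim$scenarios) * length(sim$group_sets))
  base <- rep_[rep_$scenario == "no_hrp", ]
  expect_true(all(base$power_reduction == 0))
  expect_true(all(base$wmar_change == 0))
  expect_true(all(rep_$wmar >= 0))

  bad <- sim$scenarios
  bad[[2]]$subgroup_results <- bad[[2]]$subgroup_results[-1, ]
  expect_error(build_report(bad, sim$group_sets), "inconsistent subgroup")
  expect_error(build_report(sim$scenarios["top_2%"], sim$group_sets),
               "no_hrp")
})
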