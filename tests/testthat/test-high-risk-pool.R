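# helper building a minimal evaluated sample where predictions rank person
# ids 1, 2, ... highest, and residuals are set directly
make_instance <- function(residual_by_rank, n_total) {
  n <- length(residual_by_rank)
  ids <- seq_len(n_total)
  resid <- c(residual_by_rank, rep(-1, n_total - n))
  pred <- data.frame(person_id = ids,
                     predicted_residual = rev(seq_len(n_total)))
  persons <- data.frame(person_id = ids, spending = 1000 + resid)
  residuals <- data.frame(person_id = ids, predicted_spending = 1000,
                          residual_spending = resid)
  list(persons = persons, predictions = pred, residuals = residuals)
}

test_that("solve_threshold matches the hand-solved piecewise-linear roots", {
  expect_equal(solve_threshold(c(-1000, 500, 3000)), 500)
  expect_equal(solve_threshold(c(-10, -10, 20)), 20)
  expect_equal(solve_threshold(c(42, 42, 42)), 0)
  expect_equal(solve_threshold(7), 0)
  # retained values at the root have mean zero
  for (v in list(c(-1000, 500, 3000), c(-3, 1, 1, 7), runif(20, -5, 10))) {
    if (mean(v) < 0) next
    tau <- solve_threshold(v)
    expect_lt(abs(mean(v - pmax(v - tau, 0))), 1e-9)
  }
  expect_error(solve_threshold(c(-5, -10)), "no threshold")
  expect_error(solve_threshold(numeric(0)), "empty pool")
})

test_that("build_pool solves the documented 100-person example", {
  inst <- make_instance(c(3000, 500), 100)
  pool <- build_pool(inst$persons, inst$predictions, inst$residuals,
                     pool_config(0.02))
  expect_setequal(pool$member_ids, c(1, 2))
  expect_equal(pool$threshold, 0)
  expect_equal(sort(unname(pool$compensation)), c(500, 3000))
  expect_equal(pool$total_compensation, 3500)
  expect_equal(pool$n_complement, 98)
  expect_equal(pool$flat_contribution, 3500 / 98)
})

test_that("share-1 residual-basis compensation totals the members' residuals", {
  sim <- small_pipeline_fixture()
  for (s in setdiff(names(sim$scenarios), "no_hrp")) {
    pool <- sim$scenarios[[s]]$pool
    ri <- match(pool$member_ids, sim$residuals$person_id)
    member_resid <- sim$residuals$residual_spending[ri]
    expect_equal(pool$total_compensation, sum(member_resid))
    # defining construction: pool mean post-compensation residual is zero
    expect_lt(abs(mean(member_resid -
                         pool$compensation[as.character(pool$member_ids)])),
              pool$config$solver_tolerance)
    # budget balance
    expect_equal(pool$flat_contribution * pool$n_complement,
                 pool$total_compensation)
  }
})

test_that("the threshold is non-decreasing across nested pools", {
  # deterministic instance: predicted ranking equals the residual ranking,
  # so growing the pool dilutes it with lower-residual members and the
  # zero-mean construction pushes the threshold up
  inst <- make_instance(seq(8000, -1000, length.out = 100), 100)
  thr <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.5), function(f) {
    build_pool(inst$persons, inst$predictions, inst$residuals,
               pool_config(f))$threshold
  }, numeric(1))
  expect_true(all(diff(thr) >= 0))
})

test_that("an infeasible pool raises the documented error", {
  inst <- make_instance(c(-100, -200), 50)
  expect_error(
    build_pool(inst$persons, inst$predictions, inst$residuals, pool_config(0.04)),
    "no threshold can raise pool mean to zero")
})

test_that("the actual-spending basis still zeroes the pool's mean residual", {
  inst <- make_instance(c(4000, 1500, -500, 200), 200)
  pool <- build_pool(inst$persons, inst$predictions, inst$residuals,
                     pool_config(0.02, compensation_basis = "actual"))
  ri <- match(pool$member_ids, inst$residuals$person_id)
  retained <- inst$residuals$residual_spending[ri] -
    pool$compensation[as.character(pool$member_ids)]
  expect_lt(abs(mean(retained)), pool$config$solver_tolerance)
})

test_that("revenues follow the payment identity and conserve profits", {
  inst <- make_instance(c(3000, 500, 100, -400), 100)
  no_pool <- compute_revenues(inst$persons, inst$residuals, NULL)
  expect_equal(no_pool$profit, -inst$residuals$residual_spending)

  pool <- build_pool(inst$persons, inst$predictions, inst$residuals,
                     pool_config(0.02))
  with_pool <- compute_revenues(inst$persons, inst$residuals, pool)
  # member profit = compensation - residual
  m <- match(pool$member_ids, with_pool$person_id)
  expect_equal(with_pool$profit[m],
               unname(pool$compensation[as.character(pool$member_ids)]) -
                 inst$residuals$residual_spending[m])
  # financing exactly recycles compensation within the evaluated sample
  expect_equal(sum(with_pool$profit), sum(no_pool$profit))
})

test_that("revenues match a per-person brute-force recomputation", {
  sim <- small_pipeline_fixture()
  expect_lte(nrow(sim$test), 1000)
  for (s in names(sim$scenarios)) {
    got <- sim$scenarios[[s]]$revenues
    want <- oracle_revenues(sim$test, sim$residuals, sim$scenarios[[s]]$pool)
    expect_equal(got$revenue, want$revenue, tolerance = 1e-12)
    expect_equal(got$profit, want$profit, tolerance = 1e-12)
  }
})
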