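#' Run the full high-risk-pooling simulation
#'
#' End-to-end pipeline: generate the population, fit the risk-equalization
#' model on the full population, compute residual spending, rake the survey
#' responders to population margins (all adjuster families, spending
#' quantile bins and the mortality proxy), split responders 70/30 into
#' training and test samples, fit the residual-spending predictor on the
#' training sample, score the test sample, and for the no-HRP baseline plus
#' each pool-size scenario build the pool, compute revenues, subgroup
#' profits/losses, WMAR per group set and the power reduction.
#'
#' @param config a [generator_config()].
#' @param fractions pool sizes to evaluate (proportions of the test sample).
#' @param predictor a [predictor_config()].
#' @param train_fraction training share of the survey responders.
#' @param raking a [raking_spec()]; default rakes on all adjuster families,
#'   18 spending-quantile bins and `died`.
#' @param compensation_basis,compensation_share forwarded to [pool_config()].
#' @param weighted if `TRUE` (default) subgroup evaluation uses the raking
#'   weights; otherwise unweighted.
#' @param keep_population if `TRUE` the full population table is kept on the
#'   returned object (memory!); the survey frame is always kept.
#' @return object of class `hrp_simulation`: the fitted `model`, the raked
#'   `survey` frame (with `weight`), `split`, `predictions` (test) and
#'   `predictions_train`, `fit_mse` (train/test), per-scenario `scenarios`
#'   (pool, revenues, subgroup results, power reduction), `subgroup_results`
#'   (long data.frame) and the incentive `report`.
#' @export
#' @examples
#' \donttest{
#' sim <- run_hrp_simulation(generator_config(n_population = 20000, seed = 3),
#'                           fractions = c(0.01, 0.05))
#' sim$report
#' }
run_hrp_simulation <- function(config = generator_config(),
                               fractions = c(0.01, 0.02, 0.03, 0.04, 0.05),
                               predictor = predictor_config(),
                               train_fraction = 0.7,
                               raking = NULL,
                               compensation_basis = "residual",
                               compensation_share = 1,
                               weighted = TRUE,
                               keep_population = FALSE) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, config)
  }
  pop <- generate_population(config)
  model <- fit_risk_equalization(pop, families = names(config$adjusters))
  residuals <- compute_residuals(model, pop)

  if (is.null(raking)) {
    raking <- raking_spec(
      margin_variables = c(names(config$adjusters), "spending_bin", "died"))
  }
  if ("spending_bin" %in% raking$margin_variables) {
    pop$spending_bin <- bin_spending_quantiles(pop, raking$n_spending_quantiles)
  }
  survey <- pop[pop$survey_responded, , drop = FALSE]
  margins <- population_margins(pop, raking$margin_variables)
  survey$weight <- rake_weights(survey, margins, raking)

  split <- split_train_test(survey, train_fraction, seed = config$seed)
  train <- survey[survey$person_id %in% split$train_ids, , drop = FALSE]
  test <- survey[survey$person_id %in% split$test_ids, , drop = FALSE]

  fitted <- fit_predictor(train, residuals, predictor)
  pred_train <- score(fitted, train)
  pred_test <- score(fitted, test)
  actual <- function(p) {
    residuals$residual_spending[match(p$person_id, residuals$person_id)]
  }
  fit_mse <- c(
    train = mean((pred_train$predicted_residual - actual(pred_train))^2),
    test = mean((pred_test$predicted_residual - actual(pred_test))^2))

  groups <- default_subgroups(test)
  wts <- if (weighted) test$weight else rep(1, nrow(test))

  eval_scenario <- function(pool) {
    rev <- compute_revenues(test, residuals, pool)
    sg <- do.call(rbind, lapply(names(groups), function(g) {
      subgroup_profit_loss(rev, groups[[g]], wts, name = g)
    }))
    list(pool = pool, revenues = rev, subgroup_results = sg,
         power_reduction = power_reduction(test, residuals, pool))
  }

  scenarios <- list(no_hrp = eval_scenario(NULL))
  for (f in fractions) {
    cfg <- pool_config(f, compensation_basis = compensation_basis,
                       compensation_share = compensation_share)
    scenarios[[sprintf("top_%g%%", 100 * f)]] <-
      eval_scenario(build_pool(test, pred_test, residuals, cfg))
  }

  group_sets <- default_group_sets(names(groups))
  report <- build_report(scenarios, group_sets)

  long <- do.call(rbind, lapply(names(scenarios), function(s) {
    cbind(scenario = s, scenarios[[s]]$subgroup_results)
  }))

  out <- list(config = config, model = model, residuals = residuals,
              survey = survey, split = split, test = test,
              predictor = fitted, predictions = pred_test,
              predictions_train = pred_train, fit_mse = fit_mse,
              scenarios = scenarios, subgroup_results = long,
              report = report, group_sets = group_sets, weighted = weighted)
  if (keep_population) out$population <- pop
  class(out) <- "hrp_simulation"
  out
}

#' @export
print.hrp_simulation <- function(x, ...) {
  cat("High-risk pooling simulation\n")
  cat(sprintf("  population n = %d, survey responders = %d (test sample %d)\n",
              x$config$n_population, nrow(x$survey), nrow(x$test)))
  cat(sprintf("  predictor: %s (train MSE %.0f, test MSE %.0f)\n",
              x$predictor$method, x$fit_mse["train"], x$fit_mse["test"]))
  sc <- x$report[x$report$group_set == "selective", ]
  cat("  scenario        WMAR(selective)  power reduction\n")
  for (i in seq_len(nrow(sc))) {
    cat(sprintf("  %-14s %12.1f %16.4f\n",
                sc$scenario[i], sc$wmar[i], sc$power_reduction[i]))
  }
  invisible(x)
}
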