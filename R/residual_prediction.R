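#' Configuration of the insurer's residual-spending predictor
#'
#' @param method `"random_forest"` or `"stepwise_linear"`.
#' @param rf_n_trees number of trees in the regression forest (default 100).
#' @param rf_min_node minimum terminal-node size (default 100).
#' @param stepwise_criterion selection rule for the stepwise model; only
#'   `"AIC"` (forward selection minimising AIC) is implemented.
#' @param seed integer seed (forest bootstraps).
#' @return object of class `predictor_config`.
#' @export
predictor_config <- function(method = c("random_forest", "stepwise_linear"),
                             rf_n_trees = 100, rf_min_node = 100,
                             stepwise_criterion = "AIC", seed = 1L) {
  method <- match.arg(method)
  check_count(rf_n_trees, "rf_n_trees", min = 1)
  check_count(rf_min_node, "rf_min_node", min = 1)
  if (!identical(stepwise_criterion, "AIC")) {
    config_error("stepwise_criterion", 'must be "AIC"')
  }
  structure(list(method = method, rf_n_trees = as.integer(rf_n_trees),
                 rf_min_node = as.integer(rf_min_node),
                 stepwise_criterion = stepwise_criterion,
                 seed = as.integer(seed)),
            class = "predictor_config")
}

# Numeric 0/1 feature frame from survey indicators. Features are the
# condition flags, the ever-condition flags, the designed uc_flag and a
# fair/poor general-health dummy -- deliberately *not* the adjusters, which
# are already in the risk-equalization model.
survey_features <- function(persons, feature_names = NULL) {
  if (is.null(feature_names)) {
    feature_names <- c(grep("^cond_|^ever_", names(persons), value = TRUE),
                       intersect("uc_flag", names(persons)),
                       intersect("general_health", names(persons)))
  }
  missing_f <- setdiff(feature_names, names(persons))
  if (length(missing_f) > 0) {
    stop("missing predictor features: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(persons)))
  for (f in feature_names) {
    v <- persons[[f]]
    if (identical(f, "general_health")) {
      out[["gh_fair_poor"]] <- as.numeric(v == "fair_poor")
    } else {
      out[[f]] <- as.numeric(v)
    }
  }
  if (anyNA(out)) {
    stop("survey indicators contain NA; score only survey responders",
         call. = FALSE)
  }
  out
}

#' Fit a predictor of residual spending from survey indicators
#'
#' The insurer's model: predict individual residual spending after risk
#' equalization from self-reported survey indicators only. Two learners are
#' supported, a forward-stepwise OLS (adding the survey dummy that most
#' improves AIC until no addition improves) and a regression random forest
#' (`ranger`, single-threaded for reproducibility) with the configured
#' number of trees and minimum terminal-node size.
#'
#' @param train data.frame of training-sample survey responders carrying the
#'   survey indicator columns.
#' @param residuals [compute_residuals()] table covering the training sample
#'   (matched by `person_id`).
#' @param config a [predictor_config()].
#' @return object of class `hrp_predictor`.
#' @export
fit_predictor <- function(train, residuals, config = predictor_config()) {
  stopifnot(inherits(config, "predictor_config"))
  if (nrow(train) == 0) stop("empty training sample", call. = FALSE)
  i <- match(train$person_id, residuals$person_id)
  if (anyNA(i)) stop("residuals missing for some training persons", call. = FALSE)
  y <- residuals$residual_spending[i]
  X <- survey_features(train)
  if (ncol(X) == 0) stop("no survey features available", call. = FALSE)
  dat <- cbind(X, .y = y)

  if (config$method == "stepwise_linear") {
    base <- stats::lm(.y ~ 1, data = dat)
    scope <- stats::as.formula(
      paste("~", paste(names(X), collapse = " + ")))
    fit <- stats::step(base, scope = list(lower = ~1, upper = scope),
                       direction = "forward", trace = 0, k = 2)
    obj <- list(method = config$method, fit = fit, features = names(X),
                config = config)
  } else {
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = dat,
      num.trees = config$rf_n_trees, min.node.size = config$rf_min_node,
      seed = config$seed, num.threads = 1, verbose = FALSE
    )
    obj <- list(method = config$method, fit = fit, features = names(X),
                config = config)
  }
  class(obj) <- "hrp_predictor"
  obj
}

#' Score persons with a fitted residual-spending predictor
#'
#' @param predictor an [fit_predictor()] object.
#' @param persons data.frame of survey responders to score.
#' @return data.frame `person_id`, `predicted_residual` (empty for an empty
#'   input).
#' @export
score <- function(predictor, persons) {
  stopifnot(inherits(predictor, "hrp_predictor"))
  if (nrow(persons) == 0) {
    return(data.frame(person_id = integer(0), predicted_residual = numeric(0)))
  }
  # rebuild the exact training feature frame; errors if any feature is absent
  raw <- c(grep("^(cond_|ever_)", predictor$features, value = TRUE),
           intersect("uc_flag", predictor$features))
  if ("gh_fair_poor" %in% predictor$features) raw <- c(raw, "general_health")
  X <- survey_features(persons, feature_names = raw)
  X <- X[, predictor$features, drop = FALSE]
  pred <- if (predictor$method == "stepwise_linear") {
    unname(stats::predict(predictor$fit, newdata = X))
  } else {
    stats::predict(predictor$fit, data = X, num.threads = 1)$predictions
  }
  data.frame(person_id = persons$person_id, predicted_residual = pred)
}

#' Select the top fraction of predicted residual spending
#'
#' Returns the `ceiling(fraction * n)` persons with the highest predicted
#' residual spending. Ties are broken by ascending person id (stable,
#' reproducible), so selections are nested across fractions:
#' top-1% is a subset of top-2%, and so on.
#'
#' @param predictions data.frame from [score()].
#' @param fraction proportion in (0, 1).
#' @return integer vector of selected person ids (ranked, highest first).
#' @export
top_fraction <- function(predictions, fraction) {
  check_proportion(fraction, "fraction")
  n <- nrow(predictions)
  if (n == 0) stop("no predictions to rank", call. = FALSE)
  k <- ceiling(fraction * n)
  ord <- order(-predictions$predicted_residual, predictions$person_id)
  predictions$person_id[ord[seq_len(k)]]
}
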