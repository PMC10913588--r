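#' Fit a prospective risk-equalization model
#'
#' Ordinary least squares of annual spending on dummy variables for every
#' adjuster-class, one family of dummies per adjuster with the first observed
#' class as reference, plus an intercept. This is the standard estimation
#' approach for prospective payment models: with an intercept the residuals
#' are mean-zero on the estimation population (the model's zero-sum
#' property), and because the model is estimated on the full population no
#' survey weights are involved.
#'
#' @param population data.frame with `spending` and the adjuster family
#'   columns (factors).
#' @param families character vector of adjuster family column names; default
#'   taken from the `"adjuster_families"` attribute left by
#'   [generate_population()].
#' @return object of class `riskeq_model`: intercept, per-family named
#'   coefficient vectors (reference class 0), family levels, `estimation_n`.
#' @export
fit_risk_equalization <- function(population, families = NULL) {
  if (is.null(families)) families <- attr(population, "adjuster_families")
  if (is.null(families)) {
    stop("adjuster families must be named via `families`", call. = FALSE)
  }
  missing_fam <- setdiff(families, names(population))
  if (length(missing_fam) > 0) {
    stop("adjuster families absent from data: ",
         paste(missing_fam, collapse = ", "), call. = FALSE)
  }
  dat <- population[, c("spending", families), drop = FALSE]
  for (f in families) {
    dat[[f]] <- droplevels(factor(dat[[f]]))
    if (nlevels(dat[[f]]) < 2) {
      stop(sprintf("adjuster family `%s` has fewer than 2 observed classes", f),
           call. = FALSE)
    }
  }
  n_params <- 1 + sum(vapply(dat[families], nlevels, integer(1)) - 1L)
  if (nrow(dat) <= n_params) {
    stop("fewer observations than model parameters", call. = FALSE)
  }
  fml <- stats::as.formula(paste("spending ~", paste(families, collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("collinear or empty adjuster classes: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cf <- stats::coef(fit)
  coefs <- list()
  for (f in families) {
    lv <- levels(dat[[f]])
    v <- stats::setNames(numeric(length(lv)), lv)
    hit <- paste0(f, lv)
    v[lv] <- ifelse(hit %in% names(cf), cf[hit], 0)
    coefs[[f]] <- v
  }
  structure(list(intercept = unname(cf["(Intercept)"]),
                 coefficients = coefs,
                 families = families,
                 estimation_n = nrow(dat)),
            class = "riskeq_model")
}

#' @export
print.riskeq_model <- function(x, ...) {
  cat("Prospective risk-equalization model (OLS on adjuster-class dummies)\n")
  cat(sprintf("  estimated on n = %d persons\n", x$estimation_n))
  cat(sprintf("  intercept: %.2f euro\n", x$intercept))
  for (f in x$families) {
    cat(sprintf("  %s: %d classes\n", f, length(x$coefficients[[f]])))
  }
  invisible(x)
}

#' Predicted and residual spending under a risk-equalization model
#'
#' Applies a fitted [fit_risk_equalization()] model: predicted spending is
#' the intercept plus the class coefficient of every adjuster family;
#' residual spending is actual minus predicted, the quantity a pool-assigning
#' insurer tries to forecast (positive residual = loss to the insurer).
#'
#' @param model a `riskeq_model`.
#' @param persons data.frame with the model's adjuster family columns and
#'   `spending`.
#' @return data.frame `person_id`, `predicted_spending`, `residual_spending`.
#' @export
compute_residuals <- function(model, persons) {
  stopifnot(inherits(model, "riskeq_model"))
  pred <- rep(model$intercept, nrow(persons))
  for (f in model$families) {
    if (is.null(persons[[f]])) {
      stop(sprintf("adjuster family `%s` absent from persons", f), call. = FALSE)
    }
    cls <- as.character(persons[[f]])
    cf <- model$coefficients[[f]]
    unseen <- setdiff(unique(cls), names(cf))
    if (length(unseen) > 0) {
      stop(sprintf("unseen class in family `%s`: %s", f,
                   paste(unseen, collapse = ", ")), call. = FALSE)
    }
    pred <- pred + cf[cls]
  }
  data.frame(person_id = persons$person_id,
             predicted_spending = unname(pred),
             residual_spending = persons$spending - unname(pred))
}
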