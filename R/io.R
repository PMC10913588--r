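#' Write and read the person-level table
#'
#' Plain-CSV serialization of the person-level table. Column dictionary:
#' `person_id` integer id; one factor column per adjuster family; `spending`
#' annual euros (>= 0); `died` mortality proxy; `latent_severity` and
#' `true_group_effect` generator-only diagnostics; `survey_invited` /
#' `survey_responded` survey linkage; `cond_*` / `ever_*` / `uc_flag`
#' self-reported condition indicators (empty unless responded);
#' `general_health` `"good"` or `"fair_poor"` (empty unless responded);
#' `weight` raking weight when present; `spending_bin` population spending
#' quantile when present.
#'
#' @param persons person-level data.frame.
#' @param path CSV path.
#' @return `write_population_csv()` the path, invisibly;
#'   `read_population_csv()` the data.frame.
#' @export
write_population_csv <- function(persons, path) {
  utils::write.csv(persons, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population_csv
#' @export
read_population_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("died", "survey_invited", "survey_responded", "uc_flag")) {
    if (col %in% names(out)) out[[col]] <- as.logical(out[[col]])
  }
  for (col in grep("^cond_|^ever_", names(out), value = TRUE)) {
    out[[col]] <- as.logical(out[[col]])
  }
  if ("general_health" %in% names(out)) {
    out$general_health <- factor(out$general_health,
                                 levels = c("good", "fair_poor"))
  }
  out
}

#' Serialize a risk-equalization model as JSON
#'
#' @param model a `riskeq_model`.
#' @param path JSON path.
#' @return `write_model_json()` the path invisibly; `read_model_json()` the
#'   model.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "riskeq_model"))
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = lapply(model$coefficients, as.list),
         families = model$families,
         estimation_n = model$estimation_n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(intercept = x$intercept,
                 coefficients = lapply(x$coefficients, unlist),
                 families = x$families,
                 estimation_n = x$estimation_n),
            class = "riskeq_model")
}

#' Read a run configuration from JSON or YAML
#'
#' The file may carry any [generator_config()] field plus the optional
#' top-level entries `fractions`, `predictor` (fields of
#' [predictor_config()]) and `train_fraction`, which are returned alongside
#' the generator config for [run_hrp_simulation()].
#'
#' @param path path ending in `.json`, `.yaml` or `.yml`.
#' @return list with `config`, `fractions`, `predictor`, `train_fraction`.
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the `yaml` package is needed to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  fractions <- x$fractions %||% c(0.01, 0.02, 0.03, 0.04, 0.05)
  predictor <- do.call(predictor_config, as.list(x$predictor %||% list()))
  train_fraction <- x$train_fraction %||% 0.7
  x$fractions <- x$predictor <- x$train_fraction <- NULL
  list(config = do.call(generator_config, x),
       fractions = fractions, predictor = predictor,
       train_fraction = train_fraction)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records the seed and the headline settings of a simulation so a run can
#' be reproduced exactly.
#'
#' @param sim an `hrp_simulation`.
#' @param path JSON path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(sim, path) {
  stopifnot(inherits(sim, "hrp_simulation"))
  jsonlite::write_json(
    list(seed = sim$config$seed,
         n_population = sim$config$n_population,
         survey_fraction = sim$config$survey_fraction,
         hidden_severity_sd = sim$config$hidden_severity_sd,
         predictor = sim$predictor$config[c("method", "rf_n_trees",
                                            "rf_min_node", "seed")],
         weighted_evaluation = sim$weighted,
         scenarios = names(sim$scenarios)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
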