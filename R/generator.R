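#' Default risk-adjuster families
#'
#' Three categorical adjuster families mirroring the structure (not the
#' coefficients) of a prospective somatic risk-equalization model: age
#' interacted with sex (10 classes), region (4 classes) and a pharmacy-like
#' yes/no morbidity flag (2 classes). Each family carries class probabilities
#' and additive euro effects on conditional mean spending; the first class of
#' every family is the reference (effect 0).
#'
#' @return named list of families, each a list with `classes`, `probs`,
#'   `effects`.
#' @export
default_adjusters <- function() {
  list(
    age_sex = list(
      classes = c("m19_34", "m35_44", "m45_54", "m55_64", "m65p",
                  "f19_34", "f35_44", "f45_54", "f55_64", "f65p"),
      probs   = c(0.118, 0.087, 0.098, 0.084, 0.101,
                  0.118, 0.088, 0.098, 0.084, 0.124),
      effects = c(0, 250, 550, 950, 2100,
                  350, 550, 850, 1150, 2300)
    ),
    region = list(
      classes = c("r1", "r2", "r3", "r4"),
      probs   = c(0.30, 0.30, 0.25, 0.15),
      effects = c(0, 60, 110, 170)
    ),
    morbidity = list(
      classes = c("none", "flagged"),
      probs   = c(0.76, 0.24),
      effects = c(0, 2800)
    )
  )
}

#' Default survey condition indicators
#'
#' A set of self-reported chronic-condition indicators: `n_current` conditions
#' reportable for the last 12 months (`cond_01`, ...) plus four conditions
#' reportable as ever suffered from (diabetes, stroke, heart attack, cancer).
#' Each condition has a base prevalence, a loading of the latent severity
#' factor on the reporting logit, and an optional logit shift for persons in
#' the flagged morbidity class (so some conditions, like diabetes, are
#' already partly captured by the risk adjusters).
#'
#' @param n_current number of 12-month condition indicators.
#' @return data.frame with columns `name`, `prevalence`, `loading`,
#'   `morbidity_logit`, `ever`.
#' @export
default_conditions <- function(n_current = 10) {
  check_count(n_current, "n_conditions", min = 1)
  prev <- rep(c(0.03, 0.05, 0.08, 0.10, 0.14), length.out = n_current)
  load <- rep(c(1.3, 1.1, 0.9, 0.7, 0.6), length.out = n_current)
  morb <- rep(c(0.8, 0, 0.5, 0, 0), length.out = n_current)
  current <- data.frame(
    name = sprintf("cond_%02d", seq_len(n_current)),
    prevalence = prev, loading = load, morbidity_logit = morb,
    ever = FALSE, stringsAsFactors = FALSE
  )
  ever <- data.frame(
    name = c("ever_diabetes", "ever_stroke", "ever_heart_attack", "ever_cancer"),
    prevalence = c(0.07, 0.02, 0.03, 0.05),
    loading = c(0.5, 0.9, 0.8, 0.7),
    morbidity_logit = c(1.5, 0.3, 0.4, 0.3),
    ever = TRUE, stringsAsFactors = FALSE
  )
  rbind(current, ever)
}

#' Configuration for the synthetic population generator
#'
#' Defines the joint distribution of a synthetic insured population with a
#' linked health-survey subsample. Spending is zero-inflated lognormal: an
#' any-use Bernoulli gate times a lognormal draw whose mean is additive in
#' the adjuster-class effects, plus a latent-severity euro component
#' `hidden_severity_sd * exp(S - 1/2)` (mean `hidden_severity_sd`) that is
#' *not* captured by the adjusters. The same latent severity `S ~ N(0,1)`
#' raises condition-reporting probabilities and lowers survey response, so
#' survey indicators predict residual spending and the raw survey sample is
#' selectively healthy.
#'
#' @param n_population population size.
#' @param survey_fraction probability of being invited to the survey.
#' @param seed integer seed; generation is fully deterministic given the seed.
#' @param adjusters adjuster families, see [default_adjusters()].
#' @param conditions condition table, see [default_conditions()].
#' @param hidden_severity_sd euro-scale spread of the latent severity
#'   component of spending; 0 switches residual predictability off entirely.
#' @param spending_noise list with `p_zero` (point mass at zero spending) and
#'   `sdlog` (log-scale sd of the conditional spending draw).
#' @param nonresponse_beta effect of latent severity on the response logit
#'   (positive values make sicker people respond less).
#' @param response_intercept baseline response logit among invitees.
#' @param mortality_rate proportion dying in the year (independent proxy);
#'   decedents' spending is multiplied by `mortality_multiplier`.
#' @param mortality_multiplier spending multiplier for decedents.
#' @param base_mean euro intercept of conditional mean spending.
#' @param uc_prevalence prevalence of a designed, independently drawn flag
#'   (`uc_flag`) marking a group with built-in undercompensation.
#' @param group_undercompensation euro mean residual built in for the
#'   `uc_flag` group under a correctly specified adjuster-only model; used
#'   for parameter-recovery validation. Default 0 (flag inert).
#' @param general_health list with `intercept` and `loading` of the
#'   fair/poor self-reported general-health logit.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_population = 100000,
                             survey_fraction = 0.3,
                             seed = 1L,
                             adjusters = default_adjusters(),
                             conditions = default_conditions(),
                             hidden_severity_sd = 1000,
                             spending_noise = list(p_zero = 0.2, sdlog = 1.1),
                             nonresponse_beta = 0.4,
                             response_intercept = 1.4,
                             mortality_rate = 0.01,
                             mortality_multiplier = 4,
                             base_mean = 1000,
                             uc_prevalence = 0.2,
                             group_undercompensation = 0,
                             general_health = list(intercept = -1.1, loading = 0.9)) {
  check_count(n_population, "n_population", min = 1)
  check_proportion(survey_fraction, "survey_fraction")
  check_count(seed, "seed", min = -.Machine$integer.max)
  if (!is.list(adjusters) || length(adjusters) == 0 || is.null(names(adjusters))) {
    config_error("adjuster_spec", "must be a non-empty named list of families")
  }
  for (fam in names(adjusters)) {
    f <- adjusters[[fam]]
    if (length(f$classes) < 2) {
      config_error(paste0("adjuster_spec$", fam), "needs at least 2 classes")
    }
    if (length(f$probs) != length(f$classes) ||
        abs(sum(f$probs) - 1) > 1e-8 || any(f$probs <= 0)) {
      config_error(paste0("adjuster_spec$", fam, "$probs"),
                   "must be positive and sum to 1")
    }
    if (length(f$effects) != length(f$classes)) {
      config_error(paste0("adjuster_spec$", fam, "$effects"),
                   "must match the number of classes")
    }
  }
  if (!is.data.frame(conditions) ||
      !all(c("name", "prevalence", "loading", "morbidity_logit", "ever") %in%
           names(conditions))) {
    config_error("conditions", "must be a data.frame like default_conditions()")
  }
  if (any(conditions$prevalence <= 0 | conditions$prevalence >= 1)) {
    config_error("conditions$prevalence", "must lie in (0, 1)")
  }
  if (!is.numeric(hidden_severity_sd) || hidden_severity_sd < 0) {
    config_error("hidden_severity_sd", "must be >= 0")
  }
  check_proportion(spending_noise$p_zero, "spending_noise$p_zero", open = FALSE)
  if (spending_noise$p_zero >= 1) config_error("spending_noise$p_zero", "must be < 1")
  if (!is.numeric(spending_noise$sdlog) || spending_noise$sdlog < 0) {
    config_error("spending_noise$sdlog", "must be >= 0")
  }
  check_proportion(mortality_rate, "mortality_rate", open = FALSE)
  if (mortality_multiplier < 1) config_error("mortality_multiplier", "must be >= 1")
  if (base_mean <= 0) config_error("base_mean", "must be > 0")
  check_proportion(uc_prevalence, "uc_prevalence")
  if (group_undercompensation < 0) {
    config_error("group_undercompensation", "must be >= 0")
  }

  structure(
    list(n_population = as.integer(n_population),
         survey_fraction = survey_fraction, seed = as.integer(seed),
         adjusters = adjusters, conditions = conditions,
         hidden_severity_sd = hidden_severity_sd,
         spending_noise = spending_noise,
         nonresponse_beta = nonresponse_beta,
         response_intercept = response_intercept,
         mortality_rate = mortality_rate,
         mortality_multiplier = mortality_multiplier,
         base_mean = base_mean,
         uc_prevalence = uc_prevalence,
         group_undercompensation = group_undercompensation,
         general_health = general_health),
    class = "generator_config"
  )
}

#' Generate a synthetic insured population with a linked health survey
#'
#' Draws one person-level table according to a [generator_config()]. Spending
#' for person i in adjuster classes with additive euro effects summing to
#' \eqn{m_i} is
#' \deqn{Y_i = k_i A_i (L_i + h e^{S_i - 1/2}) + F_i \delta/(1-q),}
#' where \eqn{A_i} is the any-use Bernoulli gate, \eqn{L_i} a lognormal with
#' mean \eqn{m_i}, \eqn{S_i \sim N(0,1)} the latent severity,
#' \eqn{h} = `hidden_severity_sd`, \eqn{k_i} the decedent multiplier,
#' \eqn{F_i} the designed undercompensation flag (prevalence \eqn{q}) and
#' \eqn{\delta} = `group_undercompensation`. The column `true_group_effect`
#' records each person's expected residual under a correctly specified
#' adjuster-only model,
#' \eqn{p\,\bar k\,h(e^{S_i-1/2}-1) + \delta/(1-q)(F_i - q)}, which is
#' identically zero when `hidden_severity_sd = 0` and \eqn{\delta = 0}.
#'
#' Survey condition indicators and general health are drawn from logits
#' increasing in severity; response among invitees has logit
#' `response_intercept - nonresponse_beta * S`. Condition columns and
#' `general_health` are `NA` for non-responders.
#'
#' @param config a [generator_config()].
#' @return data.frame with one row per person; columns documented in
#'   [write_population_csv()].
#' @export
#' @examples
#' pop <- generate_population(generator_config(n_population = 500, seed = 7))
#' mean(pop$spending)
generate_population <- function(config) {
  if (!inherits(config, "generator_config")) {
    config <- do.call(generator_config, config)
  }
  n <- config$n_population
  set.seed(config$seed)

  out <- data.frame(person_id = seq_len(n))
  m <- rep(config$base_mean, n)
  for (fam in names(config$adjusters)) {
    f <- config$adjusters[[fam]]
    cls <- sample.int(length(f$classes), n, replace = TRUE, prob = f$probs)
    out[[fam]] <- factor(f$classes[cls], levels = f$classes)
    m <- m + f$effects[cls]
  }

  severity <- stats::rnorm(n)
  h <- config$hidden_severity_sd
  sev_euro <- h * exp(severity - 0.5)

  p_use <- 1 - config$spending_noise$p_zero
  sdlog <- config$spending_noise$sdlog
  any_use <- stats::rbinom(n, 1, p_use)
  L <- stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)

  died <- stats::rbinom(n, 1, config$mortality_rate) == 1
  mult <- ifelse(died, config$mortality_multiplier, 1)

  q <- config$uc_prevalence
  delta_raw <- config$group_undercompensation / (1 - q)
  uc_flag <- stats::rbinom(n, 1, q) == 1

  out$spending <- mult * any_use * (L + sev_euro) + uc_flag * delta_raw
  out$died <- died
  out$latent_severity <- severity

  # expected mortality factor enters the expected-residual bookkeeping
  f_mort <- 1 - config$mortality_rate +
    config$mortality_rate * config$mortality_multiplier
  out$true_group_effect <- p_use * f_mort * h * (exp(severity - 0.5) - 1) +
    delta_raw * (as.numeric(uc_flag) - q)

  invited <- stats::runif(n) < config$survey_fraction
  p_resp <- stats::plogis(config$response_intercept -
                            config$nonresponse_beta * severity)
  responded <- invited & (stats::runif(n) < p_resp)
  out$survey_invited <- invited
  out$survey_responded <- responded

  morb_flag <- if (is.null(out$morbidity)) rep(0, n) else
    as.numeric(out$morbidity == "flagged")
  cond <- config$conditions
  for (i in seq_len(nrow(cond))) {
    p <- stats::plogis(stats::qlogis(cond$prevalence[i]) +
                         cond$loading[i] * severity +
                         cond$morbidity_logit[i] * morb_flag)
    flag <- stats::runif(n) < p
    out[[cond$name[i]]] <- ifelse(responded, flag, NA)
  }
  out$uc_flag <- ifelse(responded, uc_flag, NA)

  gh <- config$general_health
  fair_poor <- stats::runif(n) < stats::plogis(gh$intercept + gh$loading * severity)
  out$general_health <- factor(
    ifelse(responded, ifelse(fair_poor, "fair_poor", "good"), NA),
    levels = c("good", "fair_poor")
  )

  attr(out, "adjuster_families") <- names(config$adjusters)
  attr(out, "condition_names") <- cond$name
  attr(out, "generator_config") <- config
  out
}

#' Split survey responders into training and test samples
#'
#' Random, seeded, disjoint and exhaustive split of the survey responders,
#' mirroring an insurer training a prediction model on one period and
#' applying it to the next.
#'
#' @param survey data.frame of persons; only rows with
#'   `survey_responded == TRUE` are split (a pure responder table works too).
#' @param train_fraction proportion assigned to the training sample.
#' @param seed integer seed.
#' @return list with integer vectors `train_ids` and `test_ids` (person ids).
#' @export
split_train_test <- function(survey, train_fraction = 0.7, seed = 1L) {
  check_proportion(train_fraction, "train_fraction")
  if ("survey_responded" %in% names(survey)) {
    survey <- survey[survey$survey_responded, , drop = FALSE]
  }
  ids <- survey$person_id
  if (length(ids) == 0) stop("no survey responders to split", call. = FALSE)
  set.seed(seed)
  n_train <- max(1L, min(length(ids) - 1L, round(train_fraction * length(ids))))
  train <- sort(sample(ids, n_train))
  list(train_ids = train, test_ids = sort(setdiff(ids, train)))
}
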