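#' Raking specification
#'
#' Controls the iterative proportional fitting (IPF) used to reweight the
#' survey responders so that weighted class frequencies match population
#' margins on every listed variable.
#'
#' @param margin_variables character vector of categorical variable names
#'   (typically all adjuster families, the spending-quantile bin and the
#'   mortality proxy).
#' @param n_spending_quantiles number of population spending-quantile bins
#'   used as a margin (default 18).
#' @param tolerance maximum absolute relative margin error at convergence.
#' @param max_iterations IPF iteration cap.
#' @return object of class `raking_spec`.
#' @export
raking_spec <- function(margin_variables,
                        n_spending_quantiles = 18,
                        tolerance = 1e-6,
                        max_iterations = 500) {
  if (length(margin_variables) == 0) {
    config_error("margin_variables", "must be non-empty")
  }
  if (!is.numeric(tolerance) || tolerance <= 0) {
    config_error("tolerance", "must be > 0")
  }
  check_count(n_spending_quantiles, "n_spending_quantiles", min = 2)
  check_count(max_iterations, "max_iterations", min = 1)
  structure(list(margin_variables = as.character(margin_variables),
                 n_spending_quantiles = as.integer(n_spending_quantiles),
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "raking_spec")
}

#' Bin spending into population quantile groups
#'
#' Computes `n_bins` quantile cut-points on the population spending
#' distribution and labels every person with the bin containing their
#' spending. With heavy ties (e.g. the point mass at zero) duplicate
#' cut-points are collapsed deterministically and the actual bin count is
#' reported via a warning and the `"n_bins"` attribute.
#'
#' @param population data.frame with a `spending` column (or a numeric
#'   vector of spending).
#' @param n_bins requested number of quantile bins (>= 2).
#' @return factor of bin labels (`q01`, `q02`, ...), one per person, with
#'   attribute `n_bins` giving the realised bin count.
#' @export
bin_spending_quantiles <- function(population, n_bins = 18) {
  check_count(n_bins, "n_bins", min = 2)
  x <- if (is.data.frame(population)) population$spending else population
  if (is.null(x) || anyNA(x)) stop("spending must be present for all persons",
                                   call. = FALSE)
  breaks <- stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                            names = FALSE)
  breaks <- unique(breaks)
  if (length(breaks) == 1) {
    warning("constant spending: a single quantile bin was produced")
    f <- factor(rep("q01", length(x)), levels = "q01")
    attr(f, "n_bins") <- 1L
    return(f)
  }
  k <- length(breaks) - 1L
  if (k < n_bins) {
    warning(sprintf("tied spending values collapsed %d requested bins to %d",
                    n_bins, k))
  }
  labels <- sprintf("q%02d", seq_len(k))
  f <- cut(x, breaks = breaks, labels = labels, include.lowest = TRUE)
  attr(f, "n_bins") <- k
  f
}

#' Population margins for raking
#'
#' Class counts of each margin variable in the population table.
#'
#' @param population data.frame holding the margin variables.
#' @param variables character vector of variable names.
#' @return named list: variable -> named vector of class counts.
#' @export
population_margins <- function(population, variables) {
  missing_vars <- setdiff(variables, names(population))
  if (length(missing_vars) > 0) {
    stop("margin variables absent from population: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  out <- lapply(variables, function(v) {
    tab <- table(factor(population[[v]]))
    stats::setNames(as.numeric(tab), names(tab))
  })
  stats::setNames(out, variables)
}

#' Rake survey weights to population margins
#'
#' Iterative proportional fitting: starting from uniform weights
#' `N / n_survey`, weights are multiplied per margin variable by the ratio of
#' the target class count to the current weighted class count, cycling over
#' the variables in the order given by the spec until the worst relative
#' margin error falls below the tolerance. Converged weights are strictly
#' positive, reproduce every margin within tolerance and sum to the
#' population size (exactly, after a final normalisation whose factor is
#' itself within tolerance of 1).
#'
#' With a single margin variable one pass reproduces classical
#' post-stratification weights exactly.
#'
#' @param survey data.frame of survey responders carrying the margin
#'   variables.
#' @param population_margins named list of class counts, see
#'   [population_margins()]. All margins must total the same population size.
#' @param spec a [raking_spec()].
#' @return numeric vector of weights, one per survey row.
#' @export
rake_weights <- function(survey, population_margins, spec) {
  stopifnot(inherits(spec, "raking_spec"))
  vars <- spec$margin_variables
  missing_vars <- setdiff(vars, names(population_margins))
  if (length(missing_vars) > 0) {
    stop("margins missing for variables: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  totals <- vapply(population_margins[vars], sum, numeric(1))
  n_pop <- totals[[1]]
  if (any(abs(totals - n_pop) > 1e-6 * n_pop)) {
    stop("population margins disagree on the population total", call. = FALSE)
  }

  n <- nrow(survey)
  if (n == 0) stop("empty survey", call. = FALSE)

  # pre-resolve class indices; verify class correspondence both ways
  idx <- list()
  targets <- list()
  empty_cells <- character(0)
  for (v in vars) {
    target <- population_margins[[v]]
    cls <- as.character(survey[[v]])
    unseen <- setdiff(unique(cls), names(target))
    if (length(unseen) > 0) {
      stop(sprintf("survey classes absent from population margins for `%s`: %s",
                   v, paste(unseen, collapse = ", ")), call. = FALSE)
    }
    present <- table(factor(cls, levels = names(target)))
    empty <- names(target)[present == 0 & target > 0]
    if (length(empty) > 0) {
      empty_cells <- c(empty_cells, paste0(v, "=", empty))
    }
    target <- target[target > 0]
    idx[[v]] <- factor(cls, levels = names(target))
    targets[[v]] <- target
  }
  if (length(empty_cells) > 0) {
    stop("population classes with no survey members: ",
         paste(empty_cells, collapse = ", "), call. = FALSE)
  }

  w <- rep(n_pop / n, n)
  worst <- Inf
  for (iter in seq_len(spec$max_iterations)) {
    for (v in vars) {
      cur <- tapply(w, idx[[v]], sum)
      w <- w * (targets[[v]] / cur)[idx[[v]]]
    }
    # normalise before the convergence check so converged weights satisfy
    # both the margins and the exact population total
    w <- as.numeric(w) * n_pop / sum(w)
    worst <- max(vapply(vars, function(v) {
      cur <- tapply(w, idx[[v]], sum)
      max(abs(cur - targets[[v]]) / targets[[v]])
    }, numeric(1)))
    if (worst < spec$tolerance) {
      attr(w, "iterations") <- iter
      return(w)
    }
  }
  stop(sprintf(
    "raking did not converge in %d iterations (worst relative margin error %.3g)",
    spec$max_iterations, worst), call. = FALSE)
}
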