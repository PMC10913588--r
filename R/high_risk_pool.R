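#' High-risk pool configuration
#'
#' @param fraction proportion of the evaluated sample assigned to the pool
#'   (typical scenarios use 0.01 ... 0.05).
#' @param compensation_basis `"residual"` (default) or `"actual"`: whether
#'   spending above the threshold is measured on residual or on actual
#'   spending. In both cases the threshold is solved so the pool's mean
#'   post-compensation *residual* is zero.
#' @param compensation_share share of the excess over the threshold that is
#'   compensated (default 1).
#' @param solver_tolerance euro tolerance of the threshold solver.
#' @return object of class `pool_config`.
#' @export
pool_config <- function(fraction,
                        compensation_basis = c("residual", "actual"),
                        compensation_share = 1,
                        solver_tolerance = 1e-6) {
  check_proportion(fraction, "fraction")
  compensation_basis <- match.arg(compensation_basis)
  if (!is.numeric(compensation_share) || compensation_share <= 0 ||
      compensation_share > 1) {
    config_error("compensation_share", "must lie in (0, 1]")
  }
  if (solver_tolerance <= 0) config_error("solver_tolerance", "must be > 0")
  structure(list(fraction = fraction,
                 compensation_basis = compensation_basis,
                 compensation_share = compensation_share,
                 solver_tolerance = solver_tolerance),
            class = "pool_config")
}

# Exact piecewise-linear solve of share * sum(pmax(basis - tau, 0)) = target.
# The left side is non-increasing in tau (strictly while any basis > tau), so
# for target > 0 the root is unique; for target == 0 the smallest root is
# max(basis).
solve_excess_threshold <- function(basis, target, share, tolerance) {
  n <- length(basis)
  if (target <= 0) return(max(basis))
  v <- sort(basis, decreasing = TRUE)
  cum <- cumsum(v)
  goal <- target / share
  for (k in seq_len(n)) {
    tau <- (cum[k] - goal) / k
    lo <- if (k < n) v[k + 1] else -Inf
    if (tau >= lo - tolerance && tau <= v[k] + tolerance) return(tau)
  }
  # numerically the loop always returns for feasible targets
  stop("threshold solve failed", call. = FALSE)  # nocov
}

#' Solve the pool compensation threshold
#'
#' Finds the smallest threshold \eqn{\tau} such that the mean over pool
#' members of \eqn{v_i - s\,\max(v_i - \tau, 0)} is zero, i.e. compensating
#' the share \eqn{s} of each member's basis value above \eqn{\tau} drives the
#' pool's mean retained value to zero. The retained mean is piecewise linear
#' and non-decreasing in \eqn{\tau}, so the root is found exactly on the
#' sorted breakpoints. When the mean of the values is already zero the
#' smallest root is the maximum value; a negative mean is infeasible (no
#' threshold can raise the pool mean to zero).
#'
#' @param values euro basis values of the pool members (residual spending in
#'   the default design).
#' @param share compensated share of the excess, in (0, 1].
#' @param tolerance euro tolerance used in the feasibility test.
#' @return the threshold \eqn{\tau} in euros.
#' @export
#' @examples
#' solve_threshold(c(-1000, 500, 3000))  # 500
#' solve_threshold(c(-10, -10, 20))      # 20 (mean already zero)
solve_threshold <- function(values, share = 1, tolerance = 1e-6) {
  if (length(values) == 0) stop("empty pool", call. = FALSE)
  if (share <= 0 || share > 1) config_error("share", "must lie in (0, 1]")
  m <- mean(values)
  if (m < -tolerance) {
    stop("no threshold can raise pool mean to zero (mean basis value ",
         sprintf("%.2f", m), " < 0)", call. = FALSE)
  }
  solve_excess_threshold(values, max(sum(values), 0), share, tolerance)
}

#' Build a high-risk pool
#'
#' Assigns the top `fraction` of predicted residual spending to the pool,
#' solves the compensation threshold on the members' realised basis values so
#' the pool's mean post-compensation residual is zero, computes per-member
#' compensations, and finances the total by a retrospective flat-rate
#' contribution charged to every person in the complementary group
#' (`flat_contribution * n_complement == total_compensation`).
#'
#' @param test_persons data.frame of the evaluated (test) sample.
#' @param predictions [score()] output covering the test sample.
#' @param residuals [compute_residuals()] table covering the test sample.
#' @param config a [pool_config()].
#' @return object of class `pool_assignment` with `member_ids`, `threshold`,
#'   `compensation` (named euro vector over members), `total_compensation`,
#'   `flat_contribution`, `n_complement` and the config.
#' @export
build_pool <- function(test_persons, predictions, residuals, config) {
  stopifnot(inherits(config, "pool_config"))
  ids <- test_persons$person_id
  predictions <- predictions[predictions$person_id %in% ids, , drop = FALSE]
  if (nrow(predictions) < nrow(test_persons)) {
    stop("predictions missing for some test persons", call. = FALSE)
  }
  members <- top_fraction(predictions, config$fraction)
  if (length(members) < 1) stop("pool has no members", call. = FALSE)
  n_complement <- length(ids) - length(members)
  if (n_complement < 1) stop("complementary group is empty", call. = FALSE)

  ri <- match(members, residuals$person_id)
  if (anyNA(ri)) stop("residuals missing for some pool members", call. = FALSE)
  member_residual <- residuals$residual_spending[ri]
  basis <- if (config$compensation_basis == "residual") {
    member_residual
  } else {
    test_persons$spending[match(members, ids)]
  }

  if (mean(member_residual) < -config$solver_tolerance) {
    stop("no threshold can raise pool mean to zero (mean residual ",
         sprintf("%.2f", mean(member_residual)), " < 0)", call. = FALSE)
  }
  tau <- solve_excess_threshold(basis, max(sum(member_residual), 0),
                                config$compensation_share,
                                config$solver_tolerance)
  comp <- config$compensation_share * pmax(basis - tau, 0)
  total <- sum(comp)
  structure(list(member_ids = members,
                 threshold = tau,
                 compensation = stats::setNames(comp, members),
                 total_compensation = total,
                 flat_contribution = total / n_complement,
                 n_complement = n_complement,
                 config = config),
            class = "pool_assignment")
}

#' @export
print.pool_assignment <- function(x, ...) {
  cat(sprintf(
    "High-risk pool: %d members (top %.1f%%), threshold %.2f euro\n",
    length(x$member_ids), 100 * x$config$fraction, x$threshold))
  cat(sprintf("  total compensation %.2f euro, flat contribution %.2f euro x %d\n",
              x$total_compensation, x$flat_contribution, x$n_complement))
  invisible(x)
}

#' Per-person revenues and profits under a payment scenario
#'
#' Revenue is the spending predicted by the risk-equalization model, plus the
#' high-risk-pool compensation for pool members, minus the flat financing
#' contribution for the complementary group; profit is revenue minus actual
#' spending. With `pool = NULL` (no HRP) revenue is simply predicted
#' spending, so profit equals minus the residual.
#'
#' @param persons data.frame of the evaluated sample (needs `person_id`,
#'   `spending`).
#' @param residuals [compute_residuals()] table covering `persons`.
#' @param pool a [build_pool()] result, or `NULL` for the no-HRP scenario.
#' @return data.frame `person_id`, `pool_member`, `revenue`, `profit`.
#' @export
compute_revenues <- function(persons, residuals, pool = NULL) {
  i <- match(persons$person_id, residuals$person_id)
  if (anyNA(i)) stop("residuals missing for some persons", call. = FALSE)
  revenue <- residuals$predicted_spending[i]
  member <- rep(FALSE, nrow(persons))
  if (!is.null(pool)) {
    stopifnot(inherits(pool, "pool_assignment"))
    mi <- match(pool$member_ids, persons$person_id)
    if (anyNA(mi)) stop("pool member missing from persons", call. = FALSE)
    member[mi] <- TRUE
    revenue[mi] <- revenue[mi] + pool$compensation[as.character(pool$member_ids)]
    revenue[!member] <- revenue[!member] - pool$flat_contribution
  }
  data.frame(person_id = persons$person_id,
             pool_member = member,
             revenue = revenue,
             profit = revenue - persons$spending)
}
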