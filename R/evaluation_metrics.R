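#' Default subgroups for selection-incentive evaluation
#'
#' Builds membership indicators over survey responders for the groups an
#' insurer could target: every 12-month condition, every ever-condition, the
#' complementary pair any/no chronic condition (ever or in the past
#' 12 months), and the two self-reported general-health groups.
#'
#' @param persons data.frame of survey responders.
#' @return named list of logical vectors, one per group, aligned with the
#'   rows of `persons`.
#' @export
default_subgroups <- function(persons) {
  cond_cols <- grep("^cond_|^ever_", names(persons), value = TRUE)
  if (length(cond_cols) == 0) stop("no condition indicators found", call. = FALSE)
  groups <- lapply(cond_cols, function(cc) persons[[cc]] %in% TRUE)
  names(groups) <- cond_cols
  any_chronic <- Reduce(`|`, groups)
  groups$any_chronic <- any_chronic
  groups$no_chronic <- !any_chronic
  if ("general_health" %in% names(persons)) {
    groups$gh_good <- persons$general_health %in% "good"
    groups$gh_fair_poor <- persons$general_health %in% "fair_poor"
  }
  groups
}

#' Default WMAR group sets
#'
#' The four sets over which the weighted mean absolute result is computed:
#' `selective` (no chronic condition plus the four ever-conditions), `all`
#' (every subgroup), `chronic` (any/no chronic condition) and
#' `general_health`.
#'
#' @param subgroup_names names of the available subgroups.
#' @return named list of character vectors.
#' @export
default_group_sets <- function(subgroup_names) {
  ever <- grep("^ever_", subgroup_names, value = TRUE)
  list(
    selective = c("no_chronic", ever),
    all = subgroup_names,
    chronic = c("any_chronic", "no_chronic"),
    general_health = intersect(c("gh_good", "gh_fair_poor"), subgroup_names)
  )
}

#' Weighted mean profit/loss of a subgroup
#'
#' Weighted mean of per-person profit over the group, with the weighted
#' standard error and a two-sided one-sample t-test against zero at the 5%
#' level. Sign convention: positive mean = profit (overcompensation),
#' negative = loss (undercompensation).
#'
#' @param revenues [compute_revenues()] table.
#' @param membership logical vector over the rows of `revenues`, or a vector
#'   of member person ids.
#' @param weights raking weights aligned with `revenues` (default equal).
#' @param name group label carried into the result.
#' @return one-row data.frame: `group`, `n`, `N_g` (weighted count),
#'   `mean_result`, `se`, `significant`.
#' @export
subgroup_profit_loss <- function(revenues, membership, weights = NULL,
                                 name = "group") {
  if (!is.logical(membership)) {
    membership <- revenues$person_id %in% membership
  }
  if (length(membership) != nrow(revenues)) {
    stop("membership length does not match revenues", call. = FALSE)
  }
  if (!any(membership)) stop(sprintf("empty subgroup `%s`", name), call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(revenues))
  x <- revenues$profit[membership]
  w <- weights[membership]
  m <- weighted_mean(x, w)
  se <- weighted_se(x, w)
  n <- length(x)
  signif <- n > 1 && se > 0 && abs(m) / se > stats::qt(0.975, df = n - 1)
  data.frame(group = name, n = n, N_g = sum(w), mean_result = m, se = se,
             significant = signif, stringsAsFactors = FALSE)
}

#' Weighted mean absolute result (WMAR)
#'
#' \deqn{WMAR = \sum_g N_g |\bar e_g| / \sum_g N_g} over a named set of
#' subgroups, where \eqn{N_g} is the (weighted) group size and
#' \eqn{\bar e_g} the group's mean profit/loss. A higher WMAR means stronger
#' incentives for risk selection.
#'
#' @param results data.frame of [subgroup_profit_loss()] rows.
#' @param group_set character vector of group names to include.
#' @return WMAR in euros.
#' @export
wmar <- function(results, group_set = results$group) {
  i <- match(group_set, results$group)
  if (anyNA(i)) {
    stop("unknown subgroup(s): ",
         paste(group_set[is.na(i)], collapse = ", "), call. = FALSE)
  }
  sum(results$N_g[i] * abs(results$mean_result[i])) / sum(results$N_g[i])
}

#' Power reduction from the high-risk pool
#'
#' Simulates the loss of cost-control incentives: spending is inflated by
#' `shock` (default 10%) while pool membership, the threshold and the flat
#' financing contribution are held fixed (ex-ante quantities of a single
#' insurer small relative to the market); compensations are recomputed on
#' the shocked basis values, and the reduction in power is the total change
#' in revenues divided by the total change in spending. Without a pool all
#' payments are prospective, so the reduction is 0; full cost reimbursement
#' would give 1.
#'
#' @param persons evaluated sample (needs `person_id`, `spending`).
#' @param residuals [compute_residuals()] table covering `persons`.
#' @param pool a [build_pool()] result or `NULL`.
#' @param shock proportional spending increase (> 0).
#' @param shock_scope `"all"` (every person's spending rises) or `"pool"`
#'   (only pool members').
#' @param recompute_financing if `TRUE` the flat contribution is recomputed
#'   after the shock (system-wide reading; the extra compensation is then
#'   clawed back from the complement, so the aggregate revenue change nets
#'   out against financing).
#' @return proportion in [0, 1].
#' @export
power_reduction <- function(persons, residuals, pool = NULL, shock = 0.10,
                            shock_scope = c("all", "pool"),
                            recompute_financing = FALSE) {
  if (shock <= 0) config_error("shock", "must be > 0")
  shock_scope <- match.arg(shock_scope)
  if (is.null(pool)) return(0)
  stopifnot(inherits(pool, "pool_assignment"))

  i <- match(persons$person_id, residuals$person_id)
  if (anyNA(i)) stop("residuals missing for some persons", call. = FALSE)
  shocked <- if (shock_scope == "all") rep(TRUE, nrow(persons)) else
    persons$person_id %in% pool$member_ids
  spend0 <- persons$spending
  spend1 <- ifelse(shocked, spend0 * (1 + shock), spend0)
  d_spending <- sum(spend1 - spend0)
  if (d_spending == 0) return(0)

  mi <- match(pool$member_ids, persons$person_id)
  share <- pool$config$compensation_share
  basis1 <- if (pool$config$compensation_basis == "residual") {
    spend1[mi] - residuals$predicted_spending[i][mi]
  } else {
    spend1[mi]
  }
  comp1 <- share * pmax(basis1 - pool$threshold, 0)
  d_revenue <- sum(comp1) - pool$total_compensation
  if (recompute_financing) {
    d_flat <- sum(comp1) / pool$n_complement - pool$flat_contribution
    d_revenue <- d_revenue - d_flat * pool$n_complement
  }
  d_revenue / d_spending
}

#' Incentive report across HRP scenarios
#'
#' Combines subgroup profits/losses, WMAR per group set and the power
#' reduction for a no-HRP baseline and a set of pool-size scenarios into the
#' selection-versus-cost-control trade-off table (the data behind a
#' WMAR-versus-power-reduction curve).
#'
#' @param scenarios named list; each element a list with components
#'   `subgroup_results` (data.frame of [subgroup_profit_loss()] rows) and
#'   `power_reduction` (scalar). Must include a `"no_hrp"` element; all
#'   scenarios must cover the same groups.
#' @param group_sets named list of group-name vectors, see
#'   [default_group_sets()].
#' @return data.frame with one row per scenario x group set: `scenario`,
#'   `group_set`, `wmar`, `power_reduction`, `wmar_change` (relative change
#'   vs no-HRP, 0 for the baseline).
#' @export
build_report <- function(scenarios, group_sets) {
  if (!"no_hrp" %in% names(scenarios)) {
    stop('scenarios must include a "no_hrp" baseline', call. = FALSE)
  }
  base_groups <- sort(scenarios[[1]]$subgroup_results$group)
  for (s in names(scenarios)) {
    if (!identical(sort(scenarios[[s]]$subgroup_results$group), base_groups)) {
      stop("scenarios evaluate inconsistent subgroup sets", call. = FALSE)
    }
  }
  rows <- list()
  for (gs in names(group_sets)) {
    w0 <- wmar(scenarios$no_hrp$subgroup_results, group_sets[[gs]])
    for (s in names(scenarios)) {
      w <- wmar(scenarios[[s]]$subgroup_results, group_sets[[gs]])
      rows[[length(rows) + 1]] <- data.frame(
        scenario = s, group_set = gs, wmar = w,
        power_reduction = scenarios[[s]]$power_reduction,
        wmar_change = if (w0 > 0) (w - w0) / w0 else 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
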