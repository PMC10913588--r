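# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: loops and closed forms instead of vectorised
# pipeline functions.

# Expected spending gap between carriers and non-carriers of one condition,
# by numerical integration over the latent severity. Valid when the
# condition has no morbidity-logit link and response is severity-independent.
expected_condition_gap <- function(config, prevalence, loading) {
  b <- stats::qlogis(prevalence)
  # exp(s - 1/2) * dnorm(s) == dnorm(s - 1), avoiding overflow in the tail
  f1 <- function(s) stats::plogis(b + loading * s) * stats::dnorm(s - 1)
  f2 <- function(s) stats::plogis(b + loading * s) * stats::dnorm(s)
  num1 <- stats::integrate(f1, -Inf, Inf)$value
  den1 <- stats::integrate(f2, -Inf, Inf)$value
  e1 <- num1 / den1
  e0 <- (1 - num1) / (1 - den1)  # E[exp(S - 1/2)] = 1
  p_use <- 1 - config$spending_noise$p_zero
  f_mort <- 1 - config$mortality_rate +
    config$mortality_rate * config$mortality_multiplier
  p_use * f_mort * config$hidden_severity_sd * (e1 - e0)
}

# IPF limit on a 2x2 table from the odds-ratio invariance: the fitted cell
# totals m_rc preserve the cross-product ratio of the observed counts and
# satisfy both margins; solve the resulting scalar equation for m_11.
ipf_2x2_oracle <- function(counts, row_targets, col_targets) {
  stopifnot(all(dim(counts) == c(2, 2)))
  or <- (counts[1, 1] * counts[2, 2]) / (counts[1, 2] * counts[2, 1])
  N <- sum(row_targets)
  g <- function(t) {
    m12 <- row_targets[1] - t
    m21 <- col_targets[1] - t
    m22 <- N - row_targets[1] - col_targets[1] + t
    (t * m22) / (m12 * m21) - or
  }
  lo <- max(0, row_targets[1] + col_targets[1] - N) + 1e-9
  hi <- min(row_targets[1], col_targets[1]) - 1e-9
  t <- stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
  matrix(c(t, col_targets[1] - t,
           row_targets[1] - t, N - row_targets[1] - col_targets[1] + t),
         nrow = 2)  # m_rc by [row, col]
}

# Per-person revenue recomputation with explicit loops.
oracle_revenues <- function(persons, residuals, pool) {
  n <- nrow(persons)
  rev <- numeric(n)
  for (i in seq_len(n)) {
    id <- persons$person_id[i]
    j <- which(residuals$person_id == id)
    r <- residuals$predicted_spending[j]
    if (!is.null(pool) && id %in% pool$member_ids) {
      basis <- if (pool$config$compensation_basis == "residual") {
        residuals$residual_spending[j]
      } else {
        persons$spending[i]
      }
      r <- r + pool$config$compensation_share * max(basis - pool$threshold, 0)
    } else if (!is.null(pool)) {
      r <- r - pool$flat_contribution
    }
    rev[i] <- r
  }
  data.frame(person_id = persons$person_id, revenue = rev,
             profit = rev - persons$spending)
}

# WMAR recomputed from person-level data with loops.
oracle_wmar <- function(revenues, groups, weights, group_set) {
  num <- 0; den <- 0
  for (g in group_set) {
    idx <- which(groups[[g]])
    wg <- weights[idx]
    eg <- sum(wg * revenues$profit[idx]) / sum(wg)
    num <- num + sum(wg) * abs(eg)
    den <- den + sum(wg)
  }
  num / den
}

# Power reduction recomputed per person.
oracle_power <- function(persons, residuals, pool, shock = 0.10) {
  if (is.null(pool)) return(0)
  d_rev <- 0; d_spend <- 0
  for (i in seq_len(nrow(persons))) {
    id <- persons$person_id[i]
    s0 <- persons$spending[i]
    s1 <- s0 * (1 + shock)
    d_spend <- d_spend + (s1 - s0)
    if (id %in% pool$member_ids) {
      j <- which(residuals$person_id == id)
      base0 <- if (pool$config$compensation_basis == "residual") {
        s0 - residuals$predicted_spending[j]
      } else s0
      base1 <- if (pool$config$compensation_basis == "residual") {
        s1 - residuals$predicted_spending[j]
      } else s1
      sh <- pool$config$compensation_share
      d_rev <- d_rev + sh * (max(base1 - pool$threshold, 0) -
                               max(base0 - pool$threshold, 0))
    }
  }
  d_rev / d_spend
}

# Small end-to-end simulation reused by oracle-equivalence tests; evaluated
# sample stays under 1000 persons.
small_pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(run_hrp_simulation(
        generator_config(n_population = 12000, survey_fraction = 0.3,
                         seed = 301, group_undercompensation = 500),
        fractions = c(0.02, 0.05)))
    }
    cache
  }
})
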