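#' Weighted mean and its standard error
#'
#' Helpers used throughout subgroup evaluation. The standard error of a
#' weighted mean uses the common design-based approximation
#' \eqn{\sqrt{\sum w_i^2 (x_i - \bar x_w)^2} / \sum w_i}, which reduces to the
#' usual \eqn{s/\sqrt n} for equal weights.
#'
#' @param x numeric vector.
#' @param w positive weights, same length as `x`.
#' @return `weighted_mean()` a scalar; `weighted_se()` a scalar standard error.
#' @keywords internal
weighted_mean <- function(x, w) {
  stopifnot(length(x) == length(w))
  sum(w * x) / sum(w)
}

#' @rdname weighted_mean
#' @keywords internal
weighted_se <- function(x, w) {
  m <- weighted_mean(x, w)
  sqrt(sum(w^2 * (x - m)^2)) / sum(w)
}

# stop() with a consistent prefix naming the offending field
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

check_proportion <- function(value, field, open = TRUE) {
  ok <- is.numeric(value) && length(value) == 1 && !is.na(value) &&
    (if (open) value > 0 && value < 1 else value >= 0 && value <= 1)
  if (!ok) {
    config_error(field, if (open) "must be a proportion in (0, 1)"
                 else "must be a proportion in [0, 1]")
  }
  invisible(value)
}

check_count <- function(value, field, min = 1) {
  ok <- is.numeric(value) && length(value) == 1 && !is.na(value) &&
    value >= min && value == as.integer(value)
  if (!ok) config_error(field, sprintf("must be an integer >= %d", min))
  invisible(value)
}
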