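#' Sample agent activities from a truncated power law
#'
#' Agent activities follow a power-law density `F(a) ~ a^(-gamma)` truncated to
#' `[eps_act, 1]` and normalized, so that most agents are rarely active and a
#' few are highly active, as observed for posting rates in social networks.
#' Draws use inverse-transform sampling of the analytic CDF:
#' `a(u) = (eps_act^(1 - gamma) + u * (1 - eps_act^(1 - gamma)))^(1 / (1 - gamma))`.
#'
#' @param n Number of agents to draw activities for.
#' @param gamma Power-law exponent (> 1); larger values concentrate activity
#'   near the minimum. Default 2.1.
#' @param eps_act Minimum activity, in (0, 1). Default 0.01.
#' @return Numeric vector of `n` activities in `[eps_act, 1]`.
#' @examples
#' set.seed(1)
#' a <- sample_activities(1000)
#' range(a)
#' @export
sample_activities <- function(n, gamma = 2.1, eps_act = 0.01) {
  n <- check_number(n, "n", lower = 1, integerish = TRUE)
  gamma <- check_number(gamma, "gamma", lower = 1, closed_lower = FALSE)
  eps_act <- check_number(eps_act, "eps_act",
    lower = 0, upper = 1,
    closed_lower = FALSE, closed_upper = FALSE
  )
  activity_quantile(runif(n), gamma, eps_act)
}

#' Quantile and distribution functions of the truncated power-law activity law
#'
#' `activity_quantile()` maps uniform quantiles `u` to activities (the inverse
#' CDF used by [sample_activities()]); `activity_cdf()` is the analytic CDF on
#' `[eps_act, 1]`.
#'
#' @param u Quantiles in `[0, 1]`.
#' @param a Activity values in `[eps_act, 1]`.
#' @inheritParams sample_activities
#' @return Numeric vector.
#' @export
activity_quantile <- function(u, gamma = 2.1, eps_act = 0.01) {
  e1 <- eps_act^(1 - gamma)
  (e1 + u * (1 - e1))^(1 / (1 - gamma))
}

#' @rdname activity_quantile
#' @export
activity_cdf <- function(a, gamma = 2.1, eps_act = 0.01) {
  e1 <- eps_act^(1 - gamma)
  (a^(1 - gamma) - e1) / (1 - e1)
}

#' Maximum-likelihood exponent of truncated power-law activities
#'
#' Fits `gamma` of the truncated power-law density on `[eps_act, 1]` by
#' numerical maximum likelihood (the normalizing constant depends on `gamma`,
#' so the textbook closed-form Hill estimator does not apply).
#'
#' @param a Activity draws in `[eps_act, 1]`.
#' @param eps_act Known lower truncation point.
#' @param interval Search interval for the exponent.
#' @return A one-row tibble with `gamma_hat`, `logLik` and `n`.
#' @export
fit_activity_exponent <- function(a, eps_act = 0.01, interval = c(1.01, 8)) {
  if (length(a) < 2L || any(a < eps_act - 1e-12) || any(a > 1 + 1e-12)) {
    stop_param("`a` must hold at least two values inside [eps_act, 1]")
  }
  sum_log <- sum(log(a))
  nn <- length(a)
  negll <- function(g) {
    # log C(g) with C = (1 - g) / (1 - eps^(1 - g)) > 0 for g > 1
    logc <- log((g - 1) / (eps_act^(1 - g) - 1))
    -(nn * logc - g * sum_log)
  }
  opt <- optimize(negll, interval = interval)
  tibble(gamma_hat = opt$minimum, logLik = -opt$objective, n = nn)
}
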