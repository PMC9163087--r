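#' Configure a random dynamical nudge (RDN)
#'
#' The RDN presents each agent with a stochastic input built from randomly
#' sampled peer opinions, added to the opinion dynamics with strength `D`.
#' The reference form is `R_i = sqrt(n) * (<X_n>_i - <X>)`: the difference
#' between agent `i`'s own random sample mean of `n` opinions and the exact
#' population mean, scaled as in the central limit theorem so its spread
#' approaches the population spread of opinions. Simpler variants drop the
#' scaling, the population mean, or the aggregation altogether.
#'
#' @param variant One of:
#'   \describe{
#'     \item{`"none"`}{no nudge (all zeros).}
#'     \item{`"clt_scaled"`}{`sqrt(n) * (<X_n>_i - <X>)`, per agent.}
#'     \item{`"clt_unscaled"`}{`<X_n>_i - <X>`, per agent.}
#'     \item{`"sample_vs_sample_mean"`}{`X_1 - <X_n>`: one sampled opinion
#'       against an independently sampled mean, per agent.}
#'     \item{`"pair_difference"`}{`X_1 - X_1'`: two independently sampled
#'       opinions, per agent.}
#'     \item{`"single_opinion"`}{`+/- X_1`: a single sampled opinion with
#'       sign set by `sign_mode`, per agent.}
#'     \item{`"shared_sample_mean"`}{one `sqrt(n) * (<X_n> - <X>)` draw per
#'       step shown identically to every agent (the control showing that a
#'       shared nudge fails to depolarize).}
#'     \item{`"wiener"`}{a per-agent Wiener process, advanced by
#'       [wiener_step()]; external noise rather than network feedback.}
#'   }
#' @param D Nudge strength (>= 0). `D = 0` short-circuits to exact zeros.
#' @param n Sample size for mean-based variants (>= 1).
#' @param exclude_self Exclude the receiving agent's own opinion from its
#'   draws (default TRUE: the nudge is built from *other* agents' opinions).
#' @param sign_mode For `"single_opinion"`: `"random"` (fresh +/- sign with
#'   equal probability per draw, default) or `"positive"` (always `+X_1`).
#' @return An object of class `nudge_config`.
#' @examples
#' nudge_config("clt_scaled", D = 3, n = 30)
#' @export
nudge_config <- function(variant = c(
                           "none", "clt_scaled", "clt_unscaled",
                           "sample_vs_sample_mean", "pair_difference",
                           "single_opinion", "shared_sample_mean", "wiener"
                         ),
                         D = 0, n = 30, exclude_self = TRUE,
                         sign_mode = c("random", "positive")) {
  variant <- match.arg(variant)
  cfg <- list(
    variant = variant,
    D = check_number(D, "D", lower = 0),
    n = check_number(n, "n", lower = 1, integerish = TRUE),
    exclude_self = check_flag(exclude_self, "exclude_self"),
    sign_mode = match.arg(sign_mode)
  )
  structure(cfg, class = "nudge_config")
}

#' @export
print.nudge_config <- function(x, ...) {
  cat(sprintf(
    "<nudge_config> variant=%s D=%g n=%d exclude_self=%s\n",
    x$variant, x$D, x$n, x$exclude_self
  ))
  invisible(x)
}

#' CLT-style nudge values
#'
#' For each agent independently, draws `n` opinions uniformly without
#' replacement and returns `sqrt(n) * (<X_n>_i - <X>)` (scaled) or
#' `<X_n>_i - <X>` (unscaled), where `<X>` is the exact population mean.
#'
#' @param opinions Numeric opinion vector.
#' @param n Sample size, `1 <= n <=` available pool.
#' @param scaled Apply the `sqrt(n)` CLT scaling (default TRUE).
#' @param exclude_self Exclude each agent's own opinion from its draw.
#' @return Numeric vector of per-agent nudge values `R_i`.
#' @export
rdn_clt <- function(opinions, n, scaled = TRUE, exclude_self = TRUE) {
  cfg <- nudge_config(if (scaled) "clt_scaled" else "clt_unscaled",
    D = 1, n = n, exclude_self = exclude_self
  )
  rdn_values(opinions, cfg)
}

# Draw k indices uniformly without replacement from agents other than `i`
# (or from everyone when exclude_self is FALSE).
draw_others <- function(N, k, i, exclude_self) {
  if (!exclude_self) {
    return(sample.int(N, k))
  }
  j <- sample.int(N - 1L, k)
  j + (j >= i)
}

#' Per-agent nudge values for any RDN variant
#'
#' Dispatches on `cfg$variant` (see [nudge_config()]). All per-agent variants
#' use independent draws for different agents within one step;
#' `"shared_sample_mean"` makes a single draw shown to all. Returns the raw
#' `R_i` values, *not* multiplied by the strength `D` (the simulators apply
#' `D` when adding the term to the dynamics); however `D = 0` or
#' `variant = "none"` short-circuits to exact zeros without consuming
#' random numbers.
#'
#' @param opinions Numeric opinion vector for the whole population.
#' @param cfg A [nudge_config()].
#' @param agents Agents to compute values for (default: all). Useful when
#'   only one agent updates per step.
#' @return Numeric vector of `R` values, one per requested agent.
#' @export
rdn_values <- function(opinions, cfg, agents = NULL) {
  stopifnot(inherits(cfg, "nudge_config"))
  N <- length(opinions)
  if (is.null(agents)) agents <- seq_len(N)
  if (cfg$variant == "none" || cfg$D == 0) {
    return(numeric(length(agents)))
  }
  if (cfg$variant == "wiener") {
    stop_param("wiener nudges carry state; advance them with wiener_step()")
  }
  pool_size <- if (cfg$exclude_self) N - 1L else N
  needs_n <- cfg$variant %in% c(
    "clt_scaled", "clt_unscaled", "sample_vs_sample_mean", "shared_sample_mean"
  )
  if (needs_n && cfg$n > pool_size) {
    abort(
      sprintf("sample size n = %d exceeds available pool of %d opinions", cfg$n, pool_size),
      class = c("rdnudge_error_sampling", "rdnudge_error")
    )
  }

  if (cfg$variant == "shared_sample_mean") {
    s <- opinions[sample.int(N, cfg$n)]
    shared <- sqrt(cfg$n) * (mean(s) - mean(opinions))
    return(rep.int(shared, length(agents)))
  }

  pop_mean <- mean(opinions)
  out <- numeric(length(agents))
  for (k in seq_along(agents)) {
    i <- agents[k]
    out[k] <- switch(cfg$variant,
      clt_scaled = {
        s <- opinions[draw_others(N, cfg$n, i, cfg$exclude_self)]
        sqrt(cfg$n) * (mean(s) - pop_mean)
      },
      clt_unscaled = {
        s <- opinions[draw_others(N, cfg$n, i, cfg$exclude_self)]
        mean(s) - pop_mean
      },
      sample_vs_sample_mean = {
        x1 <- opinions[draw_others(N, 1L, i, cfg$exclude_self)]
        s <- opinions[draw_others(N, cfg$n, i, cfg$exclude_self)]
        x1 - mean(s)
      },
      pair_difference = {
        x1 <- opinions[draw_others(N, 1L, i, cfg$exclude_self)]
        x2 <- opinions[draw_others(N, 1L, i, cfg$exclude_self)]
        x1 - x2
      },
      single_opinion = {
        x1 <- opinions[draw_others(N, 1L, i, cfg$exclude_self)]
        sgn <- if (cfg$sign_mode == "random") sample(c(-1, 1), 1L) else 1
        sgn * x1
      }
    )
  }
  out
}

#' Advance per-agent Wiener processes by one step
#'
#' Each agent's process value advances by an independent Gaussian increment
#' with mean 0 and variance `dt`; the emitted nudge is the current process
#' value. Initialize with a zero vector of length `N`.
#'
#' @param values Numeric vector of current process values.
#' @param dt Time step (> 0).
#' @return Updated numeric vector.
#' @examples
#' xi <- numeric(100)
#' xi <- wiener_step(xi, 0.01)
#' @export
wiener_step <- function(values, dt) {
  dt <- check_number(dt, "dt", lower = 0, closed_lower = FALSE)
  values + rnorm(length(values), mean = 0, sd = sqrt(dt))
}
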