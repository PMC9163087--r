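#' Configuration for the activity-driven opinion model
#'
#' Bundles and validates all parameters of the activity-driven temporal-network
#' model. Each agent `i` carries an unbounded opinion `x_i` whose sign is its
#' stance and magnitude its conviction. Opinions follow
#' `dx_i/dt = -x_i + K * sum_j A_ij(t) * tanh(alpha * x_j) + D * R_i`,
#' where `A_ij(t)` marks an input from agent `j` to `i` at time `t` and
#' `D * R_i` is an optional nudge term (see [nudge_config()]).
#'
#' @param N Number of agents.
#' @param m Partners contacted per activation (`1 <= m <= N - 1`).
#' @param K Social interaction strength (>= 0).
#' @param alpha Controversialness of the issue (> 0): gain of the saturating
#'   `tanh` influence, so that for large `alpha` even mild opinions exert
#'   near-maximal influence.
#' @param beta Homophily exponent (>= 0): connection probability decays as
#'   `|x_i - x_j|^(-beta)`; `beta = 0` gives uniform partner choice.
#' @param gamma Activity power-law exponent (> 1).
#' @param eps_act Minimum activity, in (0, 1).
#' @param r Reciprocity probability: chance that a drawn interaction also
#'   feeds back from the active agent to its partner in the same step.
#' @param p_opp Probability, per activation, of flipping the sign of `beta`
#'   for that activation so the agent preferentially contacts opposed peers.
#' @param dt Euler integration step (time units).
#' @param T Total simulated time.
#' @param x0_low,x0_high Bounds of the uniform initial-opinion distribution.
#' @param activation_mode `"per_step"` (agent active with probability `a_i`
#'   at each Euler step; default) or `"rate_times_dt"` (probability
#'   `a_i * dt`, reading the activity as a rate per unit time).
#' @param seed RNG seed used by [run_activity_model()].
#' @param stride Time interval between recorded trajectory snapshots.
#' @param delta Opinion-resolution floor for the connection probabilities:
#'   distances below `delta` are clamped to `delta` before the `^(-beta)`
#'   weighting. Besides avoiding division by zero for coincident opinions,
#'   the floor keeps the power-law kernel from collapsing all of an agent's
#'   contact weight onto its single nearest opinion-neighbour; the default
#'   0.1 (10% of the initial opinion scale) treats smaller differences as
#'   socially equivalent.
#' @param max_abs_opinion Abort threshold: the simulation stops with a
#'   diagnostic if any `|x_i|` exceeds this (surfaces numerical instability).
#' @param record_interactions Keep the full event log (needed for
#'   nearest-neighbour and in-degree metrics). Disable in large sweeps.
#' @return An object of class `activity_config` (a validated named list).
#' @seealso [run_activity_model()]
#' @examples
#' cfg <- activity_config(N = 50, T = 1, seed = 1)
#' cfg$K
#' @export
activity_config <- function(N = 1000, m = 10, K = 3, alpha = 3, beta = 3,
                            gamma = 2.1, eps_act = 0.01, r = 0.5, p_opp = 0,
                            dt = 0.01, T = 10, x0_low = -1, x0_high = 1,
                            activation_mode = c("per_step", "rate_times_dt"),
                            seed = 1L, stride = 0.1, delta = 0.1,
                            max_abs_opinion = 1e6,
                            record_interactions = TRUE) {
  N <- check_number(N, "N", lower = 2, integerish = TRUE)
  m <- check_number(m, "m", lower = 1, upper = N - 1, integerish = TRUE)
  cfg <- list(
    N = N,
    m = m,
    K = check_number(K, "K", lower = 0),
    alpha = check_number(alpha, "alpha", lower = 0, closed_lower = FALSE),
    beta = check_number(beta, "beta", lower = 0),
    gamma = check_number(gamma, "gamma", lower = 1, closed_lower = FALSE),
    eps_act = check_number(eps_act, "eps_act",
      lower = 0, upper = 1,
      closed_lower = FALSE, closed_upper = FALSE
    ),
    r = check_number(r, "r", lower = 0, upper = 1),
    p_opp = check_number(p_opp, "p_opp", lower = 0, upper = 1),
    dt = check_number(dt, "dt", lower = 0, closed_lower = FALSE),
    T = check_number(T, "T", lower = 0, closed_lower = FALSE),
    x0_low = check_number(x0_low, "x0_low"),
    x0_high = check_number(x0_high, "x0_high"),
    activation_mode = match.arg(activation_mode),
    seed = check_number(seed, "seed", integerish = TRUE),
    stride = check_number(stride, "stride", lower = 0, closed_lower = FALSE),
    delta = check_number(delta, "delta", lower = 0, closed_lower = FALSE),
    max_abs_opinion = check_number(max_abs_opinion, "max_abs_opinion", lower = 1),
    record_interactions = check_flag(record_interactions, "record_interactions")
  )
  if (cfg$T < cfg$dt) stop_param("`T` must be at least one integration step `dt`")
  if (cfg$x0_high < cfg$x0_low) stop_param("`x0_high` must be >= `x0_low`")
  structure(cfg, class = "activity_config")
}

#' @export
print.activity_config <- function(x, ...) {
  cat("<activity_config>\n")
  cat(sprintf(
    "  N=%d m=%d K=%g alpha=%g beta=%g gamma=%g eps_act=%g r=%g p_opp=%g\n",
    x$N, x$m, x$K, x$alpha, x$beta, x$gamma, x$eps_act, x$r, x$p_opp
  ))
  cat(sprintf(
    "  dt=%g T=%g x0=[%g, %g] activation=%s seed=%d\n",
    x$dt, x$T, x$x0_low, x$x0_high, x$activation_mode, x$seed
  ))
  invisible(x)
}
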