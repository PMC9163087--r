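#' Homophilic connection probabilities for one agent
#'
#' Probability that agent `i` contacts each other agent, decaying as a power
#' law of opinion distance: `p_ij ~ |x_i - x_j|^(-beta_eff)`, normalized over
#' `j != i` with `p_ii = 0`. A negative `beta_eff` (used when the homophily
#' flip fires) instead favours distant opinions. Distances below `delta` are
#' clamped to `delta` so coincident opinions do not divide by zero.
#'
#' @param opinions Numeric vector of all agents' opinions.
#' @param i Index of the focal agent.
#' @param beta_eff Effective homophily exponent (any real).
#' @param delta Distance regularization floor.
#' @return Numeric probability vector of length `length(opinions)`, summing to
#'   1, with a structural zero at position `i`.
#' @examples
#' connection_probabilities(c(0, 1, 3), i = 1, beta_eff = 1)
#' @export
connection_probabilities <- function(opinions, i, beta_eff, delta = 1e-9) {
  n <- length(opinions)
  if (n < 2L) {
    abort("at least two agents are needed to form a connection",
      class = c("rdnudge_error_no_peer", "rdnudge_error")
    )
  }
  i <- check_number(i, "i", lower = 1, upper = n, integerish = TRUE)
  w <- connection_weights(opinions, i, beta_eff, delta)
  w / sum(w)
}

# Unnormalized weights; kept separate because sample.int() renormalizes.
connection_weights <- function(opinions, i, beta_eff, delta) {
  d <- pmax(abs(opinions[i] - opinions), delta)
  w <- d^(-beta_eff)
  w[i] <- 0
  w
}

#' Draw one step of activity-driven interactions
#'
#' Each agent activates independently (probability `a_i` per step, or
#' `a_i * dt` in `"rate_times_dt"` mode). An active agent `i` draws `m`
#' distinct partners without replacement, weighted by
#' [connection_probabilities()]; with probability `p_opp` the homophily
#' exponent is negated for that activation. Every drawn partner `j`
#' contributes a directed `j -> i` input event, and with probability `r`
#' the reciprocal `i -> j` event is also recorded.
#'
#' @param opinions Numeric opinion vector.
#' @param activities Numeric activity vector in `[eps_act, 1]`.
#' @param cfg An [activity_config()].
#' @return A tibble with integer columns `source`, `target` (input flows from
#'   `source` to `target`).
#' @export
sample_interactions <- function(opinions, activities, cfg) {
  ev <- step_interactions(opinions, activities, cfg)
  tibble(source = ev$src, target = ev$tgt)
}

# Fast internal path used by the run loop: returns list(src=, tgt=) int vectors.
step_interactions <- function(opinions, activities, cfg) {
  N <- length(opinions)
  p_act <- if (cfg$activation_mode == "per_step") activities else activities * cfg$dt
  active <- which(runif(N) < p_act)
  if (length(active) == 0L) {
    return(list(src = integer(0), tgt = integer(0)))
  }
  src <- vector("list", length(active))
  tgt <- vector("list", length(active))
  for (k in seq_along(active)) {
    i <- active[k]
    beta_eff <- cfg$beta
    if (cfg$p_opp > 0 && runif(1) < cfg$p_opp) beta_eff <- -beta_eff
    w <- connection_weights(opinions, i, beta_eff, cfg$delta)
    partners <- sample.int(N, cfg$m, replace = FALSE, prob = w)
    rec <- runif(cfg$m) < cfg$r
    src[[k]] <- c(partners, rep.int(i, sum(rec)))
    tgt[[k]] <- c(rep.int(i, cfg$m), partners[rec])
  }
  list(src = unlist(src, use.names = FALSE), tgt = unlist(tgt, use.names = FALSE))
}

#' One explicit-Euler opinion update
#'
#' Applies `x_i <- x_i + dt * (-x_i + K * sum_j A_ij * tanh(alpha * x_j) +
#' nudge_i)`, where the step adjacency is given as an event table and
#' `nudge_i` is the nudge term already multiplied by its strength `D`
#' (all zeros when no nudge is active).
#'
#' @param opinions Numeric opinion vector.
#' @param events Event table for this step: a data frame with `source` and
#'   `target` columns (or a list with `src`/`tgt`).
#' @param cfg An [activity_config()].
#' @param nudge_values Per-agent nudge input `D * R_i` (defaults to zeros).
#' @return Updated opinion vector.
#' @export
opinion_step <- function(opinions, events, cfg, nudge_values = NULL) {
  if (any(!is.finite(opinions))) {
    abort("non-finite opinions entering the update; simulation is unstable",
      class = c("rdnudge_error_overflow", "rdnudge_error")
    )
  }
  N <- length(opinions)
  if (is.null(nudge_values)) nudge_values <- numeric(N)
  if (length(nudge_values) != N) {
    stop_param("`nudge_values` must have one entry per agent")
  }
  if (is.data.frame(events)) {
    events <- list(src = events$source, tgt = events$target)
  }
  infl <- numeric(N)
  if (length(events$src) > 0L) {
    th <- tanh(cfg$alpha * opinions[events$src])
    sums <- rowsum(th, events$tgt)
    infl[as.integer(rownames(sums))] <- sums[, 1L]
  }
  opinions + cfg$dt * (-opinions + cfg$K * infl + nudge_values)
}

#' Run the activity-driven opinion model
#'
#' Integrates the opinion dynamics from uniform initial opinions on
#' `[x0_low, x0_high]`, with temporal interactions drawn afresh each Euler
#' step and an optional nudge applied inside scheduled time windows. Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg An [activity_config()].
#' @param nudge A [nudge_config()]; the default applies no nudge.
#' @param schedule Nudge on/off windows: `NULL` (nudge active for the whole
#'   run), a length-2 numeric `c(t_on, t_off)`, a list of such windows, or a
#'   data frame with columns `t_on`/`t_off`. Windows must be disjoint,
#'   ordered and inside `[0, T]`; the nudge acts on steps whose start time
#'   lies in `[t_on, t_off)`.
#' @return An object of class `activity_run`: a list with
#'   \describe{
#'     \item{trajectory}{tibble `t`, `agent`, `opinion`, sampled every
#'       `cfg$stride` time units (plus `t = 0` and `t = T`).}
#'     \item{final_opinions}{numeric vector at `t = T`.}
#'     \item{activities}{the sampled activity vector.}
#'     \item{interactions}{an `interaction_log` (or `NULL` when
#'       `record_interactions = FALSE`).}
#'     \item{config, nudge, schedule}{the inputs, for provenance.}
#'   }
#' @examples
#' run <- run_activity_model(activity_config(N = 50, T = 0.5, seed = 1))
#' glance(run)
#' @export
run_activity_model <- function(cfg, nudge = nudge_config("none"), schedule = NULL) {
  stopifnot(inherits(cfg, "activity_config"))
  stopifnot(inherits(nudge, "nudge_config"))
  nudge_on <- nudge$variant != "none" && nudge$D > 0
  schedule <- normalize_schedule(schedule, cfg$T)
  if (!nudge_on) schedule <- schedule[0, ]

  set.seed(cfg$seed)
  N <- cfg$N
  a <- sample_activities(N, cfg$gamma, cfg$eps_act)
  x <- runif(N, cfg$x0_low, cfg$x0_high)
  n_steps <- as.integer(round(cfg$T / cfg$dt))
  rec_every <- max(1L, as.integer(round(cfg$stride / cfg$dt)))
  rec_steps <- if (rec_every <= n_steps) {
    seq.int(rec_every, n_steps, by = rec_every)
  } else {
    integer(0)
  }
  rec_steps <- unique(c(0L, rec_steps, n_steps))
  snap <- matrix(NA_real_, nrow = length(rec_steps), ncol = N)
  snap[1L, ] <- x
  rec_idx <- 2L

  log_src <- if (cfg$record_interactions) vector("list", n_steps) else NULL
  log_tgt <- if (cfg$record_interactions) vector("list", n_steps) else NULL
  log_len <- if (cfg$record_interactions) integer(n_steps) else NULL

  wiener <- NULL
  if (nudge_on && nudge$variant == "wiener") wiener <- numeric(N)

  for (s in seq_len(n_steps)) {
    t_prev <- (s - 1L) * cfg$dt
    ev <- step_interactions(x, a, cfg)
    nv <- NULL
    if (nudge_on && schedule_active(schedule, t_prev)) {
      if (nudge$variant == "wiener") {
        wiener <- wiener_step(wiener, cfg$dt)
        nv <- nudge$D * wiener
      } else {
        nv <- nudge$D * rdn_values(x, nudge)
      }
    }
    x <- opinion_step(x, ev, cfg, nv)
    if (any(abs(x) > cfg$max_abs_opinion)) {
      abort(
        sprintf(
          "opinion magnitude exceeded %g at t = %.3f (max |x| = %.3g); simulation unstable",
          cfg$max_abs_opinion, s * cfg$dt, max(abs(x))
        ),
        class = c("rdnudge_error_overflow", "rdnudge_error")
      )
    }
    if (cfg$record_interactions) {
      log_src[[s]] <- ev$src
      log_tgt[[s]] <- ev$tgt
      log_len[s] <- length(ev$src)
    }
    if (rec_idx <= length(rec_steps) && s == rec_steps[rec_idx]) {
      snap[rec_idx, ] <- x
      rec_idx <- rec_idx + 1L
    }
  }

  times <- rec_steps * cfg$dt
  trajectory <- tibble(
    t = rep(times, each = N),
    agent = rep.int(seq_len(N), length(times)),
    opinion = as.vector(t(snap))
  )
  interactions <- NULL
  if (cfg$record_interactions) {
    interactions <- interaction_log(
      events = tibble(
        step = rep.int(seq_len(n_steps), log_len),
        source = unlist(log_src, use.names = FALSE),
        target = unlist(log_tgt, use.names = FALSE)
      ),
      N = N
    )
  }
  structure(
    list(
      trajectory = trajectory,
      final_opinions = x,
      activities = a,
      interactions = interactions,
      config = cfg,
      nudge = nudge,
      schedule = schedule
    ),
    class = "activity_run"
  )
}

#' @export
print.activity_run <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<activity_run> N=%d T=%g beta=%g K=%g alpha=%g nudge=%s D=%g seed=%d\n",
    cfg$N, cfg$T, cfg$beta, cfg$K, cfg$alpha, x$nudge$variant, x$nudge$D, cfg$seed
  ))
  s <- classify_state(x$final_opinions)
  cat(sprintf("  final state: %s\n", s))
  invisible(x)
}

#' Directed interaction event log
#'
#' Stores the per-step directed interaction events of an activity-driven run
#' (`source -> target` meaning input from `source` to `target`). The
#' accumulated count matrix indicates which agents interacted most often.
#'
#' @param events Tibble with integer columns `step`, `source`, `target`.
#' @param N Number of agents.
#' @return An object of class `interaction_log`.
#' @export
interaction_log <- function(events, N) {
  events <- as_tibble(events)
  stopifnot(all(c("step", "source", "target") %in% names(events)))
  if (any(events$source == events$target)) {
    stop_param("interaction events must not contain self-loops")
  }
  structure(list(events = events, N = as.integer(N)), class = "interaction_log")
}

#' @export
print.interaction_log <- function(x, ...) {
  cat(sprintf(
    "<interaction_log> %d events over %d steps among %d agents\n",
    nrow(x$events), length(unique(x$events$step)), x$N
  ))
  invisible(x)
}

#' Accumulate an interaction log into a count matrix
#'
#' Folds the event sequence into an `N x N` sparse matrix `C` with `C[i, j]`
#' counting inputs from agent `j` to agent `i` (zero diagonal by
#' construction).
#'
#' @param log An [interaction_log()].
#' @param steps Optional integer range `c(first, last)` restricting the
#'   window of steps to accumulate.
#' @return A `dgCMatrix` of event counts.
#' @export
accumulate_interactions <- function(log, steps = NULL) {
  stopifnot(inherits(log, "interaction_log"))
  ev <- log$events
  if (!is.null(steps)) {
    ev <- ev[ev$step >= steps[1] & ev$step <= steps[2], ]
  }
  Matrix::sparseMatrix(
    i = ev$target, j = ev$source, x = rep.int(1, nrow(ev)),
    dims = c(log$N, log$N)
  )
}
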