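#' Configuration for the selective social-influence model
#'
#' In this model agents sit on a directed follow graph with `E` edges and
#' communicate through messages. Each time step one agent is chosen, sees a
#' screen of its followees' `m` most recent messages, moves its opinion
#' towards the mean of concordant messages (those within the bounded-
#' confidence threshold `eps_conf`), posts or reposts a message, and may
#' rewire away from a discordant poster.
#'
#' @param N Number of agents.
#' @param E Number of directed follow edges (`E <= N * (N - 1)`).
#' @param m Screen size: number of recent messages shown.
#' @param eps_conf Bounded-confidence threshold: opinions closer than this
#'   are concordant (strict inequality).
#' @param mu Influence strength in `[0, 1]`: fraction of the mean concordant
#'   opinion difference adopted per update.
#' @param p Repost probability: chance of re-posting a concordant message
#'   instead of posting the agent's own (new) opinion.
#' @param q Rewire probability: chance of replacing the tie to one discordant
#'   message's poster with a tie to a random non-followed agent.
#' @param steps Total number of time steps (one agent updates per step).
#' @param dt_sel Step size of the per-activation update map, in (0, 1].
#' @param include_decay Include the `-x_i` self-decay term in the update map.
#'   Off by default: with the decay applied at `dt_sel = 1` every
#'   self-consistent opinion cluster contracts to zero, which contradicts the
#'   persistent nonzero echo chambers this model is known to produce; the
#'   decay-free map is the original formulation. Set TRUE for the literal
#'   continuous-time reading.
#' @param x0_low,x0_high Bounds of the uniform initial-opinion distribution.
#' @param seed RNG seed.
#' @param stride Steps between recorded snapshots (opinions and peak count).
#' @param instability_window,instability_jump Runaway criterion: the run is
#'   flagged unstable (and truncated, partial trajectory retained) when any
#'   agent's opinion changes by more than `instability_jump` in one update
#'   within a trailing window of `instability_window` time steps. Single
#'   updates this large only occur when the opinion spread has already
#'   self-amplified, so this detects genuine runaway rather than benign
#'   jitter.
#' @return An object of class `selective_config`.
#' @seealso [run_selective_model()]
#' @export
selective_config <- function(N = 100, E = 400, m = 10, eps_conf = 0.5,
                             mu = 0.5, p = 0.5, q = 0.5, steps = 5000,
                             dt_sel = 1, include_decay = FALSE,
                             x0_low = -1, x0_high = 1, seed = 1L,
                             stride = 50,
                             instability_window = 10, instability_jump = 1) {
  N <- check_number(N, "N", lower = 2, integerish = TRUE)
  E <- check_number(E, "E", lower = 1, upper = N * (N - 1), integerish = TRUE)
  cfg <- list(
    N = N,
    E = E,
    m = check_number(m, "m", lower = 1, integerish = TRUE),
    eps_conf = check_number(eps_conf, "eps_conf", lower = 0, closed_lower = FALSE),
    mu = check_number(mu, "mu", lower = 0),
    p = check_number(p, "p", lower = 0, upper = 1),
    q = check_number(q, "q", lower = 0, upper = 1),
    steps = check_number(steps, "steps", lower = 1, integerish = TRUE),
    dt_sel = check_number(dt_sel, "dt_sel",
      lower = 0, upper = 1,
      closed_lower = FALSE
    ),
    include_decay = check_flag(include_decay, "include_decay"),
    x0_low = check_number(x0_low, "x0_low"),
    x0_high = check_number(x0_high, "x0_high"),
    seed = check_number(seed, "seed", integerish = TRUE),
    stride = check_number(stride, "stride", lower = 1, integerish = TRUE),
    instability_window = check_number(instability_window, "instability_window",
      lower = 1,
      integerish = TRUE
    ),
    instability_jump = check_number(instability_jump, "instability_jump",
      lower = 0,
      closed_lower = FALSE
    )
  )
  if (cfg$x0_high < cfg$x0_low) stop_param("`x0_high` must be >= `x0_low`")
  structure(cfg, class = "selective_config")
}

#' @export
print.selective_config <- function(x, ...) {
  cat(sprintf(
    "<selective_config> N=%d E=%d m=%d eps=%g mu=%g p=%g q=%g steps=%d seed=%d\n",
    x$N, x$E, x$m, x$eps_conf, x$mu, x$p, x$q, x$steps, x$seed
  ))
  invisible(x)
}

#' Initialize a selective social-influence world
#'
#' Draws `E` distinct directed follow edges uniformly (no self-loops),
#' initial opinions uniform on `[x0_low, x0_high]`, and pre-seeds the message
#' board with one message per agent holding its initial opinion, so early
#' screens are not empty. Seeds the RNG from `cfg$seed`, so equal configs
#' give identical worlds.
#'
#' @param cfg A [selective_config()].
#' @return An object of class `selective_world`: a list with `opinions`,
#'   `following` (list of each agent's followee indices; edge `i -> j` means
#'   `i` receives messages from `j`), the message board (`msg_poster`,
#'   `msg_value`, `msg_step`, `posted_by`), `step`, and a `rewire_skips`
#'   counter.
#' @export
init_selective_world <- function(cfg) {
  stopifnot(inherits(cfg, "selective_config"))
  set.seed(cfg$seed)
  N <- cfg$N
  # uniform E distinct ordered pairs, decoded from a flat index over the
  # N*(N-1) off-diagonal cells
  idx <- sample.int(N * (N - 1L), cfg$E)
  from <- (idx - 1L) %/% (N - 1L) + 1L
  off <- (idx - 1L) %% (N - 1L) + 1L
  to <- off + (off >= from)
  following <- unname(split(to, factor(from, levels = seq_len(N))))
  opinions <- runif(N, cfg$x0_low, cfg$x0_high)
  world <- list(
    opinions = opinions,
    following = following,
    msg_poster = seq_len(N),
    msg_value = opinions,
    msg_step = rep.int(0L, N),
    posted_by = as.list(seq_len(N)),
    step = 0L,
    rewire_skips = 0L
  )
  structure(world, class = "selective_world")
}

#' @export
print.selective_world <- function(x, ...) {
  cat(sprintf(
    "<selective_world> %d agents, %d follow edges, %d messages, step %d\n",
    length(x$opinions), sum(lengths(x$following)), length(x$msg_poster), x$step
  ))
  invisible(x)
}

#' Concordance indicator for bounded confidence
#'
#' Two opinions are concordant when strictly closer than the bounded-
#' confidence threshold: `|x_i - x_j| < eps_conf`. Distances exactly equal to
#' the threshold are discordant.
#'
#' @param x_i,x_j Opinion values (vectorized).
#' @param eps_conf Bounded-confidence threshold.
#' @return Integer 0/1 vector.
#' @examples
#' concordance(0, 0.5, eps_conf = 0.5) # exactly at the threshold: discordant
#' @export
concordance <- function(x_i, x_j, eps_conf) {
  as.integer(abs(x_i - x_j) < eps_conf)
}

# Indices (into the message board) of the agent's screen, newest first.
# Recency is global posting order; the pre-seeded initial messages share
# step 0 and tie-break by insertion order.
screen_indices <- function(world, agent, m) {
  followees <- world$following[[agent]]
  if (length(followees) == 0L) {
    return(integer(0))
  }
  cand <- unlist(
    lapply(followees, function(f) tail(world$posted_by[[f]], m)),
    use.names = FALSE
  )
  if (length(cand) == 0L) {
    return(integer(0))
  }
  sort(cand, decreasing = TRUE)[seq_len(min(m, length(cand)))]
}

#' Message screen shown to an agent
#'
#' The opinion values of the `m` most recent messages (newest first) among
#' those posted or reposted by accounts the agent follows; reposted messages
#' carry their original opinion value. Fewer than `m` are returned when fewer
#' exist; an agent following no one sees an empty screen.
#'
#' @param world A [init_selective_world()] world.
#' @param agent Agent index.
#' @param m Screen size (defaults to 10, the usual screen length).
#' @return Numeric vector of up to `m` message opinion values, newest first.
#' @export
screen <- function(world, agent, m = 10) {
  world$msg_value[screen_indices(world, agent, m)]
}

#' Selective opinion update
#'
#' Moves an agent's opinion towards the mean of concordant screen messages:
#' `x_i <- x_i + dt_sel * (mu * mean(x_j - x_i over concordant) + nudge)`,
#' with an optional `-x_i` decay term when `include_decay` is set. When no
#' screen message is concordant the opinion is unchanged (the update's
#' normalization is undefined for an empty concordant set).
#'
#' @param x_i Current opinion.
#' @param screen_values Opinion values on the agent's screen.
#' @param cfg A [selective_config()].
#' @param nudge_value Nudge input `D * R_i`, already multiplied by strength.
#' @return Updated opinion (scalar).
#' @examples
#' cfg <- selective_config()
#' selective_update(0, c(0.2, 0.4, 0.9), cfg) # concordant: 0.2, 0.4
#' @export
selective_update <- function(x_i, screen_values, cfg, nudge_value = 0) {
  conc <- screen_values[abs(screen_values - x_i) < cfg$eps_conf]
  if (length(conc) == 0L) {
    return(x_i)
  }
  drift <- cfg$mu * mean(conc - x_i) + nudge_value
  if (cfg$include_decay) drift <- drift - x_i
  x_i + cfg$dt_sel * drift
}

#' Post or repost a message
#'
#' With probability `p`, and if the agent's screen holds at least one
#' concordant message, the agent reposts one of them chosen uniformly (the
#' repost carries the original opinion value, attributed to the reposting
#' agent). Otherwise the agent posts a new message with its current opinion.
#'
#' @param world A `selective_world`.
#' @param agent Agent index.
#' @param cfg A [selective_config()].
#' @return The updated world.
#' @export
post_message <- function(world, agent, cfg) {
  scr <- screen_indices(world, agent, cfg$m)
  vals <- world$msg_value[scr]
  conc <- scr[abs(vals - world$opinions[agent]) < cfg$eps_conf]
  value <- if (length(conc) > 0L && runif(1) < cfg$p) {
    world$msg_value[conc[sample.int(length(conc), 1L)]]
  } else {
    world$opinions[agent]
  }
  idx <- length(world$msg_poster) + 1L
  world$msg_poster[idx] <- as.integer(agent)
  world$msg_value[idx] <- value
  world$msg_step[idx] <- as.integer(world$step)
  world$posted_by[[agent]] <- c(world$posted_by[[agent]], idx)
  world
}

#' Rewire away from a discordant poster
#'
#' With probability `q`, and only if the agent's screen contained at least
#' one discordant message, removes the follow edge to one uniformly chosen
#' discordant message's poster and adds a follow edge to a uniformly chosen
#' agent that is neither followed already nor the agent itself. The total
#' edge count is conserved; if no new target is available the rewire is
#' skipped (counted in `world$rewire_skips`).
#'
#' @inheritParams post_message
#' @return The updated world.
#' @export
rewire <- function(world, agent, cfg) {
  if (runif(1) >= cfg$q) {
    return(world)
  }
  scr <- screen_indices(world, agent, cfg$m)
  vals <- world$msg_value[scr]
  disc <- scr[abs(vals - world$opinions[agent]) >= cfg$eps_conf]
  if (length(disc) == 0L) {
    return(world)
  }
  drop_poster <- world$msg_poster[disc[sample.int(length(disc), 1L)]]
  followees <- world$following[[agent]]
  candidates <- setdiff(seq_len(length(world$opinions)), c(agent, followees))
  if (length(candidates) == 0L) {
    world$rewire_skips <- world$rewire_skips + 1L
    return(world)
  }
  new_target <- candidates[sample.int(length(candidates), 1L)]
  pos <- which(followees == drop_poster)[1L]
  followees[pos] <- new_target
  world$following[[agent]] <- followees
  world
}

#' Run the selective social-influence model
#'
#' Per time step: one agent is chosen uniformly (or taken from
#' `agent_order`), sees its screen, updates its opinion (with a scheduled
#' nudge, if any), posts or reposts a message, and possibly rewires.
#' Opinions and the peak count of the opinion distribution are recorded every
#' `cfg$stride` steps. The run is flagged unstable and truncated (partial
#' trajectory retained) if any agent's opinion changes by more than
#' `instability_jump` within `instability_window` steps.
#'
#' @param cfg A [selective_config()].
#' @param nudge A [nudge_config()].
#' @param schedule Nudge windows in step units (same forms as in
#'   [run_activity_model()]); `NULL` applies the nudge for the whole run.
#' @param agent_order Optional integer vector of length `cfg$steps` fixing
#'   which agent updates at each step (useful for deterministic traces);
#'   default is uniform random choice.
#' @return An object of class `selective_run`: list with `trajectory`
#'   (tibble `t`, `agent`, `opinion`; `t` is the step index), `peak_series`
#'   (tibble `t`, `n_peaks`), `final_opinions`, `world` (final state),
#'   `unstable` flag, and the inputs.
#' @examples
#' run <- run_selective_model(selective_config(steps = 200, seed = 1))
#' glance(run)
#' @export
run_selective_model <- function(cfg, nudge = nudge_config("none"),
                                schedule = NULL, agent_order = NULL) {
  stopifnot(inherits(cfg, "selective_config"))
  stopifnot(inherits(nudge, "nudge_config"))
  nudge_on <- nudge$variant != "none" && nudge$D > 0
  schedule <- normalize_schedule(schedule, cfg$steps)
  if (!nudge_on) schedule <- schedule[0, ]
  if (!is.null(agent_order) && length(agent_order) < cfg$steps) {
    stop_param("`agent_order` must supply an agent for every step")
  }

  world <- init_selective_world(cfg) # seeds the RNG
  N <- cfg$N
  wiener <- if (nudge_on && nudge$variant == "wiener") numeric(N) else NULL

  rec_steps <- if (cfg$stride <= cfg$steps) {
    seq.int(cfg$stride, cfg$steps, by = cfg$stride)
  } else {
    integer(0)
  }
  rec_steps <- unique(c(0L, rec_steps, cfg$steps))
  snap <- matrix(NA_real_, nrow = length(rec_steps), ncol = N)
  peak_counts <- integer(length(rec_steps))
  snap[1L, ] <- world$opinions
  peak_counts[1L] <- count_peaks(world$opinions)
  rec_idx <- 2L

  # trailing window of per-step opinion changes for the instability criterion
  win <- cfg$instability_window
  recent_jump <- numeric(win)
  unstable <- FALSE
  last_step <- cfg$steps

  for (s in seq_len(cfg$steps)) {
    world$step <- s
    agent <- if (is.null(agent_order)) sample.int(N, 1L) else as.integer(agent_order[s])
    x_before <- world$opinions
    # Nudge first: the selected agent's opinion evolves under the nudge
    # continuously, so the bounded-confidence screen comparison acts on the
    # nudged opinion. This is what lets the nudge bridge otherwise-discordant
    # clusters.
    if (nudge_on && schedule_active(schedule, s - 1L)) {
      nv <- if (nudge$variant == "wiener") {
        wiener <- wiener_step(wiener, cfg$dt_sel)
        nudge$D * wiener[agent]
      } else {
        nudge$D * rdn_values(world$opinions, nudge, agents = agent)
      }
      world$opinions[agent] <- world$opinions[agent] + cfg$dt_sel * nv
    }
    scr <- screen_indices(world, agent, cfg$m)
    world$opinions[agent] <- selective_update(
      world$opinions[agent], world$msg_value[scr], cfg
    )
    world <- post_message(world, agent, cfg)
    world <- rewire(world, agent, cfg)

    recent_jump[(s - 1L) %% win + 1L] <- max(abs(world$opinions - x_before))
    if (max(recent_jump) > cfg$instability_jump) {
      unstable <- TRUE
      last_step <- s
    }

    if (rec_idx <= length(rec_steps) && s == rec_steps[rec_idx]) {
      snap[rec_idx, ] <- world$opinions
      peak_counts[rec_idx] <- count_peaks(world$opinions)
      rec_idx <- rec_idx + 1L
    }
    if (unstable) break
  }

  keep <- rec_steps <= last_step & !is.na(snap[, 1L])
  rec_steps <- rec_steps[keep]
  snap <- snap[keep, , drop = FALSE]
  peak_counts <- peak_counts[keep]
  if (unstable) {
    warn(sprintf(
      "selective run became numerically unstable at step %d (opinion change > %g within %d steps); partial trajectory retained",
      last_step, cfg$instability_jump, win
    ))
  }

  structure(
    list(
      trajectory = tibble(
        t = rep(rec_steps, each = N),
        agent = rep.int(seq_len(N), length(rec_steps)),
        opinion = as.vector(t(snap))
      ),
      peak_series = tibble(t = rec_steps, n_peaks = peak_counts),
      final_opinions = world$opinions,
      world = world,
      unstable = unstable,
      config = cfg,
      nudge = nudge,
      schedule = schedule
    ),
    class = "selective_run"
  )
}

#' @export
print.selective_run <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<selective_run> N=%d E=%d steps=%d nudge=%s D=%g seed=%d%s\n",
    cfg$N, cfg$E, cfg$steps, x$nudge$variant, x$nudge$D, cfg$seed,
    if (x$unstable) " [UNSTABLE]" else ""
  ))
  cat(sprintf(
    "  final peaks: %d\n", tail(x$peak_series$n_peaks, 1)
  ))
  invisible(x)
}
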