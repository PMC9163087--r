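# Shared helpers: independent reference implementations used as oracles, a
# hand-constructable selective world, and a cache for the heavy simulation
# runs shared between the acceptance blocks.

# Scalar per-agent reference for one Euler opinion update (independent of the
# vectorized implementation path).
ref_opinion_step <- function(x, events, K, alpha, dt, nudge = numeric(length(x))) {
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    infl <- 0
    for (k in seq_len(nrow(events))) {
      if (events$target[k] == i) {
        infl <- infl + tanh(alpha * x[events$source[k]])
      }
    }
    out[i] <- x[i] + dt * (-x[i] + K * infl + nudge[i])
  }
  out
}

# Build a selective world by hand (bypassing init_selective_world) so screen
# and posting behaviour can be traced on tiny examples.
make_world <- function(opinions, following, msg_poster = seq_along(opinions),
                       msg_value = opinions,
                       msg_step = rep.int(0L, length(msg_poster))) {
  posted_by <- lapply(seq_along(opinions), function(i) which(msg_poster == i))
  structure(
    list(
      opinions = opinions,
      following = following,
      msg_poster = msg_poster,
      msg_value = msg_value,
      msg_step = as.integer(msg_step),
      posted_by = posted_by,
      step = max(msg_step),
      rewire_skips = 0L
    ),
    class = "selective_world"
  )
}

# Independent step-by-step reference for the deterministic selective-model
# scenario (p = 0, q = 0, D = 0, fixed agent order): plain loops and its own
# screen bookkeeping.
ref_selective_trace <- function(opinions, following, agent_order, m, eps, mu,
                                include_decay = FALSE, dt_sel = 1) {
  msgs_poster <- seq_along(opinions)
  msgs_value <- opinions
  x <- opinions
  for (agent in agent_order) {
    sel <- which(msgs_poster %in% following[[agent]])
    sel <- sort(sel, decreasing = TRUE) # newest first, like the implementation
    scr <- msgs_value[sel[seq_len(min(m, length(sel)))]]
    conc <- scr[abs(scr - x[agent]) < eps]
    if (length(conc) > 0) {
      drift <- mu * mean(conc - x[agent])
      if (include_decay) drift <- drift - x[agent]
      x[agent] <- x[agent] + dt_sel * drift
    }
    # p = 0: always post own (new) opinion
    msgs_poster <- c(msgs_poster, agent)
    msgs_value <- c(msgs_value, x[agent])
  }
  list(opinions = x, msg_poster = msgs_poster, msg_value = msgs_value)
}

# Cache for expensive shared simulations (acceptance blocks reuse these).
.run_cache <- new.env(parent = emptyenv())

cached_activity_run <- function(beta, D, seed, T = 10) {
  key <- sprintf("act_b%g_D%g_s%d_T%g", beta, D, seed, T)
  if (is.null(.run_cache[[key]])) {
    nd <- if (D > 0) nudge_config("clt_scaled", D = D, n = 30) else nudge_config("none")
    cfg <- activity_config(
      N = 1000, T = T, beta = beta, seed = seed,
      record_interactions = FALSE
    )
    .run_cache[[key]] <- run_activity_model(cfg, nd)
  }
  .run_cache[[key]]
}

cached_selective_run <- function(D, seed, steps = 5000, n = 1) {
  key <- sprintf("sel_D%g_s%d_st%d_n%d", D, seed, steps, n)
  if (is.null(.run_cache[[key]])) {
    nd <- if (D > 0) nudge_config("clt_scaled", D = D, n = n) else nudge_config("none")
    .run_cache[[key]] <- suppressWarnings(
      run_selective_model(selective_config(steps = steps, seed = seed), nd)
    )
  }
  .run_cache[[key]]
}
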