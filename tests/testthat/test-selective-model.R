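test_that("world initialization satisfies the structural invariants", {
  cfg <- selective_config(N = 100, E = 400, seed = 42)
  w <- init_selective_world(cfg)
  edges <- sum(lengths(w$following))
  expect_identical(edges, 400L)
  expect_equal(edges / 100, 4) # mean out-degree exactly E/N
  for (i in seq_len(100)) {
    expect_false(i %in% w$following[[i]])
    expect_false(any(duplicated(w$following[[i]])))
  }
  # one seeded message per agent holding its initial opinion
  expect_identical(w$msg_poster, 1:100)
  expect_identical(w$msg_value, w$opinions)
  # determinism
  w2 <- init_selective_world(cfg)
  expect_identical(w, w2)
})

test_that("concordance is strict at the bounded-confidence threshold", {
  expect_identical(concordance(0, 0.5, eps_conf = 0.5), 0L)
  expect_identical(concordance(0.3, 0.3, eps_conf = 0.5), 1L)
  expect_identical(concordance(0, 0.49, eps_conf = 0.5), 1L)
  expect_identical(concordance(c(0, 0), c(0.2, 0.9), 0.5), c(1L, 0L))
})

test_that("screen shows the newest followee messages, newest first", {
  w <- make_world(
    opinions = c(0, 0.5, -0.5),
    following = list(2L, integer(0), integer(0)),
    msg_poster = c(1L, 2L, 3L, 2L, 2L),
    msg_value = c(0, 0.5, -0.5, 0.6, 0.7),
    msg_step = c(0L, 0L, 0L, 1L, 2L)
  )
  expect_identical(screen(w, 1, m = 2), c(0.7, 0.6))
  expect_identical(screen(w, 1, m = 10), c(0.7, 0.6, 0.5))
  expect_identical(screen(w, 2, m = 5), numeric(0)) # follows no one
})

test_that("a reposted message surfaces its original opinion value", {
  # agent 3 follows 2; agent 2 follows 1; agent 1 posted value 0.9 at step 0.
  # agent 2 (opinion 0.8, concordant) reposts with p = 1; agent 3 then sees 0.9.
  w <- make_world(
    opinions = c(0.9, 0.8, 0.1),
    following = list(integer(0), 1L, 2L)
  )
  cfg <- selective_config(N = 3, E = 2, p = 1, seed = 1)
  w$step <- 1L
  set.seed(1)
  w <- post_message(w, 2, cfg)
  expect_identical(tail(w$msg_poster, 1), 2L)
  expect_identical(tail(w$msg_value, 1), 0.9) # original value, not 0.8
  expect_true(0.9 %in% screen(w, 3, m = 10))
})

test_that("selective update follows the concordant-mean map", {
  cfg <- selective_config(eps_conf = 0.5, mu = 0.5, dt_sel = 1)
  # screen {0.2, 0.4, 0.9}: concordant {0.2, 0.4}, mean difference 0.3
  expect_equal(selective_update(0, c(0.2, 0.4, 0.9), cfg), 0.15)
  # all discordant: unchanged
  expect_identical(selective_update(0, c(0.9, -0.8), cfg), 0)
  # empty screen: unchanged
  expect_identical(selective_update(0.3, numeric(0), cfg), 0.3)
  # all equal to own opinion: zero differences
  expect_identical(selective_update(0.2, c(0.2, 0.2), cfg), 0.2)
  # nudge enters additively
  expect_equal(selective_update(0, c(0.2, 0.4, 0.9), cfg, nudge_value = 0.1), 0.25)
  # literal form with self-decay
  cfg_d <- selective_config(eps_conf = 0.5, mu = 0.5, dt_sel = 1, include_decay = TRUE)
  expect_equal(selective_update(0.1, c(0.2, 0.4), cfg_d), 0.1 + (-0.1 + 0.5 * 0.2))
})

test_that("posting honours the repost probability and fallback rule", {
  w0 <- make_world(
    opinions = c(0.5, 0.45),
    following = list(2L, 1L)
  )
  cfg_p0 <- selective_config(N = 2, E = 2, p = 0, seed = 1)
  set.seed(2)
  w <- post_message(w0, 1, cfg_p0)
  expect_identical(tail(w$msg_value, 1), 0.5) # always a fresh message
  cfg_p1 <- selective_config(N = 2, E = 2, p = 1, seed = 1)
  set.seed(2)
  w <- post_message(w0, 1, cfg_p1)
  expect_identical(tail(w$msg_value, 1), 0.45) # always a repost
  # discordant screen: fallback to a new message even at p = 1
  w1 <- make_world(opinions = c(0.5, -0.45), following = list(2L, 1L))
  set.seed(2)
  w <- post_message(w1, 1, cfg_p1)
  expect_identical(tail(w$msg_value, 1), 0.5)
})

test_that("rewiring conserves edges and never creates self-loops or duplicates", {
  cfg <- selective_config(N = 20, E = 60, q = 1, eps_conf = 0.3, seed = 3)
  w <- init_selective_world(cfg)
  E0 <- sum(lengths(w$following))
  set.seed(4)
  for (k in 1:200) {
    agent <- sample.int(20, 1)
    w <- rewire(w, agent, cfg)
    expect_identical(sum(lengths(w$following)), E0)
    expect_false(agent %in% w$following[[agent]])
    expect_false(any(duplicated(w$following[[agent]])))
  }
  # q = 0 never changes the graph
  cfg_q0 <- selective_config(N = 20, E = 60, q = 0, seed = 3)
  set.seed(5)
  w2 <- rewire(w, 1, cfg_q0)
  expect_identical(w2$following, w$following)
})

test_that("messages are append-only and frozen at posting time", {
  cfg <- selective_config(N = 30, E = 90, steps = 300, seed = 6)
  mid <- run_selective_model(selective_config(N = 30, E = 90, steps = 150, seed = 6))
  full <- run_selective_model(cfg)
  n_mid <- length(mid$world$msg_value)
  expect_identical(
    full$world$msg_value[seq_len(n_mid)],
    mid$world$msg_value
  )
  expect_identical(
    full$world$msg_poster[seq_len(n_mid)],
    mid$world$msg_poster
  )
})

test_that("with mu = 0 and no nudge, opinions are constant for all time", {
  cfg <- selective_config(N = 20, E = 60, mu = 0, steps = 400, seed = 7)
  run <- run_selective_model(cfg)
  x0 <- run$trajectory$opinion[run$trajectory$t == 0]
  expect_identical(run$final_opinions, x0)
})

test_that("runs are seed-reproducible and the nudge perturbs the path", {
  cfg <- selective_config(N = 30, E = 120, steps = 300, seed = 8)
  r1 <- run_selective_model(cfg)
  r2 <- run_selective_model(cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  r3 <- run_selective_model(cfg, nudge_config("clt_scaled", D = 0.2, n = 1))
  expect_false(identical(r1$final_opinions, r3$final_opinions))
})

test_that("a deterministic 5-agent scenario matches an independent trace", {
  # p = 0, q = 0, no nudge, fixed cyclic agent order: fully deterministic
  cfg <- selective_config(
    N = 5, E = 10, m = 3, eps_conf = 0.5, mu = 0.5,
    p = 0, q = 0, steps = 20, seed = 9
  )
  order <- rep(1:5, 4)
  run <- run_selective_model(cfg, agent_order = order)
  w0 <- init_selective_world(cfg)
  ref <- ref_selective_trace(
    w0$opinions, w0$following, order,
    m = 3, eps = 0.5, mu = 0.5
  )
  expect_equal(run$final_opinions, ref$opinions, tolerance = 1e-12)
  expect_identical(run$world$msg_poster, ref$msg_poster)
  expect_equal(run$world$msg_value, ref$msg_value, tolerance = 1e-12)
})

test_that("selective config invariants are enforced", {
  expect_error(selective_config(E = 100 * 99 + 1), class = "rdnudge_error_param")
  expect_error(selective_config(p = 1.5), class = "rdnudge_error_param")
  expect_error(selective_config(eps_conf = 0), class = "rdnudge_error_param")
  expect_error(selective_config(dt_sel = 0), class = "rdnudge_error_param")
})
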