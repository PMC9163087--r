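test_that("connection probabilities are uniform at beta = 0 and match hand weights", {
  p <- connection_probabilities(c(0.3, -1, 2, 0.5), i = 2, beta_eff = 0)
  expect_equal(p, c(1 / 3, 0, 1 / 3, 1 / 3))
  # opinions (0, 1, 3), focal agent x = 0, beta = 1: weights 1 and 1/3
  p <- connection_probabilities(c(0, 1, 3), i = 1, beta_eff = 1)
  expect_equal(p, c(0, 0.75, 0.25))
})

test_that("connection probabilities normalize, are nonnegative, and ignore self", {
  set.seed(5)
  for (rep in 1:20) {
    x <- rnorm(30, sd = 2)
    i <- sample.int(30, 1)
    beta <- sample(c(-3, 0, 0.7, 3), 1)
    p <- connection_probabilities(x, i, beta)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    expect_identical(p[i], 0)
  }
})

test_that("connection probabilities are invariant under a global sign flip", {
  x <- c(0.2, -1.4, 3.1, 0.01, -2)
  expect_equal(
    connection_probabilities(x, 3, 2.5),
    connection_probabilities(-x, 3, 2.5)
  )
})

test_that("fewer than two agents cannot form connections", {
  expect_error(connection_probabilities(1.5, 1, 3), class = "rdnudge_error_no_peer")
})

test_that("Euler opinion update matches closed-form decay", {
  cfg <- activity_config(N = 2, m = 1, K = 0, T = 1, dt = 0.01, seed = 1)
  no_events <- list(src = integer(0), tgt = integer(0))
  x <- c(1, 1)
  expect_equal(opinion_step(x, no_events, cfg)[1], 0.99)
  for (s in 1:100) x <- opinion_step(x, no_events, cfg)
  expect_equal(x[1], 0.99^100)
  expect_equal(x[1], exp(-1), tolerance = 2 * 0.01) # e^(-t) within O(dt)
})

test_that("opinion update applies the saturating social term", {
  # two mutually connected agents, x = (2, -2), alpha = 3, K = 3, dt = 0.01
  cfg <- activity_config(N = 2, m = 1, K = 3, alpha = 3, T = 1, dt = 0.01, seed = 1)
  ev <- data.frame(source = c(2L, 1L), target = c(1L, 2L))
  x <- opinion_step(c(2, -2), ev, cfg)
  expect_equal(x[1], 2 + 0.01 * (-2 + 3 * tanh(-6)))
  expect_equal(x[1], 1.95, tolerance = 1e-4)
  expect_equal(x[2], -x[1])
})

test_that("vectorized update equals the scalar per-agent reference", {
  set.seed(9)
  cfg <- activity_config(N = 5, m = 2, K = 2, alpha = 1.5, T = 1, dt = 0.01, seed = 1)
  for (rep in 1:10) {
    x <- rnorm(5)
    pairs <- expand.grid(source = 1:5, target = 1:5)
    pairs <- pairs[pairs$source != pairs$target, ]
    ev <- pairs[runif(nrow(pairs)) < 0.4, ]
    nudge <- rnorm(5, sd = 0.5)
    expect_equal(
      opinion_step(x, ev, cfg, nudge),
      ref_opinion_step(x, ev, cfg$K, cfg$alpha, cfg$dt, nudge),
      tolerance = 1e-12
    )
  }
})

test_that("non-finite opinions abort with a diagnostic", {
  cfg <- activity_config(N = 2, m = 1, T = 1, seed = 1)
  expect_error(
    opinion_step(c(NaN, 0), list(src = integer(0), tgt = integer(0)), cfg),
    class = "rdnudge_error_overflow"
  )
})

test_that("forced reciprocity mirrors every interaction event", {
  cfg <- activity_config(N = 20, m = 3, r = 1, T = 1, seed = 1)
  set.seed(2)
  ev <- sample_interactions(rnorm(20), rep(0.9, 20), cfg)
  key <- paste(ev$source, ev$target)
  rev_key <- paste(ev$target, ev$source)
  expect_true(all(rev_key %in% key))
  # and in-degree equals out-degree per agent
  expect_equal(tabulate(ev$target, 20), tabulate(ev$source, 20))
})

test_that("a single active agent with m = N - 1 hears every peer exactly once", {
  cfg <- activity_config(N = 10, m = 9, beta = 0, r = 0, T = 1, seed = 1)
  set.seed(3)
  act <- c(1, rep(1e-12, 9)) # only agent 1 activates
  ev <- sample_interactions(rnorm(10), act, cfg)
  expect_equal(sort(ev$source), 2:10)
  expect_equal(ev$target, rep(1L, 9))
})

test_that("events contain no self-loops and r = 0 gives m events per active agent", {
  cfg <- activity_config(N = 30, m = 4, r = 0, T = 1, seed = 1)
  set.seed(4)
  for (rep in 1:10) {
    x <- rnorm(30)
    a <- runif(30, 0.2, 0.9)
    ev <- sample_interactions(x, a, cfg)
    expect_true(all(ev$source != ev$target))
    counts <- table(ev$target)
    expect_true(all(counts == 4))
  }
})

test_that("per-step activation rate matches the binomial expectation", {
  cfg <- activity_config(N = 50, m = 2, r = 0, T = 1, seed = 1)
  set.seed(6)
  a <- runif(50, 0.05, 0.6)
  x <- rnorm(50)
  n_steps <- 1e4
  total_active <- 0
  for (s in seq_len(n_steps)) {
    ev <- rdnudge:::step_interactions(x, a, cfg)
    total_active <- total_active + length(ev$src) / cfg$m
  }
  expected <- n_steps * sum(a)
  se <- sqrt(n_steps * sum(a * (1 - a)))
  expect_lt(abs(total_active - expected), 3 * se)
})

test_that("runs are reproducible and pure decay obeys the closed-form bound", {
  cfg <- activity_config(N = 50, T = 1, seed = 123)
  r1 <- run_activity_model(cfg)
  r2 <- run_activity_model(cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$final_opinions, r2$final_opinions)

  cfg0 <- activity_config(N = 50, K = 0, T = 2, seed = 5)
  r0 <- run_activity_model(cfg0)
  x0 <- r0$trajectory$opinion[r0$trajectory$t == 0]
  steps <- round(cfg0$T / cfg0$dt)
  expect_lte(
    max(abs(r0$final_opinions)),
    max(abs(x0)) * (1 - cfg0$dt)^steps + 1e-12
  )
})

test_that("interaction log folds into the accumulated count matrix", {
  cfg <- activity_config(N = 15, m = 2, T = 0.5, seed = 8)
  run <- run_activity_model(cfg)
  log <- run$interactions
  acc <- accumulate_interactions(log)
  expect_equal(sum(acc), nrow(log$events))
  expect_true(all(Matrix::diag(acc) == 0))
  # fold independently
  ref <- matrix(0, 15, 15)
  for (k in seq_len(nrow(log$events))) {
    i <- log$events$target[k]
    j <- log$events$source[k]
    ref[i, j] <- ref[i, j] + 1
  }
  expect_equal(as.matrix(acc), ref, ignore_attr = TRUE)
})

test_that("schedule validation rejects overlapping or out-of-range windows", {
  cfg <- activity_config(N = 20, T = 1, seed = 1)
  nd <- nudge_config("clt_scaled", D = 1, n = 5)
  expect_error(
    run_activity_model(cfg, nd, schedule = data.frame(
      t_on = c(0, 0.4), t_off = c(0.5, 0.9)
    )),
    class = "rdnudge_error_schedule"
  )
  expect_error(
    run_activity_model(cfg, nd, schedule = c(0.5, 2)),
    class = "rdnudge_error_schedule"
  )
  # valid window runs fine
  expect_s3_class(
    run_activity_model(cfg, nd, schedule = c(0.2, 0.8)),
    "activity_run"
  )
})

test_that("config invariants are enforced", {
  expect_error(activity_config(N = 10, m = 10), class = "rdnudge_error_param")
  expect_error(activity_config(r = 1.2), class = "rdnudge_error_param")
  expect_error(activity_config(T = 0.001, dt = 0.01), class = "rdnudge_error_param")
  expect_error(activity_config(gamma = 1), class = "rdnudge_error_param")
})
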