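test_that("bin width is the minimum of the Sturges and Freedman-Diaconis rules", {
  x <- seq(0, 1, length.out = 256)
  # Sturges: 1 / (log2(256) + 1) = 1/9; FD: 2 * 0.5 / 256^(1/3) ~ 0.157
  expect_equal(bin_width(x), 1 / 9)
  # scale equivariance
  expect_equal(bin_width(3 * x), 3 * bin_width(x))
  expect_equal(bin_width(0.1 * x), 0.1 * bin_width(x))
  # zero IQR with nonzero range falls back to the Sturges term
  y <- c(0, rep(0.5, 20), 1)
  expect_equal(bin_width(y), 1 / (log2(22) + 1))
})

test_that("degenerate samples are rejected by the bin rule", {
  expect_error(bin_width(rep(2, 10)), class = "rdnudge_error_degenerate")
  expect_error(bin_width(1.5), class = "rdnudge_error_degenerate")
})

test_that("peak distance separates two narrow clusters and collapses for unimodal data", {
  set.seed(21)
  bimodal <- c(rnorm(500, -1, 0.05), rnorm(500, 1, 0.05))
  ps <- peak_distance(bimodal)
  expect_gt(ps$lambda_x, 1.8)
  expect_lt(ps$lambda_x, 2.2)
  expect_identical(ps$n_peaks, 2L)

  unimodal <- rnorm(1000, 0, 0.1)
  ps_u <- peak_distance(unimodal)
  expect_lt(ps_u$lambda_x, 0.5)
})

test_that("peak distance and peak count are sign-flip invariant", {
  set.seed(22)
  x <- c(rnorm(400, -0.8, 0.1), rnorm(600, 1.2, 0.2))
  expect_equal(peak_distance(x)$lambda_x, peak_distance(-x)$lambda_x)
  expect_identical(count_peaks(x), count_peaks(-x))
})

test_that("peak distance scales approximately with the opinions", {
  set.seed(23)
  x <- c(rnorm(500, -1, 0.05), rnorm(500, 1, 0.05))
  for (c_scale in c(0.5, 3)) {
    ps <- peak_distance(x)
    ps_c <- peak_distance(c_scale * x)
    w <- max(ps_c$bin_width, na.rm = TRUE)
    expect_lt(abs(ps_c$lambda_x - c_scale * ps$lambda_x), w + c_scale * max(ps$bin_width))
  }
})

test_that("one-sided distributions leave the peak distance undefined", {
  set.seed(24)
  x <- abs(rnorm(500, 2, 0.5)) + 0.1
  ps <- peak_distance(x)
  expect_true(is.na(ps$lambda_x))
  expect_true("one_sided" %in% ps$flags)
  expect_error(peak_distance(numeric(0)), class = "rdnudge_error_param")
})

test_that("peak counting resolves modes with the prominence rule", {
  set.seed(25)
  expect_identical(count_peaks(rnorm(1000)), 1L)
  two <- c(rnorm(500, -1, 0.05), rnorm(500, 1, 0.05))
  expect_identical(count_peaks(two), 2L)
  three <- c(rnorm(400, -2, 0.1), rnorm(400, 0, 0.1), rnorm(400, 2, 0.1))
  expect_identical(count_peaks(three), 3L)
  expect_identical(count_peaks(rep(0.3, 50)), 1L)
  # a tiny satellite below the prominence threshold is not a peak
  weak <- c(rnorm(2000, 0, 0.1), rnorm(20, 3, 0.02))
  expect_identical(count_peaks(weak, prominence_frac = 0.1), 1L)
  expect_error(count_peaks(numeric(0)), class = "rdnudge_error_param")
})

test_that("nearest-neighbour mean opinion weights inputs by interaction counts", {
  # agent 1 heard agent 2 twice (x = 0.5) and agent 3 once (x = -1)
  log <- interaction_log(
    tibble::tibble(
      step = c(1L, 1L, 2L, 2L),
      source = c(2L, 3L, 2L, 3L),
      target = c(1L, 1L, 1L, 2L)
    ),
    N = 3
  )
  x <- c(0, 0.5, -1)
  nn <- nn_mean_opinion(x, log)
  expect_equal(nn$nn_mean[1], (2 * 0.5 + 1 * (-1)) / 3)
  expect_equal(nn$nn_mean[1], 0)
  expect_equal(nn$nn_mean[2], -1) # single neighbour: its opinion
  expect_true(is.na(nn$nn_mean[3])) # no inputs
  expect_equal(nn$n_inputs, c(3, 1, 0))
  # always within the neighbours' range
  expect_true(all(nn$nn_mean >= min(x) & nn$nn_mean <= max(x), na.rm = TRUE))
})

test_that("in-degree summary conserves events and matches hand counts", {
  log <- interaction_log(
    tibble::tibble(
      step = c(1L, 1L, 2L, 3L),
      source = c(2L, 3L, 4L, 2L),
      target = c(1L, 1L, 2L, 3L)
    ),
    N = 4
  )
  s <- in_degree_summary(log)
  expect_equal(s$per_agent$in_degree, c(2, 1, 1, 0))
  expect_equal(sum(s$per_agent$in_degree), nrow(log$events))
  expect_equal(sum(s$histogram$prob), 1)
  # windowed
  s12 <- in_degree_summary(log, window = c(1, 2))
  expect_equal(sum(s12$per_agent$in_degree), 3)
  s_empty <- in_degree_summary(log, window = c(10, 20))
  expect_equal(nrow(s_empty$histogram), 0)
})

test_that("self-loops are rejected by the interaction log", {
  expect_error(
    interaction_log(tibble::tibble(step = 1L, source = 2L, target = 2L), N = 3),
    class = "rdnudge_error_param"
  )
})

test_that("end states are classified by sign dominance and peak structure", {
  expect_identical(classify_state(rep(2, 100)), "radicalized")
  set.seed(26)
  expect_identical(classify_state(rnorm(1000, 3, 0.4)), "radicalized")
  expect_identical(
    classify_state(c(rnorm(500, -1, 0.05), rnorm(500, 1, 0.05))),
    "polarized"
  )
  expect_identical(classify_state(rnorm(1000, 0, 0.05)), "consensus")
})

test_that("opinion summaries collect the metric set in one row", {
  set.seed(27)
  x <- c(rnorm(300, -1, 0.1), rnorm(300, 1, 0.1))
  s <- summarize_opinions(x)
  expect_identical(s$state, "polarized")
  expect_identical(s$n_peaks, 2L)
  expect_false(s$one_sided)
  td <- tidy(peak_distance(x))
  expect_identical(td$n_peaks, 2L)
  expect_equal(td$lambda_x, s$lambda_x)
})
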