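# Internal validation and seeding helpers.

stop_param <- function(msg, class = "rdnudge_error_param") {
  abort(msg, class = c(class, "rdnudge_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param(sprintf("`%s` must be a single finite number", name))
  }
  ok_lo <- if (closed_lower) x >= lower else x > lower
  ok_hi <- if (closed_upper) x <= upper else x < upper
  if (!ok_lo || !ok_hi) {
    stop_param(sprintf(
      "`%s` = %g is outside %s%g, %g%s", name, x,
      if (closed_lower) "[" else "(", lower, upper,
      if (closed_upper) "]" else ")"
    ))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop_param(sprintf("`%s` must be an integer", name))
  }
  if (integerish) as.integer(round(x)) else as.numeric(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_param(sprintf("`%s` must be TRUE or FALSE", name))
  }
  x
}

# Deterministic per-run seed from (master seed, sweep point, replicate).
# Linear-congruential style fold kept below 2^31 so it is a valid set.seed()
# input on all platforms; multiplier small enough that every intermediate
# product stays exactly representable in a double.
derive_seed <- function(master, point = 1L, rep = 1L) {
  m <- 2147483647
  h <- (abs(as.numeric(master)) %% m)
  for (k in c(point, rep)) {
    h <- (h * 69069 + as.numeric(k) + 1) %% m
  }
  as.integer(h)
}

# Normalize a nudge on/off schedule to a validated tibble with columns
# t_on/t_off. `limit` is total simulated time (or steps).
normalize_schedule <- function(schedule, limit) {
  if (is.null(schedule)) {
    return(tibble(t_on = 0, t_off = as.numeric(limit)))
  }
  if (is.numeric(schedule) && length(schedule) == 2L) {
    schedule <- tibble(t_on = schedule[1], t_off = schedule[2])
  }
  if (is.list(schedule) && !is.data.frame(schedule)) {
    schedule <- tibble(
      t_on = vapply(schedule, function(w) w[[1]], numeric(1)),
      t_off = vapply(schedule, function(w) w[[2]], numeric(1))
    )
  }
  schedule <- as_tibble(schedule)
  if (!all(c("t_on", "t_off") %in% names(schedule))) {
    abort("schedule must have columns `t_on` and `t_off`",
      class = c("rdnudge_error_schedule", "rdnudge_error")
    )
  }
  if (nrow(schedule) == 0L) {
    return(schedule[, c("t_on", "t_off")])
  }
  schedule <- schedule[order(schedule$t_on), c("t_on", "t_off")]
  bad <- schedule$t_on < 0 | schedule$t_off > limit | schedule$t_on >= schedule$t_off
  overlap <- nrow(schedule) > 1L &&
    any(schedule$t_on[-1L] < schedule$t_off[-nrow(schedule)])
  if (any(bad) || overlap) {
    abort(
      sprintf("schedule windows must be disjoint, ordered and within [0, %g]", limit),
      class = c("rdnudge_error_schedule", "rdnudge_error")
    )
  }
  schedule
}

# TRUE when time t falls inside any [t_on, t_off) window.
schedule_active <- function(schedule, t) {
  if (nrow(schedule) == 0L) {
    return(FALSE)
  }
  any(t >= schedule$t_on & t < schedule$t_off)
}
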