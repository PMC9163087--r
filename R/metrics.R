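#' Histogram bin width for an opinion subset
#'
#' The minimum of the Sturges width `(max - min) / (log2(n) + 1)` and the
#' Freedman-Diaconis width `2 * IQR / n^(1/3)`, computed on the subset
#' itself (`n` is the subset size). When the IQR is zero the Sturges term is
#' used alone; a subset with fewer than two values or zero range is
#' degenerate.
#'
#' @param sample Numeric vector of opinion values.
#' @return Bin width `w` (opinion units).
#' @examples
#' bin_width(seq(0, 1, length.out = 256))
#' @export
bin_width <- function(sample) {
  sample <- sample[is.finite(sample)]
  n <- length(sample)
  rng <- if (n > 0) max(sample) - min(sample) else 0
  if (n < 2L || rng == 0) {
    abort("bin width is undefined for fewer than 2 values or zero range",
      class = c("rdnudge_error_degenerate", "rdnudge_error")
    )
  }
  sturges <- rng / (log2(n) + 1)
  iqr <- unname(diff(quantile(sample, c(0.25, 0.75))))
  if (iqr == 0) {
    return(sturges)
  }
  fd <- 2 * iqr / n^(1 / 3)
  min(sturges, fd)
}

# Center of the maximal-count histogram bin of one opinion side at bin width
# `w`. Bins are anchored at the side's magnitude minimum (the edge nearest
# zero) and computed on |v|, so the negative side is the exact mirror of the
# positive side and the statistic is invariant under a global sign flip.
# Ties break toward the bin center nearest 0 (conservative: under-reports
# polarization).
side_argmax <- function(v, w) {
  sgn <- if (all(v < 0)) -1 else 1
  m <- abs(v)
  lo <- min(m)
  k <- pmin(floor((m - lo) / w), ceiling((max(m) - lo) / w) - 1)
  counts <- tabulate(k + 1L)
  centers <- lo + (seq_along(counts) - 0.5) * w
  best <- which(counts == max(counts))
  sgn * centers[best[which.min(abs(centers[best]))]]
}

#' Peak distance of a polarized opinion distribution
#'
#' Splits the opinions into positive and negative subsets, histograms each
#' with its own [bin_width()], and returns the distance between the centers
#' of the two maximal-density bins. A peak distance near 0 indicates a
#' depolarized (unimodal, centered) distribution; large values indicate
#' polarized echo chambers. If either side holds less than `min_side_frac`
#' of the agents the distribution is one-sided (e.g. radicalized) and the
#' peak distance is undefined (`NA`) rather than 0, so one-sided runs are
#' not mistaken for depolarized ones.
#'
#' @param opinions Numeric opinion vector.
#' @param min_side_frac Minimum fraction of agents on each side for the
#'   distance to be defined (default 0.01).
#' @return An object of class `peak_summary`: list with `lambda_x`,
#'   `n_peaks` (from [count_peaks()]), `peak_positions` (negative- and
#'   positive-side argmax), `flags` (character subset of `"one_sided"`,
#'   `"degenerate"`), and `bin_width` (named, one per side). Use [tidy()] for
#'   a one-row tibble.
#' @examples
#' x <- c(rnorm(500, -1, 0.05), rnorm(500, 1, 0.05))
#' peak_distance(x)$lambda_x
#' @export
peak_distance <- function(opinions, min_side_frac = 0.01) {
  opinions <- opinions[is.finite(opinions)]
  if (length(opinions) == 0L) {
    stop_param("`opinions` must be non-empty")
  }
  pos <- opinions[opinions > 0]
  neg <- opinions[opinions < 0]
  n_tot <- length(opinions)
  flags <- character(0)
  widths <- c(neg = NA_real_, pos = NA_real_)
  positions <- c(neg = NA_real_, pos = NA_real_)
  lambda <- NA_real_

  if (length(pos) < min_side_frac * n_tot || length(neg) < min_side_frac * n_tot) {
    flags <- c(flags, "one_sided")
  } else {
    one_side <- function(v) {
      w <- tryCatch(bin_width(v), rdnudge_error_degenerate = function(e) NA_real_)
      if (is.na(w)) {
        # all values on this side (numerically) identical: a single spike
        list(w = NA_real_, pos = v[1], degenerate = TRUE)
      } else {
        list(w = w, pos = side_argmax(v, w), degenerate = FALSE)
      }
    }
    sn <- one_side(neg)
    sp <- one_side(pos)
    widths <- c(neg = sn$w, pos = sp$w)
    positions <- c(neg = sn$pos, pos = sp$pos)
    if (sn$degenerate || sp$degenerate) flags <- c(flags, "degenerate")
    lambda <- sp$pos - sn$pos
  }

  structure(
    list(
      lambda_x = lambda,
      n_peaks = count_peaks(opinions),
      peak_positions = positions,
      flags = flags,
      bin_width = widths
    ),
    class = "peak_summary"
  )
}

#' @export
print.peak_summary <- function(x, ...) {
  cat(sprintf(
    "<peak_summary> lambda_x=%s n_peaks=%d flags=[%s]\n",
    if (is.na(x$lambda_x)) "undefined" else sprintf("%.3f", x$lambda_x),
    x$n_peaks, paste(x$flags, collapse = ", ")
  ))
  invisible(x)
}

#' @method tidy peak_summary
#' @export
tidy.peak_summary <- function(x, ...) {
  tibble(
    lambda_x = x$lambda_x,
    n_peaks = x$n_peaks,
    peak_neg = unname(x$peak_positions["neg"]),
    peak_pos = unname(x$peak_positions["pos"]),
    one_sided = "one_sided" %in% x$flags,
    degenerate = "degenerate" %in% x$flags
  )
}

#' Count the peaks of an opinion distribution
#'
#' Counts local maxima of a Gaussian kernel density estimate whose
#' topographic prominence exceeds `prominence_frac` of the global maximum
#' density. The kernel bandwidth defaults to the Sheather-Jones plug-in
#' estimate (falling back to Silverman's rule when it cannot be computed):
#' heavy-tailed opinion distributions inflate range- and IQR-based
#' bandwidths enough to smooth away a genuinely bimodal bulk, which the
#' plug-in estimate resolves. A constant (or near-constant) sample counts
#' as one peak.
#'
#' @param opinions Numeric opinion vector.
#' @param prominence_frac Minimum prominence as a fraction of the maximum
#'   density (default 0.1).
#' @param bw Kernel bandwidth override (opinion units).
#' @return Integer peak count (>= 1 for any non-empty sample).
#' @examples
#' count_peaks(c(rnorm(500, -1, 0.05), rnorm(500, 1, 0.05)))
#' @export
count_peaks <- function(opinions, prominence_frac = 0.1, bw = NULL) {
  opinions <- opinions[is.finite(opinions)]
  if (length(opinions) == 0L) {
    stop_param("`opinions` must be non-empty")
  }
  if (length(unique(opinions)) < 3L || max(opinions) - min(opinions) == 0) {
    return(1L)
  }
  if (is.null(bw)) {
    bw <- tryCatch(stats::bw.SJ(opinions),
      error = function(e) {
        tryCatch(stats::bw.nrd0(opinions), error = function(e2) NA_real_)
      }
    )
    if (!is.finite(bw) || bw <= 0) {
      return(1L)
    }
  }
  d <- density(opinions, bw = bw, n = 512)
  y <- d$y
  n <- length(y)
  is_max <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(is_max) == 0L) {
    return(1L)
  }
  prom <- vapply(is_max, function(i) peak_prominence(y, i), numeric(1))
  count <- sum(prom > prominence_frac * max(y))
  max(count, 1L)
}

# Topographic prominence of the local maximum at index i: height minus the
# higher of the two valley floors separating it from the nearest higher
# point on each side (signal edge if none).
peak_prominence <- function(y, i) {
  h <- y[i]
  left <- y[seq_len(i - 1L)]
  right <- y[seq.int(i + 1L, length(y))]
  higher_l <- which(left > h)
  base_l <- if (length(higher_l) > 0) {
    min(left[seq.int(max(higher_l), length(left))])
  } else {
    min(left)
  }
  higher_r <- which(right > h)
  base_r <- if (length(higher_r) > 0) {
    min(right[seq_len(min(higher_r))])
  } else {
    min(right)
  }
  h - max(base_l, base_r)
}

#' Nearest-neighbour mean opinion
#'
#' For each agent, the interaction-count-weighted mean opinion of the agents
#' it received input from: `<x_NN>_i = sum_j c_ij x_j / sum_j c_ij`, with
#' `c_ij` the accumulated number of inputs from `j` to `i`. Plotting agent
#' opinion against this quantity reveals echo chambers as two clusters on
#' the diagonal.
#'
#' @param opinions Numeric opinion vector.
#' @param interactions An [interaction_log()], or an `N x N` count matrix
#'   with `[i, j]` counting inputs from `j` to `i`.
#' @return A tibble with `agent`, `opinion`, `nn_mean` (NA for agents that
#'   received no input), and `n_inputs`.
#' @export
nn_mean_opinion <- function(opinions, interactions) {
  counts <- if (inherits(interactions, "interaction_log")) {
    accumulate_interactions(interactions)
  } else {
    interactions
  }
  totals <- Matrix::rowSums(counts)
  weighted <- as.numeric(counts %*% opinions)
  nn <- ifelse(totals > 0, weighted / totals, NA_real_)
  tibble(
    agent = seq_along(opinions),
    opinion = opinions,
    nn_mean = nn,
    n_inputs = as.numeric(totals)
  )
}

#' Per-agent in-degree summary of an interaction log
#'
#' Counts incoming interaction events per agent within a step window, and
#' the normalized in-degree distribution.
#'
#' @param log An [interaction_log()].
#' @param window Optional `c(first_step, last_step)` range; default all.
#' @return List with `per_agent` (tibble `agent`, `in_degree`) and
#'   `histogram` (tibble `in_degree`, `prob` summing to 1).
#' @export
in_degree_summary <- function(log, window = NULL) {
  stopifnot(inherits(log, "interaction_log"))
  ev <- log$events
  if (!is.null(window)) {
    ev <- ev[ev$step >= window[1] & ev$step <= window[2], ]
  }
  deg <- tabulate(ev$target, nbins = log$N)
  per_agent <- tibble(agent = seq_len(log$N), in_degree = deg)
  histogram <- if (nrow(ev) == 0L) {
    tibble(in_degree = integer(0), prob = numeric(0))
  } else {
    dplyr::count(per_agent, .data$in_degree, name = "k") |>
      dplyr::mutate(prob = .data$k / sum(.data$k)) |>
      dplyr::select("in_degree", "prob")
  }
  list(per_agent = per_agent, histogram = histogram)
}

#' Classify the end state of an opinion distribution
#'
#' Operational classification of the three qualitative outcomes:
#' `"radicalized"` when at least `radical_frac` of the agents share one
#' stance (opinion sign) and the median magnitude exceeds
#' `radical_median`; `"polarized"` when the distribution has at least two
#' peaks and a defined peak distance above `lambda_min`; otherwise
#' `"consensus"` (a unimodal, centered distribution).
#'
#' @param opinions Numeric opinion vector.
#' @param radical_frac Majority-sign fraction for radicalization (default 0.9).
#' @param radical_median Minimum `|median|` for radicalization (default 0.5).
#' @param lambda_min Minimum peak distance for polarization (default 0.5).
#' @return One of `"consensus"`, `"polarized"`, `"radicalized"`.
#' @examples
#' classify_state(rnorm(1000, 0, 0.1))
#' @export
classify_state <- function(opinions, radical_frac = 0.9, radical_median = 0.5,
                           lambda_min = 0.5) {
  opinions <- opinions[is.finite(opinions)]
  if (length(opinions) == 0L) {
    stop_param("`opinions` must be non-empty")
  }
  sign_frac <- max(mean(opinions > 0), mean(opinions < 0))
  if (sign_frac >= radical_frac && abs(median(opinions)) > radical_median) {
    return("radicalized")
  }
  ps <- peak_distance(opinions)
  if (ps$n_peaks >= 2L && !is.na(ps$lambda_x) && ps$lambda_x > lambda_min) {
    return("polarized")
  }
  "consensus"
}

#' One-line metric summary of an opinion sample
#'
#' Convenience wrapper combining [peak_distance()], [count_peaks()] and
#' [classify_state()] into a one-row tibble; the unit of analysis in
#' experiment result tables.
#'
#' @param opinions Numeric opinion vector.
#' @return One-row tibble: `lambda_x`, `n_peaks`, `state`, `one_sided`,
#'   `mean_opinion`, `sd_opinion`.
#' @export
summarize_opinions <- function(opinions) {
  ps <- peak_distance(opinions)
  tibble(
    lambda_x = ps$lambda_x,
    n_peaks = ps$n_peaks,
    state = classify_state(opinions),
    one_sided = "one_sided" %in% ps$flags,
    mean_opinion = mean(opinions),
    sd_opinion = stats::sd(opinions)
  )
}
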