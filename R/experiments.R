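#' Define a sweep experiment
#'
#' An experiment is a base model configuration plus a nudge, an optional
#' on/off schedule, a Cartesian parameter sweep, and a number of replicate
#' seeds per sweep point. Sweep keys may name fields of the base config
#' (e.g. `beta`, `K`, `p_opp`) or of the nudge config (`variant`, `D`, `n`).
#'
#' @param model `"activity"` or `"selective"`.
#' @param base An [activity_config()] or [selective_config()] matching
#'   `model`; defaults to the model's defaults.
#' @param nudge A [nudge_config()].
#' @param schedule Nudge windows (see [run_activity_model()]).
#' @param sweep Named list mapping parameter names to value vectors.
#' @param n_seeds Replicate seeds per sweep point (>= 1).
#' @param eval_times For activity experiments: trajectory times at which to
#'   evaluate metrics (default: final time only). Selective experiments are
#'   always evaluated at the final step.
#' @return An object of class `experiment_spec`.
#' @seealso [preset()], [run_experiment()]
#' @export
experiment_spec <- function(model = c("activity", "selective"), base = NULL,
                            nudge = nudge_config("none"), schedule = NULL,
                            sweep = list(), n_seeds = 5, eval_times = NULL) {
  model <- match.arg(model)
  if (is.null(base)) {
    base <- if (model == "activity") activity_config() else selective_config()
  }
  expected <- if (model == "activity") "activity_config" else "selective_config"
  if (!inherits(base, expected)) {
    stop_param(sprintf("`base` must be a %s for model = \"%s\"", expected, model))
  }
  stopifnot(inherits(nudge, "nudge_config"))
  n_seeds <- check_number(n_seeds, "n_seeds", lower = 1, integerish = TRUE)
  if (length(sweep) > 0) {
    if (is.null(names(sweep)) || any(names(sweep) == "")) {
      stop_param("all `sweep` entries must be named")
    }
    known <- c(names(unclass(base)), names(unclass(nudge)))
    bad <- setdiff(names(sweep), known)
    if (length(bad) > 0) {
      stop_param(sprintf(
        "unknown sweep parameter(s): %s", paste(bad, collapse = ", ")
      ))
    }
  }
  structure(
    list(
      model = model, base = base, nudge = nudge, schedule = schedule,
      sweep = sweep, n_seeds = n_seeds, eval_times = eval_times
    ),
    class = "experiment_spec"
  )
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf(
    "<experiment_spec> model=%s sweep={%s} n_seeds=%d nudge=%s\n",
    x$model, paste(names(x$sweep), collapse = ", "), x$n_seeds, x$nudge$variant
  ))
  invisible(x)
}

# Cartesian sweep grid as a tibble (one row per point; a single empty point
# when there is no sweep).
sweep_grid <- function(sweep) {
  if (length(sweep) == 0) {
    return(tibble(.point = 1L))
  }
  grid <- as_tibble(expand.grid(sweep,
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  ))
  grid$.point <- seq_len(nrow(grid))
  grid
}

# Apply one sweep point to (base, nudge) configs; revalidates via the
# constructors so invariants hold for every point.
apply_point <- function(spec, point_row) {
  base_args <- unclass(spec$base)
  nudge_args <- unclass(spec$nudge)
  for (key in setdiff(names(point_row), ".point")) {
    val <- point_row[[key]]
    if (key %in% names(nudge_args)) {
      nudge_args[[key]] <- val
    } else {
      base_args[[key]] <- val
    }
  }
  base <- if (spec$model == "activity") {
    do.call(activity_config, base_args)
  } else {
    do.call(selective_config, base_args)
  }
  list(base = base, nudge = do.call(nudge_config, nudge_args))
}

#' Run a sweep experiment
#'
#' Executes the Cartesian sweep crossed with `n_seeds` replicate seeds. Each
#' run's seed is derived deterministically from the master seed, the sweep
#' point index and the replicate index, so the full result table is
#' reproducible and any single run can be replayed from its recorded seed.
#' Interaction logging is disabled for activity runs (metrics here only need
#' opinions).
#'
#' @param spec An [experiment_spec()].
#' @param master_seed Master seed for the whole experiment.
#' @param verbose Print one progress line per run.
#' @return A long tibble with one row per (sweep point x seed x evaluation
#'   time): the sweep parameters, `seed`, `t_eval`, `lambda_x`, `n_peaks`,
#'   `state`, `one_sided`, `unstable` and `runtime` (seconds). The
#'   `master_seed` and spec are attached as attributes.
#' @examples
#' spec <- experiment_spec("selective",
#'   base = selective_config(steps = 200),
#'   sweep = list(q = c(0, 0.5)), n_seeds = 2
#' )
#' run_experiment(spec, master_seed = 1, verbose = FALSE)
#' @export
run_experiment <- function(spec, master_seed = 1, verbose = TRUE) {
  stopifnot(inherits(spec, "experiment_spec"))
  grid <- sweep_grid(spec$sweep)
  rows <- vector("list", nrow(grid) * spec$n_seeds)
  k <- 0L
  for (gi in seq_len(nrow(grid))) {
    point <- grid[gi, , drop = FALSE]
    cfgs <- apply_point(spec, as.list(point))
    for (si in seq_len(spec$n_seeds)) {
      run_seed <- derive_seed(master_seed, point$.point, si)
      t0 <- proc.time()[["elapsed"]]
      res <- run_one(spec, cfgs$base, cfgs$nudge, run_seed)
      runtime <- proc.time()[["elapsed"]] - t0
      res$runtime <- runtime
      res$seed <- run_seed
      params <- point[rep(1L, nrow(res)), setdiff(names(point), ".point"), drop = FALSE]
      k <- k + 1L
      rows[[k]] <- dplyr::bind_cols(params, res)
      if (verbose) {
        message(sprintf(
          "[%s] point %d/%d seed %d/%d: state=%s (%.1fs)",
          spec$model, gi, nrow(grid), si, spec$n_seeds,
          res$state[nrow(res)], runtime
        ))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "master_seed") <- master_seed
  attr(out, "spec") <- spec
  out
}

# One simulation -> metric rows (one per evaluation time).
run_one <- function(spec, base, nudge, run_seed) {
  base$seed <- run_seed
  if (spec$model == "activity") {
    base$record_interactions <- FALSE
    run <- run_activity_model(base, nudge, spec$schedule)
    times <- spec$eval_times %||% base$T
    purrr::map_dfr(times, function(tt) {
      traj_t <- run$trajectory$t
      ut <- unique(traj_t)
      nearest <- ut[which.min(abs(ut - tt))]
      x <- run$trajectory$opinion[traj_t == nearest]
      dplyr::bind_cols(
        tibble(t_eval = nearest),
        summarize_opinions(x),
        tibble(unstable = FALSE)
      )
    })
  } else {
    run <- suppressWarnings(
      run_selective_model(base, nudge, spec$schedule)
    )
    dplyr::bind_cols(
      tibble(t_eval = max(run$trajectory$t)),
      summarize_opinions(run$final_opinions),
      tibble(unstable = run$unstable)
    )
  }
}

#' Figure-protocol experiment presets
#'
#' Ready-made [experiment_spec()]s for the standard protocols: prevention
#' from the start, homophily flipping, Wiener baseline, shared-versus-unique
#' nudges, delayed on/off depolarization, robustness sweeps, and the
#' selective-model grid. Replicate counts default to desk scale (3-5 seeds);
#' raise `n_seeds` for full-scale runs.
#'
#' @param name One of `"fig1_polarized"`, `"fig1_radicalized"`,
#'   `"fig1_popp"`, `"fig1_wiener"`, `"fig2_shared_vs_unique"`,
#'   `"fig3_delayed_rdn"`, `"fig5_variants"`, `"fig5_sweep"`,
#'   `"fig6_selective"`, `"fig6_delayed"`.
#' @param n_seeds Override the preset's replicate count.
#' @return An [experiment_spec()].
#' @examples
#' preset("fig3_delayed_rdn")$schedule
#' @export
preset <- function(name = c(
                     "fig1_polarized", "fig1_radicalized", "fig1_popp",
                     "fig1_wiener", "fig2_shared_vs_unique", "fig3_delayed_rdn",
                     "fig5_variants", "fig5_sweep", "fig6_selective",
                     "fig6_delayed"
                   ),
                   n_seeds = NULL) {
  name <- tryCatch(match.arg(name), error = function(e) {
    stop_param(sprintf("unknown preset \"%s\"", paste(name, collapse = ", ")),
      class = "rdnudge_error_config"
    )
  })
  act <- function(...) activity_config(...)
  spec <- switch(name,
    fig1_polarized = experiment_spec("activity",
      base = act(beta = 3, T = 10),
      n_seeds = 5
    ),
    fig1_radicalized = experiment_spec("activity",
      base = act(beta = 0, T = 10),
      n_seeds = 5
    ),
    fig1_popp = experiment_spec("activity",
      base = act(beta = 3, T = 10),
      sweep = list(p_opp = c(0, 0.1, 0.2, 0.3, 0.4, 0.5)),
      n_seeds = 5
    ),
    fig1_wiener = experiment_spec("activity",
      base = act(beta = 3, T = 10),
      nudge = nudge_config("wiener", D = 1),
      sweep = list(D = c(0, 1, 3, 5)),
      n_seeds = 3
    ),
    fig2_shared_vs_unique = experiment_spec("activity",
      base = act(beta = 3, T = 5),
      nudge = nudge_config("clt_scaled", D = 3, n = 30),
      sweep = list(
        variant = c("shared_sample_mean", "clt_scaled"),
        D = c(0, 1, 3, 5)
      ),
      n_seeds = 3
    ),
    fig3_delayed_rdn = experiment_spec("activity",
      base = act(beta = 3, T = 30),
      nudge = nudge_config("clt_scaled", D = 3, n = 30),
      schedule = c(10, 20),
      eval_times = c(10, 20, 30),
      n_seeds = 5
    ),
    fig5_variants = experiment_spec("activity",
      base = act(beta = 3, T = 5),
      nudge = nudge_config("clt_scaled", D = 3, n = 30),
      sweep = list(variant = c(
        "clt_scaled", "clt_unscaled", "sample_vs_sample_mean",
        "pair_difference", "single_opinion", "none"
      )),
      n_seeds = 5
    ),
    fig5_sweep = experiment_spec("activity",
      base = act(beta = 3, T = 5),
      nudge = nudge_config("clt_scaled", D = 3, n = 30),
      sweep = list(
        D = c(0, 1, 3, 5), alpha = c(1, 3), K = c(1, 3),
        beta = c(0, 1, 3)
      ),
      n_seeds = 3
    ),
    fig6_selective = experiment_spec("selective",
      base = selective_config(steps = 5000),
      nudge = nudge_config("clt_scaled", D = 0.2, n = 1),
      sweep = list(D = c(0, 0.1, 0.2), n = c(1, 10)),
      n_seeds = 5
    ),
    fig6_delayed = experiment_spec("selective",
      base = selective_config(steps = 50000),
      nudge = nudge_config("clt_scaled", D = 0.2, n = 1),
      schedule = c(5000, 50000),
      n_seeds = 3
    )
  )
  if (!is.null(n_seeds)) spec$n_seeds <- check_number(n_seeds, "n_seeds", lower = 1, integerish = TRUE)
  spec
}

#' Write experiment outputs to a directory
#'
#' Emits `results.csv` (the long result table), `manifest.json` (the full
#' spec: model, base and nudge configs, schedule, sweep, seeds and master
#' seed), and `summary.json` (per-sweep-point aggregates: mean peak
#' distance, modal peak count, end-state tallies).
#'
#' @param results A result tibble from [run_experiment()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_experiment_outputs <- function(results, dir) {
  if (!dir.exists(dir)) {
    ok <- tryCatch(dir.create(dir, recursive = TRUE), warning = function(w) FALSE)
    if (isFALSE(ok) || !dir.exists(dir)) {
      abort(sprintf("cannot create output directory '%s'", dir),
        class = c("rdnudge_error_io", "rdnudge_error")
      )
    }
  }
  spec <- attr(results, "spec")
  master_seed <- attr(results, "master_seed")

  results_path <- file.path(dir, "results.csv")
  readr::write_csv(results, results_path)

  manifest <- list(
    package = "rdnudge",
    version = as.character(utils::packageVersion("rdnudge")),
    master_seed = master_seed
  )
  if (!is.null(spec)) {
    manifest$model <- spec$model
    manifest$base <- unclass(spec$base)
    manifest$nudge <- unclass(spec$nudge)
    manifest$schedule <- if (is.null(spec$schedule)) NULL else as.data.frame(spec$schedule)
    manifest$sweep <- spec$sweep
    manifest$n_seeds <- spec$n_seeds
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )

  sweep_keys <- if (!is.null(spec)) names(spec$sweep) else character(0)
  summary_tbl <- if (nrow(results) == 0L) {
    tibble()
  } else {
    results |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c(sweep_keys, "t_eval")))) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean_lambda_x = mean(.data$lambda_x, na.rm = TRUE),
      modal_n_peaks = modal_value(.data$n_peaks),
      n_consensus = sum(.data$state == "consensus"),
      n_polarized = sum(.data$state == "polarized"),
      n_radicalized = sum(.data$state == "radicalized"),
      .groups = "drop"
    )
  }
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(summary_tbl, summary_path,
    dataframe = "rows", digits = NA, na = "null", pretty = TRUE
  )

  invisible(c(results = results_path, manifest = manifest_path, summary = summary_path))
}

#' Modal value of an integer vector
#'
#' The most frequent value; ties broken toward the smaller value.
#'
#' @param x Integer-ish vector.
#' @return Scalar mode.
#' @export
modal_value <- function(x) {
  if (length(x) == 0L) {
    return(NA_real_)
  }
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}
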