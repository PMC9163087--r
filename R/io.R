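#' Write and read opinion trajectories
#'
#' Trajectories are stored as plain CSV with header `t,agent,opinion`
#' (`t` is simulated time for activity runs and the step index for selective
#' runs), so saved runs can be re-analysed by the metrics functions without
#' rerunning the simulation.
#'
#' @param run An `activity_run` or `selective_run` (or a data frame with the
#'   trajectory columns).
#' @param path File path.
#' @return `write_trajectory()` invisibly returns `path`;
#'   `read_trajectory()` returns a tibble with columns `t`, `agent`,
#'   `opinion`.
#' @export
write_trajectory <- function(run, path) {
  traj <- if (is.data.frame(run)) run else run$trajectory
  stopifnot(all(c("t", "agent", "opinion") %in% names(traj)))
  readr::write_csv(traj[, c("t", "agent", "opinion")], path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      t = readr::col_double(),
      agent = readr::col_integer(),
      opinion = readr::col_double()
    )
  )
}

#' Write an interaction log as CSV
#'
#' Events are written with header `step,source,target` (input flows from
#' `source` to `target`).
#'
#' @param log An [interaction_log()].
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_interactions <- function(log, path) {
  stopifnot(inherits(log, "interaction_log"))
  readr::write_csv(log$events, path)
  invisible(path)
}

#' Write a run manifest as JSON
#'
#' Echoes the full configuration (model config, nudge config, schedule and
#' seed) of a single run, for provenance and replay.
#'
#' @param run An `activity_run` or `selective_run`.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(run, path) {
  manifest <- list(
    package = "rdnudge",
    version = as.character(utils::packageVersion("rdnudge")),
    model = if (inherits(run, "activity_run")) "activity" else "selective",
    config = unclass(run$config),
    nudge = unclass(run$nudge),
    schedule = as.data.frame(run$schedule),
    seed = run$config$seed
  )
  jsonlite::write_json(manifest, path,
    auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE
  )
  invisible(path)
}

#' Metric summary of a trajectory file or table
#'
#' Computes the per-time metric summary (peak distance, peak count, end-state
#' classification) from a saved trajectory, one row per recorded time.
#'
#' @param trajectory A tibble from [read_trajectory()] or a run object.
#' @return Tibble with `t`, `lambda_x`, `n_peaks`, `state`, `one_sided`,
#'   `mean_opinion`, `sd_opinion`.
#' @export
summarize_trajectory <- function(trajectory) {
  traj <- if (is.data.frame(trajectory)) trajectory else trajectory$trajectory
  traj |>
    dplyr::group_by(t = .data$t) |>
    dplyr::group_modify(~ summarize_opinions(.x$opinion)) |>
    dplyr::ungroup()
}
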