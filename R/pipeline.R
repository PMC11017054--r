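#' Run the full density pipeline on one video's detections
#'
#' Chains the analysis stages: trajectory reconstruction, zone of influence,
#' per-second in-zone counts, baseline, relative density, summary time
#' points, and the linear repopulation fit with its extrapolated full
#' repopulation time. For control videos (no robot to define a trajectory or
#' a t = 0) pass a previously saved `zone` and an explicit `t0_s`.
#'
#' @param detections A [detection_series()] or a path to a detection CSV.
#' @param zone Optional zone: a [build_zone()] result or a path to a zone
#'   JSON (see [zone_write_json()]). When omitted, the zone is built from
#'   the video's own robot detections.
#' @param t0_s Optional explicit t = 0 (seconds, absolute clock). Defaults
#'   to the first robot detection; required when the video has no robot.
#' @param zone_factor Zone half-width in robot widths (default 1.5).
#' @param robot_width_px Optional override of the apparent robot width.
#' @param baseline_window,min_baseline_samples See [compute_baseline()].
#' @param fit_start `"exit"` (default: last robot detection, i.e. after the
#'   passage), `"entry"`, or an explicit time on the relative clock.
#' @param fit_end_s End of the fit window on the relative clock.
#' @param out_dir Optional directory; when given, writes `density.csv`,
#'   `summary.csv`, `zone.json` and `report.json` into it.
#' @return A list report: `video_id`, `entry_time_s`, `exit_time_s`,
#'   `zone`, `baseline`, `density` (the [relative_density()] series),
#'   `summary`, `fit`, `full_repopulation_time_s`, `warnings`.
#' @export
run_pipeline <- function(detections, zone = NULL, t0_s = NULL,
                         zone_factor = 1.5, robot_width_px = NULL,
                         baseline_window = c(-60, -15),
                         min_baseline_samples = 10,
                         fit_start = "exit", fit_end_s = 240,
                         out_dir = NULL) {
  if (is.character(detections)) {
    detections <- read_detections(detections)
  }
  stopifnot(inherits(detections, "detection_series"))
  warnings <- character()

  has_robot <- any(detections$detections$class == "robot")
  trajectory <- NULL
  if (has_robot && sum(detections$detections$class == "robot") >= 2) {
    trajectory <- estimate_trajectory(detections)
  }

  if (is.null(zone)) {
    if (is.null(trajectory)) {
      abort("no robot trajectory available; supply a zone (and t0_s)",
            class = "flockzone_trajectory_error")
    }
    if (is.null(robot_width_px)) {
      robot_width_px <- robot_pixel_width(detections)
    }
    zone <- build_zone(trajectory, robot_width_px, factor = zone_factor)
  } else if (is.character(zone)) {
    zone <- zone_read_json(zone)
  }

  if (is.null(t0_s)) {
    if (is.null(trajectory)) {
      abort("no robot detections to define t = 0; supply t0_s",
            class = "flockzone_parameter_error")
    }
    t0_s <- trajectory$entry_time_s
  }

  counts <- counts_in_zone(detections, zone)
  baseline <- compute_baseline(counts, t0_s, window = baseline_window,
                               min_baseline_samples = min_baseline_samples)
  density <- relative_density(counts, baseline, t0_s,
                              video_id = detections$video_id)
  summary_pts <- summarize_density(density)
  if (any(summary_pts$approximated)) {
    warnings <- c(warnings,
                  "summary time point(s) taken from nearest sample")
  }

  t_start <- if (identical(fit_start, "exit")) {
    if (is.null(trajectory)) 0 else trajectory$exit_time_s - t0_s
  } else if (identical(fit_start, "entry")) {
    0
  } else {
    as.numeric(fit_start)
  }
  fit <- fit_repopulation(density, t_start,
                          min(fit_end_s, max(density$t_rel_s)))
  t_full <- full_repopulation_time(fit)

  report <- list(
    video_id = detections$video_id,
    entry_time_s = t0_s,
    exit_time_s = if (is.null(trajectory)) NA else trajectory$exit_time_s,
    zone = zone,
    baseline = baseline,
    density = density,
    summary = summary_pts,
    fit = fit,
    full_repopulation_time_s = t_full,
    warnings = warnings
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(
      tibble::as_tibble(density),
      file.path(out_dir, "density.csv"), progress = FALSE
    )
    readr::write_csv(
      tibble::tibble(
        video_id = detections$video_id,
        moment_prior_pct = summary_pts$moment_prior_pct,
        minute_after_pct = summary_pts$minute_after_pct,
        two_min_after_pct = summary_pts$two_min_after_pct,
        baseline_count = baseline$baseline_count,
        n_baseline_samples = baseline$n_samples
      ),
      file.path(out_dir, "summary.csv"), progress = FALSE
    )
    zone_write_json(zone, file.path(out_dir, "zone.json"))
    jsonlite::write_json(
      list(
        video_id = detections$video_id,
        entry_time_s = t0_s,
        exit_time_s = report$exit_time_s,
        baseline_count = baseline$baseline_count,
        n_baseline_samples = baseline$n_samples,
        moment_prior_pct = summary_pts$moment_prior_pct,
        minute_after_pct = summary_pts$minute_after_pct,
        two_min_after_pct = summary_pts$two_min_after_pct,
        slope_pct_per_s = fit$slope,
        intercept_pct = fit$intercept,
        r_squared = fit$r_squared,
        fit_window_s = fit$fit_window,
        n_fit_points = fit$n_points,
        full_repopulation_time_s = t_full,
        warnings = warnings
      ),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
      na = "null"
    )
  }
  report
}
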