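#' Count birds inside the zone of influence
#'
#' Counts the chicken-class detections of one frame whose centroids fall
#' inside the zone (boundary inclusive). Robot and feeder detections are
#' never counted.
#'
#' @param frame Tibble of one frame's detections (e.g. from [frame_at()]).
#' @param zone A [build_zone()] result.
#' @return Non-negative integer.
#' @export
count_in_zone <- function(frame, zone) {
  chickens <- dplyr::filter(frame, .data$class == "chicken")
  if (nrow(chickens) == 0) return(0L)
  sum(points_in_zone(chickens$cx, chickens$cy, zone))
}

#' Per-second in-zone counts for a whole series
#'
#' @param series A [detection_series()].
#' @param zone A [build_zone()] result.
#' @return Tibble with `time_s` and `count`, one row per frame present in the
#'   series (missing seconds stay missing).
#' @export
counts_in_zone <- function(series, zone) {
  stopifnot(inherits(series, "detection_series"))
  times <- sort(unique(series$detections$time_s))
  chickens <- dplyr::filter(series$detections, .data$class == "chicken")
  if (nrow(chickens) == 0) {
    return(tibble::tibble(time_s = times, count = rep(0L, length(times))))
  }
  chickens$in_zone <- points_in_zone(chickens$cx, chickens$cy, zone)
  tallied <- chickens |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(count = sum(.data$in_zone), .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(time_s = times), tallied,
                          by = "time_s")
  out$count <- as.integer(ifelse(is.na(out$count), 0L, out$count))
  out
}

#' Baseline in-zone count before robot entry
#'
#' The baseline is the mean number of birds in the zone between 60 and 15 s
#' before the robot is first detected (window inclusive on both ends).
#' Relative density is undefined for a zero baseline.
#'
#' @param counts Tibble with `time_s` and `count` (see [counts_in_zone()]).
#' @param entry_time_s Time of first robot detection (t = 0 of the relative
#'   clock).
#' @param window Baseline window in seconds relative to entry, default
#'   `c(-60, -15)`.
#' @param min_baseline_samples Minimum number of seconds that must be present
#'   inside the window (default 10 of the 46 possible), bounding the baseline
#'   standard error while tolerating dropped frames.
#' @return Object of class `baseline_estimate`: list with `baseline_count`,
#'   `window`, `n_samples`.
#' @export
compute_baseline <- function(counts, entry_time_s, window = c(-60, -15),
                             min_baseline_samples = 10) {
  stopifnot(length(window) == 2, window[1] < window[2])
  in_win <- counts$time_s >= entry_time_s + window[1] &
    counts$time_s <= entry_time_s + window[2]
  n <- sum(in_win)
  if (n < min_baseline_samples) {
    abort(
      paste0("only ", n, " baseline samples in [",
             window[1], ", ", window[2], "] s relative to entry; need >= ",
             min_baseline_samples),
      class = "flockzone_baseline_error"
    )
  }
  m <- mean(counts$count[in_win])
  if (m == 0) {
    abort("baseline count is zero; relative density is undefined",
          class = "flockzone_baseline_error")
  }
  structure(
    list(baseline_count = m, window = window, n_samples = n),
    class = "baseline_estimate"
  )
}

#' Baseline-normalized relative density series
#'
#' Expresses each per-second in-zone count as a percentage of the baseline
#' count and re-expresses time relative to robot entry (entry = 0, negative =
#' before).
#'
#' @param counts Tibble with `time_s` and `count`.
#' @param baseline A [compute_baseline()] result.
#' @param entry_time_s Time of first robot detection.
#' @param video_id Identifier carried into the output.
#' @return Object of class `density_series`: tibble with `video_id`,
#'   `t_rel_s`, `count`, `relative_density_pct`; the baseline is attached as
#'   attribute `baseline`.
#' @export
relative_density <- function(counts, baseline, entry_time_s,
                             video_id = "video") {
  stopifnot(inherits(baseline, "baseline_estimate"))
  if (baseline$baseline_count <= 0) {
    abort("baseline count must be positive",
          class = "flockzone_baseline_error")
  }
  out <- tibble::tibble(
    video_id = as.character(video_id),
    t_rel_s = counts$time_s - entry_time_s,
    count = as.integer(counts$count),
    relative_density_pct = 100 * counts$count / baseline$baseline_count
  )
  out <- dplyr::arrange(out, .data$t_rel_s)
  attr(out, "baseline") <- baseline
  class(out) <- c("density_series", class(out))
  out
}

#' Summary time points of a relative-density series
#'
#' Three statistics summarise each series: the *moment prior* is the maximum
#' relative density over the 15 s immediately before robot entry (window
#' `[-15, 0)`, capturing the pre-entry pile-up of birds pushed ahead of the
#' robot); the *minute after* and *two minutes after* are the relative
#' densities at t = +60 s and t = +120 s. When the exact second is missing
#' the nearest sample within 2 s is used and flagged.
#'
#' @param series A [relative_density()] result.
#' @param tolerance_s Maximum distance (seconds) to the nearest sample when
#'   the exact +60 / +120 s sample is missing. Ties at equal distance go to
#'   the earlier sample.
#' @return Object of class `density_summary`: list with `moment_prior_pct`,
#'   `minute_after_pct`, `two_min_after_pct`, the times actually used
#'   (`minute_after_t`, `two_min_after_t`) and a logical `approximated`
#'   vector flagging fallback samples.
#' @export
summarize_density <- function(series, tolerance_s = 2) {
  stopifnot(inherits(series, "density_series"))
  pre <- series$t_rel_s >= -15 & series$t_rel_s < 0
  if (!any(pre)) {
    abort("no samples in the moment-prior window [-15, 0)",
          class = "flockzone_coverage_error")
  }
  at_or_near <- function(target) {
    diffs <- abs(series$t_rel_s - target)
    i <- which.min(diffs)
    if (diffs[i] > tolerance_s) {
      abort(
        paste0("no sample within ", tolerance_s, " s of t = +", target, " s"),
        class = "flockzone_coverage_error"
      )
    }
    list(value = series$relative_density_pct[i],
         t = series$t_rel_s[i],
         approx = series$t_rel_s[i] != target)
  }
  one <- at_or_near(60)
  two <- at_or_near(120)
  structure(
    list(
      moment_prior_pct = max(series$relative_density_pct[pre]),
      minute_after_pct = one$value,
      two_min_after_pct = two$value,
      minute_after_t = one$t,
      two_min_after_t = two$t,
      approximated = c(minute_after = one$approx, two_min_after = two$approx)
    ),
    class = "density_summary"
  )
}
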