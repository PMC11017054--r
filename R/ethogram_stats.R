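## Behavior vocabulary of the ethogram, grouped as scored:
## bird-initiated interactions with the robot, robot-initiated contacts,
## and post-passage interactions with the ground.
ETHOGRAM_BEHAVIORS <- c(
  "close_approach", "peck_robot", "jump_on_robot",
  "touched_by_robot", "pushed_by_robot",
  "scratch_ground", "peck_ground"
)

#' Ethogram behavior groups
#'
#' Named list of the three behavior groups scored per video: interactions
#' initiated by birds towards the robot (`bird_to_robot`), contacts
#' initiated by the robot (`robot_to_bird`) and post-passage interactions
#' with the litter (`ground`).
#'
#' @return Named list of character vectors of behavior flags.
#' @export
behavior_groups <- function() {
  list(
    bird_to_robot = c("close_approach", "peck_robot", "jump_on_robot"),
    robot_to_bird = c("touched_by_robot", "pushed_by_robot"),
    ground = c("scratch_ground", "peck_ground")
  )
}

#' Read an ethogram annotation table
#'
#' One row per video with 0/1 flags for each behavior in the fixed
#' vocabulary and a count of birds touched/pushed by the robot. Columns:
#' `video_id,week,treatment,close_approach,peck_robot,jump_on_robot,`
#' `touched_by_robot,pushed_by_robot,scratch_ground,peck_ground,birds_touched`.
#'
#' @param path CSV file path.
#' @return Tibble with flags as logicals.
#' @export
read_ethogram <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("ethogram file not found: ", path),
          class = "flockzone_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("video_id", "week", "treatment", ETHOGRAM_BEHAVIORS,
                "birds_touched")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("ethogram table is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "flockzone_schema_error"
    )
  }
  for (b in ETHOGRAM_BEHAVIORS) raw[[b]] <- as.logical(raw[[b]])
  if (!all(raw$treatment %in% c("robot", "control"))) {
    abort("treatment must be 'robot' or 'control'",
          class = "flockzone_parse_error")
  }
  if (any(raw$birds_touched < 0)) {
    abort("birds_touched must be non-negative",
          class = "flockzone_parse_error")
  }
  bad <- raw$birds_touched > 0 & !raw$touched_by_robot & !raw$pushed_by_robot
  if (any(bad)) {
    abort("birds_touched > 0 requires touched_by_robot or pushed_by_robot",
          class = "flockzone_parse_error")
  }
  tibble::as_tibble(raw)
}

#' Proportion of videos showing a behavior group
#'
#' Tallies the videos in which any behavior of the group was flagged and
#' tests whether occurrence is non-negligible. A literal test against zero
#' occurrence is degenerate (a single success rejects p = 0 exactly), so the
#' test is an exact one-sided binomial test of H0: p = `null_p` against
#' p > `null_p`, with a small default null of 1%.
#'
#' @param records Ethogram tibble (see [read_ethogram()]).
#' @param behaviors Character vector of behavior flags defining the group
#'   (see [behavior_groups()]).
#' @param null_p Null occurrence probability.
#' @return Object of class `proportion_result`: list with `successes`,
#'   `trials`, `proportion` (percent), `fraction` (exact), `p_value`.
#' @export
behavior_proportions <- function(records, behaviors, null_p = 0.01) {
  if (nrow(records) == 0) {
    abort("no ethogram records", class = "flockzone_parameter_error")
  }
  bad <- setdiff(behaviors, ETHOGRAM_BEHAVIORS)
  if (length(bad) > 0) {
    abort(paste0("unknown behavior(s): ", paste(bad, collapse = ", ")),
          class = "flockzone_parameter_error")
  }
  flags <- as.matrix(records[behaviors])
  successes <- sum(rowSums(flags, na.rm = TRUE) > 0)
  trials <- nrow(records)
  p_value <- binom.test(successes, trials, p = null_p,
                        alternative = "greater")$p.value
  structure(
    list(successes = successes, trials = trials,
         proportion = 100 * successes / trials,
         fraction = successes / trials,
         p_value = p_value),
    class = "proportion_result"
  )
}

#' Mean and standard error of birds touched by the robot
#'
#' @param records Ethogram tibble; only robot-treatment rows are used.
#' @return Tibble with one row per week plus an `"overall"` row: `week`,
#'   `n`, `mean`, `sem` (sd / sqrt(n); 0 for n = 1).
#' @export
birds_touched_summary <- function(records) {
  robot <- records[records$treatment == "robot", , drop = FALSE]
  if (nrow(robot) == 0) {
    abort("no robot-treatment records", class = "flockzone_parameter_error")
  }
  sem <- function(x) if (length(x) < 2) 0 else sd(x) / sqrt(length(x))
  per_week <- robot |>
    dplyr::group_by(week = as.character(.data$week)) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$birds_touched),
                     sem = sem(.data$birds_touched), .groups = "drop")
  overall <- tibble::tibble(
    week = "overall", n = nrow(robot),
    mean = mean(robot$birds_touched), sem = sem(robot$birds_touched)
  )
  dplyr::bind_rows(per_week, overall)
}

#' Rank-transform a numeric vector
#'
#' Ascending ranks starting at 1, with ties given mid-ranks — the
#' transformation applied to the post-entry relative-density time points
#' before normal-theory mixed modelling.
#'
#' @param values Numeric vector of finite values.
#' @return Numeric vector of ranks.
#' @export
rank_transform <- function(values) {
  if (length(values) == 0) {
    abort("cannot rank an empty vector", class = "flockzone_parameter_error")
  }
  if (any(!is.finite(values))) {
    abort("values must be finite to rank", class = "flockzone_parameter_error")
  }
  rank(values, ties.method = "average")
}

#' Long-format table of summary time points for mixed modelling
#'
#' Pivots per-video summary time points into the tidy long format expected
#' by standard mixed-model tools (one row per video and time point), adding
#' within-time-point ranks. Model fitting itself (e.g. gamma-family GLMM for
#' the moment prior, normal-on-ranks for the post-entry points) is left to
#' dedicated packages.
#'
#' @param summaries Tibble with `video_id`, `week`, `treatment`, `batch` and
#'   the columns `moment_prior_pct`, `minute_after_pct`, `two_min_after_pct`.
#' @return Tibble `video_id, week, treatment, batch, timepoint, value, rank`.
#' @export
density_long_table <- function(summaries) {
  required <- c("video_id", "week", "treatment", "batch",
                "moment_prior_pct", "minute_after_pct", "two_min_after_pct")
  missing_cols <- setdiff(required, names(summaries))
  if (length(missing_cols) > 0) {
    abort(
      paste0("summary table is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "flockzone_schema_error"
    )
  }
  long <- tidyr::pivot_longer(
    summaries,
    cols = c("moment_prior_pct", "minute_after_pct", "two_min_after_pct"),
    names_to = "timepoint", values_to = "value"
  )
  long$timepoint <- sub("_pct$", "", long$timepoint)
  long |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::mutate(rank = rank_transform(.data$value)) |>
    dplyr::ungroup() |>
    dplyr::select("video_id", "week", "treatment", "batch",
                  "timepoint", "value", "rank")
}
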