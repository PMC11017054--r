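#' Fit the linear repopulation model
#'
#' After the robot's passage the zone of influence refills roughly linearly
#' on the few-minute timescale studied here. The model is an ordinary
#' least-squares regression of relative density (%) on time after the
#' fit-window start, so the slope is in percent per second and the intercept
#' is the fitted relative density at `t_start`.
#'
#' @param series A [relative_density()] result (or any data frame with
#'   `t_rel_s` and `relative_density_pct`).
#' @param t_start,t_end Fit window in seconds on the relative clock
#'   (inclusive). Typical use starts the window at the robot's exit time
#'   (time after the passage).
#' @return Object of class `repopulation_fit`: list with `slope` (%/s),
#'   `intercept` (% at `t_start`), `r_squared`, `fit_window`, `n_points`. A
#'   response with zero variance yields slope 0 and `r_squared = 0` (no
#'   explained variance), not `NaN`.
#' @export
fit_repopulation <- function(series, t_start, t_end) {
  stopifnot(is.numeric(t_start), is.numeric(t_end), t_start < t_end)
  keep <- series$t_rel_s >= t_start & series$t_rel_s <= t_end
  tt <- series$t_rel_s[keep] - t_start
  y <- series$relative_density_pct[keep]
  if (length(tt) < 3) {
    abort(
      paste0("need >= 3 samples in the fit window [", t_start, ", ", t_end,
             "]; got ", length(tt)),
      class = "flockzone_fit_error"
    )
  }
  if (var(tt) == 0) {
    abort("zero time variance in the fit window; regression is degenerate",
          class = "flockzone_fit_error")
  }
  if (var(y) == 0) {
    slope <- 0
    intercept <- y[1]
    r2 <- 0
  } else {
    fit <- lm(y ~ tt)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         fit_window = c(t_start, t_end), n_points = length(tt)),
    class = "repopulation_fit"
  )
}

#' @export
print.repopulation_fit <- function(x, ...) {
  cat(sprintf(
    "<repopulation_fit> slope %.4f %%/s, intercept %.1f %%, R^2 %.3f (n = %d, window [%g, %g] s)\n",
    x$slope, x$intercept, x$r_squared, x$n_points,
    x$fit_window[1], x$fit_window[2]
  ))
  invisible(x)
}

#' Extrapolated full-repopulation time
#'
#' Extrapolates the fitted repopulation line to the time at which relative
#' density reaches `target_pct` (default 100%, i.e. back to baseline). A
#' slope at or below `slope_epsilon` denotes a lack of repopulation and
#' yields `NA`; an intercept already at or above the target yields 0
#' (already repopulated at the window start).
#'
#' @param fit A [fit_repopulation()] result.
#' @param target_pct Relative density considered full repopulation.
#' @param slope_epsilon Smallest slope (%/s) treated as actual repopulation.
#' @return Time in seconds on the relative clock, 0, or `NA` (no
#'   repopulation within the linear model).
#' @export
full_repopulation_time <- function(fit, target_pct = 100,
                                   slope_epsilon = 1e-6) {
  stopifnot(inherits(fit, "repopulation_fit"))
  if (fit$intercept >= target_pct) return(0)
  if (fit$slope <= slope_epsilon) return(NA_real_)
  fit$fit_window[1] + (target_pct - fit$intercept) / fit$slope
}

#' Average aligned density series and fit the mean curve
#'
#' Group-level repopulation is estimated by averaging the replicate series
#' pointwise on the relative clock (mean over the series that have a sample
#' at each second) and fitting the linear model to the mean curve.
#'
#' @param series_list List of [relative_density()] results aligned on the
#'   same relative clock.
#' @param t_start,t_end Fit window, as in [fit_repopulation()].
#' @return List with `mean_series` (tibble `t_rel_s`,
#'   `relative_density_pct`, `n_series`) and `fit` (a `repopulation_fit`).
#' @export
fit_mean_curve <- function(series_list, t_start, t_end) {
  stopifnot(length(series_list) >= 1)
  pooled <- dplyr::bind_rows(lapply(series_list, function(s) {
    tibble::tibble(t_rel_s = s$t_rel_s,
                   relative_density_pct = s$relative_density_pct)
  }))
  mean_series <- pooled |>
    dplyr::group_by(.data$t_rel_s) |>
    dplyr::summarise(
      relative_density_pct = mean(.data$relative_density_pct),
      n_series = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$t_rel_s)
  list(
    mean_series = mean_series,
    fit = fit_repopulation(mean_series, t_start, t_end)
  )
}
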