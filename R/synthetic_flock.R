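#' Configuration for the synthetic flock simulator
#'
#' Builds and validates the parameter set of the agent-based generator. The
#' simulated scene emulates the study conditions the pipeline was designed
#' for: a fixed overhead camera viewing a floor section of a broiler house,
#' birds clustered near conspecifics and drifting by a small random walk,
#' and a ground robot traversing a straight transect at 0.2 m/s. Birds
#' within the flee radius of the robot move radially away at the flee speed
#' until they are outside the radius plus a margin; once the robot has moved
#' on and a latency has elapsed, displaced birds drift back toward their
#' pre-displacement home at the return-drift speed (zero drift = no
#' repopulation beyond diffusion). Positions are rendered to pixel bounding
#' boxes, optionally with detection noise: per-detection misses, spurious
#' boxes and box-coordinate jitter.
#'
#' @param arena_m `c(width, height)` of the camera's field of vision, metres.
#' @param n_birds Number of birds.
#' @param cluster_count,cluster_spread_m Number of social clusters and the
#'   Gaussian spread of birds around their cluster centre.
#' @param robot_present If `FALSE`, no robot exists (control condition).
#' @param robot_speed_mps Robot travel speed (default 0.2 m/s, its maximum).
#' @param robot_width_m,robot_length_m Robot footprint (0.31 m x 0.38 m).
#' @param robot_transect `list(start =, end =)` endpoints (metres) of the
#'   robot's route across the arena; both must lie inside the arena.
#' @param lead_in_s Seconds of approach before the robot reaches the
#'   transect start: it travels along the transect direction extended
#'   backwards, outside the field of vision, so a pre-entry baseline exists.
#' @param flee_radius_m Distance at which a bird starts fleeing the robot.
#' @param flee_speed_mps Speed of the radial flight (must outrun the robot
#'   for birds directly ahead of it).
#' @param flee_margin_m A fleeing bird keeps fleeing until it is beyond
#'   `flee_radius_m + flee_margin_m` of the robot.
#' @param return_drift_mps Speed of the drift back home after release.
#' @param return_latency_s Delay between the robot moving on and the start
#'   of the drift back.
#' @param random_walk_sigma_m Random-walk displacement SD per sqrt(second).
#' @param cohesion_rate Per-second rate at which undisturbed birds are
#'   pulled back toward their home point (keeps clusters stationary).
#' @param wall_margin_m Birds keep this distance from the arena walls, so
#'   every rendered box fits inside the frame.
#' @param duration_s Simulated seconds (samples at 0, 1, ..., duration_s).
#' @param dt_s Internal integration step; 0.1 s so flee/return motion is not
#'   aliased at the robot's speed.
#' @param pixel_scale Pixels per metre of the overhead rendering (affine,
#'   no perspective).
#' @param bird_size_px,bird_size_cv Mean rendered bird box side and its
#'   coefficient of variation across birds (age is encoded through size and
#'   the behavioural parameters; there is no growth model).
#' @param detect_miss_rate Probability that a bird detection is dropped.
#' @param false_positive_rate Expected number of spurious boxes per frame.
#' @param box_jitter_px SD of the Gaussian jitter added to box corners.
#' @param zone_factor Zone half-width in robot widths (used for the
#'   simulator's own true in-zone counts).
#' @param seed Integer seed; fixes the full realization. Movement and each
#'   noise channel draw from separately derived seeds, so toggling detection
#'   noise does not change the movement realization.
#' @return Object of class `flock_sim_config` (a validated named list).
#' @export
flock_sim_config <- function(arena_m = c(8, 4.5),
                             n_birds = 120,
                             cluster_count = 8,
                             cluster_spread_m = 1.0,
                             robot_present = TRUE,
                             robot_speed_mps = 0.2,
                             robot_width_m = 0.31,
                             robot_length_m = 0.38,
                             robot_transect = list(start = c(0, 2.25),
                                                   end = c(8, 2.25)),
                             lead_in_s = 60,
                             flee_radius_m = 0.8,
                             flee_speed_mps = 0.5,
                             flee_margin_m = 0.2,
                             return_drift_mps = 0.015,
                             return_latency_s = 15,
                             random_walk_sigma_m = 0.05,
                             cohesion_rate = 0.05,
                             wall_margin_m = 0.15,
                             duration_s = 300,
                             dt_s = 0.1,
                             pixel_scale = 160,
                             bird_size_px = 28,
                             bird_size_cv = 0.1,
                             detect_miss_rate = 0,
                             false_positive_rate = 0,
                             box_jitter_px = 0,
                             zone_factor = 1.5,
                             seed = 1) {
  cfg <- list(
    arena_m = as.numeric(arena_m), n_birds = as.integer(n_birds),
    cluster_count = as.integer(cluster_count),
    cluster_spread_m = cluster_spread_m,
    robot_present = isTRUE(robot_present),
    robot_speed_mps = robot_speed_mps, robot_width_m = robot_width_m,
    robot_length_m = robot_length_m,
    robot_transect = lapply(robot_transect, as.numeric),
    lead_in_s = lead_in_s,
    flee_radius_m = flee_radius_m, flee_speed_mps = flee_speed_mps,
    flee_margin_m = flee_margin_m,
    return_drift_mps = return_drift_mps,
    return_latency_s = return_latency_s,
    random_walk_sigma_m = random_walk_sigma_m,
    cohesion_rate = cohesion_rate, wall_margin_m = wall_margin_m,
    duration_s = as.integer(duration_s), dt_s = dt_s,
    pixel_scale = pixel_scale,
    bird_size_px = bird_size_px, bird_size_cv = bird_size_cv,
    detect_miss_rate = detect_miss_rate,
    false_positive_rate = false_positive_rate,
    box_jitter_px = box_jitter_px,
    zone_factor = zone_factor, seed = as.integer(seed)
  )
  if (length(cfg$arena_m) != 2 || any(cfg$arena_m <= 0)) {
    abort("arena_m must be positive c(width, height)",
          class = "flockzone_config_error")
  }
  if (cfg$n_birds <= 0) {
    abort("n_birds must be positive", class = "flockzone_config_error")
  }
  rates <- c(cfg$detect_miss_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("detect_miss_rate must lie in [0, 1]",
          class = "flockzone_config_error")
  }
  if (cfg$false_positive_rate < 0 || cfg$box_jitter_px < 0) {
    abort("noise parameters must be non-negative",
          class = "flockzone_config_error")
  }
  speeds <- c(cfg$robot_speed_mps, cfg$flee_speed_mps, cfg$return_drift_mps,
              cfg$random_walk_sigma_m)
  if (any(speeds < 0)) {
    abort("speeds must be non-negative", class = "flockzone_config_error")
  }
  tran <- rbind(cfg$robot_transect$start, cfg$robot_transect$end)
  if (ncol(tran) != 2 ||
      any(tran[, 1] < 0 | tran[, 1] > cfg$arena_m[1] |
          tran[, 2] < 0 | tran[, 2] > cfg$arena_m[2])) {
    abort("robot_transect endpoints must lie inside the arena",
          class = "flockzone_config_error")
  }
  if (all(cfg$robot_transect$start == cfg$robot_transect$end)) {
    abort("robot_transect start and end coincide",
          class = "flockzone_config_error")
  }
  structure(cfg, class = "flock_sim_config")
}

#' Scenario presets for the synthetic flock
#'
#' Named parameterisations spanning the growing cycle as the analysis sees
#' it: `wk1` — small, sparse birds that flee deeply and do not drift back
#' (repopulation limited to diffusion); `wk2` — denser flock, shallower
#' flight, slow drift-back; `wk6` — dense flock of large birds with a
#' shallow flight and the fastest drift-back; `control` — same flock, no
#' robot. The presets target only the qualitative age ordering (older birds
#' depopulate less and repopulate faster); they are not calibrated to any
#' measured flock.
#'
#' @param name One of `"wk1"`, `"wk2"`, `"wk6"`, `"control"`.
#' @param seed Integer seed passed to the config.
#' @param ... Overrides forwarded to [flock_sim_config()].
#' @return A [flock_sim_config()].
#' @export
scenario_preset <- function(name, seed = 1, ...) {
  presets <- list(
    wk1 = list(n_birds = 60L, bird_size_px = 12, cluster_count = 6L,
               cluster_spread_m = 0.9, flee_radius_m = 1.3,
               flee_speed_mps = 0.7, return_drift_mps = 0,
               return_latency_s = 20, random_walk_sigma_m = 0.02),
    wk2 = list(n_birds = 100L, bird_size_px = 18, cluster_count = 7L,
               cluster_spread_m = 1.0, flee_radius_m = 1.0,
               flee_speed_mps = 0.6, return_drift_mps = 0.005,
               return_latency_s = 25, random_walk_sigma_m = 0.04),
    wk6 = list(n_birds = 150L, bird_size_px = 32, cluster_count = 8L,
               cluster_spread_m = 1.2, flee_radius_m = 0.55,
               flee_speed_mps = 0.5, return_drift_mps = 0.012,
               return_latency_s = 20),
    control = list(robot_present = FALSE)
  )
  if (!name %in% names(presets)) {
    abort(paste0("unknown preset '", name, "'; expected one of: ",
                 paste(names(presets), collapse = ", ")),
          class = "flockzone_config_error")
  }
  args <- utils::modifyList(presets[[name]], list(seed = seed, ...))
  do.call(flock_sim_config, args)
}

## Robot centre position (metres) at continuous time t. The robot reaches
## the transect start exactly at lead_in_s and keeps going past the end.
robot_position_m <- function(cfg, t) {
  s <- cfg$robot_transect$start
  e <- cfg$robot_transect$end
  dir <- (e - s) / sqrt(sum((e - s)^2))
  sweep(outer(t - cfg$lead_in_s, dir * cfg$robot_speed_mps), 2, s, "+")
}

#' Run the synthetic flock simulation
#'
#' Integrates the flock and robot dynamics described in
#' [flock_sim_config()] at the internal time step, records positions at 1-s
#' samples, renders them to the pipeline's detection schema (with and
#' without detection noise) and computes the simulator's own ground-truth
#' in-zone counts from the true positions and the configured zone. A fixed
#' seed reproduces the realization exactly.
#'
#' @param config A [flock_sim_config()].
#' @return Object of class `flock_sim`: list with `config`,
#'   `true_positions` (tibble `time_s`, `bird`, `x_m`, `y_m`, `x_px`,
#'   `y_px`), `robot_positions` (tibble `time_s`, `x_m`, `y_m`, `visible`),
#'   `detections` (noisy [detection_series()]), `truth_detections`
#'   (noise-free series, confidence 100), `true_in_zone_counts` (tibble
#'   `time_s`, `count`), `zone` (the configured zone of influence),
#'   `entry_time_s` / `exit_time_s` (first/last second the robot is fully
#'   visible; `NA` for control) and `nominal_entry_s` (where the relative
#'   clock would sit, defined even without a robot).
#' @export
simulate_flock <- function(config) {
  stopifnot(inherits(config, "flock_sim_config"))
  cfg <- config
  frame_px <- c(cfg$arena_m[1] * cfg$pixel_scale,
                cfg$arena_m[2] * cfg$pixel_scale)

  ## --- movement substream -------------------------------------------------
  set.seed(cfg$seed)
  n <- cfg$n_birds
  ccx <- runif(cfg$cluster_count, 0.6, cfg$arena_m[1] - 0.6)
  ccy <- runif(cfg$cluster_count, 0.6, cfg$arena_m[2] - 0.6)
  cluster <- sample.int(cfg$cluster_count, n, replace = TRUE)
  clamp <- function(v, lo, hi) pmin(hi, pmax(lo, v))
  home_x <- clamp(ccx[cluster] + rnorm(n, 0, cfg$cluster_spread_m),
                  cfg$wall_margin_m, cfg$arena_m[1] - cfg$wall_margin_m)
  home_y <- clamp(ccy[cluster] + rnorm(n, 0, cfg$cluster_spread_m),
                  cfg$wall_margin_m, cfg$arena_m[2] - cfg$wall_margin_m)
  ## per-bird rendered box size (px), fixed for the whole video
  size <- pmax(4, cfg$bird_size_px *
                 (1 + cfg$bird_size_cv * rnorm(n)))
  bw <- pmax(4, size * (1 + 0.05 * rnorm(n)))
  bh <- pmax(4, size * (1 + 0.05 * rnorm(n)))
  ## every rendered box must fit in the frame, whatever size was drawn
  margin_m <- max(cfg$wall_margin_m,
                  (max(c(bw, bh)) / 2 + 0.5) / cfg$pixel_scale)
  home_x <- clamp(home_x, margin_m, cfg$arena_m[1] - margin_m)
  home_y <- clamp(home_y, margin_m, cfg$arena_m[2] - margin_m)

  ## start at the stationary spread of the home-anchored random walk so the
  ## undisturbed process has no initial transient
  sd_stat <- if (cfg$cohesion_rate > 0) {
    cfg$random_walk_sigma_m / sqrt(2 * cfg$cohesion_rate)
  } else 0
  x <- clamp(home_x + rnorm(n, 0, sd_stat), margin_m,
             cfg$arena_m[1] - margin_m)
  y <- clamp(home_y + rnorm(n, 0, sd_stat), margin_m,
             cfg$arena_m[2] - margin_m)
  fleeing <- rep(FALSE, n)
  displaced <- rep(FALSE, n)
  release_time <- rep(Inf, n)

  n_sec <- cfg$duration_s + 1L
  pos_x <- matrix(NA_real_, n, n_sec)
  pos_y <- matrix(NA_real_, n, n_sec)
  pos_x[, 1] <- x
  pos_y[, 1] <- y

  steps_per_s <- round(1 / cfg$dt_s)
  dt <- 1 / steps_per_s
  sq_dt <- sqrt(dt)
  t_grid <- seq(0L, cfg$duration_s)
  rob_xy <- robot_position_m(cfg, t_grid)   # per-second robot centre

  for (k in seq_len(cfg$duration_s * steps_per_s)) {
    t <- k * dt
    if (cfg$robot_present) {
      r <- robot_position_m(cfg, t)
      dx <- x - r[1]
      dy <- y - r[2]
      d <- sqrt(dx * dx + dy * dy)
      new_flee <- d < cfg$flee_radius_m
      fleeing <- new_flee |
        (fleeing & d < cfg$flee_radius_m + cfg$flee_margin_m)
      just_displaced <- fleeing & !displaced
      displaced[just_displaced] <- TRUE
      release_time[fleeing] <- Inf
      ## birds that just stopped fleeing start the return clock
      stopped <- displaced & !fleeing & !is.finite(release_time)
      release_time[stopped] <- t + cfg$return_latency_s
      if (any(fleeing)) {
        dd <- pmax(d[fleeing], 1e-6)
        step <- cfg$flee_speed_mps * dt
        x[fleeing] <- x[fleeing] + step * dx[fleeing] / dd
        y[fleeing] <- y[fleeing] + step * dy[fleeing] / dd
      }
    }
    returning <- displaced & !fleeing & t >= release_time &
      cfg$return_drift_mps > 0
    if (any(returning)) {
      hx <- home_x[returning] - x[returning]
      hy <- home_y[returning] - y[returning]
      hd <- sqrt(hx * hx + hy * hy)
      step <- cfg$return_drift_mps * dt
      arrived <- hd <= step
      frac <- ifelse(arrived, 1, step / pmax(hd, 1e-9))
      x[returning] <- x[returning] + frac * hx
      y[returning] <- y[returning] + frac * hy
      idx <- which(returning)[arrived]
      displaced[idx] <- FALSE
      release_time[idx] <- Inf
    }
    quiet <- !fleeing
    if (any(quiet)) {
      nq <- sum(quiet)
      x[quiet] <- x[quiet] + cfg$random_walk_sigma_m * sq_dt * rnorm(nq)
      y[quiet] <- y[quiet] + cfg$random_walk_sigma_m * sq_dt * rnorm(nq)
      settled <- quiet & !displaced
      if (any(settled)) {
        pull <- cfg$cohesion_rate * dt
        x[settled] <- x[settled] + pull * (home_x[settled] - x[settled])
        y[settled] <- y[settled] + pull * (home_y[settled] - y[settled])
      }
    }
    x <- clamp(x, margin_m, cfg$arena_m[1] - margin_m)
    y <- clamp(y, margin_m, cfg$arena_m[2] - margin_m)
    if (k %% steps_per_s == 0) {
      s <- k %/% steps_per_s
      pos_x[, s + 1] <- x
      pos_y[, s + 1] <- y
    }
  }

  ## --- rendering ----------------------------------------------------------
  true_positions <- tibble::tibble(
    time_s = rep(t_grid, each = n),
    bird = rep(seq_len(n), times = n_sec),
    x_m = as.vector(pos_x),
    y_m = as.vector(pos_y),
    x_px = as.vector(pos_x) * cfg$pixel_scale,
    y_px = as.vector(pos_y) * cfg$pixel_scale
  )

  rob_w_px <- cfg$robot_length_m * cfg$pixel_scale  # along-track extent
  rob_h_px <- cfg$robot_width_m * cfg$pixel_scale
  robot_positions <- tibble::tibble(
    time_s = t_grid,
    x_m = rob_xy[, 1], y_m = rob_xy[, 2],
    visible = cfg$robot_present &
      rob_xy[, 1] * cfg$pixel_scale - rob_w_px / 2 >= 0 &
      rob_xy[, 1] * cfg$pixel_scale + rob_w_px / 2 <= frame_px[1] &
      rob_xy[, 2] * cfg$pixel_scale - rob_h_px / 2 >= 0 &
      rob_xy[, 2] * cfg$pixel_scale + rob_h_px / 2 <= frame_px[2]
  )

  video_id <- paste0("sim_seed", cfg$seed)
  bird_rows <- tibble::tibble(
    video_id = video_id,
    time_s = true_positions$time_s,
    class = "chicken",
    x_min = true_positions$x_px - rep(bw, n_sec) / 2,
    y_min = true_positions$y_px - rep(bh, n_sec) / 2,
    width = rep(bw, n_sec),
    height = rep(bh, n_sec),
    confidence = 100
  )
  vis <- robot_positions[robot_positions$visible, , drop = FALSE]
  robot_rows <- tibble::tibble(
    video_id = video_id,
    time_s = vis$time_s,
    class = "robot",
    x_min = vis$x_m * cfg$pixel_scale - rob_w_px / 2,
    y_min = vis$y_m * cfg$pixel_scale - rob_h_px / 2,
    width = rob_w_px,
    height = rob_h_px,
    confidence = 100
  )
  truth_tbl <- dplyr::bind_rows(bird_rows, robot_rows)
  truth_detections <- detection_series(truth_tbl, frame_size = frame_px,
                                       video_id = video_id)

  ## --- detection-noise substreams -----------------------------------------
  noisy <- cfg$detect_miss_rate > 0 || cfg$false_positive_rate > 0 ||
    cfg$box_jitter_px > 0
  if (!noisy) {
    detections <- truth_detections
  } else {
    set.seed(cfg$seed + 104729L)  # miss substream
    keep <- runif(nrow(bird_rows)) >= cfg$detect_miss_rate
    kept <- bird_rows[keep, , drop = FALSE]
    set.seed(cfg$seed + 224737L)  # jitter + confidence substream
    m <- nrow(kept)
    if (cfg$box_jitter_px > 0) {
      kept$x_min <- kept$x_min + rnorm(m, 0, cfg$box_jitter_px)
      kept$y_min <- kept$y_min + rnorm(m, 0, cfg$box_jitter_px)
    }
    kept$confidence <- runif(m, 60, 100)
    set.seed(cfg$seed + 350377L)  # false-positive substream
    n_fp <- rpois(n_sec, cfg$false_positive_rate)
    total_fp <- sum(n_fp)
    if (total_fp > 0) {
      fp_w <- pmax(4, cfg$bird_size_px * (1 + cfg$bird_size_cv *
                                            rnorm(total_fp)))
      fp_h <- pmax(4, cfg$bird_size_px * (1 + cfg$bird_size_cv *
                                            rnorm(total_fp)))
      fp_rows <- tibble::tibble(
        video_id = video_id,
        time_s = rep(t_grid, times = n_fp),
        class = "chicken",
        x_min = runif(total_fp, 0, frame_px[1] - fp_w),
        y_min = runif(total_fp, 0, frame_px[2] - fp_h),
        width = fp_w,
        height = fp_h,
        confidence = runif(total_fp, 50, 95)
      )
    } else {
      fp_rows <- NULL
    }
    noisy_tbl <- dplyr::bind_rows(kept, fp_rows, robot_rows)
    noisy_tbl$x_min <- clamp(noisy_tbl$x_min, 0,
                             frame_px[1] - noisy_tbl$width)
    noisy_tbl$y_min <- clamp(noisy_tbl$y_min, 0,
                             frame_px[2] - noisy_tbl$height)
    detections <- detection_series(noisy_tbl, frame_size = frame_px,
                                   video_id = video_id)
  }

  ## --- configured zone and true in-zone counts ----------------------------
  half_width_src <- min(cfg$robot_width_m, cfg$robot_length_m) *
    cfg$pixel_scale
  if (cfg$robot_present && nrow(robot_rows) >= 2) {
    zone <- build_zone(estimate_trajectory(truth_detections),
                       robot_pixel_width(truth_detections),
                       factor = cfg$zone_factor)
    entry_time_s <- min(robot_rows$time_s)
    exit_time_s <- max(robot_rows$time_s)
  } else {
    tran_px <- rbind(cfg$robot_transect$start,
                     cfg$robot_transect$end) * cfg$pixel_scale
    zone <- build_zone(tran_px, half_width_src, factor = cfg$zone_factor)
    entry_time_s <- NA_integer_
    exit_time_s <- NA_integer_
  }
  nominal_entry_s <- cfg$lead_in_s +
    ceiling((cfg$robot_length_m / 2) / max(cfg$robot_speed_mps, 1e-9))

  in_zone <- points_in_zone(true_positions$x_px, true_positions$y_px, zone)
  true_in_zone_counts <- tibble::tibble(
    time_s = t_grid,
    count = as.integer(tapply(in_zone, true_positions$time_s, sum))
  )

  structure(
    list(
      config = cfg,
      true_positions = true_positions,
      robot_positions = robot_positions,
      detections = detections,
      truth_detections = truth_detections,
      true_in_zone_counts = true_in_zone_counts,
      zone = zone,
      entry_time_s = entry_time_s,
      exit_time_s = exit_time_s,
      nominal_entry_s = nominal_entry_s
    ),
    class = "flock_sim"
  )
}

#' @export
print.flock_sim <- function(x, ...) {
  cat("<flock_sim> ", x$config$n_birds, " birds, ",
      x$config$duration_s, " s",
      if (x$config$robot_present) {
        paste0(", robot visible ", x$entry_time_s, "-", x$exit_time_s, " s")
      } else ", no robot",
      ", seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}
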