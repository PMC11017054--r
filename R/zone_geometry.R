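#' Reconstruct the robot trajectory from detected centroids
#'
#' The robot's per-frame centroids define its path through the camera's field
#' of vision. Frames without a robot detection are skipped; frames with more
#' than one robot box keep the highest-confidence one (ties broken by larger
#' box area, then first occurrence). The polyline uses observed points only;
#' for bookkeeping a per-second linear interpolation between the first and
#' last observation is also returned.
#'
#' @param series A [detection_series()] containing at least two frames with a
#'   robot detection.
#' @return An object of class `trajectory`: list with `points` (tibble
#'   `time_s`, `x`, `y` of observed robot centroids, time-ordered),
#'   `per_second` (tibble of 1-s interpolated positions spanning entry to
#'   exit), `entry_time_s` (first robot detection) and `exit_time_s` (last).
#' @export
estimate_trajectory <- function(series) {
  stopifnot(inherits(series, "detection_series"))
  robot <- dplyr::filter(series$detections, .data$class == "robot")
  if (nrow(robot) > 0) {
    robot$.__area <- robot$width * robot$height
    robot$.__row <- seq_len(nrow(robot))
    robot <- robot |>
      dplyr::group_by(.data$time_s) |>
      dplyr::arrange(dplyr::desc(.data$confidence), dplyr::desc(.data$.__area),
                     .data$.__row, .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$time_s)
  }
  if (nrow(robot) < 2) {
    abort(
      paste0("need >= 2 frames with a robot detection to form a trajectory (got ",
             nrow(robot), ")"),
      class = "flockzone_trajectory_error"
    )
  }
  entry <- min(robot$time_s)
  exit <- max(robot$time_s)
  grid <- seq(entry, exit)
  per_second <- tibble::tibble(
    time_s = grid,
    x = approx(robot$time_s, robot$cx, xout = grid)$y,
    y = approx(robot$time_s, robot$cy, xout = grid)$y,
    observed = grid %in% robot$time_s
  )
  structure(
    list(
      points = tibble::tibble(time_s = robot$time_s, x = robot$cx, y = robot$cy),
      per_second = per_second,
      entry_time_s = entry,
      exit_time_s = exit
    ),
    class = "trajectory"
  )
}

#' Apparent robot width in pixels
#'
#' The robot's physical width (its smaller horizontal dimension) appears in
#' the image as the smaller side of its bounding box, whichever way the robot
#' is oriented. The estimate is therefore the median over all robot
#' detections of `min(width, height)`, robust to orientation and to the odd
#' bad box.
#'
#' @param series A [detection_series()] with at least one robot detection.
#' @return Width in pixels (scalar).
#' @export
robot_pixel_width <- function(series) {
  stopifnot(inherits(series, "detection_series"))
  robot <- dplyr::filter(series$detections, .data$class == "robot")
  if (nrow(robot) == 0) {
    abort("no robot detections; cannot estimate robot width",
          class = "flockzone_trajectory_error")
  }
  median(pmin(robot$width, robot$height))
}

#' Build the robot's zone of influence
#'
#' The zone of influence is the band of floor extending `factor` robot-widths
#' to either side of the trajectory (default 1.5), i.e. the set of points
#' within Euclidean distance `half_width = factor * robot_width` of the
#' trajectory polyline, with round caps at the endpoints and an inclusive
#' boundary.
#'
#' @param trajectory A [estimate_trajectory()] result, or a two-column
#'   matrix/data frame of polyline vertices (x, y) in pixels.
#' @param robot_width Apparent robot width in pixels (see
#'   [robot_pixel_width()]).
#' @param factor Zone half-width as a multiple of the robot width.
#' @param extend_to_edges If `TRUE`, the polyline is extended beyond its
#'   first and last vertices along the end-segment directions to the frame
#'   edges, so the zone spans the whole field of vision.
#' @param frame_size `c(width, height)` in pixels; required when
#'   `extend_to_edges = TRUE`.
#' @return Object of class `zone_of_influence`: list with `polyline` (matrix
#'   of vertices), `half_width` (pixels) and `boundary_inclusive = TRUE`.
#' @export
build_zone <- function(trajectory, robot_width, factor = 1.5,
                       extend_to_edges = FALSE, frame_size = NULL) {
  if (!is.numeric(robot_width) || length(robot_width) != 1 ||
      !is.finite(robot_width) || robot_width <= 0) {
    abort("robot_width must be a positive number",
          class = "flockzone_parameter_error")
  }
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0) {
    abort("factor must be a positive number",
          class = "flockzone_parameter_error")
  }
  poly <- as_polyline(trajectory)
  if (extend_to_edges) {
    if (is.null(frame_size)) {
      abort("extend_to_edges requires frame_size",
            class = "flockzone_parameter_error")
    }
    poly <- extend_polyline_to_frame(poly, frame_size)
  }
  structure(
    list(polyline = poly, half_width = factor * robot_width,
         boundary_inclusive = TRUE),
    class = "zone_of_influence"
  )
}

as_polyline <- function(trajectory) {
  if (inherits(trajectory, "trajectory")) {
    poly <- cbind(trajectory$points$x, trajectory$points$y)
  } else {
    poly <- as.matrix(as.data.frame(trajectory))
    if (ncol(poly) != 2) {
      abort("polyline must have two columns (x, y)",
            class = "flockzone_parameter_error")
    }
  }
  storage.mode(poly) <- "double"
  dimnames(poly) <- NULL
  if (nrow(poly) < 2 || nrow(unique(poly)) < 2) {
    abort("polyline needs >= 2 distinct vertices",
          class = "flockzone_parameter_error")
  }
  if (any(!is.finite(poly))) {
    abort("polyline vertices must be finite",
          class = "flockzone_parameter_error")
  }
  poly
}

## Extend first/last segments outward until they leave [0,W]x[0,H].
extend_polyline_to_frame <- function(poly, frame_size) {
  extend_one <- function(p, dir) {
    if (all(dir == 0)) return(p)
    ts <- c()
    if (dir[1] > 0) ts <- c(ts, (frame_size[1] - p[1]) / dir[1])
    if (dir[1] < 0) ts <- c(ts, (0 - p[1]) / dir[1])
    if (dir[2] > 0) ts <- c(ts, (frame_size[2] - p[2]) / dir[2])
    if (dir[2] < 0) ts <- c(ts, (0 - p[2]) / dir[2])
    ts <- ts[ts > 0]
    if (length(ts) == 0) return(p)
    p + min(ts) * dir
  }
  n <- nrow(poly)
  first_dir <- poly[1, ] - poly[2, ]
  last_dir <- poly[n, ] - poly[n - 1, ]
  rbind(extend_one(poly[1, ], first_dir), poly, extend_one(poly[n, ], last_dir))
}

## Vectorized minimum Euclidean distance from points to a polyline.
dist_to_polyline <- function(px, py, poly) {
  n <- nrow(poly)
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n - 1)) {
    ax <- poly[i, 1]; ay <- poly[i, 2]
    dx <- poly[i + 1, 1] - ax; dy <- poly[i + 1, 2] - ay
    l2 <- dx * dx + dy * dy
    if (l2 == 0) {
      t <- 0
    } else {
      t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / l2))
    }
    ex <- ax + t * dx - px
    ey <- ay + t * dy - py
    d2 <- pmin(d2, ex * ex + ey * ey)
  }
  sqrt(d2)
}

#' Test points for zone membership
#'
#' A point is in the zone iff its minimum distance to the trajectory
#' polyline is at most the zone half-width (boundary inclusive).
#'
#' `point_in_zone()` is the scalar form; `points_in_zone()` is vectorized
#' over coordinate vectors.
#'
#' @param point Numeric `c(x, y)` in pixels.
#' @param zone A [build_zone()] result.
#' @return Logical.
#' @export
point_in_zone <- function(point, zone) {
  stopifnot(inherits(zone, "zone_of_influence"),
            length(point) == 2, all(is.finite(point)))
  points_in_zone(point[1], point[2], zone)
}

#' @rdname point_in_zone
#' @param x,y Coordinate vectors in pixels.
#' @export
points_in_zone <- function(x, y, zone) {
  stopifnot(inherits(zone, "zone_of_influence"), length(x) == length(y))
  if (length(x) == 0) return(logical(0))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("point coordinates must be finite",
          class = "flockzone_parameter_error")
  }
  dist_to_polyline(x, y, zone$polyline) <= zone$half_width
}

#' Serialize / restore a zone of influence as JSON
#'
#' Zones are stored as plain JSON (polyline vertices plus half-width) so a
#' zone computed from a robot video can be reused for a control video, where
#' no robot exists to define one.
#'
#' @param zone A [build_zone()] result.
#' @param path JSON file path.
#' @return `zone_write_json()`: `path`, invisibly. `zone_read_json()`: a
#'   `zone_of_influence`.
#' @export
zone_write_json <- function(zone, path) {
  stopifnot(inherits(zone, "zone_of_influence"))
  jsonlite::write_json(
    list(
      polyline = unname(as.data.frame(zone$polyline)),
      half_width = zone$half_width,
      boundary_inclusive = zone$boundary_inclusive
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname zone_write_json
#' @export
zone_read_json <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("zone file not found: ", path), class = "flockzone_io_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  poly <- as.matrix(raw$polyline)
  structure(
    list(polyline = unname(poly), half_width = raw$half_width,
         boundary_inclusive = isTRUE(raw$boundary_inclusive)),
    class = "zone_of_influence"
  )
}
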