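robot_series <- function(times, xs, ys, w = 40, h = 30, confidence = 90) {
  detection_series(make_detections(
    time_s = times, class = "robot",
    x_min = xs - w / 2, y_min = ys - h / 2,
    width = w, height = h, confidence = confidence
  ))
}

test_that("trajectory uses observed robot centroids in time order", {
  s <- robot_series(c(60, 120), xs = c(0, 500) + 20, ys = c(100, 100) + 15)
  traj <- estimate_trajectory(s)
  expect_equal(traj$points$x, c(20, 520))
  expect_equal(traj$points$y, c(115, 115))
  expect_equal(traj$entry_time_s, 60)
  expect_equal(traj$exit_time_s, 120)
})

test_that("gaps are interpolated per second but the polyline stays observed", {
  s <- robot_series(c(60, 62, 63), xs = c(100, 140, 150), ys = c(50, 70, 90))
  traj <- estimate_trajectory(s)
  expect_equal(nrow(traj$points), 3)
  mid <- traj$per_second[traj$per_second$time_s == 61, ]
  expect_equal(mid$x, (100 + 140) / 2)
  expect_equal(mid$y, (50 + 70) / 2)
  expect_false(mid$observed)
})

test_that("too few robot observations is an error", {
  expect_error(
    estimate_trajectory(detection_series(
      make_detections(0, "chicken", 0, 0, 10, 10)
    )),
    class = "flockzone_trajectory_error"
  )
  expect_error(estimate_trajectory(robot_series(60, 10, 10)),
               class = "flockzone_trajectory_error")
})

test_that("multiple robot boxes keep highest confidence, ties by area", {
  df <- dplyr::bind_rows(
    make_detections(0, "robot", 0, 0, 10, 10, confidence = 80),
    make_detections(0, "robot", 100, 100, 10, 10, confidence = 95),
    make_detections(1, "robot", 0, 0, 10, 10, confidence = 90),   # area 100
    make_detections(1, "robot", 200, 200, 20, 20, confidence = 90) # area 400
  )
  traj <- estimate_trajectory(detection_series(df))
  expect_equal(traj$points$x, c(105, 210))
})

test_that("robot pixel width is the median of min(box sides)", {
  s <- robot_series(c(0, 1, 2), xs = c(0, 0, 0), ys = c(0, 0, 0))
  s$detections$width <- c(40, 30, 42)
  s$detections$height <- c(30, 40, 31)
  # min sides are {30, 30, 31}; enumerated median = 30
  expect_equal(robot_pixel_width(s), 30)
  s1 <- robot_series(5, 100, 100, w = 38, h = 31)
  expect_equal(robot_pixel_width(s1), 31)
  s2 <- robot_series(c(0, 1), c(0, 0), c(0, 0), w = 50, h = 20)
  expect_equal(robot_pixel_width(s2), 20)
})

test_that("zone half-width is factor times robot width", {
  zone <- build_zone(cbind(c(0, 100), c(0, 0)), robot_width = 31,
                     factor = 1.5)
  expect_equal(zone$half_width, 46.5)
  expect_true(zone$boundary_inclusive)
  expect_error(build_zone(cbind(c(0, 100), c(0, 0)), 31, factor = 0),
               class = "flockzone_parameter_error")
  expect_error(build_zone(cbind(c(0, 100), c(0, 0)), -3),
               class = "flockzone_parameter_error")
})

test_that("membership matches the buffered-band geometry with round caps", {
  zone <- build_zone(cbind(c(0, 200), c(100, 100)), robot_width = 10,
                     factor = 1)
  expect_true(point_in_zone(c(50, 109.9), zone))
  expect_false(point_in_zone(c(50, 110.1), zone))
  expect_true(point_in_zone(c(0, 100), zone))      # polyline vertex
  expect_true(point_in_zone(c(50, 110), zone))     # exactly on the boundary
  expect_true(point_in_zone(c(-9.9, 100), zone))   # round end cap
  expect_false(point_in_zone(c(-10.1, 100), zone))
})

test_that("membership agrees with the brute-force distance oracle", {
  withr::with_seed(42, {
    poly <- cbind(runif(5, 0, 300), runif(5, 0, 300))
    zone <- build_zone(poly, robot_width = 20, factor = 1.5)
    px <- runif(1000, -50, 350)
    py <- runif(1000, -50, 350)
  })
  got <- points_in_zone(px, py, zone)
  want <- vapply(seq_along(px), function(i) {
    oracle_point_polyline_dist(c(px[i], py[i]), poly) <= zone$half_width
  }, logical(1))
  expect_identical(got, want)
})

test_that("membership is invariant under joint rigid motion", {
  withr::with_seed(7, {
    poly <- cbind(runif(4, 0, 100), runif(4, 0, 100))
    px <- runif(200, -20, 120)
    py <- runif(200, -20, 120)
  })
  zone <- build_zone(poly, 15, factor = 1.2)
  base <- points_in_zone(px, py, zone)
  theta <- 0.73
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  shift <- c(37, -12)
  rot <- function(m) sweep(m %*% t(R), 2, shift, "+")
  zone2 <- build_zone(rot(poly), 15, factor = 1.2)
  pts2 <- rot(cbind(px, py))
  expect_identical(points_in_zone(pts2[, 1], pts2[, 2], zone2), base)
})

test_that("enlarging the buffer factor never removes members", {
  withr::with_seed(3, {
    poly <- cbind(runif(4, 0, 100), runif(4, 0, 100))
    px <- runif(300, -20, 120)
    py <- runif(300, -20, 120)
  })
  inner <- points_in_zone(px, py, build_zone(poly, 10, factor = 1))
  outer <- points_in_zone(px, py, build_zone(poly, 10, factor = 1.8))
  expect_true(all(outer[inner]))
})

test_that("zones round-trip through JSON", {
  zone <- build_zone(cbind(c(0, 50, 100), c(0, 30, 0)), 12, factor = 1.5)
  path <- withr::local_tempfile(fileext = ".json")
  zone_write_json(zone, path)
  zone2 <- zone_read_json(path)
  expect_equal(zone2$polyline, zone$polyline)
  expect_equal(zone2$half_width, zone$half_width)
  withr::with_seed(1, {
    px <- runif(100, -20, 120); py <- runif(100, -20, 60)
  })
  expect_identical(points_in_zone(px, py, zone2),
                   points_in_zone(px, py, zone))
})

test_that("extending the polyline to the frame edges widens coverage", {
  zone <- build_zone(cbind(c(100, 200), c(100, 100)), 10, factor = 1,
                     extend_to_edges = TRUE, frame_size = c(400, 200))
  expect_true(point_in_zone(c(5, 100), zone))
  expect_true(point_in_zone(c(395, 100), zone))
})
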