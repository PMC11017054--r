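# Independent oracles used across the suite. Each is deliberately written
# from first principles, separate from the package implementation paths it
# checks.

# Scalar point-to-segment distance, vertex-by-vertex.
oracle_point_segment_dist <- function(p, a, b) {
  ab <- b - a
  l2 <- sum(ab^2)
  if (l2 == 0) return(sqrt(sum((p - a)^2)))
  t <- sum((p - a) * ab) / l2
  if (t < 0) {
    sqrt(sum((p - a)^2))
  } else if (t > 1) {
    sqrt(sum((p - b)^2))
  } else {
    foot <- a + t * ab
    sqrt(sum((p - foot)^2))
  }
}

oracle_point_polyline_dist <- function(p, poly) {
  min(vapply(seq_len(nrow(poly) - 1), function(i) {
    oracle_point_segment_dist(p, poly[i, ], poly[i + 1, ])
  }, numeric(1)))
}

# Closed-form simple linear regression (sum formulas) of y on x.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  resid <- y - intercept - slope * x
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(resid^2) / sst
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# Pixel-count IoU on the integer grid for half-open integer boxes.
oracle_raster_iou <- function(a, b) {
  cells <- function(box) {
    g <- expand.grid(x = seq(box[1], box[1] + box[3] - 1),
                     y = seq(box[2], box[2] + box[4] - 1))
    paste(g$x, g$y)
  }
  ca <- cells(a); cb <- cells(b)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

# Exhaustive maximum bipartite matching: the largest number of
# prediction/truth pairs with IoU >= threshold (feasible only for small
# instances).
oracle_optimal_tp <- function(pred, truth, iou_threshold) {
  np <- nrow(pred); ng <- nrow(truth)
  if (np == 0 || ng == 0) return(0L)
  ok <- matrix(FALSE, np, ng)
  for (i in seq_len(np)) {
    for (j in seq_len(ng)) {
      ok[i, j] <- box_iou(pred[i, ], truth[j, ]) >= iou_threshold
    }
  }
  best <- 0L
  recurse <- function(i, used) {
    if (i > np) {
      best <<- max(best, sum(used))
      return(invisible())
    }
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      recurse(i + 1, used)
      used[j] <- FALSE
    }
    recurse(i + 1, used)
  }
  recurse(1L, rep(FALSE, ng))
  best
}

# Build a detection tibble row-wise from box parameters.
make_detections <- function(time_s, class, x_min, y_min, width, height,
                            confidence = 90, video_id = "v1") {
  tibble::tibble(
    video_id = video_id, time_s = time_s, class = class,
    x_min = x_min, y_min = y_min, width = width, height = height,
    confidence = confidence
  )
}

# A density series with an exact (optionally noisy) linear trend, built
# directly rather than through the pipeline.
make_density_series <- function(t, pct, video_id = "v1") {
  out <- tibble::tibble(
    video_id = video_id, t_rel_s = t, count = NA_integer_,
    relative_density_pct = pct
  )
  attr(out, "baseline") <- structure(
    list(baseline_count = 1, window = c(-60, -15), n_samples = 46),
    class = "baseline_estimate"
  )
  class(out) <- c("density_series", class(out))
  out
}

# Random axis-aligned boxes inside a W x H frame.
random_boxes <- function(n, w = 200, h = 200, max_side = 40) {
  width <- runif(n, 5, max_side)
  height <- runif(n, 5, max_side)
  tibble::tibble(
    video_id = "v1", time_s = 0, class = "chicken",
    x_min = runif(n, 0, w - width), y_min = runif(n, 0, h - height),
    width = width, height = height, confidence = runif(n, 50, 100)
  )
}
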