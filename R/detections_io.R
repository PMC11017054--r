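#' Build a detection series from a per-frame detection table
#'
#' A detection series is the in-memory form of the pipeline's tabular input:
#' one row per detected object, sampled at (nominally) 1-s intervals from a
#' fixed camera. Boxes use pixel coordinates with the origin at the image
#' top-left, x rightward and y downward, 0-based, half-open on the right and
#' bottom edges. Centroids are computed as `x_min + width / 2` and
#' `y_min + height / 2`.
#'
#' @param detections Data frame with columns `video_id`, `time_s`, `class`,
#'   `x_min`, `y_min`, `width`, `height`, `confidence`. `class` must be one of
#'   `"chicken"`, `"robot"`, `"feeder"`; `confidence` is on the 0--100 scale;
#'   `time_s` must be integer-valued (sample times in seconds). May have zero
#'   rows.
#' @param frame_size Optional `c(width, height)` of the image in pixels. When
#'   given, all boxes must lie within the frame.
#' @param video_id Optional video identifier; defaults to the (single) value
#'   found in `detections`, or `"video"` for an empty table.
#'
#' @return An object of class `detection_series`: a list with elements
#'   `video_id`, `detections` (a tibble with centroid columns `cx`, `cy`
#'   added, sorted by `time_s` then `class`) and `frame_size`.
#' @export
#' @examples
#' df <- tibble::tibble(
#'   video_id = "v1", time_s = c(0, 0, 1), class = c("chicken", "robot", "chicken"),
#'   x_min = c(10, 100, 12), y_min = c(20, 50, 22),
#'   width = c(30, 60, 30), height = c(30, 50, 30), confidence = 90
#' )
#' detection_series(df)
detection_series <- function(detections, frame_size = NULL, video_id = NULL) {
  detections <- tibble::as_tibble(detections)
  missing_cols <- setdiff(DETECTION_COLUMNS, names(detections))
  if (length(missing_cols) > 0) {
    abort(
      paste0("detection table is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "flockzone_schema_error"
    )
  }
  detections <- detections[DETECTION_COLUMNS]

  num_cols <- c("time_s", "x_min", "y_min", "width", "height", "confidence")
  for (col in num_cols) {
    v <- detections[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      abort(
        paste0("column '", col, "' is not numeric (first bad row: ",
               if (length(bad) > 0) bad[1] else 1, ")"),
        class = "flockzone_parse_error"
      )
    }
    if (anyNA(v) || any(!is.finite(v))) {
      abort(
        paste0("column '", col, "' has missing or non-finite values (row ",
               which(!is.finite(v))[1], ")"),
        class = "flockzone_parse_error"
      )
    }
  }

  if (nrow(detections) > 0) {
    bad_class <- !detections$class %in% FLOCKZONE_CLASSES
    if (any(bad_class)) {
      abort(
        paste0("unknown object class '", detections$class[which(bad_class)[1]],
               "' (row ", which(bad_class)[1], "); expected one of: ",
               paste(FLOCKZONE_CLASSES, collapse = ", ")),
        class = "flockzone_parse_error"
      )
    }
    bad_dim <- detections$width <= 0 | detections$height <= 0
    if (any(bad_dim)) {
      abort(
        paste0("non-positive box width/height at row ", which(bad_dim)[1]),
        class = "flockzone_parse_error"
      )
    }
    if (any(detections$time_s != round(detections$time_s))) {
      abort("time_s must be integer-valued seconds",
            class = "flockzone_parse_error")
    }
    if (any(detections$confidence < 0 | detections$confidence > 100)) {
      abort("confidence must lie in [0, 100]",
            class = "flockzone_parse_error")
    }
    ids <- unique(detections$video_id)
    if (length(ids) > 1) {
      abort(
        paste0("detection table contains ", length(ids),
               " video_id values; a series holds one video"),
        class = "flockzone_schema_error"
      )
    }
    if (is.null(video_id)) video_id <- as.character(ids)
  }
  if (is.null(video_id)) video_id <- "video"

  detections$video_id <- as.character(video_id)
  detections$time_s <- as.integer(round(detections$time_s))
  detections$cx <- detections$x_min + detections$width / 2
  detections$cy <- detections$y_min + detections$height / 2
  detections <- dplyr::arrange(detections, .data$time_s, .data$class)

  if (!is.null(frame_size)) {
    stopifnot(length(frame_size) == 2, all(frame_size > 0))
    out_of_frame <- detections$x_min < 0 | detections$y_min < 0 |
      detections$x_min + detections$width > frame_size[1] |
      detections$y_min + detections$height > frame_size[2]
    if (any(out_of_frame)) {
      abort(
        paste0("box outside frame_size at row ", which(out_of_frame)[1]),
        class = "flockzone_parse_error"
      )
    }
  }

  structure(
    list(video_id = video_id, detections = detections,
         frame_size = frame_size),
    class = "detection_series"
  )
}

#' @export
print.detection_series <- function(x, ...) {
  cat("<detection_series> video ", x$video_id, ": ",
      nrow(x$detections), " detections over ",
      length(unique(x$detections$time_s)), " frames\n", sep = "")
  invisible(x)
}

#' Read a detection CSV into a detection series
#'
#' Reads the pipeline's detection schema
#' (`video_id,time_s,class,x_min,y_min,width,height,confidence`), groups rows
#' into frames by `time_s` and computes centroids. An empty file (header only
#' or zero bytes) yields an empty series. Sample spacing is nominally 1 s but
#' any strictly increasing set of integer times is accepted; downstream
#' operations tolerate missing seconds.
#'
#' @param path Path to a CSV file.
#' @param frame_size Optional `c(width, height)` in pixels, checked against
#'   all boxes.
#' @return A [detection_series()].
#' @export
read_detections <- function(path, frame_size = NULL) {
  if (!file.exists(path)) {
    abort(paste0("detection file not found: ", path),
          class = "flockzone_io_error")
  }
  if (file.size(path) == 0) {
    return(empty_detection_series(frame_size = frame_size))
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  progress = FALSE))
  missing_cols <- setdiff(DETECTION_COLUMNS, header)
  if (length(missing_cols) > 0) {
    abort(
      paste0("detection file ", path, " is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "flockzone_schema_error"
    )
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      video_id = readr::col_character(),
      time_s = readr::col_double(),
      class = readr::col_character(),
      x_min = readr::col_double(),
      y_min = readr::col_double(),
      width = readr::col_double(),
      height = readr::col_double(),
      confidence = readr::col_double()
    ),
    progress = FALSE, show_col_types = FALSE, lazy = FALSE
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(
      paste0("could not parse ", path, ": ", prob$expected[1],
             " expected at row ", prob$row[1]),
      class = "flockzone_parse_error"
    )
  }
  detection_series(raw, frame_size = frame_size)
}

empty_detection_series <- function(video_id = "video", frame_size = NULL) {
  empty <- tibble::tibble(
    video_id = character(), time_s = double(), class = character(),
    x_min = double(), y_min = double(), width = double(), height = double(),
    confidence = double()
  )
  detection_series(empty, frame_size = frame_size, video_id = video_id)
}

#' Write a detection series to CSV
#'
#' Writes the exact schema read by [read_detections()], one row per
#' detection, sorted by `time_s` then `class`. `read_detections()` after
#' `write_detections()` reproduces the series field by field.
#'
#' @param series A [detection_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(series, path) {
  stopifnot(inherits(series, "detection_series"))
  out <- series$detections[DETECTION_COLUMNS]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Extract the detections of a single frame
#'
#' @param series A [detection_series()].
#' @param time_s Frame time in seconds.
#' @return Tibble of the frame's detections (possibly zero rows).
#' @export
frame_at <- function(series, time_s) {
  stopifnot(inherits(series, "detection_series"))
  dplyr::filter(series$detections, .data$time_s == !!time_s)
}
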