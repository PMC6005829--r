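#' Colour thresholds for marker segmentation
#'
#' The marker is segmented in HSV space: a pixel is "red" when its hue falls
#' in the wrap-around band `[hue_lo, 1] U [0, hue_hi]` and its saturation and
#' value clear minimum floors. Defaults suit a saturated red marker on a
#' black-cloth background; loosen `s_min`/`v_min` for dim lighting.
#'
#' @param hue_lo,hue_hi Hue band edges in `[0, 1]` (red wraps through 0).
#' @param s_min,v_min Minimum saturation and value in `[0, 1]`.
#' @param min_area Minimum pixel count of the largest red component for a
#'   detection. Default 5.
#' @return A list of class `marker_color_config`.
#' @export
marker_color_config <- function(hue_lo = 0.92, hue_hi = 0.08, s_min = 0.4,
                                v_min = 0.2, min_area = 5) {
  stopifnot(hue_lo >= 0, hue_lo <= 1, hue_hi >= 0, hue_hi <= 1,
            s_min >= 0, s_min <= 1, v_min >= 0, v_min <= 1, min_area >= 1)
  structure(list(hue_lo = hue_lo, hue_hi = hue_hi, s_min = s_min,
                 v_min = v_min, min_area = min_area),
            class = "marker_color_config")
}

#' Locate the red marker in a single frame
#'
#' Thresholds the frame in HSV space, labels the connected red components,
#' and returns the intensity-weighted centroid (weights = pixel value V) of
#' the largest component. Coordinates are in pixels, `x` along columns and
#' `y` along rows, both 1-based at pixel centres.
#'
#' @param frame An `height x width x 3` RGB array with values in `[0, 1]`
#'   (as returned by [png::readPNG()]).
#' @param config A [marker_color_config()].
#' @return A one-row tibble with `x`, `y`, `area`, `found`. When no
#'   component passes the thresholds, `found` is `FALSE` and `x`/`y` are `NA`.
#' @export
segment_marker <- function(frame, config = marker_color_config()) {
  if (!is.array(frame) || length(dim(frame)) != 3 || dim(frame)[3] < 3 ||
      !is.numeric(frame)) {
    stop("decode error: `frame` must be a numeric height x width x 3 RGB array",
         call. = FALSE)
  }
  h <- dim(frame)[1]; w <- dim(frame)[2]
  rgb <- rbind(as.vector(frame[, , 1]), as.vector(frame[, , 2]),
               as.vector(frame[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hue <- hsv[1, ]; s <- hsv[2, ]; v <- hsv[3, ]
  in_hue <- if (config$hue_lo > config$hue_hi) {
    hue >= config$hue_lo | hue <= config$hue_hi  # red wraps through 0
  } else {
    hue >= config$hue_lo & hue <= config$hue_hi
  }
  mask <- in_hue & s >= config$s_min & v >= config$v_min
  not_found <- tibble::tibble(x = NA_real_, y = NA_real_, area = 0L,
                              found = FALSE)
  if (!any(mask)) return(not_found)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow = h, ncol = w))
  labv <- as.vector(lab)
  counts <- tabulate(labv[labv > 0])
  biggest <- which.max(counts)
  if (counts[biggest] < config$min_area) return(not_found)
  idx <- which(labv == biggest)
  wt <- v[idx]
  row <- (idx - 1) %% h + 1
  col <- (idx - 1) %/% h + 1
  tibble::tibble(x = sum(col * wt) / sum(wt), y = sum(row * wt) / sum(wt),
                 area = counts[biggest], found = TRUE)
}

#' Track the marker through a frame-sequence video
#'
#' Reads every `frame_*.png` in a video directory in order, locates the
#' marker per frame, and linearly interpolates runs of at most `max_gap`
#' missed frames so the series stays uniformly sampled for the FFT. A longer
#' run of misses fails the sample.
#'
#' @param dir Directory holding numbered `frame_*.png` files and optionally a
#'   `meta.json` with an `fps` field.
#' @param fps Frames per second; overrides `meta.json`. Default 240 when
#'   neither is given.
#' @param config A [marker_color_config()].
#' @param max_gap Longest run of missed frames to bridge by interpolation.
#'   Default 5.
#' @return A tibble of class `centroid_series` with columns `frame`, `t`,
#'   `x`, `y`, `found`, and attributes `fps` and `source_id`.
#' @export
track_frames <- function(dir, fps = NULL, config = marker_color_config(),
                         max_gap = 5) {
  files <- sort(list.files(dir, pattern = "^frame_.*\\.png$",
                           full.names = TRUE))
  if (length(files) < 2) {
    stop("no video: ", dir, " holds fewer than 2 frame_*.png files",
         call. = FALSE)
  }
  meta_path <- file.path(dir, "meta.json")
  if (is.null(fps) && file.exists(meta_path)) {
    fps <- jsonlite::read_json(meta_path)$fps
  }
  if (is.null(fps)) fps <- 240
  cents <- purrr::map_dfr(files, function(f) {
    segment_marker(png::readPNG(f)[, , 1:3, drop = FALSE], config)
  })
  gap <- longest_run(!cents$found)
  if (gap > max_gap) {
    stop("tracking-failure: marker lost for ", gap,
         " consecutive frames (max_gap = ", max_gap, ") in ", dir,
         call. = FALSE)
  }
  x <- cents$x; y <- cents$y
  if (anyNA(x)) {
    x <- zoo::na.approx(x, na.rm = FALSE)
    y <- zoo::na.approx(y, na.rm = FALSE)
    # edge gaps have no second anchor; hold the nearest found position
    x <- zoo::na.locf(zoo::na.locf(x, na.rm = FALSE), fromLast = TRUE)
    y <- zoo::na.locf(zoo::na.locf(y, na.rm = FALSE), fromLast = TRUE)
  }
  out <- tibble::tibble(frame = seq_along(files),
                        t = (seq_along(files) - 1) / fps,
                        x = x, y = y, found = cents$found)
  attr(out, "fps") <- fps
  attr(out, "source_id") <- basename(dir)
  class(out) <- c("centroid_series", class(out))
  out
}

longest_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}

#' Centroid series to a mean-centred displacement trace
#'
#' Projects the tracked centroid onto the oscillation axis, subtracts the
#' mean, and (by default) crops the series at the frame of global maximum
#' absolute displacement — the release point, discarding the pre-release
#' hold. `axis = "principal"` projects onto the first principal axis of the
#' `(x, y)` scatter for tilted cameras.
#'
#' @param centroids A `centroid_series` from [track_frames()], or any data
#'   frame with `t`, `x`, `y` columns and no unresolved gaps.
#' @param axis `"x"` (default: stems are pulled sideways), `"y"`, or
#'   `"principal"`.
#' @param crop `"max"` (default) to start the trace at the global
#'   absolute-maximum displacement, `"none"` to keep every frame, or a
#'   numeric start time in seconds.
#' @return A [vib_trace()] (time restarts at 0 after cropping).
#' @export
to_displacement <- function(centroids, axis = c("x", "y", "principal"),
                            crop = "max") {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(centroids),
            all(c("t", "x", "y") %in% names(centroids)))
  if (anyNA(centroids$x) || anyNA(centroids$y)) {
    stop("unresolved gaps: interpolate or re-track before converting",
         call. = FALSE)
  }
  d <- switch(axis,
    x = centroids$x,
    y = centroids$y,
    principal = {
      xy <- cbind(centroids$x - mean(centroids$x),
                  centroids$y - mean(centroids$y))
      ev <- eigen(crossprod(xy), symmetric = TRUE)$vectors[, 1]
      as.vector(xy %*% ev)
    })
  d <- d - mean(d)
  if (max(abs(d)) < 1e-9) {
    stop("degenerate-trace: no vibration (constant centroid)", call. = FALSE)
  }
  start <- if (identical(crop, "max")) {
    which.max(abs(d))
  } else if (identical(crop, "none")) {
    1L
  } else if (is.numeric(crop)) {
    which(centroids$t >= crop)[1]
  } else {
    stop("`crop` must be \"max\", \"none\" or a start time in seconds",
         call. = FALSE)
  }
  if (is.na(start) || nrow(centroids) - start + 1 < 2) {
    stop("cropping leaves fewer than 2 samples", call. = FALSE)
  }
  d <- d[start:length(d)]
  d <- d - mean(d)
  fps <- attr(centroids, "fps")
  if (is.null(fps)) fps <- 1 / median(diff(centroids$t))
  id <- attr(centroids, "source_id")
  vib_trace(seq_along(d) / fps - 1 / fps, d, fps = fps,
            source_id = if (is.null(id)) "video" else id)
}
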