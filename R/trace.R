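#' Displacement trace container
#'
#' A `vib_trace` is a tibble with columns `t` (seconds) and `d` (displacement,
#' pixels), uniformly sampled, carrying the frame rate and a sample label as
#' attributes. All spectral and peak-detection functions in the package take
#' and return this shape, so traces pipe through `dplyr` verbs like any tibble.
#'
#' @param t Time vector, seconds, strictly increasing with uniform step.
#' @param d Displacement vector, pixels, same length as `t`.
#' @param fps Frames per second. If `NULL`, inferred as `1/median(diff(t))`.
#' @param source_id Sample label.
#' @return A tibble of class `vib_trace` with attributes `fps` and `source_id`.
#' @export
vib_trace <- function(t, d, fps = NULL, source_id = "trace") {
  stopifnot(is.numeric(t), is.numeric(d), length(t) == length(d))
  if (length(t) < 2) stop("a trace needs at least 2 samples", call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0)) stop("`t` must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    stop("`t` must be uniformly sampled", call. = FALSE)
  }
  if (is.null(fps)) fps <- 1 / stats::median(dt)
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  out <- tibble::tibble(t = t, d = d)
  attr(out, "fps") <- fps
  attr(out, "source_id") <- source_id
  class(out) <- c("vib_trace", class(out))
  out
}

#' @rdname vib_trace
#' @param x A `vib_trace`.
#' @export
trace_fps <- function(x) {
  fps <- attr(x, "fps")
  if (is.null(fps)) fps <- 1 / stats::median(diff(x$t))
  fps
}

#' @rdname vib_trace
#' @export
trace_id <- function(x) {
  id <- attr(x, "source_id")
  if (is.null(id)) "trace" else id
}

#' @export
print.vib_trace <- function(x, ...) {
  cat(sprintf("# vib_trace '%s': %d samples at %.6g fps (%.3g s)\n",
              trace_id(x), nrow(x), trace_fps(x), nrow(x) / trace_fps(x)))
  NextMethod()
}

#' Plot a displacement trace
#'
#' @param object A `vib_trace`.
#' @param ... Unused.
#' @return A ggplot of displacement (px) against time (s).
#' @method autoplot vib_trace
#' @export
autoplot.vib_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$d)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = "Displacement (px)",
                  title = trace_id(object)) +
    ggplot2::theme_minimal()
}

# rebuild a vib_trace with new displacement values, keeping metadata
retrace <- function(x, d, suffix = NULL) {
  id <- trace_id(x)
  if (!is.null(suffix)) id <- paste0(id, suffix)
  vib_trace(x$t, d, fps = trace_fps(x), source_id = id)
}
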