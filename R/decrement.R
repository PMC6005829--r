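#' Detect per-period amplitude peaks in a raw displacement trace
#'
#' Finds the positive-side maxima of the un-windowed waveform, at most one
#' per oscillation period, for logarithmic-decrement estimation. Candidate
#' local maxima must be separated by at least `spacing_factor / omega_d`
#' seconds (0.7 periods by default, so noise ripples inside a period cannot
#' produce two peaks) and rise above `prominence * max(|d|)` (2% by default).
#' Peaks are numbered from the first post-release maximum.
#'
#' @param trace A raw (un-windowed) [vib_trace()].
#' @param omega_d Damped natural frequency, Hz (from
#'   [estimate_damped_frequency()]), used to set the minimum peak spacing.
#' @param spacing_factor Minimum peak separation in periods. Default 0.7.
#' @param prominence Minimum peak height as a fraction of the maximum
#'   absolute displacement. Default 0.02.
#' @return A tibble of class `peak_series`: `ordinal` (1-based peak number),
#'   `t_peak` (s), `amplitude` (px, positive).
#' @export
detect_peaks <- function(trace, omega_d, spacing_factor = 0.7,
                         prominence = 0.02) {
  stopifnot(inherits(trace, "vib_trace"), omega_d > 0)
  d <- trace$d - mean(trace$d)
  amax <- max(abs(d))
  if (amax == 0) stop("insufficient-peaks: flat trace", call. = FALSE)
  fps <- trace_fps(trace)
  min_dist <- max(1, ceiling(spacing_factor / omega_d * fps))
  # only the active vibration span carries per-period maxima; local maxima of
  # tracking noise after the envelope has died are not oscillation peaks
  d <- d[seq_len(active_length(d, fps))]
  pk <- pracma::findpeaks(d, minpeakheight = prominence * amax)
  if (is.null(pk) || nrow(pk) < 4) {
    stop("insufficient-peaks: fewer than 4 positive peaks detected", call. = FALSE)
  }
  # enforce the per-period spacing ourselves: accept candidates from the
  # highest down, rejecting any within min_dist of an accepted peak
  cand <- pk[order(-pk[, 1]), , drop = FALSE]
  kept_pos <- integer(0)
  for (j in seq_len(nrow(cand))) {
    if (!length(kept_pos) || all(abs(kept_pos - cand[j, 2]) >= min_dist)) {
      kept_pos <- c(kept_pos, cand[j, 2])
    }
  }
  kept_pos <- sort(kept_pos)
  if (length(kept_pos) < 4) {
    stop("insufficient-peaks: fewer than 4 positive peaks detected", call. = FALSE)
  }
  # read each amplitude by quadrature demodulation over one period around
  # the sampled maximum: least-squares fit of a*cos + b*sin at omega_d,
  # amplitude = sqrt(a^2 + b^2). This interpolates the true crest between
  # samples (the sampled maximum sits below the crest by an alignment-
  # dependent factor when fps/omega_d is small) and averages tracking noise
  # over the window; the envelope decay across the window biases every
  # period by the same factor, which cancels from the log-decay slope.
  # The window runs forward from the crest so that every peak sees the same
  # window shape (a centred window would be clipped at the trace start for
  # the first peak, breaking the cancellation).
  span <- 2L * round(1.0 / omega_d * fps)
  t <- trace$t
  fit1 <- vapply(kept_pos, function(pos) {
    j <- pos:min(length(d), pos + span)
    if (length(j) < 5) return(c(d[pos], 0))
    ph <- 2 * pi * omega_d * (t[j] - t[pos])
    cf <- stats::coef(stats::lm.fit(cbind(cos(ph), sin(ph)), d[j]))
    if (!all(is.finite(cf))) return(c(d[pos], 0))
    # phase offset of the fitted crest relative to the sampled maximum
    c(sqrt(sum(cf^2)), atan2(cf[2], cf[1]))
  }, numeric(2))
  amp <- fit1[1, ]
  # The sampled maximum sits up to half a sample off the true crest, so the
  # demodulated amplitude references the envelope at a jittered time while
  # the ordinal regression assumes exact one-period spacing. Shift each
  # amplitude to its crest time using a first-pass decay-rate estimate
  # (second-order residual only).
  pos_ok <- amp > 0
  if (sum(pos_ok) >= 2) {
    delta0 <- median(-diff(log(amp[pos_ok])))
    if (is.finite(delta0) && delta0 > 0) {
      dt_crest <- fit1[2, ] / (2 * pi * omega_d)   # t*_crest - t_sample
      amp <- amp * exp(-delta0 * omega_d * dt_crest)
    }
  }
  keep <- amp > 0
  out <- tibble::tibble(ordinal = seq_along(kept_pos),
                        t_peak = trace$t[kept_pos],
                        amplitude = amp)[keep, ]
  attr(out, "source_id") <- trace_id(trace)
  class(out) <- c("peak_series", class(out))
  out
}

#' Logarithmic decrement by the four-peak regression-selection rule
#'
#' The decrement \eqn{\delta = \frac{1}{r}\ln(A_i / A_{i+r})} is estimated by
#' regression rather than a single peak ratio, to damp measurement error:
#' for every window of four consecutive peak ordinals starting at ordinals
#' 1 through 6 (using only peaks 1-9), `ln(amplitude)` is regressed on the
#' ordinal. Among windows whose slope is significant at p < 0.05, the one
#' with maximum r-squared wins (earliest window on ties) and
#' \eqn{\delta = |slope|}. If no window qualifies — e.g. amplitudes that do
#' not decay monotonically — the sample is flagged for manual re-measurement
#' and no decrement is reported.
#'
#' @param peaks A `peak_series` from [detect_peaks()] (or any data frame with
#'   `ordinal` and `amplitude` columns).
#' @param p_max Significance threshold on the window slope. Default 0.05.
#' @param max_start Last window start ordinal considered. Default 6.
#' @return An object of class `decrement_fit`: a list with `delta`,
#'   `window_start`, `slope`, `r2`, `p_value`, `n_points`, `flagged_manual`
#'   and a `windows` tibble of all candidate regressions. [tidy()] returns
#'   the window table; [glance()] the selected fit as one row.
#' @export
estimate_log_decrement <- function(peaks, p_max = 0.05, max_start = 6) {
  stopifnot(is.data.frame(peaks),
            all(c("ordinal", "amplitude") %in% names(peaks)))
  pk <- dplyr::filter(peaks, .data$ordinal <= 9, .data$amplitude > 0)
  if (nrow(pk) < 4) {
    stop("insufficient-peaks: need >= 4 usable peaks among ordinals 1-9",
         call. = FALSE)
  }
  starts <- seq_len(min(max_start, max(pk$ordinal) - 3))
  windows <- purrr::map_dfr(starts, function(s) {
    w <- dplyr::filter(pk, .data$ordinal >= s, .data$ordinal <= s + 3)
    if (nrow(w) < 4) return(NULL)
    fit <- lm(log(amplitude) ~ ordinal, data = w)
    # exact exponential decays trigger a harmless perfect-fit warning
    sm <- suppressWarnings(summary(fit))
    tibble::tibble(window_start = s,
                   slope = coef(fit)[["ordinal"]],
                   r2 = sm$r.squared,
                   p_value = sm$coefficients["ordinal", "Pr(>|t|)"])
  })
  ok <- !is.na(windows$p_value) & windows$p_value < p_max
  if (!any(ok)) {
    res <- list(delta = NA_real_, window_start = NA_integer_,
                slope = NA_real_, r2 = NA_real_, p_value = NA_real_,
                n_points = 4L, flagged_manual = TRUE, windows = windows,
                peaks = pk)
  } else {
    cand <- windows[ok, ]
    best <- cand[which.max(cand$r2), ]  # which.max: earliest window on ties
    res <- list(delta = abs(best$slope), window_start = best$window_start,
                slope = best$slope, r2 = best$r2, p_value = best$p_value,
                n_points = 4L, flagged_manual = FALSE, windows = windows,
                peaks = pk)
  }
  res$source_id <- attr(peaks, "source_id")
  class(res) <- "decrement_fit"
  res
}

#' @export
print.decrement_fit <- function(x, ...) {
  if (x$flagged_manual) {
    cat("# decrement_fit: no qualifying 4-peak window (flagged for manual",
        "re-measurement)\n")
  } else {
    cat(sprintf(
      "# decrement_fit: delta = %.4g (window %d-%d, r2 = %.3f, p = %.3g)\n",
      x$delta, x$window_start, x$window_start + 3, x$r2, x$p_value))
  }
  invisible(x)
}

#' @rdname estimate_log_decrement
#' @param x A `decrement_fit`.
#' @param ... Unused.
#' @method tidy decrement_fit
#' @export
tidy.decrement_fit <- function(x, ...) {
  dplyr::mutate(x$windows,
                selected = !x$flagged_manual &
                  .data$window_start == x$window_start)
}

#' @rdname estimate_log_decrement
#' @method glance decrement_fit
#' @export
glance.decrement_fit <- function(x, ...) {
  tibble::tibble(delta = x$delta, window_start = x$window_start,
                 slope = x$slope, r2 = x$r2, p_value = x$p_value,
                 n_points = x$n_points, flagged_manual = x$flagged_manual)
}

#' Plot the log-amplitude decay and the selected regression window
#'
#' @param object A `decrement_fit`.
#' @param ... Unused.
#' @return A ggplot of `ln(amplitude)` against peak ordinal; the selected
#'   four-peak window and its regression line are highlighted.
#' @method autoplot decrement_fit
#' @export
autoplot.decrement_fit <- function(object, ...) {
  pk <- dplyr::mutate(object$peaks, ln_amplitude = log(.data$amplitude))
  p <- ggplot2::ggplot(pk, ggplot2::aes(x = .data$ordinal,
                                        y = .data$ln_amplitude)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Peak number", y = "ln(amplitude, px)",
                  title = object$source_id) +
    ggplot2::theme_minimal()
  if (!object$flagged_manual) {
    sel <- dplyr::filter(pk, .data$ordinal >= object$window_start,
                         .data$ordinal <= object$window_start + 3)
    fit <- lm(ln_amplitude ~ ordinal, data = sel)
    sel$pred <- stats::predict(fit)
    p <- p +
      ggplot2::geom_point(data = sel, colour = "red", size = 2) +
      ggplot2::geom_line(data = sel, ggplot2::aes(y = .data$pred),
                         colour = "red")
  }
  p
}
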