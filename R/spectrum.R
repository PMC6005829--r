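#' Apply a Hanning taper to a displacement trace
#'
#' Multiplies the mean-centred displacement by a symmetric zero-endpoint
#' Hanning window, suppressing the spectral leakage a truncated decaying
#' oscillation would otherwise spread across bins. The mean is subtracted
#' first so the window does not smear a DC offset into the low-frequency
#' search band.
#'
#' With `span = "active"` the taper covers only the active vibration span —
#' from the release to where the displacement envelope falls to the
#' tracking-noise floor — and the samples beyond it are zeroed. The output
#' keeps the full trace length (so the FFT frequency grid is unchanged), but
#' a rapidly decaying oscillation is no longer annihilated by the near-zero
#' leading edge of a record-length taper, which matters once the record is
#' much longer than the decay time and the trace carries visible tracking
#' jitter. When the envelope never reaches the noise floor (slow decay, or a
#' noiseless trace) the active span is the whole record and the two settings
#' coincide.
#'
#' @param trace A [vib_trace()] with at least 8 samples.
#' @param span `"full"` (default): taper across the whole record;
#'   `"active"`: taper across the active vibration span only.
#' @param noise_mult For `span = "active"`: the envelope is considered dead
#'   once below `noise_mult` times the noise floor estimated from the trace
#'   tail. Default 5.
#' @return A windowed [vib_trace()] of the same length.
#' @export
apply_hanning <- function(trace, span = c("full", "active"), noise_mult = 5) {
  stopifnot(inherits(trace, "vib_trace"))
  span <- match.arg(span)
  n <- nrow(trace)
  if (n < 8) stop("trace too short to window (need >= 8 samples)", call. = FALSE)
  d <- trace$d - mean(trace$d)
  len <- if (span == "active") active_length(d, trace_fps(trace), noise_mult) else n
  w <- numeric(n)
  w[seq_len(len)] <- as.numeric(signal::hanning(len))
  retrace(trace, d * w)
}

# Length of the active vibration span of a mean-centred displacement vector.
# The noise floor is the RMS of the trailing 10% of the record; if the head
# RMS does not dominate it (sustained oscillation) or the floor is ~0
# (noiseless), the whole record is active. Otherwise the span runs to the
# last point where a sliding per-quarter-second envelope exceeds
# noise_mult * floor, plus the envelope window as margin.
active_length <- function(d, fps, noise_mult = 5) {
  n <- length(d)
  n10 <- max(8L, floor(n * 0.1))
  rms <- function(x) sqrt(mean(x^2))
  floor_rms <- rms(d[(n - n10 + 1):n])
  head_rms <- rms(d[seq_len(n10)])
  if (floor_rms <= 1e-9 * max(abs(d)) || head_rms < 10 * floor_rms) return(n)
  w <- min(n, max(8L, ceiling(fps * 0.25)))
  env <- zoo::rollmax(abs(d), k = w, align = "left", fill = NA)
  alive <- which(!is.na(env) & env > noise_mult * floor_rms)
  if (!length(alive)) return(n)
  min(n, max(alive) + w)
}

#' One-sided FFT power spectrum of a displacement trace
#'
#' Computes `|FFT|^2` of the (typically Hanning-windowed) displacement over
#' the non-negative frequencies. With `n_fft` equal to the trace length the
#' bin width is `fps / n` — 1/3 Hz for a 3-s capture at 240 fps, the
#' resolution at which damped frequencies are reported.
#'
#' @param trace A [vib_trace()].
#' @param n_fft FFT length; defaults to the trace length. Values larger than
#'   the trace zero-pad (finer display grid, same underlying resolution).
#' @return A tibble of class `vib_spectrum` with columns `freq` (Hz) and
#'   `power`, and attributes `bin_width` (Hz) and `n_samples`.
#' @export
power_spectrum <- function(trace, n_fft = NULL) {
  stopifnot(inherits(trace, "vib_trace"))
  n <- nrow(trace)
  if (n < 8) stop("trace too short for a spectrum (need >= 8 samples)",
                  call. = FALSE)
  if (is.null(n_fft)) n_fft <- n
  if (n_fft < n) stop("`n_fft` must be >= trace length", call. = FALSE)
  fps <- trace_fps(trace)
  d <- c(trace$d, rep(0, n_fft - n))
  p <- Mod(fft(d))^2
  n_keep <- floor(n_fft / 2) + 1
  out <- tibble::tibble(freq = (seq_len(n_keep) - 1) * fps / n_fft,
                        power = p[seq_len(n_keep)])
  attr(out, "bin_width") <- fps / n_fft
  attr(out, "n_samples") <- n
  attr(out, "fps") <- fps
  attr(out, "source_id") <- trace_id(trace)
  class(out) <- c("vib_spectrum", class(out))
  out
}

#' @rdname power_spectrum
#' @param x A `vib_spectrum`.
#' @export
bin_width <- function(x) attr(x, "bin_width")

#' Damped natural frequency as the in-band spectral peak
#'
#' The damped natural frequency is read off as the frequency of maximum
#' power inside a search band, at the spectrum's native resolution (no peak
#' interpolation). Ties go to the lower bin. A peak that does not stand
#' clearly above the in-band noise floor (median in-band power times
#' `noise_factor`) is rejected: a flat spectrum carries no vibration.
#'
#' @param spectrum A `vib_spectrum` from [power_spectrum()].
#' @param band Two-element search band in Hz. Default `c(1, 60)`; the upper
#'   edge must stay below the Nyquist frequency `fps/2`.
#' @param noise_factor Peak power must exceed `noise_factor * median` in-band
#'   power. Default 10. Set to 0 to disable.
#' @return A one-row tibble with `omega_d` (Hz), `peak_power` and
#'   `resolution` (= bin width, Hz).
#' @export
estimate_damped_frequency <- function(spectrum, band = c(1, 60),
                                      noise_factor = 10) {
  stopifnot(inherits(spectrum, "vib_spectrum"), length(band) == 2)
  if (band[1] >= band[2]) stop("`band` must be increasing", call. = FALSE)
  fps <- attr(spectrum, "fps")
  if (!is.null(fps) && band[2] > fps / 2) {
    stop("band upper edge ", band[2], " Hz exceeds the Nyquist frequency ",
         fps / 2, " Hz", call. = FALSE)
  }
  in_band <- spectrum$freq >= band[1] & spectrum$freq <= band[2]
  if (!any(in_band)) stop("no spectral bins inside the search band", call. = FALSE)
  fr <- spectrum$freq[in_band]
  pw <- spectrum$power[in_band]
  i <- which.max(pw)  # which.max returns the first (lowest-frequency) maximum
  if (noise_factor > 0 && pw[i] <= noise_factor * median(pw)) {
    stop("no-peak: maximum in-band power does not exceed ", noise_factor,
         "x the in-band median (flat spectrum?)", call. = FALSE)
  }
  tibble::tibble(omega_d = fr[i], peak_power = pw[i],
                 resolution = bin_width(spectrum))
}

#' Plot a power spectrum
#'
#' @param object A `vib_spectrum`.
#' @param band Optional band to shade.
#' @param ... Unused.
#' @return A ggplot of power against frequency.
#' @method autoplot vib_spectrum
#' @export
autoplot.vib_spectrum <- function(object, band = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "Frequency (Hz)", y = "Power",
                  title = attr(object, "source_id")) +
    ggplot2::theme_minimal()
  if (!is.null(band)) {
    p <- p + ggplot2::annotate("rect", xmin = band[1], xmax = band[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.08,
                               fill = "steelblue")
  }
  p
}
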