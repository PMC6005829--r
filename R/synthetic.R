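#' Generate a synthetic damped-oscillation displacement trace
#'
#' Emulates the free vibration of a released cantilever stem as seen by the
#' marker tracker: an exponentially damped cosine plus Gaussian tracking
#' jitter,
#' \deqn{d(t) = A_0 e^{-2\pi f_n \zeta t} \cos(2\pi f_d t + \phi) + \epsilon_t,}
#' with \eqn{f_n = f_d/\sqrt{1-\zeta^2}} and
#' \eqn{\epsilon_t \sim N(0, \sigma^2)}. The true logarithmic decrement of the
#' noiseless waveform is \eqn{2\pi\zeta/\sqrt{1-\zeta^2}}.
#'
#' @param f_d Damped natural frequency, Hz.
#' @param zeta Damping ratio in `[0, 1)`.
#' @param amplitude0 Initial amplitude, pixels. Default 30 px, a typical
#'   marker excursion for a 20-30 degree release.
#' @param phase Phase at t = 0, radians. Default 0 (release from maximum
#'   deflection).
#' @param noise_sigma Tracking-jitter standard deviation, pixels. Default 0.5.
#' @param fps Frames per second; must exceed `2 * f_d`. Default 240, the
#'   slow-motion rate of the capture protocol.
#' @param duration Seconds. Default 3.
#' @param seed Integer seed; the trace is a pure function of the arguments.
#' @param source_id Sample label.
#' @return A [vib_trace()].
#' @examples
#' tr <- generate_trace(f_d = 20.5, zeta = 0.047, seed = 1)
#' @export
generate_trace <- function(f_d, zeta, amplitude0 = 30, phase = 0,
                           noise_sigma = 0.5, fps = 240, duration = 3,
                           seed = 1, source_id = "synthetic") {
  stopifnot(f_d > 0, zeta >= 0, zeta < 1, duration > 0, amplitude0 > 0)
  if (fps <= 2 * f_d) {
    stop("aliasing guard: `fps` must exceed 2 * f_d (", 2 * f_d, " Hz)",
         call. = FALSE)
  }
  n <- round(fps * duration)
  t <- seq(0, by = 1 / fps, length.out = n)
  f_n <- f_d / sqrt(1 - zeta^2)
  d <- amplitude0 * exp(-2 * pi * f_n * zeta * t) * cos(2 * pi * f_d * t + phase)
  if (noise_sigma > 0) {
    d <- d + withr::with_seed(as.integer(seed), rnorm(n, 0, noise_sigma))
  }
  vib_trace(t, d, fps = fps, source_id = source_id)
}

#' Render a displacement trace as a red-marker video
#'
#' Writes one PNG per frame showing a red disc on a black background at
#' `x = base_x + d(t)`, `y = base_y`, emulating the marker videos the tracker
#' consumes, plus a `meta.json` with the frame rate. Disc edges are
#' anti-aliased (partial pixel coverage scales brightness) so the
#' intensity-weighted centroid recovers sub-pixel positions.
#'
#' @param trace A [vib_trace()].
#' @param dir Output directory (created if needed); one video per directory.
#' @param radius Disc radius, pixels. Default 6.
#' @param base_x,base_y Disc centre at zero displacement, pixels.
#' @param width,height Frame size, pixels.
#' @return Invisibly, a one-row tibble with `dir`, `n_frames`, `fps`,
#'   `width`, `height`.
#' @export
render_frames <- function(trace, dir, radius = 6, base_x = NULL,
                          base_y = NULL, width = 192, height = 64) {
  stopifnot(inherits(trace, "vib_trace"))
  if (is.null(base_x)) base_x <- width / 2
  if (is.null(base_y)) base_y <- height / 2
  xs <- base_x + trace$d
  if (any(xs - radius < 1) || any(xs + radius > width) ||
      base_y - radius < 1 || base_y + radius > height) {
    stop("layout error: marker trajectory leaves the frame", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(trace)
  # pixel-centre grids, reused across frames
  px <- matrix(seq_len(width), nrow = height, ncol = width, byrow = TRUE)
  py <- matrix(seq_len(height), nrow = height, ncol = width)
  img <- array(0, dim = c(height, width, 3))
  for (i in seq_len(n)) {
    dist <- sqrt((px - xs[i])^2 + (py - base_y)^2)
    cov <- pmin(pmax(radius + 0.5 - dist, 0), 1)  # soft 1-px edge
    img[, , 1] <- cov
    png::writePNG(img, file.path(dir, sprintf("frame_%05d.png", i)))
  }
  jsonlite::write_json(
    list(fps = trace_fps(trace), n_frames = n, width = width, height = height,
         source_id = trace_id(trace)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(tibble::tibble(dir = dir, n_frames = n, fps = trace_fps(trace),
                           width = width, height = height))
}

#' Generate a synthetic stem population with known ground truth
#'
#' Emulates the statistical structure of a wild-type growth-trait table:
#' height `H` (cm) is Gaussian, fresh weight `FW` (mg) is linear in `H` with
#' noise, and the measured damped frequency follows
#' `omega_d = beta0 + beta_H * H + beta_FW * FW + N(0, sigma)`. Mutants share
#' the growth-trait distribution but have `omega_d` multiplied by
#' `mutant_shift` (e.g. 0.35 for a soft secondary-cell-wall-less stem, 1.17
#' for a stiffened one). The defaults put H in roughly 15-40 cm, FW in
#' 20-120 mg and omega_d in 15-35 Hz, with fresh weight the dominant
#' standardized predictor.
#'
#' @param n_wt Number of wild-type records.
#' @param n_mutant Number of mutant records.
#' @param mutant_shift Multiplicative shift of mutant `omega_d`. Default 1.
#' @param beta0,beta_H,beta_FW Regression structure of `omega_d` (Hz, Hz/cm,
#'   Hz/mg).
#' @param sigma Residual standard deviation of `omega_d`, Hz.
#' @param H_mean,H_sd Height distribution, cm.
#' @param seed Integer seed.
#' @return A tibble with `sample_id`, `genotype` (`"wt"`/`"mutant"`), `H_cm`,
#'   `FW_mg`, `omega_d` and `omega_d_expected` (the noiseless regression
#'   value before any mutant shift, kept for scoring).
#' @export
generate_population <- function(n_wt = 63, n_mutant = 0, mutant_shift = 1,
                                beta0 = 8, beta_H = 0.2, beta_FW = 0.15,
                                sigma = 1.5, H_mean = 28, H_sd = 5,
                                seed = 1) {
  stopifnot(n_wt >= 1, n_mutant >= 0, mutant_shift > 0, sigma > 0)
  n <- n_wt + n_mutant
  withr::with_seed(as.integer(seed), {
    H <- pmax(rnorm(n, H_mean, H_sd), 10)
    FW <- pmax(3 * H - 20 + rnorm(n, 0, 8), 5)
    mu <- beta0 + beta_H * H + beta_FW * FW
    omega <- mu + rnorm(n, 0, sigma)
  })
  genotype <- rep(c("wt", "mutant"), c(n_wt, n_mutant))
  shift <- ifelse(genotype == "mutant", mutant_shift, 1)
  tibble::tibble(
    sample_id = sprintf("s%04d", seq_len(n)),
    genotype = genotype,
    H_cm = H, FW_mg = FW,
    omega_d = omega * shift,
    omega_d_expected = mu)
}
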