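#' Damping ratio from the logarithmic decrement
#'
#' Converts a logarithmic decrement \eqn{\delta} (per-period natural-log decay
#' of peak amplitude) into the dimensionless damping ratio
#' \deqn{\zeta = \delta / \sqrt{(2\pi)^2 + \delta^2},}
#' the exact relation for an underdamped linear oscillator. The inverse is
#' \eqn{\delta = 2\pi\zeta/\sqrt{1-\zeta^2}}.
#'
#' @param delta Numeric vector of logarithmic decrements, `delta >= 0`.
#' @return Numeric vector of damping ratios in `[0, 1)`.
#' @examples
#' damping_ratio(0.374) # ~0.0594, a typical wild-type Arabidopsis stem
#' @export
damping_ratio <- function(delta) {
  stopifnot(is.numeric(delta))
  if (any(delta < 0, na.rm = TRUE)) {
    stop("`delta` must be non-negative (it is |slope| of a log-amplitude decay)",
         call. = FALSE)
  }
  delta / sqrt((2 * pi)^2 + delta^2)
}

#' Undamped natural frequency from the damped frequency
#'
#' \deqn{\omega_n = \omega_d / \sqrt{1 - \zeta^2}} in the same units as
#' `omega_d` (Hz throughout this package). For the weakly damped stems this
#' method targets (\eqn{\zeta \le 0.09}) the correction is below typical FFT
#' bin width.
#'
#' @param omega_d Damped natural frequency, Hz, `> 0`.
#' @param zeta Damping ratio in `[0, 1)`.
#' @return Natural frequency, Hz.
#' @export
natural_frequency <- function(omega_d, zeta) {
  stopifnot(is.numeric(omega_d), is.numeric(zeta))
  if (any(omega_d <= 0, na.rm = TRUE)) {
    stop("`omega_d` must be positive", call. = FALSE)
  }
  if (any(zeta < 0 | zeta >= 1, na.rm = TRUE)) {
    stop("`zeta` must lie in [0, 1): the model assumes an underdamped oscillator",
         call. = FALSE)
  }
  omega_d / sqrt(1 - zeta^2)
}

#' Equivalent point mass of the vibrating stem
#'
#' A uniform cantilever of beam mass `m_b` oscillating in its first mode
#' behaves as a point mass \eqn{m_{eq} = \alpha m_b + M} at the tip, with
#' \eqn{\alpha = 0.245} for a uniform weight distribution and `M` any attached
#' tip mass. For a 10-cm basal stem segment of which 1 cm is clamped, the
#' vibrating beam mass is `vibrating_fraction = 0.9` of the measured fresh
#' weight, giving the default \eqn{m_{eq} = 0.245 \times 0.9 \times FW}.
#'
#' @param fw_mg Fresh weight of the 10-cm stem segment, milligrams, `> 0`.
#' @param alpha Modal mass coefficient, in `(0, 1]`. Default 0.245 (uniform beam).
#' @param vibrating_fraction Fraction of the weighed segment free to vibrate,
#'   in `(0, 1]`. Default 0.9 (1 cm of 10 clamped).
#' @param tip_mass_mg Attached tip-point mass `M`, milligrams. Default 0: the
#'   marker paint is about 1% of stem mass and is ignored.
#' @return Equivalent mass in kilograms.
#' @examples
#' equivalent_mass(100) # 0.245 * 0.9 * 100 mg = 2.205e-5 kg
#' @export
equivalent_mass <- function(fw_mg, alpha = 0.245, vibrating_fraction = 0.9,
                            tip_mass_mg = 0) {
  stopifnot(is.numeric(fw_mg))
  if (any(fw_mg <= 0, na.rm = TRUE)) stop("`fw_mg` must be positive", call. = FALSE)
  if (any(alpha <= 0 | alpha > 1)) stop("`alpha` must lie in (0, 1]", call. = FALSE)
  if (any(vibrating_fraction <= 0 | vibrating_fraction > 1)) {
    stop("`vibrating_fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (any(tip_mass_mg < 0)) stop("`tip_mass_mg` must be non-negative", call. = FALSE)
  (alpha * vibrating_fraction * fw_mg + tip_mass_mg) * 1e-6
}

#' Viscous damping coefficient
#'
#' \deqn{c = 4\pi \omega_n m_{eq} \zeta} in N/(m/s), with `omega_n` in Hz and
#' `m_eq` in kg (the \eqn{4\pi} absorbs the Hz-to-rad/s conversion in
#' \eqn{c = 2 m \omega \zeta}).
#'
#' @param omega_n Natural frequency, Hz.
#' @param m_eq Equivalent mass, kg.
#' @param zeta Damping ratio.
#' @return Damping coefficient, N/(m/s).
#' @export
damping_coefficient <- function(omega_n, m_eq, zeta) {
  stopifnot(is.numeric(omega_n), is.numeric(m_eq), is.numeric(zeta))
  if (any(omega_n <= 0 | m_eq <= 0, na.rm = TRUE)) {
    stop("`omega_n` and `m_eq` must be positive", call. = FALSE)
  }
  if (any(zeta < 0, na.rm = TRUE)) stop("`zeta` must be non-negative", call. = FALSE)
  4 * pi * omega_n * m_eq * zeta
}

#' Stiffness of the equivalent spring
#'
#' From \eqn{\omega_n = \frac{1}{2\pi}\sqrt{k/m_{eq}}}:
#' \deqn{k = (2\pi\omega_n)^2 m_{eq}} in N/m, with `omega_n` in Hz and `m_eq`
#' in kg.
#'
#' @inheritParams damping_coefficient
#' @return Stiffness, N/m.
#' @export
stiffness <- function(omega_n, m_eq) {
  stopifnot(is.numeric(omega_n), is.numeric(m_eq))
  if (any(omega_n <= 0 | m_eq <= 0, na.rm = TRUE)) {
    stop("`omega_n` and `m_eq` must be positive", call. = FALSE)
  }
  (2 * pi * omega_n)^2 * m_eq
}

#' Full spring-mass-damper characterization of stem samples
#'
#' Chains the oscillator relations for each row of a per-sample table:
#' damping ratio from the logarithmic decrement, natural frequency from the
#' damped frequency, equivalent mass from fresh weight, then damping
#' coefficient and stiffness. Rows whose decrement is missing (`NA`, e.g. a
#' sample flagged for manual re-measurement) get `NA` mechanics and status
#' `"withheld"`.
#'
#' @param data Data frame with columns `omega_d` (Hz), `delta`
#'   (dimensionless) and `fw_mg` (mg); extra columns are kept.
#' @param alpha,vibrating_fraction,tip_mass_mg Passed to [equivalent_mass()].
#' @return A tibble: the input plus `zeta`, `omega_n`, `m_eq_kg`,
#'   `c_N_per_m_s`, `k_N_per_m` and `status` (`"ok"` or `"withheld"`).
#' @examples
#' characterize(tibble::tibble(omega_d = 20.5, delta = 0.300, fw_mg = 58))
#' @export
characterize <- function(data, alpha = 0.245, vibrating_fraction = 0.9,
                         tip_mass_mg = 0) {
  stopifnot(is.data.frame(data))
  need <- c("omega_d", "delta", "fw_mg")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("`data` lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  ok <- !is.na(out$omega_d) & !is.na(out$delta) & !is.na(out$fw_mg)
  zeta <- omega_n <- m_eq <- cc <- kk <- rep(NA_real_, nrow(out))
  if (any(ok)) {
    zeta[ok] <- damping_ratio(out$delta[ok])
    omega_n[ok] <- natural_frequency(out$omega_d[ok], zeta[ok])
    m_eq[ok] <- equivalent_mass(out$fw_mg[ok], alpha, vibrating_fraction,
                                tip_mass_mg)
    cc[ok] <- damping_coefficient(omega_n[ok], m_eq[ok], zeta[ok])
    kk[ok] <- stiffness(omega_n[ok], m_eq[ok])
  }
  dplyr::mutate(out,
    zeta = zeta, omega_n = omega_n, m_eq_kg = m_eq,
    c_N_per_m_s = cc, k_N_per_m = kk,
    status = ifelse(ok, "ok", "withheld"))
}
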