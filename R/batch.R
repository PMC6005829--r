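#' Analyze one displacement trace end to end
#'
#' The single-sample pipeline behind [run_batch()]: Hanning window + FFT for
#' the damped natural frequency, then peak detection on the raw waveform and
#' the four-peak regression rule for the logarithmic decrement. Failures at
#' any stage are captured in the `status` field rather than thrown, so batch
#' callers can keep going.
#'
#' @param trace A [vib_trace()].
#' @param band Frequency search band, Hz. Default `c(1, 60)`.
#' @param noise_factor Spectral noise-floor factor, see
#'   [estimate_damped_frequency()].
#' @param keep_objects Keep the spectrum, peak table and decrement fit in the
#'   result (for plotting). Default `FALSE`.
#' @return A one-row tibble: `sample_id`, `omega_d`, `resolution_hz`,
#'   `delta`, `delta_r2`, `delta_p`, `flagged_manual`, `status` (`"ok"`,
#'   `"flagged_manual"`, or the failure message). With
#'   `keep_objects = TRUE`, the objects are attached as the `"objects"`
#'   attribute.
#' @export
analyze_trace <- function(trace, band = c(1, 60), noise_factor = 10,
                          keep_objects = FALSE) {
  stopifnot(inherits(trace, "vib_trace"))
  out <- tibble::tibble(sample_id = trace_id(trace), omega_d = NA_real_,
                        resolution_hz = NA_real_, delta = NA_real_,
                        delta_r2 = NA_real_, delta_p = NA_real_,
                        flagged_manual = FALSE, status = "ok")
  objects <- list(trace = trace)
  est <- tryCatch({
    windowed <- apply_hanning(trace, span = "active")
    spec <- power_spectrum(windowed)
    objects$windowed <- windowed
    objects$spectrum <- spec
    estimate_damped_frequency(spec, band = band, noise_factor = noise_factor)
  }, error = function(e) e)
  if (inherits(est, "error")) {
    out$status <- conditionMessage(est)
  } else {
    out$omega_d <- est$omega_d
    out$resolution_hz <- est$resolution
    dec <- tryCatch({
      peaks <- detect_peaks(trace, est$omega_d)
      objects$peaks <- peaks
      estimate_log_decrement(peaks)
    }, error = function(e) e)
    if (inherits(dec, "error")) {
      out$status <- conditionMessage(dec)
    } else {
      objects$decrement <- dec
      out$delta <- dec$delta
      out$delta_r2 <- dec$r2
      out$delta_p <- dec$p_value
      out$flagged_manual <- dec$flagged_manual
      if (dec$flagged_manual) out$status <- "flagged_manual"
    }
  }
  if (keep_objects) attr(out, "objects") <- objects
  out
}

write_sample_outputs <- function(objects, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_quiet <- function(plot, file) {
    suppressMessages(ggplot2::ggsave(file.path(dir, file), plot,
                                     width = 6, height = 3.2, dpi = 100))
  }
  if (!is.null(objects$trace)) {
    save_quiet(autoplot(objects$trace), "displacement_vibration.png")
  }
  if (!is.null(objects$windowed)) {
    save_quiet(autoplot(objects$windowed), "hanning_vibration.png")
  }
  if (!is.null(objects$spectrum)) {
    save_quiet(autoplot(objects$spectrum), "fft_power_spectrum.png")
  }
  if (!is.null(objects$peaks)) {
    pk <- dplyr::mutate(objects$peaks, ln_amplitude = log(.data$amplitude))
    write.csv(pk, file.path(dir, "peaks.csv"), row.names = FALSE)
  }
  if (!is.null(objects$decrement)) {
    save_quiet(autoplot(objects$decrement), "log_decrement_fit.png")
  }
  invisible(dir)
}

#' Batch vibration analysis of a folder of videos
#'
#' Mirrors the one-folder-per-shooting-date workflow: every subdirectory of
#' `input_dir` that contains `frame_*.png` files is treated as one sample
#' video. Each sample is tracked, converted to displacement, and analyzed
#' with [analyze_trace()]; per-sample diagnostic plots
#' (`displacement_vibration.png`, `hanning_vibration.png`,
#' `fft_power_spectrum.png`) land in a subfolder of `output_dir`, and the
#' batch-level frequency table in `omega_d_results.csv`. When a growth-trait
#' table is supplied, spring-mass-damper mechanics are computed and written
#' to `mechanics_results.csv`. Per-sample failures (lost marker, flat trace,
#' too few peaks) are recorded in the `status` column and do not stop the
#' batch.
#'
#' @param input_dir Folder containing one frame-sequence subdirectory per
#'   sample.
#' @param output_dir Where to write plots and CSVs. Default
#'   `file.path(input_dir, "results")`.
#' @param traits Optional data frame (or CSV path) with `sample_id`, `H_cm`,
#'   `FW_mg`; sample ids must match the video directory names.
#' @param fps Frame-rate override applied to every sample; by default each
#'   video's `meta.json` (or 240) is used.
#' @param config A [marker_color_config()].
#' @param max_gap Per-sample marker-loss tolerance, frames. Default 5.
#' @param band,noise_factor Passed to [analyze_trace()].
#' @param axis,crop Passed to [to_displacement()].
#' @param write_plots Write the per-sample PNGs. Default `TRUE`.
#' @return A tibble with one row per sample (the `omega_d_results.csv`
#'   content, plus mechanics columns when traits were given).
#' @export
run_batch <- function(input_dir, output_dir = file.path(input_dir, "results"),
                      traits = NULL, fps = NULL,
                      config = marker_color_config(), max_gap = 5,
                      band = c(1, 60), noise_factor = 10, axis = "x",
                      crop = "max", write_plots = TRUE) {
  if (!dir.exists(input_dir)) {
    stop("no-input: ", input_dir, " does not exist", call. = FALSE)
  }
  subdirs <- sort(list.dirs(input_dir, recursive = FALSE))
  subdirs <- subdirs[vapply(subdirs, function(d) {
    length(list.files(d, pattern = "^frame_.*\\.png$")) > 0
  }, logical(1))]
  if (!length(subdirs)) {
    stop("no-input: ", input_dir, " contains no frame-sequence video folders",
         call. = FALSE)
  }
  if (is.character(traits) && length(traits) == 1) {
    traits <- read.csv(traits, stringsAsFactors = FALSE)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map_dfr(subdirs, function(vd) {
    sid <- basename(vd)
    res <- tryCatch({
      cents <- track_frames(vd, fps = fps, config = config, max_gap = max_gap)
      trace <- to_displacement(cents, axis = axis, crop = crop)
      attr(trace, "source_id") <- sid
      analyze_trace(trace, band = band, noise_factor = noise_factor,
                    keep_objects = write_plots)
    }, error = function(e) {
      tibble::tibble(sample_id = sid, omega_d = NA_real_,
                     resolution_hz = NA_real_, delta = NA_real_,
                     delta_r2 = NA_real_, delta_p = NA_real_,
                     flagged_manual = FALSE,
                     status = conditionMessage(e))
    })
    if (write_plots && !is.null(attr(res, "objects"))) {
      write_sample_outputs(attr(res, "objects"), file.path(output_dir, sid))
    }
    message(sprintf("[stemvib] %s: %s", sid,
                    if (res$status == "ok") {
                      sprintf("omega_d = %.4g Hz, delta = %.4g",
                              res$omega_d, res$delta)
                    } else res$status))
    attr(res, "objects") <- NULL
    res
  })
  write.csv(
    dplyr::transmute(rows, sample_id = .data$sample_id,
                     omega_d_hz = .data$omega_d,
                     resolution_hz = .data$resolution_hz,
                     status = .data$status),
    file.path(output_dir, "omega_d_results.csv"), row.names = FALSE)
  if (!is.null(traits)) {
    stopifnot(all(c("sample_id", "H_cm", "FW_mg") %in% names(traits)))
    joined <- dplyr::left_join(rows, tibble::as_tibble(traits),
                               by = "sample_id")
    mech <- characterize(
      dplyr::mutate(joined, fw_mg = .data$FW_mg,
                    delta = ifelse(.data$flagged_manual, NA_real_,
                                   .data$delta)))
    mech$status <- ifelse(rows$status == "ok", mech$status, rows$status)
    write.csv(
      dplyr::transmute(mech, sample_id = .data$sample_id,
                       omega_d_hz = .data$omega_d, delta = .data$delta,
                       zeta = .data$zeta, omega_n_hz = .data$omega_n,
                       m_eq_kg = .data$m_eq_kg,
                       c_N_per_m_s = .data$c_N_per_m_s,
                       k_N_per_m = .data$k_N_per_m, status = .data$status),
      file.path(output_dir, "mechanics_results.csv"), row.names = FALSE)
    rows <- mech
  }
  n_ok <- sum(rows$status == "ok")
  message(sprintf("[stemvib] batch done: %d/%d samples ok", n_ok, nrow(rows)))
  if (n_ok == 0) warning("no sample succeeded in ", input_dir, call. = FALSE)
  rows
}

#' Train and persist a screening model from a control table
#'
#' @param data Data frame (or CSV path) with `sample_id`, `H_cm`, `FW_mg`,
#'   `omega_d` for wild-type/control samples of one growth condition.
#' @param model_path Where to write the JSON model file.
#' @param condition_label Growth-condition label stored in the model.
#' @param min_n Minimum training size. Default 10.
#' @return The fitted `screening_model`, invisibly; prints the fit summary.
#' @export
run_train <- function(data, model_path, condition_label = "unspecified",
                      min_n = 10) {
  if (is.character(data) && length(data) == 1) {
    data <- read.csv(data, stringsAsFactors = FALSE)
  }
  if ("sample_id" %in% names(data) && anyDuplicated(data$sample_id)) {
    stop("validation error: duplicated sample_id in training data",
         call. = FALSE)
  }
  model <- fit_screening_model(data, condition_label = condition_label,
                               min_n = min_n)
  write_screening_model(model, model_path)
  print(model)
  message("[stemvib] model written to ", model_path)
  invisible(model)
}

#' Screen samples against a trained model
#'
#' Joins a frequency table (either a `run_batch()` result / its
#' `omega_d_results.csv`, or any table with `sample_id` and `omega_d`) to a
#' growth-trait table, classifies every joined sample, and writes
#' `screening_results.csv`.
#'
#' @param model A `screening_model` or path to a model JSON file.
#' @param omega Data frame or CSV path with `sample_id` and `omega_d` (the
#'   column `omega_d_hz` from batch output is accepted too).
#' @param traits Data frame or CSV path with `sample_id`, `H_cm`, `FW_mg`.
#' @param out_csv Optional path for the classification CSV.
#' @param threshold Mutant-call p-value threshold. Default 0.01.
#' @param condition_label Condition of the screened samples (for the
#'   cross-condition warning).
#' @return Tibble of [classify_samples()] results for every joined sample.
#' @export
run_screen <- function(model, omega, traits, out_csv = NULL,
                       threshold = 0.01, condition_label = NULL) {
  if (is.character(model)) model <- read_screening_model(model)
  if (is.character(omega) && length(omega) == 1) {
    omega <- read.csv(omega, stringsAsFactors = FALSE)
  }
  if (is.character(traits) && length(traits) == 1) {
    traits <- read.csv(traits, stringsAsFactors = FALSE)
  }
  omega <- tibble::as_tibble(omega)
  if (!"omega_d" %in% names(omega) && "omega_d_hz" %in% names(omega)) {
    omega <- dplyr::rename(omega, omega_d = "omega_d_hz")
  }
  stopifnot(all(c("sample_id", "omega_d") %in% names(omega)),
            all(c("sample_id", "H_cm", "FW_mg") %in% names(traits)))
  omega <- dplyr::filter(omega, !is.na(.data$omega_d))
  missing_ids <- setdiff(omega$sample_id, traits$sample_id)
  if (length(missing_ids)) {
    stop("join error: no growth traits for sample(s) ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  # keep only the columns each table contributes, so shared extras
  # (e.g. both files derived from one batch table) cannot collide
  joined <- dplyr::inner_join(
    dplyr::select(omega, "sample_id", "omega_d"),
    dplyr::select(tibble::as_tibble(traits), "sample_id", "H_cm", "FW_mg"),
    by = "sample_id")
  res <- classify_samples(model, joined, threshold = threshold,
                          condition_label = condition_label)
  if (!is.null(out_csv)) write.csv(res, out_csv, row.names = FALSE)
  res
}
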