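#' Fit the wild-type screening model
#'
#' Trains the mutant-screening reference: an ordinary least-squares
#' regression of the measured damped natural frequency on stem height and
#' 10-cm fresh weight,
#' \deqn{\omega_d = \beta_0 + \beta_H H + \beta_{FW} FW + \epsilon,}
#' followed by a normal fit to the residuals (mean and unbiased standard
#' deviation). Samples are later classified by how far their measured
#' frequency falls from the regression prediction relative to that residual
#' distribution. The model is condition-specific: growth conditions shift
#' both the trait and frequency distributions, so retrain per condition.
#'
#' @param data Data frame of wild-type/control records with columns
#'   `sample_id`, `H_cm`, `FW_mg`, `omega_d`.
#' @param condition_label Free-text label of the growth condition the
#'   training records came from.
#' @param min_n Minimum number of training records. Default 10.
#' @return An object of class `screening_model`: coefficients (`beta0`,
#'   `beta_H`, `beta_FW`), residual-normal parameters (`resid_mu`,
#'   `resid_sigma`), `n_train`, `condition_label`, plus the kept `lm` fit.
#'   [tidy()] returns the coefficient table; [glance()] a one-row summary.
#' @export
fit_screening_model <- function(data, condition_label = "unspecified",
                                min_n = 10) {
  stopifnot(is.data.frame(data))
  need <- c("H_cm", "FW_mg", "omega_d")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("`data` lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::as_tibble(data)
  if (any(df$H_cm <= 0 | df$FW_mg <= 0 | df$omega_d <= 0, na.rm = TRUE) ||
      anyNA(df[need])) {
    stop("training records must have positive, non-missing H_cm, FW_mg and omega_d",
         call. = FALSE)
  }
  if (nrow(df) < min_n) {
    stop("training-size error: need >= ", min_n, " records, got ", nrow(df),
         call. = FALSE)
  }
  if (sd(df$H_cm) == 0 || sd(df$FW_mg) == 0) {
    stop("degenerate-design: H_cm or FW_mg is constant across training records",
         call. = FALSE)
  }
  fit <- lm(omega_d ~ H_cm + FW_mg, data = df)
  res <- stats::residuals(fit)
  model <- list(
    beta0 = unname(coef(fit)["(Intercept)"]),
    beta_H = unname(coef(fit)["H_cm"]),
    beta_FW = unname(coef(fit)["FW_mg"]),
    resid_mu = mean(res),
    resid_sigma = sd(res),          # unbiased (n - 1) estimator
    n_train = nrow(df),
    condition_label = condition_label,
    fit = fit)
  if (model$resid_sigma <= 0 || !is.finite(model$resid_sigma)) {
    # zero-noise training data: classification would divide by zero
    model$resid_sigma <- max(model$resid_sigma, .Machine$double.eps)
  }
  class(model) <- "screening_model"
  model
}

#' Predict the expected damped frequency for new samples
#'
#' @param object A `screening_model`.
#' @param newdata Data frame with `H_cm` and `FW_mg` columns.
#' @param ... Unused.
#' @return Numeric vector of predicted frequencies, Hz.
#' @export
predict.screening_model <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata),
            all(c("H_cm", "FW_mg") %in% names(newdata)))
  object$beta0 + object$beta_H * newdata$H_cm + object$beta_FW * newdata$FW_mg
}

#' Classify samples as mutant-like by frequency deviation
#'
#' For each record, the difference `measured - predicted` frequency is
#' referred to the training residual normal: the two-tailed p-value is
#' \deqn{p = 2\,\Phi(-|d - \mu_r| / \sigma_r),}
#' and a sample is called mutant-like when `p < threshold`. Both tails are
#' tested because cell-wall lesions can soften (lower frequency) or stiffen
#' (higher frequency) the stem.
#'
#' @param model A `screening_model` from [fit_screening_model()].
#' @param data Data frame with `sample_id`, `H_cm`, `FW_mg`, `omega_d`.
#' @param threshold p-value threshold for the mutant call. Default 0.01.
#' @param condition_label Condition of `data`; when it differs from the
#'   model's, a warning is raised (distributions shift across growth
#'   conditions and the model should be retrained).
#' @return A tibble: `sample_id`, `omega_d_measured`, `omega_d_predicted`,
#'   `difference_hz`, `p_value`, `is_mutant`.
#' @export
classify_samples <- function(model, data, threshold = 0.01,
                             condition_label = NULL) {
  if (!inherits(model, "screening_model")) {
    stop("model-state error: `model` is not a fitted screening_model",
         call. = FALSE)
  }
  stopifnot(is.data.frame(data), threshold > 0, threshold <= 1)
  need <- c("sample_id", "H_cm", "FW_mg", "omega_d")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("`data` lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(condition_label) &&
      !identical(condition_label, model$condition_label)) {
    warning("model trained on condition '", model$condition_label,
            "' applied to condition '", condition_label,
            "'; distributions shift across growth conditions - retrain for ",
            "reliable calls", call. = FALSE)
  }
  pred <- predict(model, data)
  diff <- data$omega_d - pred
  z <- abs(diff - model$resid_mu) / model$resid_sigma
  p <- 2 * pnorm(-z)
  tibble::tibble(
    sample_id = data$sample_id,
    omega_d_measured = data$omega_d,
    omega_d_predicted = pred,
    difference_hz = diff,
    p_value = p,
    is_mutant = p < threshold)
}

#' @rdname fit_screening_model
#' @param x A `screening_model`.
#' @param ... Unused.
#' @method tidy screening_model
#' @export
tidy.screening_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    sm <- summary(x$fit)$coefficients
    tibble::tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                   std.error = sm[, "Std. Error"],
                   statistic = sm[, "t value"],
                   p.value = sm[, "Pr(>|t|)"])
  } else {
    tibble::tibble(term = c("(Intercept)", "H_cm", "FW_mg"),
                   estimate = c(x$beta0, x$beta_H, x$beta_FW),
                   std.error = NA_real_, statistic = NA_real_,
                   p.value = NA_real_)
  }
}

#' @rdname fit_screening_model
#' @method glance screening_model
#' @export
glance.screening_model <- function(x, ...) {
  tibble::tibble(beta0 = x$beta0, beta_H = x$beta_H, beta_FW = x$beta_FW,
                 resid_mu = x$resid_mu, resid_sigma = x$resid_sigma,
                 n_train = x$n_train, condition_label = x$condition_label)
}

#' @export
print.screening_model <- function(x, ...) {
  cat(sprintf(
    "# screening_model (condition '%s', n = %d)\n",
    x$condition_label, x$n_train))
  cat(sprintf("  omega_d = %.4g + %.4g * H_cm + %.4g * FW_mg\n",
              x$beta0, x$beta_H, x$beta_FW))
  cat(sprintf("  residuals ~ N(mu = %.4g, sigma = %.4g) Hz\n",
              x$resid_mu, x$resid_sigma))
  invisible(x)
}

#' Persist and reload a screening model as JSON
#'
#' The model file is a small versioned JSON holding the regression
#' coefficients, residual-normal parameters, training size, condition label
#' and training date — everything classification needs; the underlying `lm`
#' object is not serialized.
#'
#' @param model A `screening_model`.
#' @param path File path (`.json`).
#' @return `write_screening_model()` returns `path` invisibly;
#'   `read_screening_model()` returns a `screening_model`.
#' @export
write_screening_model <- function(model, path) {
  stopifnot(inherits(model, "screening_model"))
  obj <- list(schema = "stemvib_screening_model", schema_version = 1L,
              beta0 = model$beta0, beta_H = model$beta_H,
              beta_FW = model$beta_FW, resid_mu = model$resid_mu,
              resid_sigma = model$resid_sigma, n_train = model$n_train,
              condition_label = model$condition_label,
              trained = format(Sys.Date()))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_screening_model
#' @param expected_condition Optional condition label the caller expects.
#' @export
read_screening_model <- function(path, expected_condition = NULL) {
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) {
                    stop("model-file error: cannot parse ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  need <- c("schema", "beta0", "beta_H", "beta_FW", "resid_mu",
            "resid_sigma", "n_train", "condition_label")
  if (!identical(obj$schema, "stemvib_screening_model") ||
      !all(need %in% names(obj))) {
    stop("model-file error: ", path,
         " is not a stemvib screening-model file or lacks required fields",
         call. = FALSE)
  }
  model <- list(beta0 = as.numeric(obj$beta0),
                beta_H = as.numeric(obj$beta_H),
                beta_FW = as.numeric(obj$beta_FW),
                resid_mu = as.numeric(obj$resid_mu),
                resid_sigma = as.numeric(obj$resid_sigma),
                n_train = as.integer(obj$n_train),
                condition_label = as.character(obj$condition_label),
                fit = NULL)
  class(model) <- "screening_model"
  if (!is.null(expected_condition) &&
      !identical(expected_condition, model$condition_label)) {
    warning("model file condition '", model$condition_label,
            "' differs from expected '", expected_condition, "'",
            call. = FALSE)
  }
  model
}

#' Plot a screening model over a sample table
#'
#' @param object A `screening_model`.
#' @param data Optional tibble with `H_cm`, `FW_mg`, `omega_d` (and
#'   optionally `is_mutant`) to overlay.
#' @param threshold p-value threshold drawn as the residual band. Default 0.01.
#' @param ... Unused.
#' @return A ggplot of measured frequency against fresh weight, with the
#'   regression line at the median height and the two-sided threshold band.
#' @method autoplot screening_model
#' @export
autoplot.screening_model <- function(object, data = NULL, threshold = 0.01,
                                     ...) {
  h_ref <- if (!is.null(data)) median(data$H_cm) else 25
  half_width <- qnorm(1 - threshold / 2) * object$resid_sigma
  fw <- seq(if (!is.null(data)) min(data$FW_mg) else 20,
            if (!is.null(data)) max(data$FW_mg) else 120, length.out = 50)
  line <- tibble::tibble(
    FW_mg = fw,
    fit = object$beta0 + object$beta_H * h_ref + object$beta_FW * fw)
  p <- ggplot2::ggplot(line, ggplot2::aes(x = .data$FW_mg, y = .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$fit + object$resid_mu - half_width,
      ymax = .data$fit + object$resid_mu + half_width),
      alpha = 0.12, fill = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Fresh weight (mg)", y = "Damped frequency (Hz)",
                  title = sprintf("Screening model ('%s'), H = %.3g cm",
                                  object$condition_label, h_ref)) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    mapping <- if ("is_mutant" %in% names(data)) {
      ggplot2::aes(x = .data$FW_mg, y = .data$omega_d,
                   colour = .data$is_mutant)
    } else {
      ggplot2::aes(x = .data$FW_mg, y = .data$omega_d)
    }
    p <- p + ggplot2::geom_point(data = data, mapping, inherit.aes = FALSE,
                                 size = 1.5, alpha = 0.8)
  }
  p
}
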