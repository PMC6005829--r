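test_that("training recovers the generating regression and residual scale", {
  pop <- generate_population(n_wt = 63, beta0 = 5, beta_H = 0.2,
                             beta_FW = 0.1, sigma = 1.5, seed = 13)
  m <- fit_screening_model(pop, condition_label = "cond-test")
  est <- tidy(m)
  truth <- c("(Intercept)" = 5, H_cm = 0.2, FW_mg = 0.1)
  for (term in names(truth)) {
    row <- est[est$term == term, ]
    expect_lt(abs(row$estimate - truth[[term]]), 2 * row$std.error)
  }
  # sd(sigma_hat) ~ sigma/sqrt(2*(n-p)): allow 3 sampling SDs around truth
  expect_lt(abs(m$resid_sigma - 1.5), 3 * 1.5 / sqrt(2 * (63 - 3)))
  expect_equal(m$n_train, 63L)
  expect_equal(glance(m)$condition_label, "cond-test")
})

test_that("noise-free training data gives an exact fit", {
  df <- tibble::tibble(sample_id = sprintf("s%02d", 1:12),
                       H_cm = seq(15, 40, length.out = 12),
                       FW_mg = seq(20, 120, length.out = 12) +
                         c(0, 3, -2, 5, 1, -4, 2, 0, -1, 3, -2, 1),
                       omega_d = 8 + 0.2 * H_cm + 0.15 * FW_mg)
  m <- fit_screening_model(df)
  expect_equal(c(m$beta0, m$beta_H, m$beta_FW), c(8, 0.2, 0.15),
               tolerance = 1e-8)
  expect_lt(m$resid_sigma, 1e-6)
})

test_that("degenerate or undersized training tables are refused", {
  base <- generate_population(n_wt = 20, seed = 1)
  expect_error(fit_screening_model(dplyr::mutate(base, H_cm = 25)),
               "degenerate-design")
  expect_error(fit_screening_model(base[1:5, ]), "training-size")
  expect_error(fit_screening_model(dplyr::select(base, -FW_mg)),
               "lacks column")
})

test_that("classification p-values follow the residual normal", {
  pop <- generate_population(n_wt = 63, seed = 17)
  m <- fit_screening_model(pop)
  rec <- function(omega) tibble::tibble(sample_id = "q", H_cm = 25,
                                        FW_mg = 60, omega_d = omega)
  centre <- predict(m, rec(1)) + m$resid_mu
  expect_equal(classify_samples(m, rec(centre))$p_value, 1)
  expect_false(classify_samples(m, rec(centre))$is_mutant)
  # the 1% two-sided boundary sits 2.5758 sigma out
  edge <- centre + qnorm(1 - 0.01 / 2) * m$resid_sigma
  expect_equal(classify_samples(m, rec(edge))$p_value, 0.01,
               tolerance = 1e-6)
  # a stem at 35% of its predicted frequency is unambiguously flagged
  soft <- rec(0.35 * predict(m, rec(1)))
  res <- classify_samples(m, soft)
  expect_lt(res$p_value, 0.001)
  expect_true(res$is_mutant)
  expect_error(classify_samples(list(), rec(20)), "model-state")
})

test_that("fresh weight dominates height in the standardized model", {
  pop <- generate_population(n_wt = 200, seed = 23)
  m <- fit_screening_model(pop)
  expect_gt(abs(m$beta_FW * sd(pop$FW_mg)), abs(m$beta_H * sd(pop$H_cm)))
})

test_that("model files round-trip losslessly and reject damage", {
  pop <- generate_population(n_wt = 30, seed = 29)
  m <- fit_screening_model(pop, condition_label = "cond1")
  path <- withr::local_tempfile(fileext = ".json")
  write_screening_model(m, path)
  m2 <- read_screening_model(path)
  for (f in c("beta0", "beta_H", "beta_FW", "resid_mu", "resid_sigma",
              "n_train", "condition_label")) {
    expect_equal(m2[[f]], m[[f]], tolerance = 1e-12)
  }
  # classification through the reloaded model is identical
  expect_equal(classify_samples(m2, pop), classify_samples(m, pop))
  writeLines(substr(paste(readLines(path), collapse = ""), 1, 40), path)
  expect_error(read_screening_model(path), "model-file")
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(schema = "something_else"), path2,
                       auto_unbox = TRUE)
  expect_error(read_screening_model(path2), "model-file")
  path3 <- withr::local_tempfile(fileext = ".json")
  write_screening_model(m, path3)
  expect_warning(read_screening_model(path3, expected_condition = "cond2"),
                 "differs")
})

test_that("cross-condition use warns but still classifies", {
  pop <- generate_population(n_wt = 30, seed = 31)
  m <- fit_screening_model(pop, condition_label = "cond1")
  expect_warning(res <- classify_samples(m, pop, condition_label = "cond2"),
                 "retrain")
  expect_equal(nrow(res), 30)
})
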