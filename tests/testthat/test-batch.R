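batch_fixture <- function(root, fs = c(12, 20, 28), duration = 1.5,
                          noise = 0, seed0 = 40) {
  input <- file.path(root, "shoot_2026-01-15")
  dir.create(input, recursive = TRUE)
  for (i in seq_along(fs)) {
    make_test_video(file.path(input, sprintf("sample%02d", i)), f_d = fs[i],
                    zeta = 0.05, duration = duration, noise_sigma = noise,
                    seed = seed0 + i)
  }
  input
}

test_that("a folder of videos becomes per-sample plots and a frequency table", {
  root <- withr::local_tempdir()
  input <- batch_fixture(root)
  out <- file.path(root, "results")
  res <- suppressMessages(
    run_batch(input, output_dir = out,
              traits = tibble::tibble(sample_id = sprintf("sample%02d", 1:3),
                                      H_cm = c(22, 28, 34),
                                      FW_mg = c(45, 60, 85))))
  expect_equal(nrow(res), 3)
  expect_true(all(res$status == "ok"))
  # recovered frequencies within one bin of the generator truth
  expect_true(all(abs(res$omega_d - c(12, 20, 28)) <= res$resolution_hz))
  for (s in sprintf("sample%02d", 1:3)) {
    for (p in c("displacement_vibration.png", "hanning_vibration.png",
                "fft_power_spectrum.png")) {
      expect_true(file.exists(file.path(out, s, p)))
    }
  }
  omega_csv <- read.csv(file.path(out, "omega_d_results.csv"))
  expect_equal(nrow(omega_csv), 3)
  expect_named(omega_csv, c("sample_id", "omega_d_hz", "resolution_hz",
                            "status"))
  mech_csv <- read.csv(file.path(out, "mechanics_results.csv"))
  expect_true(all(mech_csv$k_N_per_m > 0))
})

test_that("one broken sample does not sink the batch", {
  root <- withr::local_tempdir()
  input <- batch_fixture(root, fs = c(15, 25))
  bad <- file.path(input, "sample99")
  dir.create(bad)
  black <- array(0, dim = c(8, 8, 3))
  for (i in 1:40) {
    png::writePNG(black, file.path(bad, sprintf("frame_%05d.png", i)))
  }
  res <- suppressMessages(run_batch(input, output_dir = file.path(root, "r"),
                                    write_plots = FALSE))
  expect_equal(nrow(res), 3)
  expect_equal(sum(res$status == "ok"), 2)
  expect_true(is.na(res$omega_d[res$sample_id == "sample99"]))
  expect_error(suppressMessages(run_batch(file.path(root, "nothing_here"))),
               "no-input")
  empty <- file.path(root, "empty"); dir.create(empty)
  expect_error(suppressMessages(run_batch(empty)), "no-input")
})

test_that("batch CSV output is deterministic across reruns", {
  root <- withr::local_tempdir()
  input <- batch_fixture(root, fs = c(18, 26))
  r1 <- suppressMessages(run_batch(input, output_dir = file.path(root, "o1"),
                                   write_plots = FALSE))
  r2 <- suppressMessages(run_batch(input, output_dir = file.path(root, "o2"),
                                   write_plots = FALSE))
  expect_identical(readLines(file.path(root, "o1", "omega_d_results.csv")),
                   readLines(file.path(root, "o2", "omega_d_results.csv")))
})

test_that("train and screen runs join tables and persist models", {
  root <- withr::local_tempdir()
  pop <- generate_population(n_wt = 63, n_mutant = 21, mutant_shift = 0.35,
                             seed = 47)
  wt <- pop[pop$genotype == "wt", ]
  model_path <- file.path(root, "model.json")
  m <- suppressMessages(run_train(wt, model_path, condition_label = "c1"))
  expect_true(file.exists(model_path))
  out_csv <- file.path(root, "screening_results.csv")
  res <- run_screen(model_path, omega = pop[, c("sample_id", "omega_d")],
                    traits = pop[, c("sample_id", "H_cm", "FW_mg")],
                    out_csv = out_csv)
  expect_equal(nrow(res), 84)
  expect_true(file.exists(out_csv))
  flagged <- res$sample_id[res$is_mutant]
  expect_true(all(pop$sample_id[pop$genotype == "mutant"] %in% flagged))
  # a degenerate threshold flags everything
  res_all <- run_screen(m, omega = pop[, c("sample_id", "omega_d")],
                        traits = pop[, c("sample_id", "H_cm", "FW_mg")],
                        threshold = 1)
  expect_true(all(res_all$is_mutant))
  # missing join keys are named
  expect_error(
    run_screen(m, omega = pop[, c("sample_id", "omega_d")],
               traits = pop[1:80, c("sample_id", "H_cm", "FW_mg")]),
    "s0081")
  # undersized or duplicated training tables are refused
  expect_error(suppressMessages(run_train(wt[1:5, ], model_path)),
               "training-size")
  expect_error(suppressMessages(run_train(rbind(wt, wt[1, ]), model_path)),
               "duplicated")
})
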