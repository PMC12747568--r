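tiny_pipeline_config <- function(out_dir, seed = 1L) {
  pipeline_config(
    out_dir = out_dir, n_subjects = 9L, intox_fraction = 0.34,
    sim = y_signal_params(duration_s = 4),
    ispec = NULL,
    model = model_config(window_size = 64L, conv1_filters = 6L,
                         conv2_filters = 8L, lstm_units = 5L,
                         dense1_units = 8L, dense2_units = 8L,
                         dropout_rate = 0.1, learning_rate = 3e-3,
                         batch_size = 32L, epochs = 2L, cv_epochs = 2L),
    n_per_class = 3L, k_folds = 3L, seed = seed)
}

test_that("recordings round-trip through the long CSV format", {
  p <- quiet_params(duration_s = 2)
  recs <- simulate_cohort(3, 0.34, p)
  path <- tempfile(fileext = ".csv")
  write_recordings(recs, path)
  back <- read_recordings(path)
  expect_length(back, 3)
  orig <- recs[[1]]
  match_back <- back[[which(vapply(back, `[[`, character(1), "subject_id") ==
                            orig$subject_id)]]
  expect_equal(match_back$ax, orig$ax, tolerance = 1e-9)
  expect_equal(match_back$label, orig$label)
  expect_equal(match_back$sampling_rate_hz, orig$sampling_rate_hz,
               tolerance = 1e-6)
  unlink(path)
})

test_that("window sets persist and restore losslessly", {
  p <- quiet_params(duration_s = 3)
  ws <- segment_windows(simulate_subject(p, "sober", "S1"), 128, 0.5)
  path <- tempfile(fileext = ".rds")
  save_window_set(ws, path)
  expect_identical(load_window_set(path), ws)
  unlink(path)
})

test_that("the end-to-end pipeline emits its artifacts deterministically", {
  out1 <- file.path(tempdir(), "pipe1")
  out2 <- file.path(tempdir(), "pipe2")
  r1 <- run_pipeline(tiny_pipeline_config(out1, seed = 3))
  r2 <- run_pipeline(tiny_pipeline_config(out2, seed = 3))

  files <- c("metrics.json", "metrics.csv", "roc.csv", "history.csv",
             "channel_ablation.csv", "manifest.json")
  for (f in files) expect_true(file.exists(file.path(out1, f)), label = f)

  # identical config and seed reproduce identical reports
  expect_identical(readLines(file.path(out1, "metrics.json")),
                   readLines(file.path(out2, "metrics.json")))
  expect_identical(readLines(file.path(out1, "roc.csv")),
                   readLines(file.path(out2, "roc.csv")))

  # manifest carries the hash of the exact configuration used
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(man$config_hash,
               intoxgait:::config_hash(tiny_pipeline_config(out1, seed = 3)))
  # window counts reported by preprocessing match what training consumed
  expect_equal(unlist(man$window_counts),
               setNames(as.integer(r1$window_counts),
                        names(r1$window_counts)))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("the cross-validation runner writes disjoint fold reports", {
  out <- file.path(tempdir(), "cvrun")
  cv <- run_cv(tiny_pipeline_config(out, seed = 5))
  expect_true(file.exists(file.path(out, "cv_folds.csv")))
  folds <- read.csv(file.path(out, "cv_folds.csv"))
  expect_equal(nrow(folds), 5L)                 # 3 folds + mean + sd
  subj <- jsonlite::read_json(file.path(out, "cv_subjects.json"),
                              simplifyVector = TRUE)
  expect_length(unlist(subj), length(unique(unlist(subj))))
  unlink(out, recursive = TRUE)
})

test_that("invalid configurations fail before any compute", {
  expect_error(pipeline_config(window_size = 128L,
                               model = model_config(window_size = 64L)),
               "window_size")
  cfgbad <- tiny_pipeline_config(tempfile())
  cfgbad$input_csv <- "/nonexistent/file.csv"
  expect_error(run_pipeline(cfgbad), "not found")
})

test_that("model checkpoints round-trip with a JSON config sidecar", {
  model <- build_model(micro_config())
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_model(path)
  expect_identical(back$params, model$params)
  cfg <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(cfg$lstm_units, model$config$lstm_units)
  expect_equal(cfg$ablation, "none")
  # restored model predicts identically
  p <- y_signal_params(duration_s = 2)
  ws <- segment_windows(simulate_subject(p, "sober", "A"), 8, 0.5)
  expect_identical(predict_model(back, ws), predict_model(model, ws))
  unlink(c(path, paste0(path, ".json")))
})

test_that("attention-profile overlay plots are written to disk", {
  prof <- structure(list(timeline = cbind(sober = runif(64),
                                          intoxicated = runif(64)),
                         sigma = 10),
                    class = "attention_profile")
  path <- tempfile(fileext = ".png")
  plot_attention_profile(prof, path)
  expect_true(file.exists(path) && file.size(path) > 0)
  unlink(path)
})
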