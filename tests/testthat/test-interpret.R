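test_that("Gaussian smoothing is mass-preserving with reflect padding", {
  set.seed(6)
  x <- rnorm(200)
  expect_identical(gaussian_smooth(x, 0), x)
  for (sigma in c(1, 5, 10)) {
    y <- gaussian_smooth(x, sigma)
    expect_length(y, length(x))
    expect_equal(mean(y), mean(x), tolerance = 1e-6)
  }
  # heavy smoothing approaches the mean
  expect_lt(sd(gaussian_smooth(x, 50)), sd(x))
})

test_that("phase tables reproduce the quartile arithmetic", {
  # identical class timelines give zero differences
  tl <- cbind(sober = rep(0.1, 16), intoxicated = rep(0.1, 16))
  pt <- phase_analysis(tl)
  expect_equal(pt$delta, rep(0, 4))
  expect_equal(pt$phase, c("0-25%", "25-50%", "50-75%", "75-100%"))

  # quartile boundaries on a T = 1024 profile: means isolate each block
  tl2 <- cbind(sober = rep(c(1, 2, 3, 4), each = 256),
               intoxicated = rep(c(2, 2, 2, 2), each = 256))
  pt2 <- phase_analysis(tl2)
  expect_equal(pt2$sober, c(1, 2, 3, 4))
  expect_equal(pt2$delta, c(1, 0, -1, -2))

  expect_warning(pz <- phase_deltas(c(0, 0.1), c(0.1, 0.2)), "zero sober")
  expect_true(is.na(pz$delta_pct[1]))
})

test_that("attention profiles are built from normalized per-window vectors", {
  p <- y_signal_params(duration_s = 3)
  ws <- bind_window_sets(
    segment_windows(simulate_subject(p, "sober", "A"), 32, 0.5),
    segment_windows(simulate_subject(p, "intoxicated", "B"), 32, 0.5))
  model <- build_model(model_config(window_size = 32L, conv1_filters = 4L,
                                    conv2_filters = 6L, lstm_units = 4L,
                                    dense1_units = 8L, dense2_units = 8L,
                                    dropout_rate = 0, seed = 2))
  before <- intoxgait:::param_flatten(model$params)

  # per-window collapsed attention vectors sum to 1 before averaging
  wts <- attention_weights(model, subset_windows(ws, 1:3))
  for (c in 1:3) for (i in 1:3)
    expect_equal(sum(colMeans(wts[[c]][i, , ])), 1, tolerance = 1e-6)

  warns <- capture_warnings(
    prof <- attention_profile(model, ws, n_per_class = 50, sigma = 10, seed = 1))
  expect_match(warns, "available", all = TRUE)
  expect_s3_class(prof, "attention_profile")
  expect_equal(colSums(prof$raw), c(sober = 1, intoxicated = 1),
               tolerance = 1e-6)
  # smoothing preserves the timeline mean
  expect_equal(colMeans(prof$timeline), colMeans(prof$raw), tolerance = 1e-6)
  # sigma -> 0 leaves the raw timeline untouched
  prof0 <- attention_profile(model, ws, n_per_class = 5, sigma = 0, seed = 1)
  expect_equal(prof0$timeline, prof0$raw)

  # extraction does not mutate the model
  expect_identical(intoxgait:::param_flatten(model$params), before)

  chan <- build_model(model_config(window_size = 32L, conv1_filters = 4L,
                                   conv2_filters = 6L, lstm_units = 4L,
                                   dense1_units = 8L, dense2_units = 8L,
                                   attention_variant = "channel",
                                   dropout_rate = 0, seed = 2))
  expect_error(attention_profile(chan, ws), "channel-gate")
})

test_that("channel masking zeroes one axis and full masking kills the input", {
  p <- y_signal_params(duration_s = 3)
  ws <- bind_window_sets(
    segment_windows(simulate_subject(p, "sober", "A"), 32, 0.5),
    segment_windows(simulate_subject(p, "intoxicated", "B"), 32, 0.5))
  m2 <- mask_channel(ws, 2)
  expect_true(all(m2$windows[, , 2] == 0))
  expect_equal(m2$windows[, , c(1, 3)], ws$windows[, , c(1, 3)])

  model <- build_model(model_config(window_size = 32L, conv1_filters = 4L,
                                    conv2_filters = 6L, lstm_units = 4L,
                                    dense1_units = 8L, dense2_units = 8L,
                                    dropout_rate = 0, seed = 2))
  dead <- mask_channel(mask_channel(mask_channel(ws, 1), 2), 3)
  pd <- predict_model(model, dead)
  expect_lt(diff(range(pd)), 1e-12)             # input-independent output

  res <- channel_ablation(model, ws)
  expect_s3_class(res, "ablation_result")
  expect_equal(nrow(res), 3L)
  if (any(res$delta_acc > 0))
    expect_equal(max(res$relative), 1.0)
})

test_that("printed-operand phase arithmetic recovers the published deltas", {
  # the published quartile analysis: sober/intox per-phase means in, delta
  # out; tolerances are one ulp of the printed precision, since the source
  # table derives some rows from unrounded operands
  pt <- phase_deltas(c(0.0766, 0.0768, 0.0747, 0.0716),
                     c(0.0651, 0.0636, 0.0641, 0.0629))
  expect_equal(pt$delta[1], -0.0115, tolerance = 1e-12)
  expect_lt(max(abs(pt$delta - c(-0.0115, -0.0133, -0.0106, -0.0087))),
            1.5e-4)
  expect_lt(max(abs(pt$delta_pct - c(-15.0, -17.3, -14.2, -12.1))), 0.15)
})
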