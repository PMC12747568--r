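test_that("sigmoid and binary cross-entropy match their closed forms", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(log(3)), 0.75, tolerance = 1e-12)
  expect_equal(sigmoid(100), 1, tolerance = 1e-9)
  z <- seq(-5, 5, by = 0.5)
  expect_equal(sigmoid(-z), 1 - sigmoid(z), tolerance = 1e-12)
  expect_true(all(diff(sigmoid(z)) > 0))

  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(1, 0.5), 0.6931, tolerance = 1e-4)
  expect_equal(bce_loss(0, 0.5), bce_loss(1, 0.5))
  expect_lt(bce_loss(1, 1 - 1e-7), 1e-6)
  expect_equal(bce_loss(c(1, 0), c(0.9, 0.2)),
               mean(-c(log(0.9), log(0.8))), tolerance = 1e-12)
  # clipping keeps the loss finite at the boundary
  expect_true(is.finite(bce_loss(1, 0)))
})

test_that("the architecture preserves sequence lengths and widths", {
  # full-scale widths follow from the configuration without building it
  cfg_full <- model_config()
  expect_equal(intoxgait:::attention_width(cfg_full, "none"), 170L)  # 2 x 85
  expect_equal(intoxgait:::attention_width(cfg_full, "bidirectionality"), 85L)
  expect_equal(intoxgait:::attention_width(cfg_full, "lstm"), 175L)

  cfg <- micro_config()
  model <- build_model(cfg)
  Xb <- array(rnorm(2 * 8 * 3), c(2, 8, 3))
  fwd <- intoxgait:::model_forward(model, Xb, return_attention = TRUE)
  # 'same' padding: the attention matrices are T x T, so every stage kept T
  expect_equal(dim(fwd$attention[[1]]), c(2L, 8L, 8L))
  expect_length(fwd$prob, 2L)
  expect_true(all(fwd$prob > 0 & fwd$prob < 1))
  # pooled concatenation is 3 channels x attention width
  expect_equal(nrow(model$params$dense1$W),
               3L * intoxgait:::attention_width(cfg, "none"))

  # scaled-down configuration preserves proportional widths
  sc <- scaled_model_config()
  expect_equal(sc$conv1_filters, 29L)
  expect_equal(sc$conv2_filters, 44L)
  expect_equal(sc$lstm_units, 21L)
  expect_equal(intoxgait:::attention_width(sc, "none"), 42L)
})

test_that("attention weights are row-stochastic with the right degeneracies", {
  set.seed(10)
  X <- matrix(rnorm(6 * 4), 6, 4)
  for (v in c("self", "mha", "temporal")) {
    res <- attention_apply(X, v, seed = 3)
    w <- res$weights
    if (is.matrix(w)) expect_equal(rowSums(w), rep(1, 6), tolerance = 1e-6)
    else expect_equal(sum(w), 1, tolerance = 1e-6)
    expect_equal(dim(res$out), dim(X))
  }
  res <- attention_apply(X, "cross", context = cbind(X, X), seed = 3)
  expect_equal(rowSums(res$weights), rep(1, 6), tolerance = 1e-6)

  # T = 1: the only weight is 1
  one <- attention_apply(matrix(rnorm(4), 1, 4), "self", seed = 3)
  expect_equal(one$weights, matrix(1, 1, 1))

  # constant sequence: equal logits give uniform weights 1/T
  Xc <- matrix(rep(rnorm(4), each = 6), 6, 4)
  unif <- attention_apply(Xc, "self", seed = 3)
  expect_equal(unif$weights, matrix(1 / 6, 6, 6), tolerance = 1e-9)

  gate <- attention_apply(X, "channel", seed = 3)
  expect_length(gate$weights, 4L)
  expect_true(all(gate$weights > 0 & gate$weights < 1))

  expect_error(attention_apply(X, "cross"), "context")
})

test_that("analytic gradients agree with finite differences everywhere", {
  cases <- list(
    list(variant = "self", ablation = "none"),
    list(variant = "mha", ablation = "none"),
    list(variant = "cross", ablation = "none"),
    list(variant = "temporal", ablation = "none"),
    list(variant = "channel", ablation = "none"),
    list(variant = "self", ablation = "attention"),
    list(variant = "self", ablation = "bidirectionality"),
    list(variant = "self", ablation = "cnn"),
    list(variant = "self", ablation = "lstm"))
  for (cs in cases) {
    model <- build_model(micro_config(cs$variant), ablation = cs$ablation)
    model <- perturb_params(model)
    err <- fd_gradcheck(model)
    expect_lt(err, 1e-4)
  }
  # projection-free self-attention form
  model <- perturb_params(build_model(micro_config(self_projection = FALSE)))
  expect_lt(fd_gradcheck(model), 1e-4)
})

test_that("gradient flows into every trainable tensor in one step", {
  for (abl in c("none", "attention", "bidirectionality", "cnn", "lstm")) {
    model <- perturb_params(build_model(micro_config(), ablation = abl))
    set.seed(3)
    Xb <- array(rnorm(2 * 8 * 3), c(2, 8, 3))
    res <- intoxgait:::loss_and_grads(model, Xb, c(0L, 1L))
    grads <- intoxgait:::align_tree(model$params, res$grads)
    leaves <- rapply(grads, function(g) any(g != 0), how = "unlist")
    expect_true(all(leaves), label = paste("ablation", abl))
  }
})

test_that("ablated builders change the graph as named", {
  none <- build_model(micro_config())
  expect_true(!is.null(none$params$channels[[1]]$att))
  expect_true(!is.null(none$params$channels[[1]]$lstm_b))

  no_att <- build_model(micro_config(), ablation = "attention")
  expect_null(no_att$params$channels[[1]]$att)

  uni <- build_model(micro_config(), ablation = "bidirectionality")
  expect_null(uni$params$channels[[1]]$lstm_b)

  no_cnn <- build_model(micro_config(), ablation = "cnn")
  expect_null(no_cnn$params$channels[[1]]$conv1)

  no_lstm <- build_model(micro_config(), ablation = "lstm")
  expect_null(no_lstm$params$channels[[1]]$lstm_f)
  expect_error(build_model(micro_config(), ablation = "pooling"), "ablation")
})

test_that("inference is deterministic and stateless", {
  p <- y_signal_params(duration_s = 3)
  ws <- bind_window_sets(
    segment_windows(simulate_subject(p, "sober", "A"), 8, 0.5),
    segment_windows(simulate_subject(p, "intoxicated", "B"), 8, 0.5))
  model <- build_model(micro_config(dropout_rate = 0.5))
  p1 <- predict_model(model, ws)
  p2 <- predict_model(model, ws)
  expect_identical(p1, p2)                      # dropout off at inference
  expect_true(all(p1 > 0 & p1 < 1))
  # duplicated window gets a duplicated probability
  dup <- subset_windows(ws, c(1L, 1L, 2L))
  pd <- predict_model(model, dup)
  expect_identical(pd[1], pd[2])
})

test_that("short training reduces loss and a trained model beats chance", {
  p <- y_signal_params(duration_s = 4)
  recs <- simulate_cohort(8, 0.5, p)
  pp <- preprocess_cohort(recs, split_spec(c(train = 0.6, validation = 0.2,
                                             test = 0.2), seed = 1),
                          ispec = NULL, window_size = 64L, seed = 1)
  cfg <- model_config(window_size = 64L, conv1_filters = 8L,
                      conv2_filters = 12L, kernel_size = 6L, lstm_units = 6L,
                      dense1_units = 16L, dense2_units = 16L,
                      dropout_rate = 0.1, learning_rate = 3e-3,
                      batch_size = 16L, seed = 5)
  model <- train_model(build_model(cfg), pp$train, pp$validation, epochs = 5)
  expect_true(model$trained)
  expect_s3_class(model$history, "data.frame")
  expect_lt(model$history$train_loss[nrow(model$history)],
            model$history$train_loss[1])
  expect_error(train_model(build_model(cfg), pp$train,
                           window_set(array(0, c(0, 64, 3)), integer(0),
                                      character(0))),
               "empty")
})
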