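#' Multichannel hybrid model configuration
#'
#' Hyperparameters of the multichannel Conv1D-BiLSTM-attention classifier.
#' The defaults are the Bayesian-optimization optimum reported for the full
#' model: two Conv1D layers (117 and 175 filters, kernel 6, ReLU, 'same'
#' padding) per channel, a BiLSTM with 85 units returning sequences,
#' per-channel attention, global average pooling, concatenation, dense layers
#' of 129 and 188 ReLU units each followed by dropout (rate
#' 0.696581562334145), a single sigmoid output, Adam at learning rate
#' 0.00024227083179696293 and binary cross-entropy loss.
#'
#' @param window_size input window length T (default 1024).
#' @param n_channels number of accelerometer channels (fixed at 3).
#' @param conv1_filters,conv2_filters Conv1D filter counts.
#' @param kernel_size Conv1D kernel length.
#' @param lstm_units LSTM units per direction.
#' @param attention_variant one of `"self"`, `"mha"`, `"cross"`,
#'   `"temporal"`, `"channel"`.
#' @param self_projection use learned Q/K/V projections for self-attention
#'   (default TRUE); FALSE selects the projection-free scaled dot-product
#'   form.
#' @param mha_heads number of heads for multi-head attention.
#' @param dense1_units,dense2_units dense layer widths.
#' @param dropout_rate dropout rate after each dense layer, in `[0, 1)`.
#' @param learning_rate Adam learning rate.
#' @param epochs maximum training epochs (50; 30 within cross-validation).
#' @param cv_epochs maximum epochs per cross-validation fold.
#' @param batch_size minibatch size.
#' @param early_stopping halt when validation loss stops improving.
#' @param patience early-stopping patience in epochs.
#' @param lr_factor,lr_patience learning-rate-on-plateau reduction factor and
#'   patience.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return an object of class `model_config`.
#' @export
model_config <- function(window_size = 1024L, n_channels = 3L,
                         conv1_filters = 117L, conv2_filters = 175L,
                         kernel_size = 6L, lstm_units = 85L,
                         attention_variant = c("self", "mha", "cross",
                                               "temporal", "channel"),
                         self_projection = TRUE, mha_heads = 4L,
                         dense1_units = 129L, dense2_units = 188L,
                         dropout_rate = 0.696581562334145,
                         learning_rate = 0.00024227083179696293,
                         epochs = 50L, cv_epochs = 30L, batch_size = 64L,
                         early_stopping = TRUE, patience = 5L,
                         lr_factor = 0.5, lr_patience = 3L, seed = 1L) {
  attention_variant <- match.arg(attention_variant)
  for (nm in c("window_size", "conv1_filters", "conv2_filters", "kernel_size",
               "lstm_units", "dense1_units", "dense2_units", "batch_size"))
    stopifnot_positive(get(nm), nm)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must be in [0, 1)", call. = FALSE)
  structure(list(window_size = as.integer(window_size),
                 n_channels = as.integer(n_channels),
                 conv1_filters = as.integer(conv1_filters),
                 conv2_filters = as.integer(conv2_filters),
                 kernel_size = as.integer(kernel_size),
                 lstm_units = as.integer(lstm_units),
                 attention_variant = attention_variant,
                 self_projection = self_projection,
                 mha_heads = as.integer(mha_heads),
                 dense1_units = as.integer(dense1_units),
                 dense2_units = as.integer(dense2_units),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 epochs = as.integer(epochs), cv_epochs = as.integer(cv_epochs),
                 batch_size = as.integer(batch_size),
                 early_stopping = early_stopping, patience = as.integer(patience),
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 seed = as.integer(seed)), class = "model_config")
}

#' Desk-scale model configuration
#'
#' A proportionally shrunk configuration for CPU-scale experiments and tests:
#' all layer widths at `scale` (default 25%) of the full model, a shorter
#' window, a learning rate and dropout suited to the smaller parameter count
#' and short epoch budgets. Shape contracts (width ratios, sequence lengths)
#' are preserved, so every structural property of the full model can be
#' exercised cheaply.
#'
#' @param window_size window length (default 256).
#' @param scale width multiplier applied to filters/units (default 0.25).
#' @param ... overrides passed to [model_config()].
#' @return a `model_config`.
#' @export
scaled_model_config <- function(window_size = 256L, scale = 0.25, ...) {
  args <- list(window_size = as.integer(window_size),
               conv1_filters = max(1L, round(117 * scale)),
               conv2_filters = max(1L, round(175 * scale)),
               lstm_units = max(1L, round(85 * scale)),
               dense1_units = max(1L, round(129 * scale)),
               dense2_units = max(1L, round(188 * scale)),
               dropout_rate = 0.3, learning_rate = 2e-3,
               epochs = 10L, cv_epochs = 8L)
  override <- list(...)
  args[names(override)] <- override
  do.call(model_config, args)
}

ABLATIONS <- c("none", "attention", "bidirectionality", "cnn", "lstm")

check_ablation <- function(ablation) {
  if (!ablation %in% ABLATIONS)
    stop("ablation must be one of: ", paste(ABLATIONS, collapse = ", "),
         call. = FALSE)
  ablation
}
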