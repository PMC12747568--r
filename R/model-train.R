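#' Train a multichannel hybrid model
#'
#' Minibatch Adam on binary cross-entropy with seeded shuffling and dropout,
#' validation-loss early stopping (best weights restored) and
#' learning-rate reduction on plateau. The training set is expected to be
#' class-balanced (see [oversample_minority()]); the validation set is used
#' as-is.
#'
#' @param model an [build_model()] result.
#' @param train_ws training [window_set()] (balanced).
#' @param val_ws validation [window_set()] (never oversampled).
#' @param epochs maximum epochs; defaults to the config's `epochs`.
#' @param verbose print one line per epoch.
#' @return the trained `mch_model`, with a `history` data frame of per-epoch
#'   train/validation loss, validation AUC/accuracy and learning rate.
#' @export
train_model <- function(model, train_ws, val_ws, epochs = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "mch_model"))
  cfg <- model$config
  if (n_windows(train_ws) == 0L || n_windows(val_ws) == 0L)
    stop("empty training or validation set", call. = FALSE)
  if (dim(train_ws$windows)[2] != cfg$window_size)
    stop("window length does not match the model configuration", call. = FALSE)
  if (is.null(epochs)) epochs <- cfg$epochs

  N <- n_windows(train_ws)
  y <- train_ws$labels
  lr <- cfg$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  flat <- param_flatten(model$params)
  m <- numeric(length(flat)); v <- numeric(length(flat)); step <- 0L

  best_loss <- Inf; best_params <- model$params
  wait <- 0L; lr_wait <- 0L
  hist <- list()

  for (epoch in seq_len(epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, paste0("shuffle-", epoch)),
                     sample.int(N))
    batch_losses <- numeric(0)
    nb <- ceiling(N / cfg$batch_size)
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, N)]
      Xb <- train_ws$windows[idx, , , drop = FALSE]
      res <- with_seed(derive_seed(cfg$seed, paste0("drop-", epoch, "-", bi)),
                       loss_and_grads(model, Xb, y[idx], training = TRUE))
      batch_losses <- c(batch_losses, res$loss)
      g <- param_flatten(align_tree(model$params, res$grads))
      step <- step + 1L
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      flat <- param_flatten(model$params) - lr * mhat / (sqrt(vhat) + eps)
      model$params <- param_unflatten(flat, model$params)
    }
    vp <- predict_model(model, val_ws)
    val_loss <- bce_loss(val_ws$labels, vp)
    val_auc <- auc_trapezoid(val_ws$labels, vp)
    val_acc <- mean(as.integer(vp >= 0.5) == val_ws$labels)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = mean(batch_losses),
                                val_loss = val_loss, val_auc = val_auc,
                                val_acc = val_acc, lr = lr)
    if (verbose)
      message(sprintf("epoch %02d  train %.4f  val %.4f  auc %.4f  acc %.4f  lr %.2e",
                      epoch, mean(batch_losses), val_loss, val_auc, val_acc, lr))
    if (val_loss < best_loss - 1e-8) {
      best_loss <- val_loss; best_params <- model$params
      wait <- 0L; lr_wait <- 0L
    } else {
      wait <- wait + 1L; lr_wait <- lr_wait + 1L
      if (lr_wait >= cfg$lr_patience) { lr <- lr * cfg$lr_factor; lr_wait <- 0L }
      if (cfg$early_stopping && wait >= cfg$patience) break
    }
  }
  model$params <- best_params
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

#' Predict intoxication probabilities for a window set
#'
#' Inference is deterministic: dropout is disabled and no randomness is used.
#'
#' @param model a trained (or untrained) `mch_model`.
#' @param ws a [window_set()] whose window length matches the model.
#' @param batch_size windows per forward batch.
#' @return numeric vector of probabilities in (0, 1), one per window.
#' @export
predict_model <- function(model, ws, batch_size = 128L) {
  stopifnot(inherits(model, "mch_model"), inherits(ws, "window_set"))
  if (dim(ws$windows)[2] != model$config$window_size)
    stop("window length does not match the model configuration", call. = FALSE)
  N <- n_windows(ws)
  probs <- numeric(N)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    fwd <- model_forward(model, ws$windows[idx, , , drop = FALSE],
                         training = FALSE)
    probs[idx] <- fwd$prob
  }
  probs
}

#' Extract attention weights for a window set
#'
#' Runs a forward pass with attention retrieval; the model is not modified.
#' For matrix-valued variants (self, mha, cross) each channel yields an
#' `N x T x T` array of row-normalized attention matrices; the temporal
#' variant yields `N x T` weight vectors; the channel variant yields `N x d`
#' feature gates.
#'
#' @param model a trained `mch_model` (ablation must retain attention).
#' @param ws a [window_set()].
#' @return list of per-channel weight arrays (X, Y, Z order).
#' @export
attention_weights <- function(model, ws) {
  if (model$ablation == "attention")
    stop("model was built without an attention stage", call. = FALSE)
  fwd <- model_forward(model, ws$windows, training = FALSE,
                       return_attention = TRUE)
  fwd$attention
}

#' Apply one attention stage to a plain sequence
#'
#' Standalone application of any attention variant to a `T x d` sequence
#' (one window, one channel), returning the transformed sequence and the
#' attention weights. Parameters default to fresh seeded initializations.
#' For the cross variant, `context` supplies the `T x 2d` key/value source.
#'
#' @param X `T x d` numeric matrix.
#' @param variant attention variant name.
#' @param params optional parameter list (as [build_model()] initializes).
#' @param context `T x 2d` matrix for the cross variant.
#' @param self_projection use learned projections for `"self"`.
#' @param mha_heads heads for `"mha"`.
#' @param seed seed for fresh parameter draws when `params` is NULL.
#' @return list with `out` (`T x d`) and `weights` (`T x T` matrix, length-T
#'   vector, or length-d gate depending on the variant).
#' @export
attention_apply <- function(X, variant = c("self", "mha", "cross",
                                           "temporal", "channel"),
                            params = NULL, context = NULL,
                            self_projection = TRUE, mha_heads = 4L,
                            seed = 1L) {
  variant <- match.arg(variant)
  X <- as.matrix(X)
  T <- nrow(X); d <- ncol(X)
  cfg <- list(attention_variant = variant, self_projection = self_projection,
              mha_heads = as.integer(mha_heads))
  if (is.null(params))
    params <- with_seed(seed, attn_init(variant, d, cfg))
  if (variant == "cross") {
    if (is.null(context)) stop("cross attention needs a `context` matrix",
                               call. = FALSE)
    Xs <- list(array(X, c(T, 1L, d)),
               array(context[, 1:d, drop = FALSE], c(T, 1L, d)),
               array(context[, (d + 1L):(2L * d), drop = FALSE], c(T, 1L, d)))
    P <- list(params, attn_init("cross", d, cfg), attn_init("cross", d, cfg))
    res <- att_forward(Xs, P, cfg, return_weights = TRUE)
    return(list(out = matrix(res$out[[1]][, 1L, ], T, d),
                weights = matrix(res$weights[[1]][1L, , ], T, T)))
  }
  Xs <- rep(list(array(X, c(T, 1L, d))), 3)
  P <- rep(list(params), 3)
  res <- att_forward(Xs, P, cfg, return_weights = TRUE)
  w <- res$weights[[1]]
  w <- if (variant == "temporal") as.numeric(w[1L, ])
       else if (variant == "channel") as.numeric(w[1L, ])
       else matrix(w[1L, , ], T, T)
  list(out = matrix(res$out[[1]][, 1L, ], T, d), weights = w)
}

#' Save / load a trained model
#'
#' The network weights and training history are serialized as RDS; the
#' configuration is additionally written alongside as human-readable JSON
#' (`<path>.json`).
#'
#' @param model an `mch_model`.
#' @param path file path for the checkpoint (RDS).
#' @return `load_model` returns the `mch_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mch_model"))
  saveRDS(model, path)
  cfg <- model$config
  class(cfg) <- NULL
  jsonlite::write_json(c(cfg, list(ablation = model$ablation)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "mch_model"))
  model
}
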