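# Model assembly and the full forward/backward pass.
#
# Architecture per channel c in {X, Y, Z} (input T x 1):
#   Conv1D(F1, k, ReLU, same) -> Conv1D(F2, k, ReLU, same)
#   -> BiLSTM(H, sequences) -> attention(variant) -> global average pooling
# The three pooled vectors are concatenated and passed through
# Dense(D1, ReLU) -> dropout -> Dense(D2, ReLU) -> dropout -> Dense(1).
# The sigmoid is applied by the loss/prediction code, keeping the head linear
# in the logit. Ablation switches remove one named component:
#   attention        -> identity stage
#   bidirectionality -> unidirectional (forward) LSTM
#   cnn              -> raw inputs feed the BiLSTM
#   lstm             -> attention operates on the conv features

# width of the per-channel sequence entering the attention stage
attention_width <- function(cfg, ablation) {
  switch(ablation,
    lstm = cfg$conv2_filters,
    bidirectionality = cfg$lstm_units,
    2L * cfg$lstm_units)
}

#' Build an (untrained) multichannel hybrid model
#'
#' Initializes all parameters (variance-scaling uniform, seeded from the
#' config) for the configured attention variant and ablation switch.
#'
#' @param config a [model_config()].
#' @param ablation one of `"none"`, `"attention"`, `"bidirectionality"`,
#'   `"cnn"`, `"lstm"`.
#' @return an object of class `mch_model`.
#' @export
build_model <- function(config = model_config(), ablation = "none") {
  check_ablation(ablation)
  cfg <- config
  d_att <- attention_width(cfg, ablation)
  params <- with_seed(derive_seed(cfg$seed, "init"), {
    channels <- lapply(1:3, function(c) {
      p <- list()
      lstm_in <- 1L
      if (ablation != "cnn") {
        p$conv1 <- conv1d_init(1L, cfg$conv1_filters, cfg$kernel_size)
        p$conv2 <- conv1d_init(cfg$conv1_filters, cfg$conv2_filters,
                               cfg$kernel_size)
        lstm_in <- cfg$conv2_filters
      }
      if (ablation != "lstm") {
        p$lstm_f <- lstm_init(lstm_in, cfg$lstm_units)
        if (ablation != "bidirectionality")
          p$lstm_b <- lstm_init(lstm_in, cfg$lstm_units)
      }
      if (ablation != "attention") {
        att <- attn_init(cfg$attention_variant, d_att, cfg)
        if (length(att)) p$att <- att
      }
      p
    })
    list(channels = channels,
         dense1 = dense_init(3L * d_att, cfg$dense1_units),
         dense2 = dense_init(cfg$dense1_units, cfg$dense2_units),
         dense3 = dense_init(cfg$dense2_units, 1L))
  })
  structure(list(config = cfg, ablation = ablation, params = params,
                 history = NULL, trained = FALSE),
            class = "mch_model")
}

#' @export
print.mch_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<mch_model> T=%d conv=%d/%d k=%d lstm=%d attention=%s ablation=%s%s\n",
    cfg$window_size, cfg$conv1_filters, cfg$conv2_filters, cfg$kernel_size,
    cfg$lstm_units, cfg$attention_variant, x$ablation,
    if (x$trained) " [trained]" else ""))
  cat(sprintf("  parameters: %d\n", length(param_flatten(x$params))))
  invisible(x)
}

param_flatten <- function(params) as.numeric(unlist(params, use.names = FALSE))

param_unflatten <- function(vec, template) {
  i <- 0L
  rebuild <- function(p) {
    if (is.list(p)) return(lapply(p, rebuild))
    n <- length(p)
    out <- vec[(i + 1L):(i + n)]
    i <<- i + n
    if (!is.null(dim(p))) dim(out) <- dim(p)
    out
  }
  rebuild(template)
}

# Forward pass over a batch of windows Xb (N, T, 3). Returns logits,
# probabilities and the caches required for the backward pass.
model_forward <- function(model, Xb, training = FALSE, return_attention = FALSE) {
  cfg <- model$config
  abl <- model$ablation
  P <- model$params
  N <- dim(Xb)[1]; T <- dim(Xb)[2]
  seqs <- vector("list", 3)
  ch_cache <- vector("list", 3)
  for (c in 1:3) {
    A <- array(t(Xb[, , c]), c(T, N, 1L))
    cc <- list()
    if (abl != "cnn") {
      s1 <- conv1d_forward(A, P$channels[[c]]$conv1$W, P$channels[[c]]$conv1$b)
      s2 <- conv1d_forward(s1$out, P$channels[[c]]$conv2$W,
                           P$channels[[c]]$conv2$b)
      cc$conv1 <- s1$cache; cc$conv2 <- s2$cache
      A <- s2$out
    }
    if (abl != "lstm") {
      if (abl == "bidirectionality") {
        l <- lstm_dir_forward(A, P$channels[[c]]$lstm_f, reverse = FALSE)
        cc$lstm <- l$cache; cc$bidir <- FALSE
      } else {
        l <- bilstm_forward(A, P$channels[[c]]$lstm_f, P$channels[[c]]$lstm_b)
        cc$lstm <- l$cache; cc$bidir <- TRUE
      }
      A <- l$out
    }
    seqs[[c]] <- A
    ch_cache[[c]] <- cc
  }

  att <- NULL
  if (abl != "attention") {
    Patt <- lapply(1:3, function(c) P$channels[[c]]$att)
    att <- att_forward(seqs, Patt, cfg, return_weights = return_attention)
    seqs <- att$out
  }

  pooled <- vector("list", 3)
  gap_dims <- vector("list", 3)
  for (c in 1:3) {
    g <- gap_forward(seqs[[c]])
    pooled[[c]] <- g$out
    gap_dims[[c]] <- g$cache
  }
  Z <- do.call(cbind, pooled)

  d1 <- dense_forward(Z, P$dense1$W, P$dense1$b, relu = TRUE)
  dr1 <- dropout_forward(d1$out, cfg$dropout_rate, training)
  d2 <- dense_forward(dr1$out, P$dense2$W, P$dense2$b, relu = TRUE)
  dr2 <- dropout_forward(d2$out, cfg$dropout_rate, training)
  d3 <- dense_forward(dr2$out, P$dense3$W, P$dense3$b, relu = FALSE)
  logit <- as.numeric(d3$out)

  list(logit = logit, prob = sigmoid(logit),
       attention = if (return_attention) att$weights,
       cache = list(ch = ch_cache, att = if (!is.null(att)) att$cache,
                    gap_dims = gap_dims,
                    d1 = d1$cache, dr1 = dr1$cache, d2 = d2$cache,
                    dr2 = dr2$cache, d3 = d3$cache, N = N, T = T))
}

# Backward pass from d(loss)/d(logit); returns gradients shaped like params.
model_backward <- function(model, fwd, dlogit) {
  cfg <- model$config
  abl <- model$ablation
  P <- model$params
  ca <- fwd$cache
  d_att <- attention_width(cfg, abl)

  g3 <- dense_backward(matrix(dlogit, ncol = 1L), ca$d3)
  dd2 <- dropout_backward(g3$dX, ca$dr2)
  g2 <- dense_backward(dd2, ca$d2)
  dd1 <- dropout_backward(g2$dX, ca$dr1)
  g1 <- dense_backward(dd1, ca$d1)
  dZ <- g1$dX

  dSeqs <- vector("list", 3)
  for (c in 1:3) {
    dpool <- dZ[, ((c - 1L) * d_att + 1L):(c * d_att), drop = FALSE]
    dSeqs[[c]] <- gap_backward(dpool, ca$gap_dims[[c]])
  }

  att_grads <- NULL
  if (abl != "attention") {
    ab <- att_backward(dSeqs, ca$att)
    dSeqs <- ab$dXs
    att_grads <- ab$grads
  }

  grads <- list(channels = vector("list", 3),
                dense1 = list(W = g1$dW, b = g1$db),
                dense2 = list(W = g2$dW, b = g2$db),
                dense3 = list(W = g3$dW, b = g3$db))
  for (c in 1:3) {
    cc <- ca$ch[[c]]
    gc <- list()
    dA <- dSeqs[[c]]
    if (abl != "lstm") {
      if (isTRUE(cc$bidir)) {
        lb <- bilstm_backward(dA, cc$lstm)
        gc$lstm_f <- list(Wx = lb$f$dWx, Wh = lb$f$dWh, b = lb$f$db)
        gc$lstm_b <- list(Wx = lb$b$dWx, Wh = lb$b$dWh, b = lb$b$db)
        dA <- lb$dA
      } else {
        lb <- lstm_dir_backward(dA, cc$lstm)
        gc$lstm_f <- list(Wx = lb$dWx, Wh = lb$dWh, b = lb$db)
        dA <- lb$dA
      }
    }
    if (abl != "cnn") {
      b2 <- conv1d_backward(dA, cc$conv2)
      b1 <- conv1d_backward(b2$dA, cc$conv1)
      gc$conv2 <- list(W = b2$dW, b = b2$db)
      gc$conv1 <- list(W = b1$dW, b = b1$db)
    }
    if (!is.null(att_grads) && !is.null(att_grads[[c]]) &&
        length(att_grads[[c]]))
      gc$att <- att_grads[[c]]
    grads$channels[[c]] <- gc
  }
  grads
}

# mean BCE loss on a batch plus gradients; dloss/dlogit = (p - y) / N
loss_and_grads <- function(model, Xb, yb, training = TRUE) {
  fwd <- model_forward(model, Xb, training = training)
  loss <- bce_loss(yb, fwd$prob)
  dlogit <- (fwd$prob - yb) / length(yb)
  grads <- model_backward(model, fwd, dlogit)
  list(loss = loss, grads = grads, prob = fwd$prob)
}

# Align a grads tree onto the params tree (grads may order keys differently).
align_tree <- function(template, tree) {
  if (!is.list(template)) return(tree)
  out <- template
  for (nm in seq_along(template)) {
    key <- names(template)[nm]
    sub <- if (!is.null(key) && !is.null(tree[[key]])) tree[[key]] else tree[[nm]]
    out[[nm]] <- align_tree(template[[nm]], sub)
  }
  out
}
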