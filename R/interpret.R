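#' Gaussian smoothing of a timeline
#'
#' Convolution with a normalized Gaussian kernel (radius `3*sigma`) under
#' half-sample symmetric (reflect) padding. The smoothing operator is doubly
#' stochastic, so the timeline mean is preserved.
#'
#' @param x numeric vector.
#' @param sigma kernel standard deviation in samples; `sigma <= 0` returns
#'   `x` unchanged.
#' @return smoothed vector, same length.
#' @export
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n <- length(x)
  r <- min(n - 1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k <- k / sum(k)
  pad <- c(x[r:1], x, x[n:(n - r + 1L)])
  y <- as.numeric(stats::filter(pad, k, sides = 2))
  y[(r + 1L):(r + n)]
}

# collapse one window's attention to a per-timestep vector:
# matrix variants average over query rows; temporal weights pass through
collapse_attention <- function(w) {
  if (is.matrix(w)) colMeans(w) else as.numeric(w)
}

#' Class-mean attention profile
#'
#' Samples `n_per_class` windows per class, extracts their attention weights,
#' collapses each T x T matrix to a per-timestep vector by averaging over
#' query rows, averages over channels and then over the sampled windows of
#' each class, and finally smooths with a Gaussian kernel. Per-window
#' collapsed vectors are row-normalized (they sum to 1), so the profile level
#' is fixed at `1/T` by construction and the information lies in its shape
#' over the gait cycle.
#'
#' @param model a trained `mch_model` with a temporal attention stage
#'   (variants self, mha, cross or temporal).
#' @param ws a [window_set()] containing both classes.
#' @param n_per_class windows sampled per class (default 10).
#' @param sigma Gaussian smoothing standard deviation in timesteps
#'   (default 10).
#' @param seed sampling seed.
#' @return object of class `attention_profile`: `timeline` (T x 2 matrix,
#'   columns sober/intoxicated), `raw` (unsmoothed), `class_means`,
#'   `n_sampled`, `sigma`.
#' @export
attention_profile <- function(model, ws, n_per_class = 10L, sigma = 10,
                              seed = 1L) {
  if (model$config$attention_variant == "channel")
    stop("the channel-gate variant has no per-timestep attention to profile",
         call. = FALSE)
  T <- ws$window_size
  timelines <- list(); n_sampled <- c(sober = 0L, intoxicated = 0L)
  for (cls in c(0L, 1L)) {
    avail <- which(ws$labels == cls)
    if (length(avail) == 0L) stop("both classes must be present", call. = FALSE)
    if (length(avail) < n_per_class)
      warning(sprintf("only %d windows of class %d available; using all",
                      length(avail), cls), call. = FALSE)
    idx <- with_seed(derive_seed(seed, paste0("profile-", cls)),
                     sample(avail, min(n_per_class, length(avail))))
    wts <- attention_weights(model, subset_windows(ws, idx))
    per_window <- sapply(seq_along(idx), function(i) {
      chans <- sapply(1:3, function(c) {
        w <- wts[[c]]
        collapse_attention(if (length(dim(w)) == 3L) matrix(w[i, , ], T, T)
                           else w[i, ])
      })
      rowMeans(chans)
    })
    timelines[[cls + 1L]] <- rowMeans(per_window)
    n_sampled[cls + 1L] <- length(idx)
  }
  raw <- cbind(sober = timelines[[1]], intoxicated = timelines[[2]])
  smooth <- apply(raw, 2, gaussian_smooth, sigma = sigma)
  structure(list(timeline = smooth, raw = raw,
                 class_means = colMeans(raw),
                 class_sd = apply(raw, 2, sd),
                 n_sampled = n_sampled, sigma = sigma, seed = seed),
            class = "attention_profile")
}

#' Quartile phase table of an attention profile
#'
#' Partitions the window into gait-phase quartiles (0-25%, 25-50%, 50-75%,
#' 75-100%) and reports per-class mean attention, the difference
#' `delta = intoxicated - sober` and `delta_pct = 100 * delta / sober` per
#' quartile. If T is not divisible by 4 the trailing remainder samples are
#' trimmed.
#'
#' @param profile an [attention_profile()], or a T x 2 timeline matrix with
#'   columns sober/intoxicated.
#' @return data frame of class `phase_table` with columns `phase`, `sober`,
#'   `intox`, `delta`, `delta_pct`.
#' @export
phase_analysis <- function(profile) {
  tl <- if (inherits(profile, "attention_profile")) profile$timeline
        else as.matrix(profile)
  T <- nrow(tl)
  Tq <- (T %/% 4L) * 4L
  if (Tq < T) tl <- tl[seq_len(Tq), , drop = FALSE]
  q <- rep(1:4, each = Tq / 4L)
  sober <- tapply(tl[, 1], q, mean)
  intox <- tapply(tl[, 2], q, mean)
  out <- phase_deltas(sober, intox)
  class(out) <- c("phase_table", class(out))
  out
}

#' Phase-difference arithmetic
#'
#' Given per-phase class means, computes `delta = intox - sober` and
#' `delta_pct = 100 * delta / sober` (flagged `NA` where the sober mean is
#' zero).
#'
#' @param sober,intox numeric vectors of per-phase mean attention.
#' @return data frame with `phase`, `sober`, `intox`, `delta`, `delta_pct`.
#' @export
phase_deltas <- function(sober, intox) {
  stopifnot(length(sober) == length(intox))
  delta <- intox - sober
  delta_pct <- ifelse(sober == 0, NA_real_, 100 * delta / sober)
  if (any(sober == 0))
    warning("zero sober mean; delta_pct undefined for that phase", call. = FALSE)
  phases <- if (length(sober) == 4L)
    c("0-25%", "25-50%", "50-75%", "75-100%") else as.character(seq_along(sober))
  data.frame(phase = phases, sober = as.numeric(sober),
             intox = as.numeric(intox), delta = delta, delta_pct = delta_pct)
}

#' Mask one channel of a window set
#'
#' Replaces the channel's values with zeros, which after per-subject
#' z-scoring equals the subject mean.
#'
#' @param ws a [window_set()].
#' @param channel 1 (X), 2 (Y) or 3 (Z).
#' @return the masked [window_set()].
#' @export
mask_channel <- function(ws, channel) {
  stopifnot(channel %in% 1:3)
  ws$windows[, , channel] <- 0
  ws
}

#' Channel-masking ablation
#'
#' Masks each input channel in turn (zeros), re-evaluates the trained model,
#' and reports the degradation `delta = full-model metric - masked metric`
#' for AUC and accuracy, plus each channel's relative importance
#' `max(delta_acc, 0) / max(delta_acc)`.
#'
#' @param model a trained `mch_model`.
#' @param ws test [window_set()] from held-out subjects.
#' @param threshold decision threshold.
#' @return object of class `ablation_result`: data frame with one row per
#'   channel plus attributes `full` (the unmasked metrics) and
#'   `importance_ratio` (largest over smallest positive accuracy drop).
#' @export
channel_ablation <- function(model, ws, threshold = 0.5) {
  full <- classification_metrics(ws$labels, predict_model(model, ws), threshold)
  rows <- lapply(1:3, function(c) {
    m <- classification_metrics(ws$labels,
                                predict_model(model, mask_channel(ws, c)),
                                threshold)
    data.frame(channel = c("X", "Y", "Z")[c],
               axis = c("lateral", "vertical", "longitudinal")[c],
               delta_auc = full$auc - m$auc,
               delta_acc = full$accuracy - m$accuracy)
  })
  df <- do.call(rbind, rows)
  top <- max(df$delta_acc)
  df$relative <- if (top > 0) pmax(df$delta_acc, 0) / top else NA_real_
  pos <- df$delta_acc[df$delta_acc > 0]
  attr(df, "importance_ratio") <- if (length(pos) >= 2L) max(pos) / min(pos)
                                  else NA_real_
  attr(df, "full") <- full
  class(df) <- c("ablation_result", class(df))
  df
}

#' Component-ablation study
#'
#' Trains the full model and its four single-component ablations (attention,
#' bidirectionality, CNN, LSTM removed) on bit-identical window sets with a
#' shared seed, and evaluates each on the same test set.
#'
#' @param train_ws,val_ws,test_ws [window_set()] splits (train oversampled).
#' @param config a [model_config()].
#' @param threshold decision threshold.
#' @param epochs epochs per variant (defaults to the config's `epochs`).
#' @param verbose print per-variant progress.
#' @return data frame with one row per variant (`full` first) and the usual
#'   metric columns; trained models attached as attribute `models`.
#' @export
component_ablation <- function(train_ws, val_ws, test_ws,
                               config = model_config(), threshold = 0.5,
                               epochs = NULL, verbose = FALSE) {
  variants <- c(none = "full", attention = "remove_attention",
                bidirectionality = "remove_bidirectionality",
                cnn = "remove_cnn", lstm = "remove_lstm")
  rows <- list(); models <- list()
  for (abl in names(variants)) {
    model <- build_model(config, ablation = abl)
    model <- train_model(model, train_ws, val_ws, epochs = epochs)
    m <- classification_metrics(test_ws$labels, predict_model(model, test_ws),
                                threshold)
    if (verbose) message(sprintf("%s: acc=%.3f auc=%.3f",
                                 variants[[abl]], m$accuracy, m$auc))
    rows[[abl]] <- cbind(data.frame(method = variants[[abl]]), metrics_row(m))
    models[[abl]] <- model
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "models") <- models
  out
}

#' Write an attention-profile overlay plot
#'
#' Draws the smoothed sober and intoxicated class-mean attention timelines
#' on one set of axes and writes the figure as a PNG.
#'
#' @param profile an [attention_profile()].
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @return (invisibly) the path.
#' @export
plot_attention_profile <- function(profile, path, width = 900, height = 500) {
  stopifnot(inherits(profile, "attention_profile"))
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  tl <- profile$timeline
  t <- seq_len(nrow(tl))
  graphics::matplot(t, tl, type = "l", lty = 1, lwd = 2,
                    col = c("#2c7d4f", "#b23a3a"),
                    xlab = "timestep", ylab = "mean attention weight",
                    main = sprintf("Class-mean attention (sigma = %g)",
                                   profile$sigma))
  graphics::abline(v = nrow(tl) * (1:3) / 4, lty = 3, col = "grey60")
  graphics::legend("topright", legend = colnames(tl), lty = 1, lwd = 2,
                   col = c("#2c7d4f", "#b23a3a"), bty = "n")
  invisible(path)
}
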