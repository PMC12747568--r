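#' Confusion counts at a threshold
#'
#' Predictions are `score >= threshold`; class 1 is intoxicated.
#'
#' @param y_true 0/1 labels.
#' @param scores numeric scores (probabilities).
#' @param threshold decision threshold (default 0.5).
#' @return list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(y_true, scores, threshold = 0.5) {
  if (length(y_true) == 0L) stop("empty input", call. = FALSE)
  if (length(y_true) != length(scores)) stop("length mismatch", call. = FALSE)
  pred <- as.integer(scores >= threshold)
  structure(list(tp = sum(pred == 1L & y_true == 1L),
                 fp = sum(pred == 1L & y_true == 0L),
                 tn = sum(pred == 0L & y_true == 0L),
                 fn = sum(pred == 0L & y_true == 1L),
                 threshold = threshold), class = "confusion_counts")
}

#' ROC curve points
#'
#' Full threshold sweep with score ties grouped; includes the (0,0) and
#' (1,1) endpoints.
#'
#' @param y_true 0/1 labels.
#' @param scores numeric scores.
#' @return data frame with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_points <- function(y_true, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  P <- sum(y_true == 1L); N <- sum(y_true == 0L)
  bounds <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(y == 1L)[bounds]
  fp <- cumsum(y == 0L)[bounds]
  data.frame(fpr = c(0, fp / max(N, 1L)), tpr = c(0, tp / max(P, 1L)),
             threshold = c(Inf, s[bounds]))
}

#' Area under the ROC curve by the trapezoid rule
#'
#' @param y_true 0/1 labels (both classes present).
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_trapezoid <- function(y_true, scores) {
  if (length(unique(y_true)) < 2L) return(NA_real_)
  r <- roc_points(y_true, scores)
  sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
}

#' Classification metrics report
#'
#' Accuracy, precision, recall (sensitivity), specificity, F1 and trapezoid
#' AUC at the given threshold. Ratios with zero denominators are reported as
#' 0 and listed in the `undefined` field.
#'
#' @param y_true 0/1 labels.
#' @param scores numeric scores.
#' @param threshold decision threshold (default 0.5).
#' @return list of class `metrics_report`.
#' @export
classification_metrics <- function(y_true, scores, threshold = 0.5) {
  cc <- confusion(y_true, scores, threshold)
  total <- cc$tp + cc$fp + cc$tn + cc$fn
  undefined <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); return(0) }
    num / den
  }
  precision <- ratio(cc$tp, cc$tp + cc$fp, "precision")
  recall <- ratio(cc$tp, cc$tp + cc$fn, "recall")
  specificity <- ratio(cc$tn, cc$tn + cc$fp, "specificity")
  f1 <- if (precision + recall == 0) { undefined <- c(undefined, "f1"); 0 }
        else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = (cc$tp + cc$tn) / total,
                 auc = auc_trapezoid(y_true, scores),
                 f1 = f1, precision = precision, recall = recall,
                 specificity = specificity, threshold = threshold,
                 counts = cc, undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> acc=%.4f auc=%s f1=%.4f prec=%.4f rec=%.4f spec=%.4f (t=%.2f)\n",
              x$accuracy, ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)),
              x$f1, x$precision, x$recall, x$specificity, x$threshold))
  invisible(x)
}

metrics_row <- function(m) {
  data.frame(accuracy = m$accuracy, auc = m$auc, f1 = m$f1,
             precision = m$precision, recall = m$recall,
             specificity = m$specificity)
}

# Class-balanced greedy partition of subjects into k folds: within each
# class, subjects (largest first, ties shuffled under the seed) go to the
# fold with the smallest current sample count.
partition_folds <- function(recordings, k, seed = 1L) {
  info <- subject_summary(recordings)
  if (nrow(info) < k) stop("fewer subjects than folds", call. = FALSE)
  fold <- setNames(integer(nrow(info)), info$subject_id)
  totals <- numeric(k)
  for (cl in sort(unique(info$class))) {
    sub <- info[info$class == cl, , drop = FALSE]
    ord <- with_seed(derive_seed(seed, paste0("folds-", cl)), {
      sub <- sub[sample.int(nrow(sub)), , drop = FALSE]
      order(-sub$n_samples)
    })
    sub <- sub[ord, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      f <- which.min(totals)
      fold[sub$subject_id[i]] <- f
      totals[f] <- totals[f] + sub$n_samples[i]
    }
  }
  fold
}

#' Subject-level k-fold cross-validation
#'
#' Partitions subjects into k class-balanced, pairwise-disjoint folds. For
#' each fold, the held-out subjects form the test set; a subject-disjoint
#' validation share (default 10% of samples) is carved from the remaining
#' subjects for early stopping; preprocessing (z-score, outlier removal,
#' filtering, windowing, train-only oversampling) runs entirely within the
#' fold's own partitions so no statistic crosses a fold boundary. Each fold
#' trains for at most `config$cv_epochs` epochs with early stopping.
#'
#' @param recordings list of [gait_recording()] objects.
#' @param k number of folds (default 5).
#' @param config a [model_config()].
#' @param fspec,ispec preprocessing specifications ([filter_spec()],
#'   [iforest_spec()] or NULL).
#' @param overlap window overlap.
#' @param val_fraction validation share carved from the training subjects.
#' @param threshold decision threshold for the confusion metrics.
#' @param seed integer seed.
#' @param verbose print per-fold progress.
#' @return list with `folds` (per-fold metrics data frame plus mean and sd
#'   rows), `assignments` (subject -> fold), and `models`.
#' @export
cross_validate <- function(recordings, k = 5L, config = model_config(),
                           fspec = filter_spec(), ispec = iforest_spec(),
                           overlap = 0.5, val_fraction = 0.1,
                           threshold = 0.5, seed = 1L, verbose = FALSE) {
  fold <- partition_folds(recordings, k, seed)
  rows <- list(); models <- list()
  for (f in seq_len(k)) {
    test_ids <- names(fold)[fold == f]
    train_recs <- Filter(function(r) !r$subject_id %in% test_ids, recordings)
    test_recs <- Filter(function(r) r$subject_id %in% test_ids, recordings)

    inner <- split_subjects(train_recs,
                            split_spec(c(train = 1 - val_fraction,
                                         validation = val_fraction, test = 0),
                                       seed = derive_seed(seed, paste0("cv-val-", f))))
    pp <- preprocess_cohort(train_recs, inner, fspec, ispec,
                            window_size = config$window_size, overlap = overlap,
                            oversample = TRUE,
                            seed = derive_seed(seed, paste0("cv-os-", f)))
    test_ws <- bind_window_sets(lapply(test_recs, preprocess_recording,
                                       fspec = fspec, ispec = ispec,
                                       window_size = config$window_size,
                                       overlap = overlap))
    cfg <- config
    cfg$seed <- derive_seed(seed, paste0("cv-model-", f))
    model <- build_model(cfg)
    model <- train_model(model, pp$train, pp$validation,
                         epochs = config$cv_epochs, verbose = verbose)
    m <- classification_metrics(test_ws$labels,
                                predict_model(model, test_ws), threshold)
    if (verbose)
      message(sprintf("fold %d: acc=%.3f auc=%.3f", f, m$accuracy, m$auc))
    rows[[f]] <- cbind(data.frame(fold = as.character(f)), metrics_row(m))
    models[[f]] <- model
  }
  df <- do.call(rbind, rows)
  num <- df[, -1, drop = FALSE]
  df <- rbind(df,
              cbind(data.frame(fold = "mean"), as.data.frame(as.list(colMeans(num)))),
              cbind(data.frame(fold = "sd"), as.data.frame(as.list(apply(num, 2, sd)))))
  list(folds = df, assignments = fold, models = models)
}

#' Precision-recall curve points
#'
#' Full threshold sweep with score ties grouped.
#'
#' @param y_true 0/1 labels.
#' @param scores numeric scores.
#' @return data frame with columns `recall`, `precision`, `threshold`.
#' @export
pr_points <- function(y_true, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  bounds <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y == 1L)[bounds]
  n_pred <- bounds
  P <- sum(y_true == 1L)
  data.frame(recall = tp / max(P, 1L), precision = tp / n_pred,
             threshold = s[bounds])
}
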