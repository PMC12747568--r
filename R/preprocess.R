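#' Split specification
#'
#' Fractions of samples assigned to train / validation / test, plus (after
#' [split_subjects()]) the subject-to-split assignment. Subjects are atomic:
#' a subject's windows never cross a split boundary.
#'
#' @param fractions named numeric `(train, validation, test)` summing to 1.
#' @param seed integer seed for tie-breaking among equal-sized subjects.
#' @param assignment optional named character vector subject_id -> split.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(train = 0.70, validation = 0.10, test = 0.20),
                       seed = 1L, assignment = NULL) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9)
    stop("`fractions` must be three values summing to 1", call. = FALSE)
  names(fractions) <- c("train", "validation", "test")
  structure(list(fractions = fractions, seed = as.integer(seed),
                 assignment = assignment), class = "split_spec")
}

# Per-subject summary used by the splitters: sample count and class.
subject_summary <- function(recordings) {
  ids <- vapply(recordings, function(r) r$subject_id, character(1))
  n <- vapply(recordings, function(r) length(r$t), numeric(1))
  lab <- vapply(recordings, function(r) r$label, integer(1))
  agg <- tapply(n, ids, sum)
  cls <- tapply(lab, ids, function(l) as.integer(any(l == 1L)))
  data.frame(subject_id = names(agg), n_samples = as.numeric(agg),
             class = as.integer(cls[names(agg)]), stringsAsFactors = FALSE)
}

# Greedy sample-count-deficit assignment of one class's subjects to splits.
greedy_assign <- function(subjects, sizes, fractions) {
  cur <- setNames(numeric(length(fractions)), names(fractions))
  assigned <- 0
  out <- character(length(subjects))
  for (i in seq_along(subjects)) {
    deficit <- fractions * (assigned + sizes[i]) - cur
    pick <- names(fractions)[which.max(deficit)]  # ties: first = train order
    out[i] <- pick
    cur[pick] <- cur[pick] + sizes[i]
    assigned <- assigned + sizes[i]
  }
  setNames(out, subjects)
}

#' Stratified subject-wise split
#'
#' Assigns whole subjects to train/validation/test so that each split's sample
#' count approximates the target fractions and each class is distributed
#' across splits in proportion. Within each class, subjects are taken in
#' decreasing order of sample count (ties shuffled under the seed) and each is
#' assigned greedily to the split with the largest sample-count deficit. Any
#' split left empty (possible for tiny cohorts) steals a subject from the
#' most over-filled split so every split is usable downstream.
#'
#' @param recordings list of [gait_recording()] objects.
#' @param spec a [split_spec()].
#' @return the `split_spec` with `assignment` filled in.
#' @export
split_subjects <- function(recordings, spec = split_spec()) {
  info <- subject_summary(recordings)
  if (nrow(info) < 3L)
    stop("infeasible split: need at least 3 subjects", call. = FALSE)
  assignment <- character(0)
  for (cl in sort(unique(info$class))) {
    sub <- info[info$class == cl, , drop = FALSE]
    ord <- with_seed(derive_seed(spec$seed, paste0("split-class-", cl)), {
      sh <- sample.int(nrow(sub))
      sub <- sub[sh, , drop = FALSE]
      order(-sub$n_samples)
    })
    sub <- sub[ord, , drop = FALSE]
    assignment <- c(assignment,
                    greedy_assign(sub$subject_id, sub$n_samples, spec$fractions))
  }
  # repair: no split with positive target may be empty if subjects allow it
  for (s in names(spec$fractions)) {
    if (spec$fractions[s] > 0 && !any(assignment == s)) {
      donor_tab <- table(assignment)
      donor <- names(donor_tab)[which.max(donor_tab)]
      cand <- names(assignment)[assignment == donor]
      sizes <- info$n_samples[match(cand, info$subject_id)]
      assignment[cand[which.min(sizes)]] <- s
    }
  }
  spec$assignment <- assignment[info$subject_id]
  spec
}

#' Per-subject z-score normalization
#'
#' Standardizes each axis of a recording to mean 0 and unit population
#' standard deviation (`sigma = sqrt(mean((x - mu)^2))`). A zero-variance axis
#' is mapped to all zeros with a warning.
#'
#' @param rec a [gait_recording()].
#' @return the normalized recording.
#' @export
zscore_per_subject <- function(rec) {
  stopifnot(inherits(rec, "gait_recording"))
  if (length(rec$t) == 0) stop("empty recording", call. = FALSE)
  for (axis in c("ax", "ay", "az")) {
    x <- rec[[axis]]
    mu <- mean(x)
    sigma <- sqrt(mean((x - mu)^2))
    if (sigma == 0) {
      warning(sprintf("axis %s has zero variance; returning zeros", axis),
              call. = FALSE)
      rec[[axis]] <- x * 0
    } else {
      rec[[axis]] <- (x - mu) / sigma
    }
  }
  rec
}

#' Low-pass filter specification
#'
#' An order-`n` analog Butterworth low-pass prototype
#' `|H(j w)|^2 = 1 / (1 + (w/wc)^(2n))`, discretized by the bilinear
#' transform and applied forward then backward (zero phase).
#'
#' @param order filter order (default 3).
#' @param cutoff_hz -3 dB cutoff in Hz (default 20).
#' @param sampling_rate_hz sampling rate in Hz (default 210).
#' @param zero_phase apply forward-backward (default TRUE).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(order = 3L, cutoff_hz = 20, sampling_rate_hz = 210,
                        zero_phase = TRUE) {
  stopifnot_positive(order, "order")
  stopifnot_positive(cutoff_hz, "cutoff_hz")
  stopifnot_positive(sampling_rate_hz, "sampling_rate_hz")
  if (cutoff_hz >= sampling_rate_hz / 2)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 sampling_rate_hz = sampling_rate_hz, zero_phase = zero_phase),
            class = "filter_spec")
}

# Zero-phase filtering with odd-reflection edge padding (forward pass, then
# backward pass on the reversed forward output), so edge transients from the
# uninitialized IIR states decay inside the padding.
filtfilt_pad <- function(b, a, x) {
  n <- length(x)
  padlen <- min(n - 1L, 300L)
  pre <- 2 * x[1] - x[(padlen + 1L):2]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  ext <- c(pre, x, post)
  y <- signal::filter(b, a, ext)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(padlen + 1L):(padlen + n)])
}

#' Zero-phase Butterworth low-pass filtering
#'
#' Filters each axis independently. With `zero_phase = TRUE` the filter runs
#' forward then backward, so the net phase shift is zero and the amplitude
#' response is the squared magnitude of a single pass (0.5 at the cutoff).
#'
#' @param rec a [gait_recording()].
#' @param spec a [filter_spec()]; its sampling rate is overridden by the
#'   recording's.
#' @return the filtered recording (sample count unchanged).
#' @export
lowpass <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "gait_recording"))
  fs <- rec$sampling_rate_hz
  if (spec$cutoff_hz >= fs / 2)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  bt <- signal::butter(spec$order, spec$cutoff_hz / (fs / 2), type = "low")
  for (axis in c("ax", "ay", "az")) {
    x <- rec[[axis]]
    rec[[axis]] <- if (spec$zero_phase) filtfilt_pad(bt$b, bt$a, x)
                   else as.numeric(signal::filter(bt, x))
  }
  rec
}

#' Window set
#'
#' Stacked fixed-length windows with per-window labels and subject ids.
#' `windows` is an `N x T x 3` array (axes ordered X, Y, Z).
#'
#' @param windows `N x T x 3` numeric array.
#' @param labels integer vector of 0/1 labels, length N.
#' @param subject_ids character vector, length N.
#' @param window_size window length T.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return an object of class `window_set`.
#' @export
window_set <- function(windows, labels, subject_ids,
                       window_size = dim(windows)[2], overlap = 0.5) {
  stopifnot(length(dim(windows)) == 3L, dim(windows)[3] == 3L)
  n <- dim(windows)[1]
  if (length(labels) != n || length(subject_ids) != n)
    stop("labels and subject_ids must match the number of windows", call. = FALSE)
  if (n > 0 && !all(labels %in% c(0L, 1L)))
    stop("labels must be 0/1", call. = FALSE)
  structure(list(windows = windows, labels = as.integer(labels),
                 subject_ids = as.character(subject_ids),
                 window_size = as.integer(window_size), overlap = overlap),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> N=%d T=%d overlap=%.2f | sober=%d intoxicated=%d | %d subjects\n",
              dim(x$windows)[1], x$window_size, x$overlap,
              sum(x$labels == 0L), sum(x$labels == 1L),
              length(unique(x$subject_ids))))
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a [window_set()].
#' @return integer count.
#' @export
n_windows <- function(ws) dim(ws$windows)[1]

#' Sliding-window segmentation
#'
#' Cuts a recording into fixed-length windows with stride
#' `round(size * (1 - overlap))`. A recording shorter than `size` yields an
#' empty set. Each window inherits the recording's subject id and label.
#'
#' @param rec a [gait_recording()].
#' @param size window length in samples (default 1024, i.e. ~4.88 s at 210 Hz).
#' @param overlap fractional overlap in `[0, 1)` (default 0.5).
#' @return a [window_set()].
#' @export
segment_windows <- function(rec, size = 1024L, overlap = 0.5) {
  stopifnot(inherits(rec, "gait_recording"))
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)", call. = FALSE)
  if (size < 2) stop("size must be >= 2", call. = FALSE)
  L <- length(rec$t)
  stride <- round(size * (1 - overlap))
  n <- if (L >= size) floor((L - size) / stride) + 1L else 0L
  w <- array(0, dim = c(n, size, 3L))
  if (n > 0) {
    mat <- cbind(rec$ax, rec$ay, rec$az)
    for (i in seq_len(n)) {
      start <- (i - 1L) * stride + 1L
      w[i, , ] <- mat[start:(start + size - 1L), ]
    }
  }
  window_set(w, rep(rec$label, n), rep(rec$subject_id, n),
             window_size = size, overlap = overlap)
}

#' Concatenate window sets
#'
#' @param ... [window_set()] objects with equal window size.
#' @return a single [window_set()].
#' @export
bind_window_sets <- function(...) {
  sets <- Filter(Negate(is.null), list(...))
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "window_set"))
    sets <- sets[[1]]
  sizes <- unique(vapply(sets, function(s) s$window_size, integer(1)))
  if (length(sizes) != 1L) stop("window sizes differ", call. = FALSE)
  n <- sum(vapply(sets, n_windows, integer(1)))
  w <- array(0, dim = c(n, sizes, 3L))
  labels <- integer(0); ids <- character(0); at <- 0L
  for (s in sets) {
    k <- n_windows(s)
    if (k > 0) w[(at + 1L):(at + k), , ] <- s$windows
    labels <- c(labels, s$labels); ids <- c(ids, s$subject_ids); at <- at + k
  }
  window_set(w, labels, ids, window_size = sizes, overlap = sets[[1]]$overlap)
}

#' Subset a window set
#' @param ws a [window_set()].
#' @param idx integer or logical index over windows.
#' @return a [window_set()].
#' @export
subset_windows <- function(ws, idx) {
  window_set(ws$windows[idx, , , drop = FALSE], ws$labels[idx],
             ws$subject_ids[idx], ws$window_size, ws$overlap)
}

#' Random oversampling of the minority class
#'
#' Duplicates randomly chosen minority-class windows (with replacement) until
#' the class counts are equal. Majority windows are untouched. Intended for
#' the training set only; validation and test sets must never be oversampled.
#'
#' @param train a [window_set()].
#' @param seed integer seed.
#' @return a balanced [window_set()].
#' @export
oversample_minority <- function(train, seed = 1L) {
  stopifnot(inherits(train, "window_set"))
  n0 <- sum(train$labels == 0L); n1 <- sum(train$labels == 1L)
  if (n0 == 0L || n1 == 0L) {
    warning("single-class window set; oversampling skipped", call. = FALSE)
    return(train)
  }
  if (n0 == n1) return(train)
  minority <- if (n0 < n1) 0L else 1L
  need <- abs(n0 - n1)
  idx_min <- which(train$labels == minority)
  extra <- with_seed(seed, sample(idx_min, need, replace = TRUE))
  bind_window_sets(train, subset_windows(train, extra))
}

#' Apply the per-subject cleaning chain to one recording
#'
#' Order: z-score normalization, Isolation Forest outlier removal, zero-phase
#' low-pass filtering, sliding-window segmentation.
#'
#' @param rec a [gait_recording()].
#' @param fspec a [filter_spec()].
#' @param ispec an [iforest_spec()]; `NULL` skips outlier removal.
#' @param window_size,overlap segmentation parameters.
#' @return a [window_set()].
#' @export
preprocess_recording <- function(rec, fspec = filter_spec(),
                                 ispec = iforest_spec(),
                                 window_size = 1024L, overlap = 0.5) {
  rec <- zscore_per_subject(rec)
  if (!is.null(ispec)) rec <- remove_outliers(rec, ispec)
  rec <- lowpass(rec, fspec)
  segment_windows(rec, size = window_size, overlap = overlap)
}

#' Run the full preprocessing pipeline over a cohort
#'
#' Splits subjects, cleans and windows every recording within its split, and
#' oversamples the training set only. The per-subject steps never see data
#' from other splits, so no statistics leak across the split boundary.
#'
#' @param recordings list of [gait_recording()] objects.
#' @param split a [split_spec()]; if its assignment is empty it is filled by
#'   [split_subjects()].
#' @param fspec,ispec,window_size,overlap see [preprocess_recording()].
#' @param oversample logical; balance the training classes (default TRUE).
#' @param seed integer seed for oversampling.
#' @return list with elements `train`, `validation`, `test` ([window_set()]s)
#'   and `split` (the filled [split_spec()]).
#' @export
preprocess_cohort <- function(recordings, split = split_spec(),
                              fspec = filter_spec(), ispec = iforest_spec(),
                              window_size = 1024L, overlap = 0.5,
                              oversample = TRUE, seed = 1L) {
  if (is.null(split$assignment)) split <- split_subjects(recordings, split)
  out <- list()
  for (s in c("train", "validation", "test")) {
    ids <- names(split$assignment)[split$assignment == s]
    recs <- Filter(function(r) r$subject_id %in% ids, recordings)
    sets <- lapply(recs, preprocess_recording, fspec = fspec, ispec = ispec,
                   window_size = window_size, overlap = overlap)
    out[[s]] <- if (length(sets))
      bind_window_sets(sets)
    else window_set(array(0, c(0L, window_size, 3L)), integer(0), character(0),
                    window_size, overlap)
  }
  if (oversample && n_windows(out$train) > 0)
    out$train <- oversample_minority(out$train, seed = derive_seed(seed, "oversample"))
  out$split <- split
  out
}
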