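make_equal_cohort <- function(n, n_intox, duration_s = 2, seed = 1L) {
  p <- quiet_params(duration_s = duration_s, seed = seed)
  recs <- list()
  for (i in seq_len(n)) {
    cond <- if (i <= n_intox) "intoxicated" else "sober"
    recs[[i]] <- simulate_subject(p, cond, sprintf("P%03d", i))
  }
  recs
}

test_that("subject-wise split is disjoint and hits the target counts", {
  recs <- make_equal_cohort(10, 3)
  sp <- split_subjects(recs, split_spec(seed = 5))
  tab <- table(sp$assignment)
  expect_equal(as.integer(tab[c("train", "validation", "test")]), c(7L, 1L, 2L))
  # a subject appears in exactly one split
  expect_length(sp$assignment, 10)
  expect_false(any(duplicated(names(sp$assignment))))
  expect_error(split_subjects(recs[1:2]), "3 subjects")
  expect_error(split_spec(c(0.5, 0.3, 0.1)), "summing to 1")
})

test_that("splits preserve the class ratio within ten points", {
  recs <- make_equal_cohort(100, 25, duration_s = 1)
  labels <- vapply(recs, `[[`, integer(1), "label")
  names(labels) <- vapply(recs, `[[`, character(1), "subject_id")
  for (seed in 1:3) {
    sp <- split_subjects(recs, split_spec(seed = seed))
    for (s in c("train", "validation", "test")) {
      ids <- names(sp$assignment)[sp$assignment == s]
      expect_lt(abs(mean(labels[ids]) - 0.25), 0.10)
    }
  }
})

test_that("z-score normalization matches the definitional formula", {
  p <- quiet_params(duration_s = 1)
  rec <- simulate_subject(p, "sober", "S1")
  rec$ax <- c(1, 2, 3, rep(0, length(rec$ax) - 3))

  small <- gait_recording("S1", "1", 3, c(0, 1/3, 2/3), c(1, 2, 3),
                          c(1, 2, 3), c(1, 2, 3), 0, 0L)
  z <- zscore_per_subject(small)
  expect_equal(z$ax, c(-1, 0, 1) / sqrt(2/3), tolerance = 1e-6)
  expect_equal(z$ax, c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  const <- gait_recording("S1", "1", 3, c(0, 1/3, 2/3), c(5, 5, 5),
                          c(1, 2, 3), c(1, 2, 3), 0, 0L)
  expect_warning(zc <- zscore_per_subject(const), "zero variance")
  expect_equal(zc$ax, c(0, 0, 0))

  rec <- simulate_subject(quiet_params(), "sober", "S2")
  z <- zscore_per_subject(rec)
  for (axis in c("ax", "ay", "az")) {
    expect_equal(mean(z[[axis]]), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean((z[[axis]] - mean(z[[axis]]))^2)), 1,
                 tolerance = 1e-9)
  }
  # idempotence: normalizing twice changes nothing beyond numerics
  z2 <- zscore_per_subject(z)
  expect_equal(z2$ay, z$ay, tolerance = 1e-6)
})

test_that("zero-phase Butterworth filter honours its amplitude contract", {
  fs <- 210
  t <- (0:(fs * 10 - 1)) / fs
  mkrec <- function(x) gait_recording("S1", "1", fs, t, x, x, x, 0, 0L)
  amp_of <- function(x, f) {
    # least-squares amplitude on the central half (edge transients excluded)
    mid <- seq(round(length(x) * 0.25), round(length(x) * 0.75))
    X <- cbind(sin(2 * pi * f * t[mid]), cos(2 * pi * f * t[mid]))
    sqrt(sum(qr.solve(X, x[mid])^2))
  }
  # DC gain 1
  dc <- lowpass(mkrec(rep(1, length(t))), filter_spec())
  expect_equal(dc$ax, rep(1, length(t)), tolerance = 1e-6)
  # two passes at the cutoff: |H|^2 = 1/2
  s20 <- sin(2 * pi * 20 * t)
  f20 <- lowpass(mkrec(s20), filter_spec())
  expect_equal(amp_of(f20$ax, 20), 0.5, tolerance = 0.02)
  # passband gain ~ 1 at 2 Hz
  s2 <- sin(2 * pi * 2 * t)
  f2 <- lowpass(mkrec(s2), filter_spec())
  expect_equal(amp_of(f2$ax, 2), 1, tolerance = 0.01)
  # zero phase: peak cross-correlation with a slow sinusoid at lag 0
  ccf_peak <- which.max(ccf(f2$ax, s2, lag.max = 20, plot = FALSE)$acf) - 21
  expect_equal(ccf_peak, 0)
  expect_error(lowpass(mkrec(s2), filter_spec(cutoff_hz = 20,
                                              sampling_rate_hz = 39)),
               "Nyquist")
  expect_error(filter_spec(cutoff_hz = 110), "Nyquist")
})

test_that("sliding-window segmentation follows the count formula", {
  fs <- 210
  mk <- function(L) gait_recording("S1", "1", fs, (0:(L - 1)) / fs,
                                   rnorm(L), rnorm(L), rnorm(L), 0.1, 1L)
  ws <- segment_windows(mk(2048), size = 1024, overlap = 0.5)
  expect_equal(n_windows(ws), 3L)
  rec <- mk(2048)
  ws <- segment_windows(rec, size = 1024, overlap = 0.5)
  expect_equal(ws$windows[1, , 1], rec$ax[1:1024])
  expect_equal(ws$windows[2, , 1], rec$ax[513:1536])
  expect_equal(ws$windows[3, , 1], rec$ax[1025:2048])
  expect_true(all(ws$labels == 1L))
  expect_true(all(ws$subject_ids == "S1"))

  expect_equal(n_windows(segment_windows(mk(1024))), 1L)
  expect_equal(n_windows(segment_windows(mk(1023))), 0L)
  # general count formula on a grid of lengths and overlaps
  for (L in c(300, 500, 1000)) for (ov in c(0, 0.25, 0.5, 0.75)) {
    stride <- round(256 * (1 - ov))
    expected <- if (L >= 256) floor((L - 256) / stride) + 1 else 0
    expect_equal(n_windows(segment_windows(mk(L), 256, ov)), expected)
  }
})

test_that("minority oversampling balances classes by duplication only", {
  p <- quiet_params(duration_s = 4)
  sober <- segment_windows(simulate_subject(p, "sober", "A"), 128, 0.5)
  intox <- segment_windows(simulate_subject(p, "intoxicated", "B"), 128, 0.5)
  train <- bind_window_sets(sober, subset_windows(intox, 1:2))
  bal <- oversample_minority(train, seed = 4)
  expect_equal(sum(bal$labels == 0L), sum(bal$labels == 1L))
  # majority windows untouched, in place
  expect_equal(bal$windows[seq_len(n_windows(train)), , ], train$windows)
  # every duplicate is bit-identical to an original minority window
  extra <- (n_windows(train) + 1):n_windows(bal)
  originals <- lapply(1:2, function(i) intox$windows[i, , ])
  for (i in extra) {
    w <- bal$windows[i, , ]
    expect_true(any(vapply(originals, function(o) identical(o, w), logical(1))))
  }
  expect_identical(oversample_minority(bal, seed = 1), bal)  # already balanced
  expect_warning(oversample_minority(sober, seed = 1), "single-class")
})

test_that("the cohort pipeline is subject-disjoint and train-only oversampled", {
  p <- y_signal_params(duration_s = 4)
  recs <- simulate_cohort(12, 0.35, p)
  pp <- preprocess_cohort(recs, split_spec(seed = 2), filter_spec(),
                          ispec = NULL, window_size = 128L, seed = 2)
  ids <- list(train = unique(pp$train$subject_ids),
              validation = unique(pp$validation$subject_ids),
              test = unique(pp$test$subject_ids))
  expect_length(intersect(ids$train, ids$validation), 0)
  expect_length(intersect(ids$train, ids$test), 0)
  expect_length(intersect(ids$validation, ids$test), 0)
  # train balanced 1:1; validation and test keep their natural imbalance
  expect_equal(sum(pp$train$labels == 0L), sum(pp$train$labels == 1L))
  raw <- preprocess_cohort(recs, pp$split, filter_spec(), ispec = NULL,
                           window_size = 128L, oversample = FALSE, seed = 2)
  expect_identical(pp$validation, raw$validation)
  expect_identical(pp$test, raw$test)
})
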