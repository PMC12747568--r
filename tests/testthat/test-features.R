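test_that("hand-computable features come out exactly", {
  w <- cbind(rep(c(1, -1), 4), rep(c(1, -1), 4), rep(c(1, -1), 4))
  f <- extract_features(w, spectral_spec())
  expect_equal(unname(f["sma"]), 3)             # mean(|x|+|y|+|z|)

  w2 <- cbind(c(0.2, -0.4, 0.1, 0, 0, 0, 0, 0), rnorm(8), rnorm(8))
  f2 <- extract_features(w2, spectral_spec())
  expect_equal(unname(f2["range_x"]), 0.6)
  expect_equal(unname(f2["max_x"]), 0.2)
  expect_equal(unname(f2["min_x"]), -0.4)

  # symmetric data has zero skewness
  w3 <- cbind(rep(c(2, -2, 1, -1), 4), rnorm(16), rnorm(16))
  expect_equal(unname(extract_features(w3, spectral_spec())["skewness_x"]), 0,
               tolerance = 1e-12)

  # printed bank has exactly 30 uniquely named features
  expect_length(f, 30)
  expect_false(any(duplicated(names(f))))
})

test_that("every feature matches a naive direct-summation oracle", {
  sp <- spectral_spec(sampling_rate_hz = 210, band = c(0.5, 3))
  set.seed(31)
  for (rep in 1:5) {
    w <- matrix(rnorm(64 * 3), 64, 3)
    fast <- extract_features(w, sp)
    slow <- naive_features(w, 210, band = c(0.5, 3))
    expect_equal(names(fast), names(slow))
    for (nm in names(slow))
      expect_equal(unname(fast[nm]), unname(slow[nm]), tolerance = 1e-6,
                   label = nm)
  }
})

test_that("frequency-domain energy satisfies Parseval's identity", {
  set.seed(5)
  for (n in c(64, 101, 256)) {
    x <- rnorm(n)
    ps <- intoxgait:::psd_onesided(x, 210)
    expect_equal(sum(ps$psd), sum(x^2), tolerance = 1e-6)
  }
})

test_that("spectral entropy spans degenerate to uniform spectra", {
  sp <- spectral_spec(sampling_rate_hz = 16)
  # pure sinusoid at an exact bin: single-line spectrum, zero entropy
  t <- 0:63
  x <- sin(2 * pi * 4 * t / 64)
  expect_equal(spectral_entropy(x, sp), 0, tolerance = 1e-6)
  # uniform one-sided power: synthesize via conjugate-symmetric magnitudes
  T <- 16
  mags <- c(sqrt(2), rep(1, 7), sqrt(2), rep(1, 7))     # DC, interior, Nyquist
  set.seed(8)
  ph <- runif(7, 0, 2 * pi)
  spec <- complex(modulus = mags,
                  argument = c(0, ph, 0, -rev(ph)))
  x <- Re(fft(spec, inverse = TRUE)) / T
  B <- T / 2 + 1
  expect_equal(spectral_entropy(x, sp), log(B), tolerance = 1e-6)
  # log(B) is the ceiling for any signal of this length
  set.seed(9)
  for (i in 1:10)
    expect_lte(spectral_entropy(rnorm(T), sp), log(B) + 1e-9)
  expect_warning(e0 <- spectral_entropy(rep(0, 16), sp), "constant")
  expect_equal(e0, 0)
})

test_that("sway volume is the time integral of the vector magnitude", {
  expect_equal(sway_volume(matrix(0, 210, 3), 1 / 210), 0)
  w <- cbind(rep(1, 210), rep(0, 210), rep(0, 210))
  expect_equal(sway_volume(w, 1 / 210), 1.0)
  set.seed(2)
  w <- matrix(rnorm(300), 100, 3)
  expect_equal(sway_volume(3 * w, 0.01), 3 * sway_volume(w, 0.01),
               tolerance = 1e-12)
})

test_that("the plug-in mutual information matches its defining double sum", {
  # exact independence: every (x-bin, y) cell equally filled
  x <- rep(c(0.1, 0.35, 0.6, 0.85), each = 2)
  y <- rep(c(0L, 1L), 4)
  expect_equal(mutual_information(x, y, n_bins = 4), 0, tolerance = 1e-9)
  # deterministic dependence: two bins split at the midrange = median here
  x <- seq(0, 1, length.out = 100)
  y <- as.integer(x > 0.5)
  expect_equal(mutual_information(x, y, n_bins = 2), log(2), tolerance = 1e-9)
  expect_equal(mutual_information(x, y, n_bins = 2), 0.6931, tolerance = 1e-4)
  # symmetry when both arguments are identically binned
  xb <- rep(c(0L, 1L), times = c(30, 70))
  yb <- c(rep(0L, 20), rep(1L, 80))
  expect_equal(mutual_information(xb, yb, 2), mutual_information(yb, xb, 2),
               tolerance = 1e-12)
  # random cases agree with the naive estimator
  set.seed(77)
  for (i in 1:5) {
    x <- rnorm(200)
    y <- as.integer(runif(200) < 0.4)
    expect_equal(mutual_information(x, y, 20), naive_mi(x, y, 20),
                 tolerance = 1e-9)
  }
  expect_error(mutual_information(1:3, 1:4, 5), "mismatch")
})

test_that("top-k selection ranks a label-equal feature first", {
  set.seed(12)
  n <- 200
  labels <- as.integer(runif(n) < 0.4)
  vals <- cbind(noise1 = rnorm(n), perfect = as.numeric(labels),
                noise2 = rnorm(n), weak = labels + rnorm(n, sd = 2))
  ft <- feature_table(vals, colnames(vals), labels)
  top <- select_top_k(ft, k = 2)
  expect_equal(top$names[1], "perfect")
  expect_equal(ncol(top$values), 2L)
  all_reordered <- select_top_k(ft, k = 4)
  expect_setequal(all_reordered$names, colnames(vals))
  expect_error(select_top_k(ft, k = 5), "exceeds")
})

test_that("feature tables round-trip through CSV", {
  p <- y_signal_params(duration_s = 3)
  ws <- segment_windows(simulate_subject(p, "sober", "S1"), 128, 0.5)
  ft <- window_features(ws, spectral_spec())
  path <- tempfile(fileext = ".csv")
  write_feature_table(ft, path)
  back <- read_feature_table(path)
  expect_equal(back$values, ft$values, tolerance = 1e-12)
  expect_equal(back$labels, ft$labels)
  expect_equal(back$names, ft$names)
  unlink(path)
})

test_that("feature extraction is permutation-covariant across windows", {
  p <- y_signal_params(duration_s = 3)
  ws <- bind_window_sets(
    segment_windows(simulate_subject(p, "sober", "A"), 64, 0.5),
    segment_windows(simulate_subject(p, "intoxicated", "B"), 64, 0.5))
  sp <- spectral_spec()
  perm <- rev(seq_len(n_windows(ws)))
  ft <- window_features(ws, sp)
  ft_perm <- window_features(subset_windows(ws, perm), sp)
  expect_equal(ft_perm$values, ft$values[perm, ], tolerance = 1e-12)
  expect_equal(ft_perm$labels, ft$labels[perm])
})
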