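# Shared fixtures and independent oracles for the test suite. All data are
# generated in code at test time; the oracles deliberately use naive direct
# summation (loops, explicit DFT) so they share no code with the fast paths
# they check.

# quiet, outlier-free generator setup used by most preprocessing tests
quiet_params <- function(..., seed = 1L) {
  defaults <- list(duration_s = 8, noise_sd = 0.02, outlier_rate = 0,
                   phase_jitter_sd = 0, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_params, args)
}

# cohort whose class signal lives only in the vertical (Y) waveform shape:
# intoxication attenuates the second Y harmonic; cadence, phase and
# amplitudes are otherwise identical across classes, and Z is pure noise.
y_signal_params <- function(seed = 1L, duration_s = 8, noise_sd = 0.03,
                            vertical_damping = 0.25) {
  simulation_params(duration_s = duration_s, cadence_slowdown = 1,
                    phase_jitter_sd = 0, sway_multiplier = 1,
                    vertical_damping = vertical_damping,
                    harmonic_amplitudes = list(x = c("1" = 0.18),
                                               y = c("1" = 0.45, "2" = 0.30),
                                               z = c("1" = 0)),
                    noise_sd = noise_sd, outlier_rate = 0, seed = seed)
}

# desk-scale configuration for training tests at T = 128
tiny_train_config <- function(seed = 1L, ...) {
  scaled_model_config(window_size = 128L, batch_size = 32L, seed = seed, ...)
}

# micro configuration for structural and gradient tests at T = 8
micro_config <- function(variant = "self", seed = 42L, dropout_rate = 0, ...) {
  model_config(window_size = 8L, conv1_filters = 3L, conv2_filters = 4L,
               kernel_size = 3L, lstm_units = 3L, attention_variant = variant,
               mha_heads = 2L, dense1_units = 4L, dense2_units = 5L,
               dropout_rate = dropout_rate, seed = seed, ...)
}

# nudge all parameters away from zero so no ReLU pre-activation sits exactly
# on the kink (finite differences would otherwise straddle it)
perturb_params <- function(model, seed = 7L) {
  flat <- intoxgait:::param_flatten(model$params)
  set.seed(seed)
  flat <- flat + runif(length(flat), 0.01, 0.05) *
    sample(c(-1, 1), length(flat), replace = TRUE)
  model$params <- intoxgait:::param_unflatten(flat, model$params)
  model
}

# central finite-difference gradient check on a random parameter subset
fd_gradcheck <- function(model, n_coords = 25L, seed = 99L, h = 1e-5) {
  set.seed(seed)
  N <- 2L; T <- model$config$window_size
  Xb <- array(rnorm(N * T * 3), c(N, T, 3L))
  y <- c(0L, 1L)
  res <- intoxgait:::loss_and_grads(model, Xb, y, training = FALSE)
  g <- intoxgait:::param_flatten(
    intoxgait:::align_tree(model$params, res$grads))
  flat <- intoxgait:::param_flatten(model$params)
  idx <- sample(length(flat), min(n_coords, length(flat)))
  num <- vapply(idx, function(i) {
    fp <- flat; fp[i] <- fp[i] + h
    m <- model; m$params <- intoxgait:::param_unflatten(fp, model$params)
    l1 <- bce_loss(y, intoxgait:::model_forward(m, Xb)$prob)
    fp[i] <- fp[i] - 2 * h
    m$params <- intoxgait:::param_unflatten(fp, model$params)
    l2 <- bce_loss(y, intoxgait:::model_forward(m, Xb)$prob)
    (l1 - l2) / (2 * h)
  }, numeric(1))
  max(abs(num - g[idx]) / pmax(1e-6, abs(num) + abs(g[idx])))
}

# ---- independent feature oracles (naive loops, explicit DFT) -------------

naive_dft_mag2 <- function(x) {
  n <- length(x)
  sapply(0:(n - 1), function(k) {
    re <- 0; im <- 0
    for (t in 0:(n - 1)) {
      re <- re + x[t + 1] * cos(2 * pi * k * t / n)
      im <- im - x[t + 1] * sin(2 * pi * k * t / n)
    }
    re^2 + im^2
  })
}

naive_psd_onesided <- function(x, fs) {
  n <- length(x)
  p2 <- naive_dft_mag2(x) / n
  K <- floor(n / 2)
  psd <- p2[1:(K + 1)]
  for (k in 2:(K + 1)) {
    interior <- if (n %% 2 == 0) k <= K else TRUE
    if (interior) psd[k] <- 2 * psd[k]
  }
  list(freq = (0:K) * fs / n, psd = psd)
}

naive_features <- function(w, fs, band = c(0.5, 3)) {
  n <- nrow(w)
  msum <- function(v) { s <- 0; for (i in seq_len(n)) s <- s + v[i]; s / n }
  out <- c()
  ax <- c("x", "y", "z")
  per <- list()
  for (a in 1:3) {
    v <- w[, a]
    mu <- msum(v)
    sigma <- sqrt(msum((v - mu)^2))
    ps <- naive_psd_onesided(v, fs)
    P <- ps$psd / sum(ps$psd)
    muf <- sum(ps$freq * P)
    per[[a]] <- list(
      max = max(v), min = min(v), range = max(v) - min(v), mean = mu,
      std = sigma,
      bandpower = sum(ps$psd[ps$freq >= band[1] & ps$freq <= band[2]]) * fs / n,
      rms = sqrt(msum(v^2)),
      energy = sum(ps$psd),
      spec_entropy = -sum(P[P > 0] * log(P[P > 0])),
      spec_bandwidth = sum((ps$freq - muf)^2 * P),
      aad = msum(abs(v - mu)),
      kurtosis = msum((v - mu)^4) / sigma^4,
      skewness = msum((v - mu)^3) / sigma^3)
  }
  pick <- list(max = 1:3, range = 1:3, min = 1:3, mean = 2, std = c(1, 3),
               bandpower = c(1, 3), rms = c(1, 3), energy = c(1, 3),
               spec_entropy = 1:3, spec_bandwidth = 1, aad = c(1, 3),
               kurtosis = 1, skewness = 1)
  for (feat in names(pick)) for (a in pick[[feat]])
    out[paste0(feat, "_", ax[a])] <- per[[a]][[feat]]
  sv <- 0
  for (i in seq_len(n)) sv <- sv + sqrt(w[i, 1]^2 + w[i, 2]^2 + w[i, 3]^2)
  out["sway_volume"] <- sv / fs
  out["sway_xz"] <- msum(sqrt(w[, 1]^2 + w[, 3]^2))
  out["sma"] <- msum(abs(w[, 1]) + abs(w[, 2]) + abs(w[, 3]))
  K <- floor(n / 2) + 1
  mags <- sapply(1:3, function(a) sqrt(naive_dft_mag2(w[, a])[1:K] / n))
  out["avg_resultant_freq"] <- mean(sapply(1:K, function(k) sqrt(sum(mags[k, ]^2))))
  out
}

naive_mi <- function(x, y, n_bins, base = exp(1)) {
  rng <- range(x)
  if (rng[1] == rng[2]) bx <- rep(1, length(x)) else {
    width <- (rng[2] - rng[1]) / n_bins
    bx <- pmin(floor((x - rng[1]) / width) + 1, n_bins)
  }
  mi <- 0
  n <- length(x)
  for (i in unique(bx)) for (j in unique(y)) {
    pij <- sum(bx == i & y == j) / n
    if (pij > 0) mi <- mi + pij * log(pij / (sum(bx == i) / n * sum(y == j) / n))
  }
  mi / log(base)
}

# logistic-regression oracle on the handcrafted feature bank: establishes
# that a synthetic cohort is separable by classical means before any deep
# model is asked to learn it
logistic_oracle <- function(train_ws, test_ws) {
  sp <- spectral_spec(band = c(0.5, 5))
  tr <- window_features(train_ws, sp, axes = "all")
  te <- window_features(test_ws, sp, axes = "all")
  dtr <- data.frame(tr$values, .y = tr$labels)
  dte <- data.frame(te$values, .y = te$labels)
  fit <- suppressWarnings(glm(.y ~ ., data = dtr, family = binomial))
  p <- suppressWarnings(predict(fit, dte, type = "response"))
  list(accuracy = mean((p >= 0.5) == dte$.y),
       auc = auc_trapezoid(dte$.y, p))
}
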