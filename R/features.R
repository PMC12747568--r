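#' Spectral analysis specification
#'
#' Conventions for the frequency-domain features. Spectra are one-sided FFT
#' power with `1/T` normalization and no taper, chosen so that the summed
#' power equals the time-domain energy `sum(x^2)` (Parseval). The band-power
#' band defaults to 0.5-3 Hz, the human locomotor band containing cadence and
#' its first harmonic.
#'
#' @param sampling_rate_hz sampling rate in Hz.
#' @param band length-2 band `(f1, f2)` in Hz for band power.
#' @param log_base logarithm base for entropies (default `exp(1)`).
#' @return an object of class `spectral_spec`.
#' @export
spectral_spec <- function(sampling_rate_hz = 210, band = c(0.5, 3),
                          log_base = exp(1)) {
  stopifnot_positive(sampling_rate_hz, "sampling_rate_hz")
  if (length(band) != 2L || band[1] < 0 || band[1] >= band[2] ||
      band[2] > sampling_rate_hz / 2)
    stop("`band` must satisfy 0 <= f1 < f2 <= Nyquist", call. = FALSE)
  structure(list(sampling_rate_hz = sampling_rate_hz, band = band,
                 log_base = log_base), class = "spectral_spec")
}

# One-sided power spectrum with 1/T normalization. Interior bins are doubled
# so sum(psd) == sum(x^2) exactly (two-sided total energy).
psd_onesided <- function(x, fs) {
  T <- length(x)
  p2 <- Mod(fft(x))^2 / T
  K <- floor(T / 2)
  psd <- p2[1:(K + 1L)]
  if (T %% 2 == 0) {
    if (K >= 2) psd[2:K] <- 2 * psd[2:K]          # Nyquist bin not doubled
  } else {
    if (K >= 1) psd[2:(K + 1L)] <- 2 * psd[2:(K + 1L)]
  }
  list(freq = (0:K) * fs / T, psd = psd)
}

#' Spectral entropy of a signal
#'
#' The one-sided power spectrum is normalized to a probability vector `P`
#' and the entropy `-sum(P log P)` is returned in the configured log base.
#' A constant signal has no spectrum to normalize and returns 0 with a
#' warning.
#'
#' @param signal numeric vector.
#' @param spec a [spectral_spec()].
#' @return entropy (>= 0, at most `log(#bins)`).
#' @export
spectral_entropy <- function(signal, spec = spectral_spec()) {
  if (sd(signal) == 0 && all(signal == 0)) {
    warning("constant signal; spectral entropy set to 0", call. = FALSE)
    return(0)
  }
  p <- psd_onesided(signal, spec$sampling_rate_hz)$psd
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p)) / log(spec$log_base)
}

#' Sway volume of a window
#'
#' Discrete approximation of the time integral of the acceleration vector
#' magnitude: `sum(sqrt(x^2 + y^2 + z^2)) * dt`.
#'
#' @param window `T x 3` numeric matrix.
#' @param dt sample spacing in seconds.
#' @return nonnegative scalar.
#' @export
sway_volume <- function(window, dt) {
  stopifnot_positive(dt, "dt")
  sum(sqrt(rowSums(window^2))) * dt
}

# population moments
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Extract the handcrafted gait feature bank from one window
#'
#' Computes the 30 per-window gait features used by the classical baselines:
#' per-axis extrema and ranges, vertical mean, mediolateral/anteroposterior
#' standard deviation, band power, RMS, frequency-domain energy, spectral
#' entropy (all axes), spectral bandwidth, absolute average deviation,
#' kurtosis and skewness of the mediolateral axis, sway volume, mean sway in
#' the XZ plane, signal magnitude area, and the average resultant acceleration
#' across frequency bins. With `axes = "all"` every per-axis feature is
#' emitted for all three axes instead of only the axes of the printed bank.
#'
#' @param window `T x 3` numeric matrix (columns X, Y, Z), `T >= 8`.
#' @param spec a [spectral_spec()].
#' @param axes `"printed"` (default, 30 features) or `"all"`.
#' @param sway_xz_summary `"mean"` (default) or `"rms"` reduction of the
#'   per-sample XZ sway.
#' @return named numeric feature vector.
#' @export
extract_features <- function(window, spec = spectral_spec(),
                             axes = c("printed", "all"),
                             sway_xz_summary = c("mean", "rms")) {
  axes <- match.arg(axes)
  sway_xz_summary <- match.arg(sway_xz_summary)
  window <- as.matrix(window)
  stopifnot(ncol(window) == 3L, nrow(window) >= 8L, all(is.finite(window)))
  fs <- spec$sampling_rate_hz
  ax_names <- c("x", "y", "z")
  colnames(window) <- ax_names

  per_axis <- lapply(ax_names, function(a) {
    v <- window[, a]
    ps <- psd_onesided(v, fs)
    df <- fs / length(v)
    sigma <- pop_sd(v)
    if (sigma == 0)
      warning(sprintf("axis %s has zero variance; kurtosis/skewness set to 0", a),
              call. = FALSE)
    list(
      max = max(v), min = min(v), range = max(v) - min(v), mean = mean(v),
      std = sigma,
      bandpower = sum(ps$psd[ps$freq >= spec$band[1] & ps$freq <= spec$band[2]]) * df,
      rms = sqrt(mean(v^2)),
      energy = sum(ps$psd),
      spec_entropy = spectral_entropy(v, spec),
      spec_bandwidth = {
        P <- ps$psd / sum(ps$psd)
        mu_f <- sum(ps$freq * P)
        sum((ps$freq - mu_f)^2 * P)
      },
      aad = mean(abs(v - mean(v))),
      kurtosis = if (sigma == 0) 0 else mean((v - mean(v))^4) / sigma^4,
      skewness = if (sigma == 0) 0 else mean((v - mean(v))^3) / sigma^3
    )
  })
  names(per_axis) <- ax_names

  pick <- if (axes == "printed") {
    list(max = ax_names, range = ax_names, min = ax_names, mean = "y",
         std = c("x", "z"), bandpower = c("x", "z"), rms = c("x", "z"),
         energy = c("x", "z"), spec_entropy = ax_names, spec_bandwidth = "x",
         aad = c("x", "z"), kurtosis = "x", skewness = "x")
  } else {
    nm <- c("max", "range", "min", "mean", "std", "bandpower", "rms",
            "energy", "spec_entropy", "spec_bandwidth", "aad", "kurtosis",
            "skewness")
    setNames(rep(list(ax_names), length(nm)), nm)
  }
  out <- numeric(0)
  for (feat in names(pick)) for (a in pick[[feat]])
    out[paste0(feat, "_", a)] <- per_axis[[a]][[feat]]

  sxz <- sqrt(window[, "x"]^2 + window[, "z"]^2)
  mags <- vapply(ax_names, function(a)
    Mod(fft(window[, a]))[seq_len(floor(nrow(window) / 2) + 1L)] / sqrt(nrow(window)),
    numeric(floor(nrow(window) / 2) + 1L))
  out["sway_volume"] <- sway_volume(window, 1 / fs)
  out["sway_xz"] <- if (sway_xz_summary == "mean") mean(sxz) else sqrt(mean(sxz^2))
  out["sma"] <- mean(abs(window[, "x"]) + abs(window[, "y"]) + abs(window[, "z"]))
  out["avg_resultant_freq"] <- mean(sqrt(rowSums(mags^2)))
  out
}

#' Per-window feature table
#'
#' @param values `N x F` numeric matrix.
#' @param names feature names (length F, unique).
#' @param labels 0/1 labels (length N).
#' @param window_ids optional window identifiers.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, names, labels, window_ids = seq_len(nrow(values))) {
  values <- as.matrix(values)
  if (anyDuplicated(names)) stop("feature names must be unique", call. = FALSE)
  if (ncol(values) != length(names)) stop("names/values mismatch", call. = FALSE)
  if (!all(is.finite(values))) stop("non-finite feature values", call. = FALSE)
  colnames(values) <- names
  structure(list(values = values, names = names, labels = as.integer(labels),
                 window_ids = window_ids), class = "feature_table")
}

#' Extract features for every window of a window set
#'
#' @param ws a [window_set()].
#' @param spec a [spectral_spec()].
#' @param ... passed to [extract_features()].
#' @return a [feature_table()].
#' @export
window_features <- function(ws, spec = spectral_spec(), ...) {
  n <- n_windows(ws)
  rows <- lapply(seq_len(n), function(i)
    extract_features(ws$windows[i, , ], spec, ...))
  vals <- do.call(rbind, rows)
  feature_table(vals, colnames(vals), ws$labels)
}

#' Plug-in mutual information between a real feature and a binary label
#'
#' Discretizes `x` into `n_bins` equal-width bins over its range, forms the
#' empirical joint distribution with `y`, and returns the plug-in estimate
#' `I(X;Y) = sum p(x,y) log( p(x,y) / (p(x) p(y)) )`.
#'
#' @param x numeric vector.
#' @param y vector of the same length (binary label).
#' @param n_bins number of equal-width bins (>= 2, default 20).
#' @param base logarithm base (default `exp(1)`).
#' @return mutual information (>= 0).
#' @export
mutual_information <- function(x, y, n_bins = 20L, base = exp(1)) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (n_bins < 2) stop("`n_bins` must be >= 2", call. = FALSE)
  rng <- range(x)
  bx <- if (rng[1] == rng[2]) rep(1L, length(x)) else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), n_bins)
  }
  joint <- table(bx, y) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    p <- joint[i, j]
    if (p > 0) mi <- mi + p * log(p / (px[i] * py[j]))
  }
  max(0, mi / log(base))
}

#' Select the k features most informative about the label
#'
#' Ranks features by mutual information with the label (equal-width binning)
#' and keeps the top `k`, ordered by decreasing score with deterministic
#' alphabetical tie-breaking.
#'
#' @param table a [feature_table()].
#' @param k number of features to keep (default 30).
#' @param n_bins bins for the mutual-information estimate.
#' @return a [feature_table()] with `k` columns; scores attached as
#'   attribute `"mi"`.
#' @export
select_top_k <- function(table, k = 30L, n_bins = 20L) {
  stopifnot(inherits(table, "feature_table"))
  F <- length(table$names)
  if (k > F) stop("`k` exceeds the number of features", call. = FALSE)
  mi <- vapply(seq_len(F), function(j)
    mutual_information(table$values[, j], table$labels, n_bins), numeric(1))
  ord <- order(-mi, table$names)[seq_len(k)]
  out <- feature_table(table$values[, ord, drop = FALSE], table$names[ord],
                       table$labels, table$window_ids)
  attr(out, "mi") <- setNames(mi[ord], table$names[ord])
  out
}

#' Write / read a feature table as CSV
#'
#' The CSV has one row per window, a header of feature names, and a trailing
#' `label` column.
#'
#' @param table a [feature_table()].
#' @param path file path.
#' @return `read_feature_table` returns a [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table$values)
  df$label <- table$labels
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  lab <- df$label
  df$label <- NULL
  feature_table(as.matrix(df), colnames(df), lab)
}
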