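#' Isolation Forest specification
#'
#' Parameters of the outlier detector applied per subject to the raw
#' `(ax, ay, az)` sample rows. Trees isolate points by recursive random
#' axis-aligned splits; points with short average isolation paths score as
#' anomalous.
#'
#' @param contamination fraction of samples flagged as outliers, in (0, 1).
#' @param n_trees number of isolation trees (default 100).
#' @param subsample_size per-tree subsample size (default 256).
#' @param seed integer seed.
#' @return an object of class `iforest_spec`.
#' @export
iforest_spec <- function(contamination = 0.05, n_trees = 100L,
                         subsample_size = 256L, seed = 1L) {
  if (contamination <= 0 || contamination >= 1)
    stop("`contamination` must be in (0, 1)", call. = FALSE)
  stopifnot_positive(n_trees, "n_trees")
  stopifnot_positive(subsample_size, "subsample_size")
  structure(list(contamination = contamination, n_trees = as.integer(n_trees),
                 subsample_size = as.integer(subsample_size),
                 seed = as.integer(seed)), class = "iforest_spec")
}

#' Average path length normalizer c(n)
#'
#' The expected path length of an unsuccessful binary search tree lookup over
#' `n` points: `c(n) = 2 H(n-1) - 2 (n-1)/n`, with `H(i)` the exact harmonic
#' sum. By convention `c(1) = 0` (a single point cannot be split further).
#'
#' @param n number of points (integer >= 1).
#' @return the normalizing constant.
#' @export
iforest_normalizer <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("`n` must be a single integer >= 1", call. = FALSE)
  n <- as.integer(n)
  if (n <= 1L) return(0)
  2 * sum(1 / seq_len(n - 1L)) - 2 * (n - 1) / n
}

#' Anomaly score from a mean isolation path length
#'
#' `s(x, n) = 2 ^ ( - E(h(x)) / c(n) )`: monotone decreasing in the mean path
#' length, approaching 1 for immediately isolated points and 0.5 when the
#' path length equals the normalizer.
#'
#' @param mean_path_length average isolation depth `E(h(x))` (>= 0).
#' @param n subsample size used to fit the trees (>= 2).
#' @return anomaly score in (0, 1].
#' @export
anomaly_score <- function(mean_path_length, n) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  if (any(mean_path_length < 0)) stop("path length must be >= 0", call. = FALSE)
  2^(-mean_path_length / iforest_normalizer(n))
}

# Build one isolation tree on rows `idx` of X. Split attribute and value are
# drawn uniformly; recursion stops at singleton/duplicate nodes or the depth
# limit. Leaves record their size so the path-length estimate can add c(size).
build_itree <- function(X, idx, depth, max_depth) {
  n <- length(idx)
  if (n <= 1L || depth >= max_depth)
    return(list(leaf = TRUE, size = n))
  q <- sample.int(ncol(X), 1L)
  rng <- range(X[idx, q])
  if (rng[1] == rng[2]) {
    # this attribute cannot split; a node of exact duplicates may never split
    ranges <- apply(X[idx, , drop = FALSE], 2, function(v) diff(range(v)))
    if (all(ranges == 0)) return(list(leaf = TRUE, size = n))
    q <- sample(which(ranges > 0), 1L)
    rng <- range(X[idx, q])
  }
  p <- runif(1, rng[1], rng[2])
  left <- idx[X[idx, q] < p]
  right <- idx[X[idx, q] >= p]
  if (length(left) == 0L || length(right) == 0L)
    return(list(leaf = TRUE, size = n))
  list(leaf = FALSE, q = q, p = p,
       left = build_itree(X, left, depth + 1L, max_depth),
       right = build_itree(X, right, depth + 1L, max_depth))
}

# Vectorized path lengths of all rows of X down one tree.
itree_paths <- function(tree, X, idx, depth, out) {
  if (tree$leaf) {
    out[idx] <- depth + if (tree$size > 1L) iforest_normalizer(tree$size) else 0
    return(out)
  }
  go_left <- X[idx, tree$q] < tree$p
  if (any(go_left)) out <- itree_paths(tree$left, X, idx[go_left], depth + 1L, out)
  if (any(!go_left)) out <- itree_paths(tree$right, X, idx[!go_left], depth + 1L, out)
  out
}

#' Fit an Isolation Forest and score points
#'
#' Fits `n_trees` isolation trees, each on a random subsample of the rows of
#' `X` (without replacement, size `min(subsample_size, nrow(X))`, depth limit
#' `ceiling(log2(subsample))`), and returns the anomaly score of every row.
#'
#' @param X numeric matrix (rows = points).
#' @param spec an [iforest_spec()].
#' @return numeric vector of anomaly scores in (0, 1), one per row.
#' @export
iforest_scores <- function(X, spec = iforest_spec()) {
  X <- as.matrix(X)
  N <- nrow(X)
  psi <- min(spec$subsample_size, N)
  if (psi < 2) stop("need at least 2 samples", call. = FALSE)
  max_depth <- ceiling(log2(psi))
  paths <- matrix(0, N, spec$n_trees)
  with_seed(spec$seed, {
    for (k in seq_len(spec$n_trees)) {
      sub <- sample.int(N, psi)
      tree <- build_itree(X, sub, 0L, max_depth)
      paths[, k] <- itree_paths(tree, X, seq_len(N), 0L, numeric(N))
    }
  })
  anomaly_score(rowMeans(paths), psi)
}

#' Remove outlier samples from a recording
#'
#' Scores the `(ax, ay, az)` rows of this subject's recording with an
#' Isolation Forest and drops the top `contamination` fraction by anomaly
#' score (exactly `N - ceiling((1 - contamination) * N)` rows). The remaining
#' samples close up into a regular time grid; the small discontinuities this
#' creates are smoothed by the subsequent low-pass filter.
#'
#' @param rec a [gait_recording()].
#' @param spec an [iforest_spec()].
#' @return the cleaned recording.
#' @export
remove_outliers <- function(rec, spec = iforest_spec()) {
  stopifnot(inherits(rec, "gait_recording"))
  N <- length(rec$t)
  if (N < spec$subsample_size) {
    warning("fewer samples than the forest subsample size; skipping outlier removal",
            call. = FALSE)
    return(rec)
  }
  scores <- iforest_scores(cbind(rec$ax, rec$ay, rec$az), spec)
  k_keep <- as.integer(ceiling((1 - spec$contamination) * N))
  keep <- sort(order(scores, seq_len(N))[seq_len(k_keep)])
  gait_recording(rec$subject_id, rec$session_id, rec$sampling_rate_hz,
                 (seq_len(k_keep) - 1) / rec$sampling_rate_hz,
                 rec$ax[keep], rec$ay[keep], rec$az[keep],
                 rec$bac, rec$label)
}
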