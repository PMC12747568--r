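#' Simulation parameters for synthetic gait recordings
#'
#' Bundles every knob of the synthetic triaxial gait generator. The generator
#' emulates waist-mounted accelerometry of walking: each axis is a sum of
#' harmonics of the step frequency (vertical Y strongest, as on a real torso),
#' with per-subject cadence/amplitude variation, white sensor noise and sparse
#' high-magnitude outlier events (falls, abrupt turns). Intoxication perturbs
#' the signal through four mechanisms: the mediolateral (X) amplitude is
#' inflated by `sway_multiplier` (postural sway), the cadence is slowed by
#' `cadence_slowdown`, stride phase receives Gaussian jitter
#' (`phase_jitter_sd`), and the harmonics of the vertical (Y) axis above the
#' fundamental are attenuated by `vertical_damping` — cautious, flat-footed
#' steps lose the sharp push-off transient that lives in the higher
#' harmonics. Because the preprocessing pipeline z-scores each axis per
#' subject, pure amplitude changes are normalized away; the harmonic-ratio
#' change reshapes the vertical waveform itself and therefore survives
#' normalization, making Y the dominant class-informative channel.
#'
#' @param sampling_rate_hz sampling rate in Hz (default 210).
#' @param duration_s recording duration in seconds.
#' @param cadence_hz sober step frequency in Hz (default 1.8).
#' @param harmonic_amplitudes named list with elements `x`, `y`, `z`; each a
#'   numeric vector of amplitudes in g whose names are harmonic indices of the
#'   step frequency.
#' @param sway_multiplier factor (>= 1) applied to X amplitudes when
#'   intoxicated.
#' @param cadence_slowdown multiplicative cadence factor (0 < f <= 1) when
#'   intoxicated.
#' @param phase_jitter_sd stride-phase jitter standard deviation in radians
#'   when intoxicated.
#' @param vertical_damping factor (<= 1) applied to the above-fundamental
#'   harmonics of Y when intoxicated.
#' @param noise_sd white sensor noise standard deviation in g.
#' @param outlier_rate outlier events per minute.
#' @param outlier_magnitude_g outlier spike amplitude in g.
#' @param bac_sober BAC assigned to sober sessions (g/dL).
#' @param bac_intox_range length-2 range (g/dL) from which intoxicated-session
#'   BAC is drawn uniformly.
#' @param bac_threshold BAC above which a session is labelled intoxicated.
#' @param subject_cadence_sd log-scale per-subject cadence variation.
#' @param subject_amp_sd log-scale per-subject amplitude variation.
#' @param seed integer seed; all generator randomness derives from it.
#' @return an object of class `simulation_params`.
#' @export
simulation_params <- function(sampling_rate_hz = 210,
                              duration_s = 60,
                              cadence_hz = 1.8,
                              harmonic_amplitudes = list(
                                x = c("1" = 0.18),
                                y = c("1" = 0.45, "2" = 0.25),
                                z = c("1" = 0.20, "2" = 0.10)),
                              sway_multiplier = 1.5,
                              cadence_slowdown = 0.92,
                              phase_jitter_sd = 0.15,
                              vertical_damping = 0.80,
                              noise_sd = 0.03,
                              outlier_rate = 0.5,
                              outlier_magnitude_g = 4,
                              bac_sober = 0,
                              bac_intox_range = c(0.08, 0.20),
                              bac_threshold = 0,
                              subject_cadence_sd = 0.10,
                              subject_amp_sd = 0.10,
                              seed = 1L) {
  stopifnot_positive(sampling_rate_hz, "sampling_rate_hz")
  stopifnot_positive(duration_s, "duration_s")
  stopifnot_positive(cadence_hz, "cadence_hz")
  if (sway_multiplier < 1) stop("`sway_multiplier` must be >= 1", call. = FALSE)
  if (cadence_slowdown <= 0 || cadence_slowdown > 1)
    stop("`cadence_slowdown` must be in (0, 1]", call. = FALSE)
  if (vertical_damping <= 0 || vertical_damping > 1)
    stop("`vertical_damping` must be in (0, 1]", call. = FALSE)
  if (outlier_rate < 0) stop("`outlier_rate` must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!all(c("x", "y", "z") %in% names(harmonic_amplitudes)))
    stop("`harmonic_amplitudes` needs elements x, y, z", call. = FALSE)
  structure(list(
    sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
    cadence_hz = cadence_hz, harmonic_amplitudes = harmonic_amplitudes,
    sway_multiplier = sway_multiplier, cadence_slowdown = cadence_slowdown,
    phase_jitter_sd = phase_jitter_sd, vertical_damping = vertical_damping,
    noise_sd = noise_sd, outlier_rate = outlier_rate,
    outlier_magnitude_g = outlier_magnitude_g, bac_sober = bac_sober,
    bac_intox_range = bac_intox_range, bac_threshold = bac_threshold,
    subject_cadence_sd = subject_cadence_sd, subject_amp_sd = subject_amp_sd,
    seed = as.integer(seed)), class = "simulation_params")
}

#' Construct a gait recording
#'
#' One subject-session triaxial accelerometer time series. X is mediolateral,
#' Y vertical, Z anteroposterior; accelerations are in g.
#'
#' @param subject_id,session_id identifiers.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param t time stamps in seconds, strictly increasing with spacing
#'   `1/sampling_rate_hz`.
#' @param ax,ay,az acceleration sequences (g), same length as `t`.
#' @param bac session blood alcohol content in g/dL.
#' @param label 0 (sober) or 1 (intoxicated).
#' @return an object of class `gait_recording`.
#' @export
gait_recording <- function(subject_id, session_id, sampling_rate_hz,
                           t, ax, ay, az, bac, label) {
  stopifnot_positive(sampling_rate_hz, "sampling_rate_hz")
  n <- length(t)
  if (!(length(ax) == n && length(ay) == n && length(az) == n))
    stop("t, ax, ay, az must have equal length", call. = FALSE)
  if (n > 1) {
    dt <- diff(t)
    if (any(dt <= 0) || max(abs(dt - 1 / sampling_rate_hz)) > 1e-6)
      stop("t must be strictly increasing with spacing 1/sampling_rate_hz",
           call. = FALSE)
  }
  if (!label %in% c(0L, 1L)) stop("label must be 0 or 1", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 session_id = as.character(session_id),
                 sampling_rate_hz = sampling_rate_hz,
                 t = as.numeric(t), ax = as.numeric(ax), ay = as.numeric(ay),
                 az = as.numeric(az), bac = bac, label = as.integer(label)),
            class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf(
    "<gait_recording> subject=%s session=%s n=%d (%.2f s @ %g Hz) bac=%.3f label=%d\n",
    x$subject_id, x$session_id, length(x$t),
    length(x$t) / x$sampling_rate_hz, x$sampling_rate_hz, x$bac, x$label))
  invisible(x)
}

#' Simulate one subject-session gait recording
#'
#' Generates a periodic triaxial walking signal for a single subject under the
#' given condition. Subject-level random effects (cadence and amplitude
#' offsets, axis phases) are drawn from a seed derived from the subject id, so
#' the sober and intoxicated renditions of the same subject share the same
#' underlying gait and differ only by the condition multipliers (plus
#' condition-specific jitter/noise draws).
#'
#' @param params a [simulation_params()] object.
#' @param condition `"sober"` or `"intoxicated"`.
#' @param subject_id subject identifier.
#' @param session_id session identifier.
#' @return a [gait_recording()].
#' @export
simulate_subject <- function(params, condition = c("sober", "intoxicated"),
                             subject_id = "S1", session_id = "1") {
  if (!inherits(params, "simulation_params"))
    params <- do.call(simulation_params, params)
  condition <- match.arg(condition)
  fs <- params$sampling_rate_hz
  n <- round(params$duration_s * fs)
  if (n < 1) stop("duration too short for one sample", call. = FALSE)
  t <- (seq_len(n) - 1) / fs

  sub <- with_seed(derive_seed(params$seed, paste0("subj:", subject_id)), {
    list(cadence = params$cadence_hz * exp(rnorm(1, 0, params$subject_cadence_sd)),
         amp = exp(rnorm(1, 0, params$subject_amp_sd)),
         phase = runif(3, 0, 2 * pi))
  })

  intox <- condition == "intoxicated"
  f <- sub$cadence * if (intox) params$cadence_slowdown else 1
  mult <- c(x = if (intox) params$sway_multiplier else 1, y = 1, z = 1)
  # vertical push-off attenuation: harmonics above the fundamental only
  damp_y <- if (intox) params$vertical_damping else 1

  sess_seed <- derive_seed(params$seed,
                           paste("sess", subject_id, session_id, condition))
  sig <- with_seed(sess_seed, {
    jit <- if (intox && params$phase_jitter_sd > 0) {
      stride <- floor(t * f) + 1L
      rnorm(max(stride), 0, params$phase_jitter_sd)[stride]
    } else rep(0, n)
    out <- lapply(c(x = "x", y = "y", z = "z"), function(axis) {
      amps <- params$harmonic_amplitudes[[axis]]
      s <- numeric(n)
      for (i in seq_along(amps)) {
        m <- as.numeric(names(amps)[i])
        a <- amps[[i]] * sub$amp * mult[[axis]]
        if (axis == "y" && m > 1) a <- a * damp_y
        s <- s + a *
          sin(2 * pi * m * f * t + sub$phase[match(axis, c("x", "y", "z"))] + m * jit)
      }
      if (params$noise_sd > 0) s <- s + rnorm(n, 0, params$noise_sd)
      s
    })
    out$bac <- if (intox) runif(1, params$bac_intox_range[1], params$bac_intox_range[2])
               else params$bac_sober
    out
  })

  rec <- gait_recording(subject_id, session_id, fs, t,
                        sig$x, sig$y, sig$z, sig$bac,
                        as.integer(sig$bac > params$bac_threshold))
  if (params$outlier_rate > 0)
    rec <- inject_outliers(rec, params$outlier_rate, params$outlier_magnitude_g,
                           seed = derive_seed(sess_seed, "outliers"))
  rec
}

#' Simulate a cohort of subjects
#'
#' Assigns a `round(intox_subject_fraction * n_subjects)`-sized random subset
#' of subjects to the intoxicated condition and simulates `n_sessions`
#' recordings for each subject. The default fraction reproduces the roughly
#' 75/25 sober/intoxicated sample imbalance typical of controlled alcohol
#' administration studies.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param intox_subject_fraction fraction of subjects intoxicated, in `[0,1]`.
#' @param params a [simulation_params()] object.
#' @param n_sessions sessions per subject.
#' @return a list of [gait_recording()] objects.
#' @export
simulate_cohort <- function(n_subjects, intox_subject_fraction = 0.2513,
                            params = simulation_params(), n_sessions = 1L) {
  if (n_subjects < 3) stop("need at least 3 subjects", call. = FALSE)
  if (intox_subject_fraction < 0 || intox_subject_fraction > 1)
    stop("`intox_subject_fraction` must be in [0, 1]", call. = FALSE)
  if (!inherits(params, "simulation_params"))
    params <- do.call(simulation_params, params)
  ids <- sprintf("S%03d", seq_len(n_subjects))
  n_intox <- round(intox_subject_fraction * n_subjects)
  intox_ids <- with_seed(derive_seed(params$seed, "cohort"),
                         sample(ids, n_intox))
  recs <- list()
  for (id in ids) {
    cond <- if (id %in% intox_ids) "intoxicated" else "sober"
    for (s in seq_len(n_sessions))
      recs[[length(recs) + 1L]] <-
        simulate_subject(params, cond, id, session_id = as.character(s))
  }
  recs
}

#' Inject sparse outlier events into a recording
#'
#' Adds short (~0.25 s) half-sine excursions at Poisson-distributed times to
#' all three axes, emulating falls or abrupt 180-degree turns during a walk.
#' The sample count is unchanged.
#'
#' @param rec a [gait_recording()].
#' @param rate_per_min expected events per minute (>= 0).
#' @param magnitude_g excursion peak amplitude in g.
#' @param seed integer seed.
#' @return the recording with outlier events added.
#' @export
inject_outliers <- function(rec, rate_per_min, magnitude_g, seed = 1L) {
  stopifnot(inherits(rec, "gait_recording"))
  if (rate_per_min < 0) stop("`rate_per_min` must be >= 0", call. = FALSE)
  if (rate_per_min == 0) return(rec)
  n <- length(rec$t)
  fs <- rec$sampling_rate_hz
  dur_min <- n / fs / 60
  with_seed(seed, {
    n_events <- rpois(1, rate_per_min * dur_min)
    if (n_events > 0) {
      width <- max(1L, round(0.25 * fs))
      env <- magnitude_g * sin(pi * seq_len(width) / (width + 1))
      starts <- sample.int(max(1L, n - width + 1L), n_events, replace = TRUE)
      for (s in starts) {
        idx <- s:min(n, s + width - 1L)
        e <- env[seq_along(idx)]
        rec$ax[idx] <- rec$ax[idx] + e
        rec$ay[idx] <- rec$ay[idx] + e
        rec$az[idx] <- rec$az[idx] + e
      }
    }
    rec
  })
}
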