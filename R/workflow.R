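#' Write / read gait recordings as long-format CSV
#'
#' Columns: `subject_id, session_id, timestamp_s, ax, ay, az, bac, label`
#' (UTF-8, '.' decimal separator). One row per sample.
#'
#' @param recordings list of [gait_recording()] objects.
#' @param path CSV file path.
#' @return `read_recordings` returns a list of [gait_recording()] objects.
#' @export
write_recordings <- function(recordings, path) {
  dfs <- lapply(recordings, function(r)
    data.frame(subject_id = r$subject_id, session_id = r$session_id,
               timestamp_s = r$t, ax = r$ax, ay = r$ay, az = r$az,
               bac = r$bac, label = r$label))
  write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recordings
#' @export
read_recordings <- function(path) {
  df <- read.csv(path)
  need <- c("subject_id", "session_id", "timestamp_s", "ax", "ay", "az",
            "bac", "label")
  if (!all(need %in% names(df)))
    stop("recording CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  keys <- interaction(df$subject_id, df$session_id, drop = TRUE)
  lapply(split(df, keys), function(d) {
    d <- d[order(d$timestamp_s), ]
    fs <- 1 / median(diff(d$timestamp_s))
    gait_recording(d$subject_id[1], d$session_id[1], fs, d$timestamp_s,
                   d$ax, d$ay, d$az, d$bac[1], d$label[1])
  })
}

#' Persist / restore a window set
#'
#' @param ws a [window_set()].
#' @param path file path (RDS).
#' @return `load_window_set` returns the [window_set()].
#' @export
save_window_set <- function(ws, path) {
  stopifnot(inherits(ws, "window_set"))
  saveRDS(ws, path)
  invisible(path)
}

#' @rdname save_window_set
#' @export
load_window_set <- function(path) {
  ws <- readRDS(path)
  stopifnot(inherits(ws, "window_set"))
  ws
}

# polynomial rolling hash of a deparsed object; stable fingerprint for
# manifests (not cryptographic)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Bundles every stage's specification. The global `seed` fans out to
#' stage-specific derived seeds (hashed with the stage name), so stages are
#' independently reproducible.
#'
#' @param out_dir output directory for artifacts.
#' @param input_csv optional path to a long-format recording CSV; when NULL,
#'   a synthetic cohort is simulated.
#' @param n_subjects,intox_fraction,n_sessions synthetic cohort shape.
#' @param sim a [simulation_params()] object.
#' @param fractions train/validation/test sample fractions.
#' @param fspec a [filter_spec()].
#' @param ispec an [iforest_spec()] or NULL to skip outlier removal.
#' @param window_size,overlap segmentation parameters (window_size defaults
#'   to the model's).
#' @param model a [model_config()].
#' @param threshold decision threshold.
#' @param k_folds folds for [run_cv()].
#' @param n_per_class,smoothing_sigma attention-profile options.
#' @param seed global seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "intoxgait-out", input_csv = NULL,
                            n_subjects = 20L, intox_fraction = 0.2513,
                            n_sessions = 1L, sim = simulation_params(),
                            fractions = c(train = 0.7, validation = 0.1,
                                          test = 0.2),
                            fspec = filter_spec(), ispec = iforest_spec(),
                            window_size = NULL, overlap = 0.5,
                            model = model_config(), threshold = 0.5,
                            k_folds = 5L, n_per_class = 10L,
                            smoothing_sigma = 10, seed = 1L) {
  seed <- as.integer(seed)
  sim$seed <- derive_seed(seed, "simulate")
  if (!is.null(ispec)) ispec$seed <- derive_seed(seed, "iforest")
  model$seed <- derive_seed(seed, "model")
  if (is.null(window_size)) window_size <- model$window_size
  if (window_size != model$window_size)
    stop("window_size must match the model's window size", call. = FALSE)
  structure(list(out_dir = out_dir, input_csv = input_csv,
                 n_subjects = as.integer(n_subjects),
                 intox_fraction = intox_fraction,
                 n_sessions = as.integer(n_sessions), sim = sim,
                 fractions = fractions, fspec = fspec, ispec = ispec,
                 window_size = as.integer(window_size), overlap = overlap,
                 model = model, threshold = threshold,
                 k_folds = as.integer(k_folds),
                 n_per_class = as.integer(n_per_class),
                 smoothing_sigma = smoothing_sigma, seed = seed),
            class = "pipeline_config")
}

pipeline_inputs <- function(config) {
  if (!is.null(config$input_csv)) {
    if (!file.exists(config$input_csv))
      stop("input CSV not found: ", config$input_csv, call. = FALSE)
    read_recordings(config$input_csv)
  } else {
    simulate_cohort(config$n_subjects, config$intox_fraction, config$sim,
                    config$n_sessions)
  }
}

write_manifest <- function(config, path, extra = list()) {
  manifest <- c(list(config_hash = config_hash(config), seed = config$seed,
                     package_version = as.character(utils::packageVersion("intoxgait")),
                     r_version = paste(R.version$major, R.version$minor, sep = ".")),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  manifest
}

#' Run the end-to-end pipeline
#'
#' Simulates (or loads) a cohort, runs the subject-wise preprocessing chain,
#' trains the classifier, evaluates it on the held-out test subjects, and
#' produces the interpretability artifacts. Everything is written under
#' `config$out_dir`: `metrics.json`/`metrics.csv`, `roc.csv`, `history.csv`,
#' `attention_profile.csv`, `phase_table.csv`, `channel_ablation.csv` and a
#' `manifest.json` recording the config hash and seeds.
#'
#' @param config a [pipeline_config()].
#' @param verbose print progress.
#' @return (invisibly) a list with the trained model, metrics, profile,
#'   phase table, channel ablation, window counts and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  recordings <- pipeline_inputs(config)

  split <- split_subjects(recordings,
                          split_spec(config$fractions,
                                     seed = derive_seed(config$seed, "split")))
  pp <- preprocess_cohort(recordings, split, config$fspec, config$ispec,
                          window_size = config$window_size,
                          overlap = config$overlap, oversample = TRUE,
                          seed = config$seed)
  counts <- vapply(pp[c("train", "validation", "test")], n_windows, integer(1))
  if (verbose)
    message(sprintf("windows: train=%d val=%d test=%d",
                    counts[1], counts[2], counts[3]))

  model <- build_model(config$model)
  model <- train_model(model, pp$train, pp$validation, verbose = verbose)
  scores <- predict_model(model, pp$test)
  metrics <- classification_metrics(pp$test$labels, scores, config$threshold)

  profile <- NULL; phases <- NULL
  if (config$model$attention_variant != "channel" &&
      length(unique(pp$test$labels)) == 2L) {
    profile <- attention_profile(model, pp$test, config$n_per_class,
                                 config$smoothing_sigma,
                                 seed = derive_seed(config$seed, "profile"))
    phases <- phase_analysis(profile)
  }
  chan <- channel_ablation(model, pp$test, config$threshold)

  out <- config$out_dir
  jsonlite::write_json(metrics_row(metrics), file.path(out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  write.csv(metrics_row(metrics), file.path(out, "metrics.csv"),
            row.names = FALSE)
  write.csv(roc_points(pp$test$labels, scores), file.path(out, "roc.csv"),
            row.names = FALSE)
  write.csv(model$history, file.path(out, "history.csv"), row.names = FALSE)
  if (!is.null(profile)) {
    write.csv(data.frame(timestep = seq_len(nrow(profile$timeline)),
                         profile$timeline),
              file.path(out, "attention_profile.csv"), row.names = FALSE)
    write.csv(phases, file.path(out, "phase_table.csv"), row.names = FALSE)
  }
  write.csv(as.data.frame(chan), file.path(out, "channel_ablation.csv"),
            row.names = FALSE)
  manifest <- write_manifest(config, file.path(out, "manifest.json"),
                             extra = list(window_counts = as.list(counts)))
  invisible(list(model = model, metrics = metrics, profile = profile,
                 phases = phases, channel_ablation = chan,
                 window_counts = counts, split = split, manifest = manifest))
}

#' Run subject-level cross-validation with artifact output
#'
#' @param config a [pipeline_config()].
#' @param verbose print progress.
#' @return (invisibly) the [cross_validate()] result plus the manifest.
#' @export
run_cv <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  recordings <- pipeline_inputs(config)
  cv <- cross_validate(recordings, k = config$k_folds, config = config$model,
                       fspec = config$fspec, ispec = config$ispec,
                       overlap = config$overlap, threshold = config$threshold,
                       seed = derive_seed(config$seed, "cv"),
                       verbose = verbose)
  out <- config$out_dir
  write.csv(cv$folds, file.path(out, "cv_folds.csv"), row.names = FALSE)
  jsonlite::write_json(split(names(cv$assignments), cv$assignments),
                       file.path(out, "cv_subjects.json"))
  manifest <- write_manifest(config, file.path(out, "manifest.json"))
  invisible(c(cv, list(manifest = manifest)))
}
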