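# End-to-end orchestration: simulate -> preprocess -> extract -> fuse ->
# classify -> evaluate, from one validated config, with every stage's output
# written in the plain-text formats of the I/O module so stages remain
# independently inspectable.

#' Default pipeline configuration
#'
#' @return nested list with every configurable key at its documented default.
#' @export
default_pipeline_config <- function() {
  list(
    cohort = list(preset = "default", n_subjects = 20, minutes_per_state = 10,
                  fs = 500),
    epoch_len = 5,
    ecg_filter = list(cutoff_hz = 45, order = 4),
    emg_filter = list(band_hz = c(20, 100), order = 4, ripple_db = 0.5),
    zero_phase = TRUE,
    hos = list(seg_len = 256, overlap = 0.5, window = "hann", log_floor = 1e-12),
    fusion = list(n_components = 2),
    eval = list(classifiers = c("knn", "lda", "qda"), knn_k = 9,
                cv = c("random", "group_kfold"), folds = 5,
                train_frac = 0.7, repeats = 20),
    seed = 1,
    out_dir = "roadhos_out"
  )
}

merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s",
                 paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", ")),
         call. = FALSE)
  }
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      merge_config(defaults[[nm]], user[[nm]], paste0(path, ".", nm))
    } else {
      user[[nm]]
    }
  }
  defaults
}

check_range <- function(ok, key, what) {
  if (!ok) stop(sprintf("config key `%s` %s", key, what), call. = FALSE)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML config file (or takes a list), fills in all documented
#' defaults, rejects unknown keys by name, and range-checks every value. An
#' empty file yields the full default config.
#'
#' @param path YAML file path, or `NULL`.
#' @param config a (possibly partial) config list, used when `path` is `NULL`.
#' @return fully-defaulted validated config list, class `pipeline_config`.
#' @export
validate_config <- function(path = NULL, config = list()) {
  if (!is.null(path)) {
    config <- yaml::read_yaml(path)
    if (is.null(config)) config <- list()
  }
  cfg <- merge_config(default_pipeline_config(), config)
  check_range(cfg$cohort$preset %in% c("default", "paper_vehicle", "paper_simulated"),
              "cohort.preset", "must be default, paper_vehicle or paper_simulated")
  check_range(cfg$cohort$n_subjects >= 1, "cohort.n_subjects", "must be >= 1")
  check_range(cfg$cohort$minutes_per_state > 0, "cohort.minutes_per_state", "must be > 0")
  check_range(cfg$cohort$fs > 2 * max(cfg$emg_filter$band_hz), "cohort.fs",
              "must exceed twice the EMG band high edge")
  check_range(cfg$epoch_len > 0, "epoch_len", "must be > 0")
  check_range(cfg$ecg_filter$cutoff_hz > 0 && cfg$ecg_filter$cutoff_hz < cfg$cohort$fs / 2,
              "ecg_filter.cutoff_hz", "must lie in (0, fs/2)")
  check_range(length(cfg$emg_filter$band_hz) == 2 &&
                cfg$emg_filter$band_hz[1] < cfg$emg_filter$band_hz[2],
              "emg_filter.band_hz", "must be (low, high) with low < high")
  check_range(cfg$hos$overlap >= 0 && cfg$hos$overlap < 1, "hos.overlap",
              "must be in [0, 1)")
  check_range(cfg$hos$seg_len >= 4 && cfg$hos$seg_len %% 2 == 0, "hos.seg_len",
              "must be an even number >= 4")
  check_range(cfg$hos$window %in% c("hann", "rect"), "hos.window",
              "must be hann or rect")
  check_range(cfg$fusion$n_components >= 1 && cfg$fusion$n_components <= 6,
              "fusion.n_components", "must be in 1..6")
  check_range(all(cfg$eval$classifiers %in% c("knn", "lda", "qda")),
              "eval.classifiers", "must be a subset of knn, lda, qda")
  check_range(all(cfg$eval$cv %in% c("random", "group_kfold")), "eval.cv",
              "must be a subset of random, group_kfold")
  check_range(cfg$eval$train_frac > 0 && cfg$eval$train_frac < 1,
              "eval.train_frac", "must be in (0, 1)")
  check_range(cfg$eval$folds >= 2, "eval.folds", "must be >= 2")
  check_range(cfg$eval$repeats >= 1, "eval.repeats", "must be >= 1")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full identification pipeline
#'
#' Simulates the cohort, writes recordings and labels, extracts the
#' bispectral features per epoch, persists the full-data PCA fusion model,
#' evaluates every requested classifier under every requested CV scheme
#' (refitting the fusion inside each training side), and writes a JSON
#' report embedding the resolved config. Rerunning with an identical config
#' reproduces the report bit for bit.
#'
#' @param config a `pipeline_config` (see [validate_config()]).
#' @param out_dir output directory (defaults to `config$out_dir`).
#' @param quiet suppress progress messages?
#' @return the report list, invisibly; files under `out_dir`:
#'   `recordings/<subject>.csv`, `labels.csv`, `features.csv`,
#'   `pca_model.json`, `report.json`.
#' @export
run_pipeline <- function(config = validate_config(), out_dir = config$out_dir,
                         quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config = config)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dir.create(file.path(out_dir, "recordings"), recursive = TRUE, showWarnings = FALSE)

  cohort <- stage("simulate", {
    cc <- cohort_config(preset = config$cohort$preset,
                        n_subjects = config$cohort$n_subjects,
                        minutes_per_state = config$cohort$minutes_per_state,
                        fs = config$cohort$fs,
                        seed = derive_seed(config$seed, 1L))
    generate_cohort(cc)
  })
  say("simulate: %d subjects, %g min per state at %g Hz",
      length(cohort$recordings), config$cohort$minutes_per_state, config$cohort$fs)
  stage("write recordings", {
    for (rec in cohort$recordings) {
      write_recording(rec, file.path(out_dir, "recordings",
                                     paste0(rec$subject_id, ".csv")))
    }
    write_labels(cohort$labels, file.path(out_dir, "labels.csv"))
  })

  features <- stage("extract", {
    extract_features(
      cohort$recordings, cohort$labels, epoch_len = config$epoch_len,
      ecg_filter = filter_spec("butterworth", config$ecg_filter$cutoff_hz,
                               order = config$ecg_filter$order,
                               zero_phase = config$zero_phase),
      emg_filter = filter_spec("chebyshev1", config$emg_filter$band_hz,
                               order = config$emg_filter$order,
                               ripple_db = config$emg_filter$ripple_db,
                               zero_phase = config$zero_phase),
      hos = hos_config(config$hos$seg_len, config$hos$overlap,
                       config$hos$window, config$hos$log_floor))
  })
  say("extract: %d epochs x %d features", nrow(features), length(feature_columns()))
  write_features(features, file.path(out_dir, "features.csv"))

  pca <- stage("fuse", fit_pca(features, n_components = config$fusion$n_components))
  write_pca_model(pca, file.path(out_dir, "pca_model.json"))

  results <- list()
  for (clf in config$eval$classifiers) {
    for (scheme in config$eval$cv) {
      res <- stage(sprintf("evaluate %s/%s", clf, scheme), {
        if (scheme == "random") {
          random_cv(features, classifier = clf, k = config$eval$knn_k,
                    train_frac = config$eval$train_frac,
                    n_repeats = config$eval$repeats,
                    seed = derive_seed(config$seed, 2L),
                    n_components = config$fusion$n_components)
        } else {
          group_kfold_cv(features, classifier = clf,
                         k_folds = config$eval$folds, k = config$eval$knn_k,
                         seed = derive_seed(config$seed, 3L),
                         n_components = config$fusion$n_components)
        }
      })
      say("evaluate %s/%s: AC %.1f%%", clf, scheme, res$pooled_metrics$AC)
      results[[paste(clf, scheme, sep = "_")]] <- cv_result_summary(res)
    }
  }

  report <- list(
    config = unclass(config),
    n_subjects = length(cohort$recordings),
    n_epochs = nrow(features),
    explained_variance = pca$explained_variance,
    results = results
  )
  write_report(report, file.path(out_dir, "report.json"))
  invisible(report)
}
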