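# End-to-end pipeline: simulate -> preprocess -> extract -> select ->
# train -> evaluate, driven by one validated config and one global seed.

.CONFIG_SECTIONS <- c("generator", "filter", "feature", "selection",
                      "train", "evaluation", "seed", "out_dir")

#' Default pipeline configuration
#'
#' Section defaults mirror the module defaults: 8 subjects x 11 classes x
#' 10 trials/class of synthetic sEMG, 0.15-450 Hz band-pass + 50 Hz
#' notch, the 57-feature catalogue, 12 mRMR-selected features, a
#' 2n+1-rule tanh network trained by SCG with a 70/15/15 split, and
#' stratified 10-fold evaluation.
#'
#' @param seed global seed.
#' @param out_dir output directory for artifacts.
#' @return A `pipeline_config` list.
#' @export
default_config <- function(seed = 11, out_dir = tempfile("semgvowel_run_")) {
  list(
    generator = list(fs = 1000, n_classes = 11, trials_per_class = 10,
                     n_subjects = 8, subject_gain_sd = 0.15,
                     dc_offset_mv = 0.5, mains_amp_mv = 0.2,
                     drift_amp_mv = 0.3, noise_sd_mv = 0.02,
                     duration_s = 1.0, spec_seed = 7),
    filter = list(band_low = 0.15, band_high = 450, notch_freq = 50,
                  order = 4, notch_q = 30),
    feature = list(),                     # feature_params() overrides
    selection = list(k = 12),
    train = list(split = c(0.70, 0.15, 0.15), max_epochs = 1000,
                 patience = 6),
    evaluation = list(k_folds = 10),
    seed = seed,
    out_dir = out_dir
  )
}

#' Validate a pipeline configuration
#'
#' Unknown top-level keys are rejected; the train split must sum to 1.
#' @param config a config list (as from [default_config()] or
#'   [read_config()]).
#' @return the validated config (invisibly usable).
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), .CONFIG_SECTIONS)
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  base <- default_config()
  for (s in .CONFIG_SECTIONS) {
    if (is.null(config[[s]])) config[[s]] <- base[[s]]
    if (is.list(base[[s]])) {
      bad <- setdiff(names(config[[s]]), names(base[[s]]))
      if (s != "feature" && length(bad) > 0)
        stop("unknown keys in config section '", s, "': ",
             paste(bad, collapse = ", "))
      miss <- setdiff(names(base[[s]]), names(config[[s]]))
      config[[s]][miss] <- base[[s]][miss]
    }
  }
  if (abs(sum(config$train$split) - 1) > 1e-8)
    stop("train split fractions must sum to 1")
  config
}

#' Read a JSON pipeline config
#' @param path JSON file with any subset of the config sections.
#' @return validated config list.
#' @export
read_config <- function(path) {
  validate_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Run the full pipeline
#'
#' Simulate, preprocess, extract the 57 features, rank by mRMR, train the
#' final network on the selected features, and cross-validate.  All
#' artifacts (feature table, selection JSON, model JSON, confusion CSV,
#' manifest JSON) are written under `config$out_dir`.
#'
#' @param config a pipeline config (validated here).
#' @param quiet suppress progress messages.
#' @return run manifest (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[semgvowel] ", ...)
  t0 <- Sys.time()

  say("simulate: ", config$generator$n_subjects, " subjects x ",
      config$generator$n_classes, " classes x ",
      config$generator$trials_per_class, " trials")
  gcfg <- do.call(generator_config,
                  c(config$generator[setdiff(names(config$generator),
                                             "spec_seed")],
                    list(seed = config$seed)))
  specs <- make_class_specs(gcfg$n_classes,
                            rng_seed = config$generator$spec_seed,
                            duration_s = gcfg$duration_s)
  ds <- generate_dataset(gcfg, specs)

  say("preprocess: band-pass ", config$filter$band_low, "-",
      config$filter$band_high, " Hz + ", config$filter$notch_freq,
      " Hz notch")
  fspec <- do.call(filter_spec, config$filter)
  trials <- lapply(ds$trials, preprocess, spec = fspec)

  say("extract: 57-feature catalogue on ", length(trials), " trials")
  fp <- do.call(feature_params, config$feature)
  feats <- t(vapply(trials, extract_features, numeric(57), p = fp))
  colnames(feats) <- feature_names()
  labels <- ds$meta$class_id
  feat_path <- file.path(config$out_dir, "features.csv")
  write_feature_table(feats, labels, ds$meta$subject_id, feat_path)

  say("select: mRMR k = ", config$selection$k)
  sel <- mrmr_rank(feats, labels, k = config$selection$k)
  sel_path <- file.path(config$out_dir, "selection.json")
  write_selection(sel, sel_path)

  say("train: ", length(sel$ranked_indices), "-",
      hidden_size(length(sel$ranked_indices)), "-", gcfg$n_classes,
      " tanh network (SCG)")
  tc <- train_config(split = config$train$split,
                     max_epochs = config$train$max_epochs,
                     patience = config$train$patience,
                     seed = config$seed)
  ncfg <- network_config(length(sel$ranked_indices),
                         n_outputs = gcfg$n_classes, seed = config$seed)
  model <- train_scg(init_network(ncfg),
                     feats[, sel$ranked_indices, drop = FALSE], labels, tc)
  model_path <- file.path(config$out_dir, "model.json")
  write_model(model, model_path)

  say("evaluate: stratified ", config$evaluation$k_folds, "-fold CV")
  cv <- cross_validate(feats, labels, n_select = config$selection$k,
                       k_folds = config$evaluation$k_folds,
                       seed = config$seed, tc = tc,
                       n_classes = gcfg$n_classes)
  cm_path <- file.path(config$out_dir, "confusion.csv")
  utils::write.csv(as.data.frame(unclass(cv$confusion)), cm_path)

  manifest <- list(
    package_version = as.character(utils::packageVersion("semgvowel")),
    seed = config$seed,
    n_trials = length(trials),
    n_features = ncol(feats),
    n_selected = length(sel$ranked_indices),
    n_hidden = model$config$n_hidden,
    n_outputs = model$config$n_outputs,
    cv_overall_accuracy = cv$overall_accuracy,
    cv_fold_accuracy = cv$fold_accuracy,
    stopped_epoch = model$stopped_epoch,
    artifacts = list(features = feat_path, selection = sel_path,
                     model = model_path, confusion = cm_path),
    hashes = as.list(tools::md5sum(c(feat_path, sel_path))),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say(sprintf("done: pooled CV accuracy %.1f %% (%.0f s)",
              cv$overall_accuracy, manifest$elapsed_s))
  invisible(c(manifest, list(cv = cv, selection = sel, model = model)))
}
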