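#' Pipeline configuration
#'
#' Assembles the configuration for a full synthetic run: which classes to
#' simulate, how many scenes per class, the scene settings, the matching
#' gate, and optionally a classifier training stage over the per-scene
#' summaries. Every stochastic stage receives a seed derived
#' deterministically from `master_seed`.
#'
#' @param output_dir directory for the result bundle.
#' @param classes character vector of class labels (see [class_profile()]).
#' @param scenes_per_class scenes simulated per class.
#' @param scene named list of [scene_config()] overrides (all scenes share
#'   them; seeds are derived per scene).
#' @param max_disp matching gate, um.
#' @param train also train a classifier on the per-scene summaries
#'   (needs at least 2 classes and several scenes per class).
#' @param classifier named list of [classifier_config()] overrides.
#' @param master_seed master seed.
#' @return a `rbc_pipeline_config` list.
#' @export
pipeline_config <- function(output_dir, classes = c("healthy", "IDA"),
                            scenes_per_class = 2L, scene = list(),
                            max_disp = 3, train = FALSE, classifier = list(),
                            master_seed = 1L) {
  structure(list(
    output_dir = output_dir, classes = classes,
    scenes_per_class = as.integer(scenes_per_class), scene = scene,
    max_disp = max_disp, train = train, classifier = classifier,
    master_seed = as.integer(master_seed)
  ), class = "rbc_pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full synthetic pipeline
#'
#' simulate -> segment -> measure -> match/Dr -> summarize (-> train), with
#' per-stage outputs written under `output_dir`: per-scene images, truth
#' and per-cell CSVs, a `summaries.csv` of population vectors, classifier
#' metrics when training is enabled, and a `manifest.json` recording the
#' configuration hash, package version and per-stage timing. Byte-stable
#' CSV outputs under a fixed `master_seed`.
#'
#' @param config a [pipeline_config()], or a path to a YAML file of its
#'   fields.
#' @return (invisibly) a list with the summaries tibble, the classifier (or
#'   `NULL`) and the manifest, all also on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timing <- list()
  n_runs <- length(config$classes) * config$scenes_per_class
  seeds <- seed_stream(config$master_seed, n_runs + 1L)
  summaries <- list()
  dataset <- list()
  k <- 0L
  for (cl in config$classes) {
    profile <- .stage("profile", class_profile(cl))
    for (s in seq_len(config$scenes_per_class)) {
      k <- k + 1L
      t1 <- Sys.time()
      sc_args <- utils::modifyList(config$scene, list(seed = seeds[k]))
      sc_cfg <- do.call(scene_config, sc_args)
      scene <- .stage("simulate", simulate_scene(profile, sc_cfg))
      dir_k <- file.path(out, sprintf("%s_scene%02d", cl, s))
      .stage("write", write_scene(scene, dir_k))
      pre_r <- .stage("segment", segment_frame(scene$pre))
      post_r <- .stage("segment", segment_frame(scene$post))
      pre_c <- .stage("measure", measure_cells(pre_r))
      post_c <- .stage("measure", measure_cells(post_r))
      utils::write.csv(pre_c, file.path(dir_k, "cells_pre.csv"),
                       row.names = FALSE)
      utils::write.csv(post_c, file.path(dir_k, "cells_post.csv"),
                       row.names = FALSE)
      m <- .stage("deform", match_cells(pre_c, post_c, config$max_disp))
      utils::write.csv(m$pairs, file.path(dir_k, "pairs.csv"),
                       row.names = FALSE)
      summ <- .stage("summarize",
                     summarize_population(pre_c, dr = m$pairs$dr))
      summaries[[k]] <- dplyr::bind_cols(
        tibble(class_label = cl, scene = s), summ)
      dataset[[k]] <- tibble(
        label = cl,
        params = list(population_vector(summ)),
        image = list(scene$pre)
      )
      timing[[paste0(cl, "_", s)]] <-
        as.numeric(difftime(Sys.time(), t1, units = "secs"))
    }
  }
  summaries <- dplyr::bind_rows(summaries)
  utils::write.csv(summaries, file.path(out, "summaries.csv"),
                   row.names = FALSE)
  clf <- NULL
  if (isTRUE(config$train)) {
    cc_args <- utils::modifyList(config$classifier,
                                 list(seed = seeds[n_runs + 1L]))
    cc <- do.call(classifier_config, cc_args)
    clf <- .stage("train", train_classifier(dplyr::bind_rows(dataset), cc))
    jsonlite::write_json(clf$metrics, file.path(out, "classifier_metrics.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    saveRDS(clf, file.path(out, "classifier.rds"))
  }
  manifest <- list(
    package = "rbcdeform",
    version = as.character(utils::packageVersion("rbcdeform")),
    config_hash = rlang::hash(config),
    master_seed = config$master_seed,
    classes = config$classes,
    scenes_per_class = config$scenes_per_class,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    stage_timing_s = timing
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(summaries = summaries, classifier = clf, manifest = manifest))
}
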