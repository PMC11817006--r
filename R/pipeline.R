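#' Read and validate a pipeline configuration
#'
#' YAML layout (all thresholds surface here as named defaults):
#' \preformatted{
#' fps: 30
#' output_dir: out
#' filter:  {median_kernel: 5, gaussian_kernel: 5, bilateral_kernel: 9}
#' tracker: {flow_threshold: 0.05, diff_threshold: 1, window_end: 40}
#' features: {trr_per_minute: false}
#' scoring:
#'   mode: search            # search | fixed | none
#'   n_iter: 1000
#'   rng_seed: 1
#'   weight_range: [1, 50]
#'   youden_min: 0.70
#'   min_specificity: 0.5
#'   weights: {trv: 48, ade_s: 3, adi_s: 46, trr: 33}  # mode: fixed
#' subjects:
#'   - id: S001
#'     video: s001.tiff
#'     label: copd           # optional
#'     chest_roi: {x: 8, y: 40, width: 80, height: 40}
#'     mouth_roi: {x: 99, y: 18, width: 48, height: 36}
#' # alternatively, skip the image stages entirely:
#' # feature_table: features.csv
#' }
#'
#' @param path YAML file, or an already-parsed list.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  validate_pipeline_config(cfg)
}

#' @noRd
parse_roi <- function(x, role, id) {
  need <- c("x", "y", "width", "height")
  if (is.null(x) || !all(need %in% names(x)))
    stopf("subject '%s': %s_roi must give x, y, width, height", id, role)
  roi(x$x, x$y, x$width, x$height, role = role)
}

#' Validate a pipeline configuration list
#' @param cfg configuration list (see [read_pipeline_config()]).
#' @return The normalized `pipeline_config`.
#' @export
validate_pipeline_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (is.null(cfg$feature_table)) {
    if (is.null(cfg$subjects) || !length(cfg$subjects))
      stopf("config needs either `subjects` or `feature_table`")
    if (is.null(cfg$fps)) stopf("config needs `fps` for video input")
    cfg$subjects <- lapply(seq_along(cfg$subjects), function(i) {
      s <- cfg$subjects[[i]]
      if (is.null(s$id)) s$id <- sprintf("S%03d", i)
      if (is.null(s$video)) stopf("subject '%s' has no video path", s$id)
      s$chest_roi <- parse_roi(s$chest_roi, "chest", s$id)
      s$mouth_roi <- parse_roi(s$mouth_roi, "mouth", s$id)
      s
    })
  }
  cfg$filter <- do.call(filter_config, as.list(cfg$filter))
  cfg$tracker <- do.call(tracker_config, as.list(cfg$tracker))
  if (is.null(cfg$features)) cfg$features <- list()
  sc <- cfg$scoring
  if (is.null(sc)) sc <- list()
  sc$mode <- if (is.null(sc$mode)) "search" else
    match.arg(sc$mode, c("search", "fixed", "none"))
  if (sc$mode == "fixed" && is.null(sc$weights))
    stopf("scoring mode 'fixed' requires `weights`")
  defaults <- list(n_iter = 1000, rng_seed = 1, weight_range = c(1, 50),
                   youden_min = 0.70, min_specificity = 0.5,
                   feature_subset = FEATURES, sd_type = "population")
  cfg$scoring <- modifyList(defaults, sc)
  if (is.null(cfg$output_dir)) cfg$output_dir <- "."
  structure(cfg, class = "pipeline_config")
}

#' Run the full screening pipeline
#'
#' Per subject: read video, preprocess, track, extract features; then
#' fit (or apply) the scoring model over the cohort and evaluate.  All
#' intermediate artifacts are written under `output_dir`: per-subject
#' traces, the feature table, the model JSON and the evaluation
#' report.  A subject whose imaging stage fails is dropped with a
#' logged reason; the cohort fit aborts if fewer than two labelled
#' subjects per class survive.
#'
#' @param config a `pipeline_config`, raw list, or YAML path.
#' @param quiet suppress progress messages?
#' @return List with `features` (data.frame), `model` (or `NULL`),
#'   `report` (or `NULL`), `scored` and `log`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else read_pipeline_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  log <- character(0)
  note <- function(fmt, ...) {
    log <<- c(log, sprintf(fmt, ...)); say(fmt, ...)
  }

  if (!is.null(cfg$feature_table)) {
    feats <- read_feature_table(cfg$feature_table)
    note("loaded feature table '%s' (%d subjects)", cfg$feature_table,
         nrow(feats))
  } else {
    rows <- list()
    for (s in cfg$subjects) {
      t0 <- Sys.time()
      res <- tryCatch({
        seq <- read_video(s$video, cfg$fps)
        seq <- preprocess_sequence(seq, cfg$filter)
        tr <- track(seq, s$chest_roi, s$mouth_roi, cfg$tracker)
        write_trace(tr, file.path(cfg$output_dir,
                                  paste0("trace_", s$id, ".csv")))
        fv <- extract_features(tr,
          trr_per_minute = isTRUE(cfg$features$trr_per_minute))
        if (any(fv$missing))
          note("subject %s: undefined feature(s) %s (too few phase starts)",
               s$id, paste(names(which(fv$missing)), collapse = ", "))
        data.frame(subject_id = s$id, trv = fv$trv, ade_s = fv$ade_s,
                   adi_s = fv$adi_s, trr = fv$trr,
                   label = if (is.null(s$label)) NA_character_
                           else s$label)
      }, error = function(e) {
        note("subject %s dropped: %s", s$id, conditionMessage(e))
        NULL
      })
      if (!is.null(res)) {
        rows[[length(rows) + 1]] <- res
        note("subject %s done in %.1f s (TRV=%g)", s$id,
             as.numeric(Sys.time() - t0, units = "secs"), res$trv)
      }
    }
    if (!length(rows)) stopf("no subject survived the imaging stages")
    feats <- do.call(rbind, rows)
  }
  write_feature_table(feats, file.path(cfg$output_dir, "features.csv"))

  model <- NULL; report <- NULL; scored <- feats
  sc <- cfg$scoring
  fit_rows <- feats[!is.na(feats$label) &
                      stats::complete.cases(feats[FEATURES]), ]
  if (sc$mode != "none") {
    if (nrow(fit_rows) < 4 ||
        min(table(positive_labels(fit_rows$label))) < 2) {
      note("scoring skipped: need >= 2 labelled subjects per class")
    } else {
      model <- if (sc$mode == "fixed") {
        fit_score_model(fit_rows, unlist(sc$weights)[sc$feature_subset],
                        sc$feature_subset, sc$sd_type)
      } else {
        weight_search(fit_rows, n_iter = sc$n_iter,
                      weight_range = sc$weight_range,
                      rng_seed = sc$rng_seed,
                      youden_min = sc$youden_min,
                      min_specificity = sc$min_specificity,
                      feature_subset = sc$feature_subset,
                      sd_type = sc$sd_type)
      }
      write_score_model(model, file.path(cfg$output_dir, "model.json"))
      scored <- score_subjects(model, feats)
      write.csv(scored, file.path(cfg$output_dir, "scored.csv"),
                row.names = FALSE)
      lab <- !is.na(scored$label)
      report <- evaluate_classification(scored$predicted[lab],
                                        scored$label[lab])
      jsonlite::write_json(
        list(evaluation = unclass(report),
             weights = as.list(model$weights),
             threshold = model$threshold, sd_type = model$sd_type,
             rng_seed = sc$rng_seed, mode = sc$mode,
             in_sample = TRUE,
             package_version =
               as.character(utils::packageVersion("thermalbreath"))),
        file.path(cfg$output_dir, "report.json"), auto_unbox = TRUE,
        digits = NA)
      note("model: weights [%s], threshold %.3f, accuracy %.3f",
           paste(model$weights, collapse = ", "), model$threshold,
           report$accuracy)
    }
  }
  writeLines(log, file.path(cfg$output_dir, "run_log.txt"))
  list(features = feats, model = model, report = report,
       scored = scored, log = log)
}
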