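# Experiment orchestration ---------------------------------------------------
#
# Walks an experiment directory tree (one subfolder per recording, each with
# its video / frame directory and geotaxis_metadata.csv), runs split ->
# detect -> track -> summarise per folder with resume logic, then the
# experiment-wide aggregation and, optionally, the statistical layer.

utils::globalVariables(c("time_s", "genotype", "metric", "neglog10_p",
                         "comparison"))

REQUIRED_OUTPUTS <- c("vial_layout.csv", "total_position.csv", "LP_pct.csv",
                      "MP_pct.csv", "HP_pct.csv")

#' Pipeline configuration
#'
#' A single declarative bundle of all stage parameters; every run writes it
#' (plus the seed) into the manifest so outputs are reproducible.
#'
#' @param splitter a [splitter_config()].
#' @param tracker a [tracker_config()].
#' @param min_confidence vial-detection confidence cutoff.
#' @param detect_frame frame index used for vial detection; `NULL` draws a
#'   seeded random frame from the first trim and records it.
#' @param detector detector callable (defaults to the rule-based backend).
#' @param control,comparisons,tmax statistical spec; statistics run only
#'   when both genotype fields are set.
#' @param seed integer seed for all stochastic choices.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(splitter = splitter_config(),
                            tracker = tracker_config(),
                            min_confidence = 0.85, detect_frame = NULL,
                            detector = detect_vials_rule_based,
                            control = NULL, comparisons = NULL, tmax = Inf,
                            seed = 1) {
  structure(list(splitter = splitter, tracker = tracker,
                 min_confidence = min_confidence,
                 detect_frame = detect_frame, detector = detector,
                 control = control, comparisons = comparisons, tmax = tmax,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Discover recording folders under an experiment root
#'
#' A valid recording folder holds `geotaxis_metadata.csv` plus either a
#' `frames/` directory or a video file (`.mp4`/`.h264`). Returned in
#' lexicographic order; malformed subfolders are reported via the
#' `rejected` attribute.
#'
#' @param root experiment root directory.
#' @return character vector of folder paths.
#' @export
discover_folders <- function(root) {
  if (!dir.exists(root)) stop_geotax("root '%s' does not exist", root)
  subs <- sort(list.dirs(root, recursive = FALSE))
  subs <- subs[!basename(subs) %in% c("Output Males", "Output Females")]
  ok <- logical(length(subs)); reason <- character(length(subs))
  for (i in seq_along(subs)) {
    has_meta <- file.exists(file.path(subs[i], "geotaxis_metadata.csv"))
    has_video <- dir.exists(file.path(subs[i], "frames")) ||
      length(list.files(subs[i], pattern = "\\.(mp4|h264)$")) > 0
    ok[i] <- has_meta && has_video
    reason[i] <- if (!has_meta) "missing geotaxis_metadata.csv"
    else if (!has_video) "missing video / frame directory" else ""
  }
  out <- subs[ok]
  attr(out, "rejected") <- data.frame(folder = subs[!ok],
                                      reason = reason[!ok])
  out
}

folder_complete <- function(folder) {
  all(vapply(REQUIRED_OUTPUTS, function(f) {
    p <- file.path(folder, f)
    file.exists(p) &&
      !inherits(tryCatch(utils::read.csv(p, nrows = 2),
                         error = function(e) e), "error")
  }, logical(1)))
}

process_folder <- function(folder, config) {
  meta <- read_metadata(folder)
  input <- file.path(folder, "frames")
  frames <- if (dir.exists(input)) read_frame_dir(input)
  else convert_video(list.files(folder, pattern = "\\.(mp4|h264)$",
                                full.names = TRUE)[1])
  trace <- build_movement_trace(frames, config$splitter,
                                fps = config$tracker$fps)
  write_trace_csv(trace, file.path(folder, "movement_trace.csv"))
  segments <- find_trials(trace, config$splitter)
  if (nrow(segments) == 0L) stop_geotax("no trials detected")
  trims <- cut_segments(frames, segments)
  det_frame <- config$detect_frame %||%
    with_seed(config$seed, sample.int(fr_n(trims[[1]]), 1))
  detections <- config$detector(fr_get(trims[[1]], det_frame))
  layout <- filter_sort_match(detections, meta, config$min_confidence)
  write_layout_csv(layout, file.path(folder, "vial_layout.csv"))
  summaries <- lapply(seq_along(trims), function(k) {
    recs <- track_trim(trims[[k]], layout, config$tracker, trim = k)
    summarize_trim(recs, layout, config$tracker)
  })
  agg <- suppressWarnings(aggregate_trims(summaries))
  write_recording_outputs(agg, folder)
  list(detect_frame = det_frame, n_trials = nrow(segments),
       segments = segments)
}

#' Run the full pipeline over an experiment tree
#'
#' Per folder: split the recording into trials, locate vials, track flies,
#' summarise; folders whose outputs already exist and validate are skipped.
#' Afterwards the ten modality tables are aggregated and written, and the
#' statistical report is produced when `control`/`comparisons` are set in
#' the config. Stage failures mark the folder failed and the run continues.
#'
#' @param root experiment root directory.
#' @param config a [pipeline_config()].
#' @param stats_only skip per-folder processing and rerun only aggregation
#'   plus statistics from existing outputs.
#' @return the run manifest (also written to `run_manifest.json`):
#'   per-folder status and details, the config snapshot, seed and package
#'   version.
#' @export
run_pipeline <- function(root, config = pipeline_config(),
                         stats_only = FALSE) {
  folders <- discover_folders(root)
  status <- list()
  for (folder in folders) {
    nm <- basename(folder)
    if (stats_only || folder_complete(folder)) {
      status[[nm]] <- list(status = "complete", skipped = TRUE)
      next
    }
    status[[nm]] <- tryCatch({
      info <- process_folder(folder, config)
      c(list(status = "complete", skipped = FALSE),
        info[c("detect_frame", "n_trials")])
    }, error = function(e) {
      warning(sprintf("folder '%s' failed: %s", nm, conditionMessage(e)))
      list(status = "failed", error = conditionMessage(e))
    })
  }
  done <- folders[vapply(status[basename(folders)],
                         function(s) s$status == "complete", logical(1))]
  tables <- NULL
  if (length(done)) {
    tables <- suppressWarnings(collect_experiment(done))
    write_modality_tables(tables, root)
  }
  reports <- list()
  if (!is.null(config$control) && length(config$comparisons) &&
      !is.null(tables)) {
    for (sex in c("M", "F")) {
      if (nrow(tables[[sex]]$position) == 0L) next
      rep_sex <- tryCatch(
        comparison_report(tables[[sex]], config$control,
                          config$comparisons, config$tmax),
        error = function(e) {
          warning(sprintf("statistics failed for sex %s: %s", sex,
                          conditionMessage(e)))
          NULL
        })
      if (is.null(rep_sex)) next
      reports[[sex]] <- rep_sex
      outdir <- file.path(root, if (sex == "M") "Output Males"
                          else "Output Females")
      utils::write.csv(rep_sex$table1,
                       file.path(outdir, "comparison_table.csv"),
                       row.names = FALSE)
      jsonlite::write_json(rep_sex$pvalues,
                           file.path(outdir, "pvalues.json"),
                           auto_unbox = TRUE, digits = NA)
      save_report_figures(rep_sex, tables[[sex]], outdir)
    }
  }
  manifest <- list(root = root, folders = status,
                   seed = config$seed,
                   tool_version =
                     as.character(utils::packageVersion("geotaxr")),
                   config = list(
                     min_confidence = config$min_confidence,
                     tmax = config$tmax,
                     control = config$control,
                     comparisons = config$comparisons,
                     splitter = unclass(config$splitter),
                     tracker = unclass(config$tracker)))
  jsonlite::write_json(manifest, file.path(root, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(c(manifest, list(tables = tables, reports = reports)))
}
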