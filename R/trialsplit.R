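# Trial segmentation by motion energy ---------------------------------------
#
# A recording holds four tap-pause cycles. Tapping the rack produces a burst
# of frame-wide motion; the splitter computes a per-frame motion energy
# ("movement units" = summed areas of large moving regions), finds the tap
# spikes, and cuts one 15-second trial after each.

#' Movement trace container
#'
#' @param values per-frame motion energy, finite and non-negative.
#' @param fps frames per second.
#' @return a `movement_trace` list.
#' @export
movement_trace <- function(values, fps = 60) {
  if (length(values) < 1L || any(!is.finite(values)) || any(values < 0))
    stop_geotax("trace values must be finite, non-negative, length >= 1")
  assert_scalar_number(fps, "fps", min = 1e-9)
  structure(list(values = as.numeric(values), fps = fps),
            class = "movement_trace")
}

#' @export
print.movement_trace <- function(x, ...) {
  cat(sprintf("<movement_trace: %d frames @ %g fps, max %.0f units>\n",
              length(x$values), x$fps, max(x$values)))
  invisible(x)
}

#' Splitter configuration
#'
#' Defaults are the assay's published constants: moving regions smaller than
#' 2,000 px^2 are ignored; a tap spike must exceed 100,000 movement units;
#' frames under 30,000 units are inactive; 270+ consecutive inactive frames
#' end a trial; trials are capped at 900 frames (15 s at 60 fps); four
#' trials are expected per recording.
#'
#' @param min_contour_area smallest moving region counted, px^2.
#' @param peak_height minimum tap-spike height, movement units.
#' @param inactive_thresh inactivity threshold, movement units.
#' @param min_inactive_run inactive frames required to end a trial.
#' @param cap_frames maximum trial length, frames.
#' @param expected_trims trials expected per recording.
#' @param diff_thresh grey-level |frame - background| threshold for the
#'   foreground mask.
#' @param bg_learning_rate running-average background update weight per
#'   frame (1/500 mirrors a 500-frame model history).
#' @return a `splitter_config` list.
#' @export
splitter_config <- function(min_contour_area = 2000, peak_height = 100000,
                            inactive_thresh = 30000, min_inactive_run = 270,
                            cap_frames = 900, expected_trims = 4,
                            diff_thresh = 25, bg_learning_rate = 1 / 500) {
  if (inactive_thresh >= peak_height)
    stop_geotax("inactive_thresh must be < peak_height")
  vals <- c(min_contour_area, peak_height, inactive_thresh,
            min_inactive_run, cap_frames, expected_trims, diff_thresh)
  if (any(vals <= 0)) stop_geotax("splitter thresholds must be positive")
  structure(list(min_contour_area = min_contour_area,
                 peak_height = peak_height,
                 inactive_thresh = inactive_thresh,
                 min_inactive_run = as.integer(min_inactive_run),
                 cap_frames = as.integer(cap_frames),
                 expected_trims = as.integer(expected_trims),
                 diff_thresh = diff_thresh,
                 bg_learning_rate = bg_learning_rate),
            class = "splitter_config")
}

#' Motion energy of one frame against a background model
#'
#' Foreground = pixels whose absolute difference from the background exceeds
#' `diff_thresh`; connected foreground regions are labelled and regions of at
#' least `min_contour_area` px^2 contribute their area to the returned total.
#'
#' @param frame,background same-size frame matrices (0-255 grey levels).
#' @param config a [splitter_config()].
#' @return motion energy in movement units (px^2).
#' @export
frame_motion_energy <- function(frame, background,
                                config = splitter_config()) {
  if (!identical(dim(frame), dim(background)))
    stop_geotax("frame and background dimensions differ")
  mask <- abs(frame - background) > config$diff_thresh
  if (!any(mask)) return(0)
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(as.integer(lab))
  sum(areas[areas >= config$min_contour_area])
}

#' Per-frame movement trace of a recording
#'
#' Runs [frame_motion_energy()] over every frame against a running-average
#' background model initialised from the first frame (so the first value is
#' the model's burn-in zero).
#'
#' @param frames list of frames or a [frame_source()].
#' @param config a [splitter_config()].
#' @param fps frames per second recorded on the trace.
#' @return a [movement_trace()], one value per input frame.
#' @export
build_movement_trace <- function(frames, config = splitter_config(),
                                 fps = 60) {
  n <- fr_n(frames)
  if (n < 1L) stop_geotax("need at least one frame")
  bg <- fr_get(frames, 1L)
  lr <- config$bg_learning_rate
  values <- numeric(n)
  for (i in seq_len(n)) {
    fr <- fr_get(frames, i)
    values[i] <- frame_motion_energy(fr, bg, config)
    bg <- (1 - lr) * bg + lr * fr
  }
  movement_trace(values, fps)
}

# Tap-spike candidates: local maxima at or above peak_height.
find_trace_peaks <- function(v, peak_height) {
  n <- length(v)
  prev <- c(-Inf, v[-n]); nxt <- c(v[-1], -Inf)
  which(v >= peak_height & v > prev & v >= nxt)
}

#' Segment a movement trace into trials
#'
#' After each tap spike (local maximum at or above `peak_height`) a trial
#' starts at the first frame whose motion drops below `inactive_thresh`. The
#' trial ends with the first inactivity run of at least `min_inactive_run`
#' frames -- at the end of that run, at `start + cap_frames`, or at the next
#' tap spike, whichever comes first. If more than `expected_trims` trials
#' emerge, the ones after the highest spikes are kept (in temporal order);
#' fewer trials produce a warning but are returned as-is.
#'
#' @param trace a [movement_trace()].
#' @param config a [splitter_config()].
#' @return data.frame with columns `index, start_frame, end_frame,
#'   peak_frame, peak_value`; `start_frame` 1-based inclusive, `end_frame`
#'   exclusive. Zero detected spikes give zero rows.
#' @export
find_trials <- function(trace, config = splitter_config()) {
  v <- trace$values
  n <- length(v)
  peaks <- find_trace_peaks(v, config$peak_height)
  segs <- list()
  last_end <- 0L
  for (pi in seq_along(peaks)) {
    p <- peaks[pi]
    if (p <= last_end) next
    next_peak <- if (pi < length(peaks)) peaks[pi + 1L] else n + 1L
    below <- which(v < config$inactive_thresh)
    start <- below[below > p]
    if (length(start) == 0L) next
    start <- start[1L]
    if (start >= next_peak) next
    end_excl <- trial_end(v, start, next_peak, config)
    segs[[length(segs) + 1L]] <-
      data.frame(start_frame = start, end_frame = end_excl,
                 peak_frame = p, peak_value = v[p])
    last_end <- end_excl - 1L
  }
  if (length(segs) == 0L)
    return(data.frame(index = integer(), start_frame = integer(),
                      end_frame = integer(), peak_frame = integer(),
                      peak_value = numeric()))
  out <- do.call(rbind, segs)
  if (nrow(out) > config$expected_trims) {
    warning(sprintf("%d trials found; keeping the %d with highest spikes",
                    nrow(out), config$expected_trims))
    keep <- order(out$peak_value, decreasing = TRUE)[
      seq_len(config$expected_trims)]
    out <- out[sort(keep), ]
  } else if (nrow(out) < config$expected_trims) {
    warning(sprintf("only %d of %d expected trials found",
                    nrow(out), config$expected_trims))
  }
  out$index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("index", "start_frame", "end_frame", "peak_frame", "peak_value")]
}

# End (exclusive) of the trial starting at `start`: close at the first
# inactivity run of >= min_inactive_run frames, the cap, or the next spike.
trial_end <- function(v, start, next_peak, config) {
  cap_end <- min(start + config$cap_frames, next_peak, length(v) + 1L)
  inactive <- v[start:(cap_end - 1L)] < config$inactive_thresh
  runs <- rle(inactive)
  pos <- start
  for (j in seq_along(runs$lengths)) {
    len <- runs$lengths[j]
    if (runs$values[j] && len >= config$min_inactive_run)
      return(min(pos + len, cap_end))
    pos <- pos + len
  }
  # No qualifying run inside the window: the trial extends to the window
  # edge (the cap, the next spike, or the end of the trace).
  cap_end
}

#' Cut trial segments out of a recording
#'
#' @param frames list of frames or a [frame_source()].
#' @param segments data.frame from [find_trials()].
#' @param dir optional directory; when given, each trim is written as a
#'   frame directory named `<name>_trim<k>`.
#' @param name recording name used for trim directories.
#' @return list of [frame_source()] windows, one per segment, each holding
#'   exactly the frames `[start_frame, end_frame)`.
#' @export
cut_segments <- function(frames, segments, dir = NULL, name = "recording") {
  n <- fr_n(frames)
  if (nrow(segments) == 0L) {
    warning("no segments to cut")
    return(list())
  }
  if (any(segments$start_frame < 1L | segments$end_frame > n + 1L))
    stop_geotax("segment out of range for a %d-frame recording", n)
  trims <- lapply(seq_len(nrow(segments)), function(k) {
    fr_window(frames, segments$start_frame[k], segments$end_frame[k])
  })
  if (!is.null(dir)) {
    for (k in seq_along(trims))
      write_frame_dir(trims[[k]], file.path(dir, sprintf("%s_trim%d",
                                                         name, k)))
  }
  trims
}

#' Write a movement trace audit CSV
#'
#' @param trace a [movement_trace()].
#' @param path output CSV path (columns `frame, movement_units`).
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(frame = seq_along(trace$values),
                              movement_units = trace$values),
                   path, row.names = FALSE)
  invisible(path)
}
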