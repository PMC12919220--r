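# Frame representation ------------------------------------------------------
#
# A frame is a numeric matrix (rows = image y, cols = image x) holding the
# red-channel intensity in [0, 255]. Image coordinates are 0-based with the
# origin at the top-left and y increasing downward; pixel at matrix position
# (r, c) covers the half-open square [c-1, c) x [r-1, r), so its centre is
# (c - 0.5, r - 0.5). Bounding boxes are (x1, y1, x2, y2), half-open
# [x1, x2) x [y1, y2).

#' Lazy frame source
#'
#' Wraps a generator function so long recordings never have to be held in
#' memory as a list. All pipeline functions that take `frames` accept either
#' a plain list of frame matrices or a `frame_source`.
#'
#' @param get function of a single 1-based frame index returning a frame
#'   matrix; must be deterministic in the index.
#' @param n total number of frames.
#' @return an object of class `frame_source`.
#' @export
frame_source <- function(get, n) {
  stopifnot(is.function(get), length(n) == 1L, n >= 1)
  structure(list(get = get, n = as.integer(n)), class = "frame_source")
}

#' @export
print.frame_source <- function(x, ...) {
  cat(sprintf("<frame_source: %d frames>\n", x$n))
  invisible(x)
}

fr_n <- function(frames) {
  if (inherits(frames, "frame_source")) frames$n else length(frames)
}

fr_get <- function(frames, i) {
  if (inherits(frames, "frame_source")) frames$get(i) else frames[[i]]
}

# Subset a frame container into a new lazy source (used to cut trims).
fr_window <- function(frames, start, end_excl) {
  idx <- start:(end_excl - 1L)
  frame_source(function(i) fr_get(frames, idx[i]), length(idx))
}

#' Write frames to a numbered PNG directory
#'
#' The on-disk recording format used throughout the package when no video
#' codec is available: greyscale PNGs named `frame_000001.png`, ... consumed
#' identically to a decoded video downstream.
#'
#' @param frames list of frame matrices or a [frame_source()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_frame_dir <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- fr_n(frames)
  for (i in seq_len(n)) {
    png::writePNG(pmin(pmax(fr_get(frames, i) / 255, 0), 1),
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  invisible(dir)
}

#' Read a numbered frame directory as a lazy frame source
#'
#' @param dir directory of PNG frames (any alphabetically ordered naming).
#' @return a [frame_source()]; frames are re-read on each access. For colour
#'   PNGs the red channel is extracted.
#' @export
read_frame_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stop_geotax("no PNG frames found in '%s'", dir)
  frame_source(function(i) {
    px <- png::readPNG(files[i])
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    px * 255
  }, length(files))
}

#' Decode a video recording into a frame directory
#'
#' Thin wrapper over ffmpeg mirroring the assay's lossless transcode step
#' (`-qscale 0`, fixed output frame rate). If the input is already a frame
#' directory it is passed through untouched. Requires `ffmpeg` on the PATH
#' for real video files; the synthetic pipeline never needs it.
#'
#' @param input path to an `.mp4`/`.h264` file or a frame directory.
#' @param output_dir where extracted frames go (ignored for directories).
#' @param fps output frame rate to enforce (default 60).
#' @return a [frame_source()] over the decoded frames.
#' @export
convert_video <- function(input, output_dir = NULL, fps = 60) {
  if (dir.exists(input)) return(read_frame_dir(input))
  if (!file.exists(input)) stop_geotax("input '%s' does not exist", input)
  if (Sys.which("ffmpeg") == "")
    stop_geotax(paste0("ffmpeg is required to decode '%s'; supply a frame ",
                       "directory instead"), input)
  output_dir <- output_dir %||% tempfile("frames_")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  status <- system2("ffmpeg", c("-y", "-i", shQuote(input),
                                "-qscale:v", "0", "-r", as.character(fps),
                                shQuote(file.path(output_dir,
                                                  "frame_%06d.png"))),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop_geotax("ffmpeg failed on '%s'", input)
  read_frame_dir(output_dir)
}
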