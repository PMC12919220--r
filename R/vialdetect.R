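# Vial localisation ---------------------------------------------------------
#
# Locates the vial regions of a rack frame, matches them to the metadata
# table, and scores detectors against ground truth by bounding-box IoU. The
# shipped backend is a deterministic rule-based detector (column-intensity
# profiling of the dark vial walls); any callable frame -> detections can be
# plugged into the evaluation and matching machinery, so a learned detector
# can stand behind the same interface.

#' Rule-based vial detector
#'
#' Finds vials as pairs of tall dark vertical strips (the vial walls)
#' against the light background: columns whose count of dark pixels reaches
#' `min_height_frac` of the tallest column are wall candidates, consecutive
#' candidates are merged into strips, and adjacent strips are paired
#' left-to-right into boxes. Confidence is the mean fraction of wall-strip
#' rows that are dark (1 for a clean rack).
#'
#' @param frame frame matrix, grey levels 0-255.
#' @param dark_thresh grey level below which a pixel counts as dark.
#' @param min_height_frac fraction of the tallest dark column a wall must
#'   reach.
#' @param min_rows minimum absolute dark-column height, px (rejects blank
#'   frames).
#' @return data.frame of detections `x1, y1, x2, y2, confidence, label`
#'   (possibly zero rows), boxes in 0-based half-open pixel coordinates.
#' @export
detect_vials_rule_based <- function(frame, dark_thresh = 128,
                                    min_height_frac = 0.5, min_rows = 20) {
  if (nrow(frame) < 32 || ncol(frame) < 32)
    stop_geotax("frame too small for vial detection")
  dark <- frame < dark_thresh
  colcount <- colSums(dark)
  empty <- data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), confidence = numeric(),
                      label = character())
  if (max(colcount) < min_rows) return(empty)
  tall <- colcount >= min_height_frac * max(colcount)
  runs <- rle(tall)
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1L
  strips <- cbind(starts, stops)[runs$values, , drop = FALSE]
  if (nrow(strips) < 2L) return(empty)
  n_pairs <- floor(nrow(strips) / 2)
  if (nrow(strips) %% 2L == 1L)
    warning("odd number of wall strips; dropping the rightmost")
  dets <- lapply(seq_len(n_pairs), function(k) {
    left <- strips[2L * k - 1L, ]; right <- strips[2L * k, ]
    cols <- c(left[1]:left[2], right[1]:right[2])
    rows_dark <- which(rowSums(dark[, cols, drop = FALSE]) > 0)
    y1 <- min(rows_dark) - 1L; y2 <- max(rows_dark)
    conf <- mean(colMeans(dark[(y1 + 1L):y2, cols, drop = FALSE]))
    data.frame(x1 = left[1] - 1L, y1 = y1, x2 = right[2], y2 = y2,
               confidence = min(1, conf), label = "vial")
  })
  out <- do.call(rbind, dets)
  rownames(out) <- NULL
  out
}

#' Filter, sort and match detections to metadata
#'
#' Drops detections below `min_confidence`, sorts the survivors
#' left-to-right by `x1`, numbers them positionally (leftmost = vial 1), and
#' keeps only positions whose vial number appears in the metadata.
#'
#' @param detections data.frame from a detector (`x1, y1, x2, y2,
#'   confidence`).
#' @param metadata data.frame with a `Vial_Num` column (see
#'   [read_metadata()]).
#' @param min_confidence detection confidence cutoff (default 0.85).
#' @return a vial layout: data.frame `vial_num, x1, y1, x2, y2` sorted by
#'   `x1`.
#' @export
filter_sort_match <- function(detections, metadata, min_confidence = 0.85) {
  keep <- detections[detections$confidence >= min_confidence, , drop = FALSE]
  keep <- keep[order(keep$x1), , drop = FALSE]
  wanted <- sort(unique(as.integer(metadata$Vial_Num)))
  if (nrow(keep) < length(wanted)) {
    missing <- setdiff(wanted, seq_len(nrow(keep)))
    stop_geotax("only %d confident detections for %d metadata vials (missing: %s)",
                nrow(keep), length(wanted), paste(missing, collapse = ", "))
  }
  keep$vial_num <- seq_len(nrow(keep))
  out <- keep[keep$vial_num %in% wanted,
              c("vial_num", "x1", "y1", "x2", "y2")]
  rownames(out) <- NULL
  out
}

#' Intersection over union of two boxes
#'
#' Boxes are `(x1, y1, x2, y2)`, half-open; degenerate (non-positive area)
#' boxes are an error. Disjoint boxes score 0, identical boxes 1.
#'
#' @param a,b numeric length-4 box vectors or one-row data.frames.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  a <- as_box(a); b <- as_box(b)
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- (a[3] - a[1]) * (a[4] - a[2]) +
    (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

as_box <- function(b) {
  if (is.data.frame(b)) b <- unlist(b[1, c("x1", "y1", "x2", "y2")])
  b <- as.numeric(b)[1:4]
  if (b[1] >= b[3] || b[2] >= b[4]) stop_geotax("degenerate box")
  b
}

#' Evaluate a detector against annotated frames
#'
#' Greedy highest-IoU matching of detections to ground-truth boxes;
#' unmatched ground-truth boxes score 0.
#'
#' @param detector function taking a frame and returning a detection
#'   data.frame (see [detect_vials_rule_based()]).
#' @param frames list of frames or a [frame_source()].
#' @param truth_boxes a single boxes data.frame (shared rack layout) or a
#'   list with one boxes data.frame per frame.
#' @return list with `mean_iou`, `per_frame` (frame, mean_iou) and `ious`
#'   (every ground-truth box's matched IoU).
#' @export
evaluate_detector <- function(detector, frames, truth_boxes) {
  n <- fr_n(frames)
  if (n < 1L) stop_geotax("need at least one annotated frame")
  per_frame <- numeric(n)
  all_ious <- list()
  for (i in seq_len(n)) {
    gt <- if (is.data.frame(truth_boxes)) truth_boxes else truth_boxes[[i]]
    det <- detector(fr_get(frames, i))
    ious <- match_boxes_greedy(det, gt)
    all_ious[[i]] <- ious
    per_frame[i] <- mean(ious)
  }
  list(mean_iou = mean(unlist(all_ious)),
       per_frame = data.frame(frame = seq_len(n), mean_iou = per_frame),
       ious = unlist(all_ious))
}

# One IoU per ground-truth box via greedy best-pair-first matching.
match_boxes_greedy <- function(det, gt) {
  ng <- nrow(gt)
  scores <- numeric(ng)
  if (nrow(det) == 0L || ng == 0L) return(scores)
  m <- outer(seq_len(nrow(det)), seq_len(ng),
             Vectorize(function(i, j) iou(det[i, ], gt[j, ])))
  repeat {
    best <- which(m == max(m), arr.ind = TRUE)[1, , drop = FALSE]
    if (m[best] <= 0) break
    scores[best[2]] <- m[best]
    m[best[1], ] <- -1
    m[, best[2]] <- -1
    if (all(m < 0)) break
  }
  scores
}

#' Write / read a vial layout CSV
#'
#' @param layout data.frame `vial_num, x1, y1, x2, y2`.
#' @param path CSV path.
#' @return `write_layout_csv` the path invisibly; `read_layout_csv` the
#'   layout data.frame.
#' @export
write_layout_csv <- function(layout, path) {
  utils::write.csv(layout[, c("vial_num", "x1", "y1", "x2", "y2")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout_csv
#' @export
read_layout_csv <- function(path) {
  layout <- utils::read.csv(path)
  need <- c("vial_num", "x1", "y1", "x2", "y2")
  if (!all(need %in% names(layout)))
    stop_geotax("layout CSV '%s' must have columns %s", path,
                paste(need, collapse = ","))
  layout[, need]
}

#' Write COCO-style annotations for vial boxes
#'
#' One image entry per frame, one `bbox = (x, y, w, h)` annotation per vial,
#' single category `"vial"`.
#'
#' @param boxes data.frame `x1, y1, x2, y2` (optionally `vial_num`).
#' @param path JSON output path.
#' @param image_files character vector of image file names.
#' @param image_size `c(width, height)` px.
#' @return the path, invisibly.
#' @export
write_coco_annotations <- function(boxes, path, image_files = "frame_1.png",
                                   image_size = c(1280, 720)) {
  images <- lapply(seq_along(image_files), function(i)
    list(id = i, file_name = image_files[i],
         width = image_size[1], height = image_size[2]))
  anns <- list(); aid <- 0L
  for (i in seq_along(image_files)) {
    for (j in seq_len(nrow(boxes))) {
      aid <- aid + 1L
      w <- boxes$x2[j] - boxes$x1[j]; h <- boxes$y2[j] - boxes$y1[j]
      anns[[aid]] <- list(id = aid, image_id = i,
                          bbox = c(boxes$x1[j], boxes$y1[j], w, h),
                          area = w * h, category_id = 1L, iscrowd = 0L)
    }
  }
  jsonlite::write_json(list(images = images, annotations = anns,
                            categories = list(list(id = 1L, name = "vial"))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO-style vial annotations
#'
#' @param path COCO JSON path.
#' @return list with `images` (id, file_name, width, height) and `boxes`
#'   (image_id, x, y, w, h, category) data.frames. Annotations referencing
#'   unknown images or out-of-bounds boxes are an error.
#' @export
read_coco_annotations <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_geotax("malformed COCO JSON '%s': %s", path,
                                conditionMessage(e)))
  cats <- vapply(doc$categories, function(c) c$name, "")
  if (!all(cats %in% "vial"))
    stop_geotax("unexpected categories in '%s'", path)
  images <- do.call(rbind, lapply(doc$images, function(im)
    data.frame(id = im$id, file_name = im$file_name,
               width = im$width, height = im$height)))
  boxes <- do.call(rbind, lapply(doc$annotations, function(a) {
    bb <- unlist(a$bbox)
    data.frame(image_id = a$image_id, x = bb[1], y = bb[2],
               w = bb[3], h = bb[4], category = "vial")
  }))
  if (!is.null(boxes)) {
    miss <- setdiff(boxes$image_id, images$id)
    if (length(miss))
      stop_geotax("annotation references missing image id %s in '%s'",
                  paste(miss, collapse = ","), path)
    dims <- images[match(boxes$image_id, images$id), ]
    if (any(boxes$x < 0 | boxes$y < 0 |
            boxes$x + boxes$w > dims$width |
            boxes$y + boxes$h > dims$height))
      stop_geotax("annotation box out of image bounds in '%s'", path)
  }
  list(images = images, boxes = boxes)
}
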