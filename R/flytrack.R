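# Fly centroid tracking and zoning ------------------------------------------
#
# Per trim: a background image is built as the per-pixel maximum of the red
# channel over all frames (flies are transient dark blobs, so the maximum
# recovers the empty scene); each frame is subtracted from it, thresholded
# separately in the upper and lower image halves, and connected components
# within an area band become fly centroids. Centroids are assigned to vials
# by box containment and to low/middle/high performer (LP/MP/HP) zones by
# their height above the vial bottom.

#' Tracker configuration
#'
#' Published assay constants: 60 fps recordings, the first 780 frames of
#' each trim tracked, subsampled every 30 frames (2 Hz), and heights mapped
#' through a 17 cm chamber imaged over 720 px. Zone fractions default to
#' vertical thirds; the thresholds and the early-frame top-of-vial guard are
#' configurable with synthetic-scene-validated defaults.
#'
#' @param fps frames per second.
#' @param subsample_step frames between summary time points (30 = 2 Hz).
#' @param frames_per_trim frames tracked per trim.
#' @param thresh_top,thresh_bottom normalised background-difference
#'   thresholds for the upper / lower image halves.
#' @param min_blob_area,max_blob_area accepted component area band, px^2.
#' @param lp_frac,mp_frac zone fractions of the vial height (LP below
#'   `lp_frac`, HP at or above `lp_frac + mp_frac`).
#' @param adder_px early-frame guard band below the vial top, px; `NULL`
#'   means 10% of each vial's height.
#' @param guard_frames frames for which the guard is active.
#' @param holder_height_cm,image_height_px the pixel-to-cm map constants.
#' @return a `tracker_config` list.
#' @export
tracker_config <- function(fps = 60, subsample_step = 30,
                           frames_per_trim = 780, thresh_top = 0.12,
                           thresh_bottom = 0.18, min_blob_area = 4,
                           max_blob_area = 400, lp_frac = 1 / 3,
                           mp_frac = 1 / 3, adder_px = NULL,
                           guard_frames = 60, holder_height_cm = 17,
                           image_height_px = 720) {
  stopifnot(lp_frac > 0, mp_frac > 0, lp_frac + mp_frac < 1,
            frames_per_trim >= subsample_step,
            thresh_top > 0, thresh_top < 1,
            thresh_bottom > 0, thresh_bottom < 1)
  structure(list(fps = fps, subsample_step = as.integer(subsample_step),
                 frames_per_trim = as.integer(frames_per_trim),
                 thresh_top = thresh_top, thresh_bottom = thresh_bottom,
                 min_blob_area = min_blob_area,
                 max_blob_area = max_blob_area,
                 lp_frac = lp_frac, mp_frac = mp_frac,
                 adder_px = adder_px,
                 guard_frames = as.integer(guard_frames),
                 holder_height_cm = holder_height_cm,
                 image_height_px = image_height_px),
            class = "tracker_config")
}

#' Per-pixel maximum background image
#'
#' Elementwise maximum of the red channel over all frames, normalised to
#' `[0, 1]`. Transient dark flies vanish; anything static (vial walls)
#' remains.
#'
#' @param frames list of frames or a [frame_source()].
#' @return background matrix in `[0, 1]`.
#' @export
compute_background <- function(frames) {
  n <- fr_n(frames)
  if (n < 1L) stop_geotax("need at least one frame")
  bg <- fr_get(frames, 1L)
  for (i in seq_len(n)[-1]) {
    fr <- fr_get(frames, i)
    if (!identical(dim(fr), dim(bg)))
      stop_geotax("inconsistent frame sizes at frame %d", i)
    bg <- pmax(bg, fr)
  }
  bg / 255
}

#' Segment fly centroids in one frame
#'
#' The clipped difference `background - frame` is binarised with
#' `thresh_top` above the image midline and `thresh_bottom` below it;
#' connected components within `[min_blob_area, max_blob_area]` px^2 are
#' returned as centroids.
#'
#' @param frame frame matrix (0-255 grey levels).
#' @param background matrix in `[0, 1]` from [compute_background()].
#' @param config a [tracker_config()].
#' @return data.frame `x, y, area` (0-based pixel-centre coordinates); zero
#'   rows when nothing is found.
#' @export
segment_flies <- function(frame, background, config = tracker_config()) {
  if (!identical(dim(frame), dim(background)))
    stop_geotax("frame and background dimensions differ")
  diffim <- pmax(background - frame / 255, 0)
  h <- nrow(diffim)
  mid <- floor(h / 2)
  thr <- matrix(config$thresh_bottom, nrow = h, ncol = ncol(diffim))
  if (mid >= 1L) thr[seq_len(mid), ] <- config$thresh_top
  mask <- diffim > thr
  empty <- data.frame(x = numeric(), y = numeric(), area = numeric())
  if (!any(mask)) return(empty)
  lab <- as.integer(EBImage::bwlabel(mask))
  areas <- tabulate(lab)
  keep <- which(areas >= config$min_blob_area &
                  areas <= config$max_blob_area)
  if (length(keep) == 0L) return(empty)
  idx <- which(lab > 0 & lab %in% keep)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  grp <- lab[idx]
  cx <- tapply(cols - 0.5, grp, mean)
  cy <- tapply(rows - 0.5, grp, mean)
  data.frame(x = as.numeric(cx), y = as.numeric(cy),
             area = areas[as.integer(names(cx))])
}

#' Assign a centroid to a vial
#'
#' Containment uses the half-open convention `x1 <= x < x2`,
#' `y1 <= y < y2`; a point on the shared edge of two boxes therefore
#' belongs to the right-hand box. Overlapping-box ties go to the smallest
#' `x1`.
#'
#' @param x,y centroid coordinates (0-based pixels).
#' @param layout vial layout data.frame (`vial_num, x1, y1, x2, y2`).
#' @return the containing `vial_num`, or `NA` if no box contains the point.
#' @export
assign_vial <- function(x, y, layout) {
  hit <- which(layout$x1 <= x & x < layout$x2 &
                 layout$y1 <= y & y < layout$y2)
  if (length(hit) == 0L) return(NA_integer_)
  if (length(hit) > 1L) hit <- hit[which.min(layout$x1[hit])]
  as.integer(layout$vial_num[hit])
}

#' Classify a centroid into LP/MP/HP zones
#'
#' With vial pixel height `H` and height-from-bottom `hfb = y2 - y`: LP if
#' `hfb < lp_frac * H`, HP if `hfb >= (lp_frac + mp_frac) * H`, MP
#' otherwise. During the first `guard_frames` frames, centroids within
#' `adder_px` of the vial top are suppressed (`NA`): flies cannot have
#' climbed there yet, so such blobs are treated as false positives not yet
#' fully in view.
#'
#' @param y centroid y (0-based pixels, increasing downward).
#' @param vial_box one-row layout entry (`x1, y1, x2, y2`).
#' @param config a [tracker_config()].
#' @param frame 1-based frame index within the trim.
#' @return `"LP"`, `"MP"`, `"HP"`, or `NA` when guarded.
#' @export
classify_zone <- function(y, vial_box, config = tracker_config(),
                          frame = Inf) {
  y1 <- vial_box$y1; y2 <- vial_box$y2
  if (y < y1 || y > y2) stop_geotax("y = %g outside vial box", y)
  H <- y2 - y1
  adder <- config$adder_px %||% (0.1 * H)
  if (frame <= config$guard_frames && (y - y1) < adder)
    return(NA_character_)
  hfb <- y2 - y
  if (hfb < config$lp_frac * H) "LP"
  else if (hfb >= (config$lp_frac + config$mp_frac) * H) "HP"
  else "MP"
}

#' Track all flies over one trim
#'
#' Builds the trim background over every frame, then processes exactly
#' `min(frames_per_trim, n)` frames, emitting one record per accepted
#' centroid. Centroids outside every vial box are dropped (counted in the
#' `dropped` attribute); guard-suppressed centroids are dropped likewise.
#'
#' @param frames trim frames (list or [frame_source()]).
#' @param layout vial layout data.frame.
#' @param config a [tracker_config()].
#' @param trim trim index recorded on the output.
#' @return data.frame `trim, frame, vial_num, x, y, zone` (frame 1-based).
#' @export
track_trim <- function(frames, layout, config = tracker_config(),
                       trim = 1L) {
  n <- fr_n(frames)
  if (n < 1L) stop_geotax("trim has no frames")
  bg <- compute_background(frames)
  n_use <- min(config$frames_per_trim, n)
  recs <- vector("list", n_use)
  dropped <- 0L
  for (i in seq_len(n_use)) {
    cent <- segment_flies(fr_get(frames, i), bg, config)
    if (nrow(cent) == 0L) next
    vial <- vapply(seq_len(nrow(cent)), function(j)
      assign_vial(cent$x[j], cent$y[j], layout), integer(1))
    ok <- !is.na(vial)
    dropped <- dropped + sum(!ok)
    if (!any(ok)) next
    cent <- cent[ok, , drop = FALSE]; vial <- vial[ok]
    zone <- vapply(seq_len(nrow(cent)), function(j)
      classify_zone(cent$y[j], layout[layout$vial_num == vial[j], ],
                    config, frame = i), character(1))
    keep <- !is.na(zone)
    dropped <- dropped + sum(!keep)
    if (!any(keep)) next
    recs[[i]] <- data.frame(trim = trim, frame = i,
                            vial_num = vial[keep],
                            x = cent$x[keep], y = cent$y[keep],
                            zone = zone[keep])
  }
  recs <- recs[!vapply(recs, is.null, TRUE)]
  out <- if (length(recs)) do.call(rbind, recs)
  else data.frame(trim = integer(), frame = integer(),
                  vial_num = integer(), x = numeric(), y = numeric(),
                  zone = character())
  attr(out, "dropped") <- dropped
  out
}

#' Convert a pixel displacement to centimetres
#'
#' The chamber holder height (17 cm by default) is imaged over
#' `image_height_px` rows, so `cm = holder_height_cm * adj /
#' image_height_px` (17 * adj / 720 with assay defaults).
#'
#' @param adj adjusted vertical displacement in pixels (>= 0, vectorised).
#' @param holder_height_cm,image_height_px the map constants.
#' @return displacement in cm.
#' @export
pixels_to_cm <- function(adj, holder_height_cm = 17, image_height_px = 720) {
  if (any(adj < 0)) stop_geotax("pixel displacement must be >= 0")
  holder_height_cm * adj / image_height_px
}

#' Convert a frame count to seconds
#'
#' @param frame frame index or count (vectorised).
#' @param fps frames per second (> 0).
#' @return `frame / fps`, seconds.
#' @export
frame_to_seconds <- function(frame, fps = 60) {
  assert_scalar_number(fps, "fps", min = 1e-9)
  frame / fps
}

#' Summarise one trim onto the 2 Hz grid
#'
#' At every `subsample_step`-th frame, per vial: mean height above the vial
#' bottom (cm, via [pixels_to_cm()]) and zone percentages (zone count /
#' detected count x 100, so populated time points always sum to 100). Vials
#' with no detection at a time point carry `NA` and `n = 0`.
#'
#' @param records output of [track_trim()].
#' @param layout vial layout data.frame.
#' @param config a [tracker_config()].
#' @return data.frame `time_s, vial_num, mean_height_cm, pct_lp, pct_mp,
#'   pct_hp, n`.
#' @export
summarize_trim <- function(records, layout, config = tracker_config()) {
  frames <- seq(1L, config$frames_per_trim, by = config$subsample_step)
  grid <- expand.grid(frame = frames, vial_num = layout$vial_num)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    f <- grid$frame[g]; v <- grid$vial_num[g]
    sub <- records[records$frame == f & records$vial_num == v, ,
                   drop = FALSE]
    y2 <- layout$y2[layout$vial_num == v]
    n <- nrow(sub)
    if (n == 0L) {
      data.frame(time_s = frame_to_seconds(f - 1L, config$fps),
                 vial_num = v, mean_height_cm = NA_real_,
                 pct_lp = NA_real_, pct_mp = NA_real_, pct_hp = NA_real_,
                 n = 0L)
    } else {
      data.frame(time_s = frame_to_seconds(f - 1L, config$fps),
                 vial_num = v,
                 mean_height_cm = mean(pixels_to_cm(
                   pmax(y2 - sub$y, 0), config$holder_height_cm,
                   config$image_height_px)),
                 pct_lp = 100 * mean(sub$zone == "LP"),
                 pct_mp = 100 * mean(sub$zone == "MP"),
                 pct_hp = 100 * mean(sub$zone == "HP"),
                 n = n)
    }
  })
  do.call(rbind, rows)
}

#' Aggregate trim summaries into mean +/- SEM series
#'
#' Technical replicates (the four trims) are averaged per time point and
#' vial; SEM = sd/sqrt(n) over trims with data. A single contributing trim
#' reports SEM 0 with a warning.
#'
#' @param summaries list of [summarize_trim()] outputs.
#' @return data.frame `time_s, vial_num, mean_height_cm, mean_height_sem,
#'   pct_lp, pct_lp_sem, pct_mp, pct_mp_sem, pct_hp, pct_hp_sem, n_trims`.
#' @export
aggregate_trims <- function(summaries) {
  if (length(summaries) < 1L) stop_geotax("no trim summaries supplied")
  all <- do.call(rbind, summaries)
  key <- interaction(all$time_s, all$vial_num, drop = TRUE)
  rows <- lapply(split(all, key), function(g) {
    agg <- function(col) {
      v <- g[[col]][!is.na(g[[col]])]
      c(mean = if (length(v)) mean(v) else NA_real_, sem = sem(v),
        n = length(v))
    }
    h <- agg("mean_height_cm"); lp <- agg("pct_lp")
    mp <- agg("pct_mp"); hp <- agg("pct_hp")
    data.frame(time_s = g$time_s[1], vial_num = g$vial_num[1],
               mean_height_cm = h["mean"], mean_height_sem = h["sem"],
               pct_lp = lp["mean"], pct_lp_sem = lp["sem"],
               pct_mp = mp["mean"], pct_mp_sem = mp["sem"],
               pct_hp = hp["mean"], pct_hp_sem = hp["sem"],
               n_trims = as.integer(h["n"]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$vial_num, out$time_s), ]
  rownames(out) <- NULL
  if (any(out$n_trims == 1L))
    warning("some time points aggregate a single trim; SEM reported as 0")
  out
}

#' Write per-recording summary CSVs
#'
#' Emits the four wide summary tables the experiment aggregator consumes:
#' `total_position.csv`, `LP_pct.csv`, `MP_pct.csv`, `HP_pct.csv`, each with
#' a `time_s` column plus one value and one `_sem` column per vial.
#'
#' @param agg output of [aggregate_trims()].
#' @param dir destination folder.
#' @return invisibly, the written file paths.
#' @export
write_recording_outputs <- function(agg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spread <- function(val_col, sem_col) {
    times <- sort(unique(agg$time_s))
    out <- data.frame(time_s = times)
    for (v in sort(unique(agg$vial_num))) {
      sub <- agg[agg$vial_num == v, ]
      out[[paste0("vial_", v)]] <- sub[[val_col]][match(times, sub$time_s)]
      out[[paste0("vial_", v, "_sem")]] <-
        sub[[sem_col]][match(times, sub$time_s)]
    }
    out
  }
  files <- c(total_position = "total_position.csv", pct_lp = "LP_pct.csv",
             pct_mp = "MP_pct.csv", pct_hp = "HP_pct.csv")
  cols <- list(c("mean_height_cm", "mean_height_sem"),
               c("pct_lp", "pct_lp_sem"), c("pct_mp", "pct_mp_sem"),
               c("pct_hp", "pct_hp_sem"))
  paths <- character(0)
  for (k in seq_along(files)) {
    p <- file.path(dir, files[k])
    utils::write.csv(spread(cols[[k]][1], cols[[k]][2]), p,
                     row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
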