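test_that("the max-projection background erases transient dark blobs", {
  fr <- matrix(200, 40, 40)
  expect_equal(compute_background(list(fr)), fr / 255)
  expect_equal(compute_background(list(fr, fr, fr)), fr / 255)
  # a dark dot moving across the field leaves no trace in the background
  frames <- lapply(1:5, function(i) { f <- fr; f[20, i * 5] <- 10; f })
  expect_equal(compute_background(frames), fr / 255)
  expect_error(compute_background(list(fr, matrix(0, 10, 10))),
               "inconsistent")
})

test_that("segmentation returns centroids of area-banded components", {
  bg <- matrix(1, 60, 60)
  cfg <- tracker_config(min_blob_area = 4, max_blob_area = 100)
  fr <- matrix(255, 60, 60)
  expect_equal(nrow(segment_flies(fr, bg, cfg)), 0)
  # one symmetric 5x5 blob centred at (30.5, 40.5) in 0-based coords
  fr[39:43, 29:33] <- 20
  cent <- segment_flies(fr, bg, cfg)
  expect_equal(nrow(cent), 1)
  expect_lt(abs(cent$x - 30.5), 1)
  expect_lt(abs(cent$y - 40.5), 1)
  # blobs below the minimum area are excluded
  tiny <- matrix(255, 60, 60); tiny[10, 10] <- 20
  cfg2 <- tracker_config(min_blob_area = 4)
  expect_equal(nrow(segment_flies(tiny, bg, cfg2)), 0)
})

test_that("vial assignment uses half-open containment with x1 ties", {
  layout <- data.frame(vial_num = 2:3, x1 = c(0, 50), y1 = 0,
                       x2 = c(50, 100), y2 = 100)
  expect_equal(assign_vial(60, 50, layout), 3L)
  expect_true(is.na(assign_vial(200, 50, layout)))
  # a centroid on the shared edge belongs to the right-hand box
  expect_equal(assign_vial(50, 10, layout), 3L)
  # overlapping boxes: smallest x1 wins
  over <- data.frame(vial_num = c(7, 8), x1 = c(0, 20), y1 = 0,
                     x2 = c(60, 80), y2 = 100)
  expect_equal(assign_vial(30, 10, over), 7L)
})

test_that("zone classification tiles the vial and guards the top early on", {
  box <- data.frame(x1 = 0, y1 = 100, x2 = 50, y2 = 700) # H = 600
  cfg <- tracker_config()
  expect_equal(classify_zone(700, box, cfg, frame = 100), "LP")
  expect_equal(classify_zone(100, box, cfg, frame = 100), "HP")
  # height-from-bottom 250 px with thirds: MP (200 <= 250 < 400)
  expect_equal(classify_zone(450, box, cfg, frame = 100), "MP")
  # exact boundaries: 200 -> MP, 400 -> HP
  expect_equal(classify_zone(500, box, cfg, frame = 100), "MP")
  expect_equal(classify_zone(300, box, cfg, frame = 100), "HP")
  # early frames suppress centroids within the top guard band
  expect_true(is.na(classify_zone(110, box, cfg, frame = 10)))
  expect_equal(classify_zone(110, box, cfg, frame = 61), "HP")
  expect_error(classify_zone(20, box, cfg), "outside")
  # every y maps to exactly one zone once the guard has lapsed
  zones <- vapply(seq(100, 699.5, by = 0.5), classify_zone, "",
                  vial_box = box, config = cfg, frame = 100)
  expect_equal(as.numeric(table(zones)[c("LP", "MP", "HP")] /
                            length(zones)),
               rep(1 / 3, 3), tolerance = 0.01)
})

test_that("unit conversions match the chamber geometry exactly", {
  expect_equal(pixels_to_cm(720), 17)
  expect_equal(pixels_to_cm(0), 0)
  expect_equal(pixels_to_cm(360), 8.5)
  expect_error(pixels_to_cm(-1), ">= 0")
  # linearity
  expect_equal(pixels_to_cm(123) + pixels_to_cm(77), pixels_to_cm(200))
  expect_equal(frame_to_seconds(0), 0)
  expect_equal(frame_to_seconds(900), 15)
  expect_equal(frame_to_seconds(30), 0.5)
})

test_that("tracking processes the configured window and recovers truth", {
  sc <- small_scene(n_vials = 2, noise_sd = 0, seed = 11)
  kin <- small_kinematics(sc, n_flies = 1, speed_sd = 0, stall_prob = 0)
  cl <- render_climb_frames(sc, kin, n_frames = 70)
  cfg <- small_tracker(sc, frames_per_trim = 50)
  recs <- track_trim(cl$frames, sc$vial_boxes, cfg)
  expect_equal(max(recs$frame), 50) # window, not trim length
  expect_equal(sort(unique(recs$vial_num)), 1:2)
  # noise-free recovery: centroids within 2 px RMS of ground truth
  tru <- cl$truth$trajectories
  err <- vapply(seq_len(nrow(recs)), function(i) {
    t1 <- tru[tru$frame == recs$frame[i] &
                tru$vial_num == recs$vial_num[i], ]
    sqrt(min((t1$x - recs$x[i])^2 + (t1$y - recs$y[i])^2))
  }, numeric(1))
  expect_lt(sqrt(mean(err^2)), 2)
})

test_that("per-frame centroid counts track the true fly count", {
  sc <- small_scene(n_vials = 2, seed = 3)
  kin <- small_kinematics(sc, n_flies = 5, stall_prob = 0, speed_sd = 0.3)
  cl <- render_climb_frames(sc, kin, n_frames = 150)
  cfg <- small_tracker(sc, frames_per_trim = 150)
  recs <- track_trim(cl$frames, sc$vial_boxes, cfg)
  # blobs that start bunched at the vial bottom need a couple of seconds to
  # separate at this scaled-down resolution; score the settled phase
  counts <- table(factor(recs$vial_num, levels = 1:2),
                  factor(recs$frame, levels = 51:150))
  expect_gte(mean(abs(counts - 5) <= 1), 0.9)
})

test_that("trim summaries are on the subsampled grid with closed sums", {
  sc <- small_scene(n_vials = 2, seed = 5)
  kin <- small_kinematics(sc, n_flies = 4)
  cl <- render_climb_frames(sc, kin, n_frames = 60)
  cfg <- small_tracker(sc, frames_per_trim = 60, subsample_step = 10)
  recs <- track_trim(cl$frames, sc$vial_boxes, cfg)
  summ <- summarize_trim(recs, sc$vial_boxes, cfg)
  expect_equal(nrow(summ), 2 * 6) # 60 / 10 time points per vial
  expect_equal(sort(unique(summ$time_s)), (seq(1, 60, 10) - 1) / 60)
  pop <- summ[summ$n > 0, ]
  expect_equal(pop$pct_lp + pop$pct_mp + pop$pct_hp,
               rep(100, nrow(pop)))
  expect_true(all(pop$mean_height_cm >= 0 &
                    pop$mean_height_cm <= cfg$holder_height_cm))
})

test_that("a fly pinned at the vial bottom reads as pure LP at height 0", {
  layout <- data.frame(vial_num = 1, x1 = 0, y1 = 0, x2 = 50, y2 = 180)
  cfg <- tracker_config(frames_per_trim = 30, subsample_step = 10,
                        image_height_px = 180)
  recs <- data.frame(trim = 1, frame = 1:30, vial_num = 1, x = 25,
                     y = 180, zone = "LP")
  summ <- summarize_trim(recs, layout, cfg)
  expect_equal(summ$mean_height_cm, rep(0, 3))
  expect_equal(summ$pct_lp, rep(100, 3))
})

test_that("mean height is non-decreasing for strictly climbing flies", {
  sc <- small_scene(n_vials = 1, noise_sd = 0, seed = 2)
  kin <- list(fly_kinematics(1, n_flies = 3, climb_speed_cm_s = 1,
                             speed_sd = 0, stall_prob = 0))
  cl <- render_climb_frames(sc, kin, n_frames = 60)
  cfg <- small_tracker(sc, frames_per_trim = 60, subsample_step = 10)
  recs <- track_trim(cl$frames, sc$vial_boxes, cfg)
  summ <- summarize_trim(recs, sc$vial_boxes, cfg)
  expect_true(all(diff(summ$mean_height_cm) > -1e-9))
  # and the recovered series matches ground-truth height within 0.2 cm
  tru <- cl$truth$trajectories
  for (f in seq(1, 60, 10)) {
    t_h <- mean(pixels_to_cm(sc$vial_boxes$y2 - tru$y[tru$frame == f],
                             sc$holder_height_cm, sc$image_size[2]))
    got <- summ$mean_height_cm[summ$time_s == (f - 1) / 60]
    expect_lt(abs(got - t_h), 0.2)
  }
})

test_that("trim aggregation averages technical replicates with SEM", {
  base <- data.frame(time_s = 0, vial_num = 1, mean_height_cm = 1,
                     pct_lp = 50, pct_mp = 30, pct_hp = 20, n = 5)
  four <- lapply(c(1, 2, 3, 4), function(v) {
    s <- base; s$mean_height_cm <- v; s
  })
  agg <- aggregate_trims(four)
  expect_equal(agg$mean_height_cm, 2.5)
  expect_equal(agg$mean_height_sem, 0.6455, tolerance = 1e-3)
  expect_equal(agg$pct_lp_sem, 0)
  expect_equal(agg$n_trims, 4L)
  # identical trims: SEM 0 everywhere
  same <- aggregate_trims(list(base, base, base, base))
  expect_equal(same$mean_height_sem, 0)
  # single trim: values pass through, SEM 0 with a warning
  expect_warning(one <- aggregate_trims(list(base)), "single trim")
  expect_equal(one$mean_height_cm, 1)
  expect_equal(one$mean_height_sem, 0)
})
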