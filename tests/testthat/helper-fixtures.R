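# Shared fixtures: small synthetic scenes and independent oracles.

# A small rack scene scaled from the full rig geometry.
small_scene <- function(n_vials = 4, image_size = c(320, 180),
                        pause_frames = 40, n_cycles = 2, seed = 7,
                        noise_sd = 2, ...) {
  scene_config(image_size = image_size, n_vials = n_vials,
               pause_frames = pause_frames, n_cycles = n_cycles,
               fly_radius_px = 3, noise_sd = noise_sd, seed = seed, ...)
}

small_kinematics <- function(scene, n_flies = 3, ...) {
  lapply(seq_len(scene$n_vials), function(v)
    fly_kinematics(v, n_flies = n_flies, ...))
}

# Splitter thresholds scaled to the small scene's pixel area and pause
# length (movement units scale with frame area).
small_splitter <- function(scene) {
  splitter_config(min_contour_area = 120, peak_height = 6000,
                  inactive_thresh = 2000, min_inactive_run = 12,
                  cap_frames = scene$pause_frames - 10,
                  expected_trims = scene$n_cycles)
}

small_tracker <- function(scene, frames_per_trim = 60,
                          subsample_step = 10, ...) {
  tracker_config(frames_per_trim = frames_per_trim,
                 subsample_step = subsample_step,
                 image_height_px = scene$image_size[2],
                 max_blob_area = 200, ...)
}

# Brute-force trial-splitting oracle: frame-by-frame scan, no vectorised
# shortcuts. Mirrors the stated rules: trial starts at the first
# sub-threshold frame after a spike; ends with the first inactivity run of
# >= min_run frames (at its end), at start + cap, or at the next spike.
oracle_trials <- function(v, cfg) {
  n <- length(v)
  peaks <- integer(0)
  for (i in seq_len(n)) {
    prev <- if (i > 1) v[i - 1] else -Inf
    nxt <- if (i < n) v[i + 1] else -Inf
    if (v[i] >= cfg$peak_height && v[i] > prev && v[i] >= nxt)
      peaks <- c(peaks, i)
  }
  segs <- NULL
  last_end <- 0
  for (pi in seq_along(peaks)) {
    p <- peaks[pi]
    if (p <= last_end) next
    np <- if (pi < length(peaks)) peaks[pi + 1] else n + 1
    start <- NA
    for (j in (p + 1):n) {
      if (j > n) break
      if (v[j] < cfg$inactive_thresh) { start <- j; break }
    }
    if (is.na(start) || start >= np) next
    limit <- min(start + cfg$cap_frames, np, n + 1)
    end <- limit
    run <- 0
    for (j in start:(limit - 1)) {
      run <- if (v[j] < cfg$inactive_thresh) run + 1 else 0
      if (run >= cfg$min_inactive_run) {
        # extend to the end of this inactivity run, bounded by the limit
        k <- j
        while (k + 1 <= limit - 1 && v[k + 1] < cfg$inactive_thresh)
          k <- k + 1
        end <- min(k + 1, limit)
        break
      }
    }
    segs <- rbind(segs, data.frame(start_frame = start, end_frame = end))
    last_end <- end - 1
  }
  if (is.null(segs)) data.frame(start_frame = integer(),
                                end_frame = integer()) else segs
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of ranks
# to the first group (no-ties case).
enumerate_mwu_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  u_of <- function(xs, ys)
    sum(rank(c(xs, ys))[seq_along(xs)]) - nx * (nx + 1) / 2
  u_obs <- u_of(x, y)
  pooled <- c(x, y)
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Wide two-genotype table simulated from the mixed model itself.
simulate_lme_table <- function(n_subj = 20, times = 0:4, effect = 0,
                               sd_b = 0.5, sd_b1 = 0.05, sd_e = 0.3,
                               seed = 1) {
  set.seed(seed)
  labels <- c(paste0("gA_rep", seq_len(n_subj)),
              paste0("gB_rep", seq_len(n_subj)))
  mat <- t(vapply(seq_along(labels), function(i) {
    b <- rnorm(1, 0, sd_b); b1 <- rnorm(1, 0, sd_b1)
    off <- if (i > n_subj) effect else 0
    b + off + b1 * times + rnorm(length(times), 0, sd_e)
  }, numeric(length(times))))
  df <- data.frame(replicate = labels, mat, check.names = FALSE)
  names(df) <- c("replicate", as.character(times))
  df
}

lme_main_p <- function(tab) {
  fit <- fit_lme(build_long_table(tab, "gA", "gB"))
  fit$coefficients$p[fit$coefficients$term == "genotypegB"]
}
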