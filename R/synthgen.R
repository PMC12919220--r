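# Synthetic assay scenes ----------------------------------------------------
#
# Renders tap-and-climb recordings that emulate the physical rig: a light
# background, a rack of vials drawn as pairs of dark vertical walls, and
# flies as small dark blobs that are knocked to the vial bottom by tap
# bursts and then climb. Ground-truth boxes, trajectories and tap frames are
# emitted alongside so every downstream stage can be scored against truth.

WALL_PX <- 2L # vial wall thickness in the rendering, px
TAP_BURST_FRAMES <- 5L # frames of rack agitation per tap event

# Run expr under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Fan a base seed out into independent integer substreams (< 2^31).
sub_seed <- function(seed, stream, k) {
  (as.numeric(seed %% 1000003L) * 9973 + stream * 1000003 + k) %% 2147483647
}

#' Default vial rack layout
#'
#' Evenly spaced vial bounding boxes across the frame width, mirroring the
#' 12-slot rack of the assay device. Boxes are 0-based half-open
#' `(x1, y1, x2, y2)` pixel rectangles.
#'
#' @param image_size `c(width, height)` in pixels.
#' @param n_vials number of vials in the rack.
#' @return data.frame with columns `vial_num, x1, y1, x2, y2`.
#' @export
default_vial_boxes <- function(image_size = c(1280, 720), n_vials = 12) {
  w <- image_size[1]; h <- image_size[2]
  margin <- round(0.03 * w)
  slot <- floor((w - 2 * margin) / n_vials)
  gap <- max(4L, round(0.2 * slot))
  x1 <- margin + (seq_len(n_vials) - 1L) * slot + floor(gap / 2)
  x2 <- x1 + slot - gap
  data.frame(vial_num = seq_len(n_vials),
             x1 = x1, y1 = round(0.06 * h),
             x2 = x2, y2 = round(0.95 * h))
}

#' Scene configuration for the synthetic recorder
#'
#' Defaults reproduce the device's recording protocol: 60 fps at 1280x720,
#' 12 vials, four tap-pause cycles with 15 s (900-frame) climbing pauses and
#' a 17 cm chamber height.
#'
#' @param image_size `c(width, height)` px.
#' @param n_vials number of vials.
#' @param vial_boxes optional data.frame of boxes (see
#'   [default_vial_boxes()]); must be x-sorted, non-overlapping, in bounds.
#' @param holder_height_cm physical chamber height mapped to the image
#'   height (cm).
#' @param fps frames per second.
#' @param n_cycles number of tap-pause cycles.
#' @param pause_frames climbing frames after each tap burst.
#' @param fly_radius_px rendered fly blob radius (px).
#' @param noise_sd additive Gaussian pixel noise, grey levels.
#' @param tap_noise_sd extra full-frame jitter during tap bursts, grey
#'   levels; the source of the splitter's high-motion spikes.
#' @param seed integer seed; all rendering randomness fans out from it.
#' @return a `scene_config` list.
#' @export
scene_config <- function(image_size = c(1280, 720), n_vials = 12,
                         vial_boxes = NULL, holder_height_cm = 17,
                         fps = 60, n_cycles = 4, pause_frames = 900,
                         fly_radius_px = 5, noise_sd = 2, tap_noise_sd = 60,
                         seed = 1) {
  assert_scalar_number(holder_height_cm, "holder_height_cm", min = 1e-9)
  assert_scalar_number(fps, "fps", min = 1e-9)
  vial_boxes <- vial_boxes %||% default_vial_boxes(image_size, n_vials)
  stopifnot(nrow(vial_boxes) == n_vials)
  if (is.unsorted(vial_boxes$x1, strictly = TRUE))
    stop_geotax("vial_boxes must be sorted by x1")
  if (any(vial_boxes$x2[-n_vials] > vial_boxes$x1[-1]))
    stop_geotax("vial_boxes overlap")
  if (any(vial_boxes$x1 < 0 | vial_boxes$y1 < 0 |
          vial_boxes$x2 > image_size[1] | vial_boxes$y2 > image_size[2]))
    stop_geotax("vial_boxes out of image bounds")
  structure(list(image_size = as.integer(image_size),
                 n_vials = as.integer(n_vials), vial_boxes = vial_boxes,
                 holder_height_cm = holder_height_cm, fps = fps,
                 n_cycles = as.integer(n_cycles),
                 pause_frames = as.integer(pause_frames),
                 fly_radius_px = fly_radius_px, noise_sd = noise_sd,
                 tap_noise_sd = tap_noise_sd, seed = as.integer(seed)),
            class = "scene_config")
}

#' Fly population kinematics for one vial
#'
#' @param vial_num vial the flies live in.
#' @param n_flies number of flies.
#' @param climb_speed_cm_s mean climbing speed, cm/s. The default 0.8 cm/s
#'   puts a healthy cohort near 10 cm after a 13 s trial, a typical
#'   wild-type climb.
#' @param speed_sd per-frame speed standard deviation, cm/s.
#' @param stall_prob per-frame probability a fly pauses.
#' @param start_zone only `"bottom"` is meaningful for a tap assay.
#' @return a `fly_kinematics` list.
#' @export
fly_kinematics <- function(vial_num, n_flies = 5, climb_speed_cm_s = 0.8,
                           speed_sd = 0.15, stall_prob = 0.05,
                           start_zone = "bottom") {
  stopifnot(n_flies >= 0, climb_speed_cm_s >= 0,
            stall_prob >= 0, stall_prob <= 1)
  structure(list(vial_num = as.integer(vial_num),
                 n_flies = as.integer(n_flies),
                 climb_speed_cm_s = climb_speed_cm_s, speed_sd = speed_sd,
                 stall_prob = stall_prob,
                 start_zone = match.arg(start_zone, "bottom")),
            class = "fly_kinematics")
}

# Frame-kind schedule for the full protocol: n_cycles x (tap burst, pause).
frame_schedule <- function(scene) {
  kinds <- rep(rep(c("tap", "pause"),
                   times = c(TAP_BURST_FRAMES, scene$pause_frames)),
               scene$n_cycles)
  tap_frames <- 1L + (seq_len(scene$n_cycles) - 1L) *
    (TAP_BURST_FRAMES + scene$pause_frames)
  list(kinds = kinds, tap_frames = tap_frames)
}

# Simulate all fly trajectories over a given frame-kind schedule.
# Returns data.frame(frame, fly_id, vial_num, x, y) in 0-based pixel coords;
# every point lies inside its vial box.
simulate_trajectories <- function(scene, kinematics, kinds) {
  boxes <- scene$vial_boxes
  px_per_cm <- scene$image_size[2] / scene$holder_height_cm
  n <- length(kinds)
  out <- list(); fly_id <- 0L
  for (kin in kinematics) {
    row <- which(boxes$vial_num == kin$vial_num)
    if (length(row) != 1L)
      stop_geotax("kinematics references unknown vial_num %d", kin$vial_num)
    b <- boxes[row, ]
    r <- scene$fly_radius_px
    xmin <- b$x1 + WALL_PX + r; xmax <- b$x2 - WALL_PX - r
    ymin <- b$y1 + r; ymax <- b$y2 - r
    H <- ymax - ymin
    if (kin$n_flies < 1L) next
    for (k in seq_len(kin$n_flies)) {
      fly_id <- fly_id + 1L
      xs <- ys <- numeric(n)
      with_seed(sub_seed(scene$seed, 1L, fly_id), {
        x <- stats::runif(1, xmin, xmax)
        y <- ymax - stats::runif(1, 0, 0.15 * H)
        # persistent per-fly speed plus per-frame jitter: cohorts are
        # heterogeneous, so initially bunched flies separate as they climb
        base_cm <- stats::rnorm(1, kin$climb_speed_cm_s, kin$speed_sd)
        step_cm <- stats::rnorm(n, base_cm, kin$speed_sd)
        stalls <- stats::runif(n) < kin$stall_prob
        wiggle <- stats::rnorm(n, 0, 0.3)
        for (i in seq_len(n)) {
          if (kinds[i] == "tap") {
            x <- stats::runif(1, xmin, xmax)
            y <- ymax - stats::runif(1, 0, 0.25 * H)
          } else {
            v <- if (stalls[i]) 0 else max(0, step_cm[i])
            y <- y - v * px_per_cm / scene$fps
            x <- x + wiggle[i]
          }
          x <- min(max(x, xmin), xmax)
          y <- min(max(y, ymin), ymax)
          xs[i] <- x; ys[i] <- y
        }
      })
      out[[fly_id]] <- data.frame(frame = seq_len(n), fly_id = fly_id,
                                  vial_num = kin$vial_num, x = xs, y = ys)
    }
  }
  if (length(out) == 0L)
    return(data.frame(frame = integer(), fly_id = integer(),
                      vial_num = integer(), x = numeric(), y = numeric()))
  do.call(rbind, out)
}

# Render one frame from simulated truth. Deterministic in (scene, frame i).
render_frame <- function(scene, traj_frame, kind, i) {
  w <- scene$image_size[1]; h <- scene$image_size[2]
  mat <- matrix(255, nrow = h, ncol = w)
  for (j in seq_len(nrow(scene$vial_boxes))) {
    b <- scene$vial_boxes[j, ]
    rows <- (b$y1 + 1L):b$y2
    mat[rows, (b$x1 + 1L):(b$x1 + WALL_PX)] <- 60
    mat[rows, (b$x2 - WALL_PX + 1L):b$x2] <- 60
  }
  r <- scene$fly_radius_px
  if (nrow(traj_frame) > 0L) {
    for (j in seq_len(nrow(traj_frame))) {
      cx <- traj_frame$x[j]; cy <- traj_frame$y[j]
      rr <- max(1L, floor(cy - r)):min(h, ceiling(cy + r + 1))
      cc <- max(1L, floor(cx - r)):min(w, ceiling(cx + r + 1))
      d2 <- outer((rr - 0.5 - cy)^2, (cc - 0.5 - cx)^2, "+")
      patch <- mat[rr, cc, drop = FALSE]
      patch[d2 <= r^2] <- 30
      mat[rr, cc] <- patch
    }
  }
  sd <- scene$noise_sd + if (kind == "tap") scene$tap_noise_sd else 0
  if (sd > 0) {
    with_seed(sub_seed(scene$seed, 2L, i), {
      mat <- mat + matrix(stats::rnorm(h * w, 0, sd), nrow = h)
    })
  }
  pmin(pmax(mat, 0), 255)
}

#' Render a full synthetic assay recording
#'
#' Produces the device's protocol: `n_cycles` tap bursts (frames of
#' whole-rack agitation that read as high motion energy) each followed by
#' `pause_frames` of climbing, with ground truth emitted alongside. Output
#' is bit-identical for identical `(scene, kinematics)`.
#'
#' @param scene a [scene_config()].
#' @param kinematics list of [fly_kinematics()], one per populated vial.
#' @param as_source if `TRUE` return a lazy [frame_source()] instead of a
#'   list (recommended beyond a few hundred frames).
#' @return list with `frames`, `truth` (list of `boxes`, `trajectories`,
#'   `tap_frames`) and `scene`.
#' @export
render_recording <- function(scene, kinematics, as_source = FALSE) {
  sched <- frame_schedule(scene)
  truth <- simulate_recording_truth(scene, kinematics, sched)
  frames <- make_frames(scene, truth$trajectories, sched$kinds, as_source)
  list(frames = frames, truth = truth, scene = scene)
}

simulate_recording_truth <- function(scene, kinematics, sched) {
  traj <- simulate_trajectories(scene, kinematics, sched$kinds)
  list(boxes = scene$vial_boxes, trajectories = traj,
       tap_frames = sched$tap_frames)
}

make_frames <- function(scene, traj, kinds, as_source) {
  by_frame <- split(traj, traj$frame)
  empty <- traj[0, ]
  get <- function(i) {
    tf <- by_frame[[as.character(i)]] %||% empty
    render_frame(scene, tf, kinds[i], i)
  }
  if (as_source) frame_source(get, length(kinds))
  else lapply(seq_along(kinds), get)
}

#' Render a single climbing bout (one trim) without tap bursts
#'
#' Convenience generator for tracker-level tests: flies start at the vial
#' bottom and climb for `n_frames` pause frames.
#'
#' @inheritParams render_recording
#' @param n_frames number of frames to render.
#' @return list with `frames` and `truth` as in [render_recording()].
#' @export
render_climb_frames <- function(scene, kinematics, n_frames,
                                as_source = FALSE) {
  kinds <- rep("pause", n_frames)
  traj <- simulate_trajectories(scene, kinematics, kinds)
  list(frames = make_frames(scene, traj, kinds, as_source),
       truth = list(boxes = scene$vial_boxes, trajectories = traj,
                    tap_frames = integer()),
       scene = scene)
}

#' Write a complete synthetic experiment folder
#'
#' Creates the on-disk layout the pipeline consumes: one subfolder per
#' recording holding a `frames/` directory and `geotaxis_metadata.csv`
#' (columns `Vial_Num,Genotype,Gender,N`), plus ground-truth sidecars
#' (`ground_truth.json` with boxes and tap frames; `trajectories.csv`).
#'
#' @param path experiment root directory.
#' @param scene a [scene_config()].
#' @param kinematics list of [fly_kinematics()].
#' @param genotype,gender per-vial labels, recycled to `length(kinematics)`;
#'   gender must be `"M"` or `"F"`.
#' @param name recording (subfolder) name.
#' @return invisibly, the recording folder path.
#' @export
write_experiment_folder <- function(path, scene, kinematics, genotype,
                                    gender, name = "recording_1") {
  gender <- rep_len(gender, length(kinematics))
  genotype <- rep_len(genotype, length(kinematics))
  if (!all(gender %in% c("M", "F")))
    stop_geotax("gender values must be 'M' or 'F'")
  folder <- file.path(path, name)
  dir.create(folder, recursive = TRUE, showWarnings = FALSE)
  rec <- render_recording(scene, kinematics, as_source = TRUE)
  write_frame_dir(rec$frames, file.path(folder, "frames"))
  meta <- data.frame(Vial_Num = vapply(kinematics, `[[`, 1L, "vial_num"),
                     Genotype = genotype, Gender = gender,
                     N = vapply(kinematics, `[[`, 1L, "n_flies"))
  utils::write.csv(meta, file.path(folder, "geotaxis_metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(boxes = rec$truth$boxes,
                            tap_frames = rec$truth$tap_frames),
                       file.path(folder, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA)
  utils::write.csv(rec$truth$trajectories,
                   file.path(folder, "trajectories.csv"), row.names = FALSE)
  invisible(folder)
}

#' Read an assay metadata table
#'
#' @param path path to a `geotaxis_metadata.csv` (or the folder holding it).
#' @return data.frame with columns `Vial_Num, Genotype, Gender, N`.
#' @export
read_metadata <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "geotaxis_metadata.csv")
  meta <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(Gender = "character"))
  need <- c("Vial_Num", "Genotype", "Gender", "N")
  if (!identical(names(meta)[seq_along(need)], need))
    stop_geotax("metadata must have columns %s", paste(need, collapse = ","))
  if (!all(meta$Gender %in% c("M", "F")))
    stop_geotax("metadata Gender values must be 'M' or 'F'")
  meta
}

#' Synthesize a motion-energy trace
#'
#' Direct fixture for the trial splitter, bypassing rendering: a baseline
#' plus optional noise, with a short decaying burst reaching `tap_height`
#' at each tap frame.
#'
#' @param n_frames trace length.
#' @param tap_frames 1-based frame indices of tap bursts.
#' @param tap_height burst apex, movement units; must exceed `baseline`.
#' @param baseline resting motion level, movement units.
#' @param noise_sd Gaussian noise sd on the baseline.
#' @param fps frames per second carried on the trace.
#' @param seed RNG seed.
#' @return a [movement_trace()].
#' @export
synth_movement_trace <- function(n_frames, tap_frames = integer(),
                                 tap_height = 150000, baseline = 5000,
                                 noise_sd = 0, fps = 60, seed = 1) {
  if (baseline < 0 || tap_height <= baseline)
    stop_geotax("need tap_height > baseline >= 0")
  if (length(tap_frames) && any(tap_frames < 1 | tap_frames > n_frames))
    stop_geotax("tap_frames must lie within 1..n_frames")
  values <- with_seed(seed,
                      pmax(0, baseline + stats::rnorm(n_frames, 0, noise_sd)))
  for (f in tap_frames) {
    idx <- f:min(f + 2L, n_frames)
    ramp <- tap_height * c(1, 0.7, 0.4)[seq_along(idx)]
    values[idx] <- pmax(values[idx], ramp)
  }
  movement_trace(values, fps)
}

#' Simulate a two-genotype mid-assay collapse experiment
#'
#' Series-level scenario generator for the statistical layer, emulating a
#' mutant that climbs normally but cannot sustain the height it gains.
#' Both cohorts follow the same saturating climb law
#' `y(t) = plateau * (1 - exp(-t / tau))` -- instantaneous velocity peaks
#' at the start (`plateau / tau`, about 2 cm/s) and decays identically for
#' both genotypes. After a replicate-staggered collapse onset the mutant
#' loses height at `slip_rate_cm_s` while the control holds its plateau.
#' The expected statistical signature is a growing late-assay
#' climbing-height deficit with no coherent difference in instantaneous
#' climbing velocity.
#'
#' @param n_replicates biological replicates (vials) per genotype.
#' @param times time grid in seconds (2 Hz over 12.5 s by default).
#' @param control,mutant genotype names.
#' @param plateau_cm,plateau_sd asymptotic climbing height, cm.
#' @param tau_s climb time constant, s.
#' @param onset_mean,onset_sd per-replicate collapse onset time, s.
#' @param slip_rate_cm_s,slip_sd mutant height-loss rate after onset.
#' @param intercept_sd between-replicate baseline sd, cm.
#' @param noise_sd per-timepoint measurement noise, cm (vial means jitter
#'   as flies redistribute).
#' @param seed RNG seed.
#' @return list of wide modality tables (`position`, `velocity`, `lp`,
#'   `mp`, `hp`), rows = replicate labels, columns = times.
#' @export
synth_dissociation_tables <- function(n_replicates = 10,
                                      times = seq(0, 12.5, by = 0.5),
                                      control = "ctrl", mutant = "collapse",
                                      plateau_cm = 10, plateau_sd = 1,
                                      tau_s = 5,
                                      onset_mean = 8, onset_sd = 0.7,
                                      slip_rate_cm_s = 0.5, slip_sd = 0.1,
                                      intercept_sd = 0.5,
                                      noise_sd = 0.7, seed = 1) {
  holder <- 17
  labels <- c(paste0(control, "_rep", seq_len(n_replicates)),
              paste0(mutant, "_rep", seq_len(n_replicates)))
  pos <- with_seed(seed, {
    t(vapply(seq_along(labels), function(i) {
      is_mut <- i > n_replicates
      h_inf <- stats::rnorm(1, plateau_cm, plateau_sd)
      b <- abs(stats::rnorm(1, 0, intercept_sd))
      onset <- max(1, stats::rnorm(1, onset_mean, onset_sd))
      slip <- if (is_mut)
        max(0, stats::rnorm(1, slip_rate_cm_s, slip_sd)) else 0
      y <- b + h_inf * (1 - exp(-times / tau_s)) -
        slip * pmax(times - onset, 0) +
        stats::rnorm(length(times), 0, noise_sd)
      pmin(pmax(y, 0), holder)
    }, numeric(length(times))))
  })
  wide <- function(mat) {
    df <- data.frame(replicate = labels, mat, check.names = FALSE)
    names(df) <- c("replicate", as.character(times))
    df
  }
  position <- wide(pos)
  lp <- wide(100 * stats::plogis((holder / 3 - pos) / 1.5))
  hp <- wide(100 * stats::plogis((pos - 2 * holder / 3) / 1.5))
  mp <- wide(100 - (100 * stats::plogis((holder / 3 - pos) / 1.5) +
                      100 * stats::plogis((pos - 2 * holder / 3) / 1.5)))
  list(position = position, velocity = velocity_from_position(position),
       lp = lp, mp = mp, hp = hp)
}
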