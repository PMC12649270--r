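#' Trial configuration
#'
#' Motion set-points and noise parameters for one simulated pass of a
#' specimen through the BVR field of view. Defaults mirror the study
#' conditions: hop trials travel horizontally at 0.9 +/- 0.3 m/s for 75
#' frames; drop trials fall vertically at 1.8 +/- 0.4 m/s for 10 frames
#' (terminated at ground contact); roughly 5% of frames are edge-of-field
#' outliers carrying inflated model-tracking noise.
#'
#' @param motion `"hop"` or `"drop"`.
#' @param seed trial RNG seed.
#' @param mean_speed set-point mean speed (m/s); defaults 0.9 (hop) /
#'   1.8 (drop).
#' @param speed_sd between-trial speed SD (m/s); defaults 0.3 / 0.4.
#' @param duration trial length (s); defaults 0.3 (75 frames) / 0.04
#'   (10 frames) at 250 Hz.
#' @param bead_pixel_noise_sd bead observation noise (pixels).
#' @param model_rot_noise_sd per-frame model-tracking rotation noise SD
#'   (degrees).
#' @param model_trans_noise_sd per-frame model-tracking translation noise
#'   SD per axis (mm).
#' @param outlier_frame_prob probability a fully-visible frame is drawn
#'   as an outlier anyway.
#' @param outlier_noise_multiplier noise inflation for outlier /
#'   partially-out-of-view frames.
#' @param id trial identifier.
#' @export
trial_config <- function(motion = c("hop", "drop"), seed,
                         mean_speed = NULL, speed_sd = NULL, duration = NULL,
                         bead_pixel_noise_sd = 0.5,
                         model_rot_noise_sd = 0.45,
                         model_trans_noise_sd = 0.40,
                         outlier_frame_prob = 0.05,
                         outlier_noise_multiplier = 4,
                         id = sprintf("%s_seed%d", motion[1], seed)) {
  motion <- match.arg(motion)
  mean_speed <- mean_speed %||% if (motion == "hop") 0.9 else 1.8
  speed_sd <- speed_sd %||% if (motion == "hop") 0.3 else 0.4
  duration <- duration %||% if (motion == "hop") 0.3 else 0.04
  if (mean_speed < 0 || speed_sd < 0 || duration <= 0)
    stop("mean_speed and speed_sd must be >= 0 and duration > 0")
  if (bead_pixel_noise_sd < 0 || model_rot_noise_sd < 0 ||
      model_trans_noise_sd < 0 || outlier_noise_multiplier < 0)
    stop("noise parameters must be >= 0")
  if (outlier_frame_prob < 0 || outlier_frame_prob > 1)
    stop("outlier_frame_prob must lie in [0, 1]")
  structure(list(id = id, motion = motion, seed = as.integer(seed),
                 mean_speed = mean_speed, speed_sd = speed_sd,
                 duration = duration,
                 bead_pixel_noise_sd = bead_pixel_noise_sd,
                 model_rot_noise_sd = model_rot_noise_sd,
                 model_trans_noise_sd = model_trans_noise_sd,
                 outlier_frame_prob = outlier_frame_prob,
                 outlier_noise_multiplier = outlier_noise_multiplier),
            class = "trial_config")
}

#' Generate a femur motion trajectory through the field of view
#'
#' Hop trials translate predominantly along lab +X (horizontal) with a
#' small vertical oscillation; drop trials fall along lab -Z in a
#' near-free-fall. The per-trial speed is drawn once from
#' `N(mean_speed, speed_sd)` (truncated at zero) and held constant, with
#' small transverse positional wobble and slow orientation wander whose
#' amplitudes scale with the speed (a stationary trial is exactly
#' static). The path is centred on the lab origin (isocentre).
#'
#' @param motion `"hop"` or `"drop"`.
#' @param mean_speed set-point mean speed (m/s).
#' @param duration trial length (s).
#' @param frame_rate sampling rate (Hz).
#' @param seed RNG seed (NULL uses the current stream).
#' @param speed_sd between-trial speed SD (m/s).
#' @param pos_wander_mm_per_mps transverse wobble amplitude per unit
#'   speed (mm per m/s).
#' @param rot_wander_deg_per_mps orientation wander amplitude per unit
#'   speed (degrees per m/s; keeps wander below 5 degrees at study
#'   speeds).
#' @param base_orientation optional fixed 3x3 starting rotation; a small
#'   random orientation is drawn when NULL.
#' @return List with `transforms` (per-frame femur pose, CT -> lab),
#'   `speed` (the sampled trial speed, m/s), `motion`, `frame_rate`.
#' @export
generate_trajectory <- function(motion = c("hop", "drop"), mean_speed,
                                duration, frame_rate = 250, seed = NULL,
                                speed_sd = 0, pos_wander_mm_per_mps = 2,
                                rot_wander_deg_per_mps = 2,
                                base_orientation = NULL) {
  motion <- match.arg(motion)
  n <- round(duration * frame_rate)
  if (n < 2) stop("duration x frame_rate must give at least 2 frames")
  with_seed(seed, {
    speed <- max(0, stats::rnorm(1, mean_speed, speed_sd))
    dir <- if (motion == "hop") c(1, 0, 0) else c(0, 0, -1)
    trans1 <- if (motion == "hop") c(0, 0, 1) else c(1, 0, 0)
    tt <- (seq_len(n) - 1) / frame_rate
    tmid <- mean(range(tt))
    pos <- outer(tt - tmid, dir * speed * 1000)        # mm
    amp <- pos_wander_mm_per_mps * speed
    phase <- stats::runif(1, 0, 2 * pi)
    freq <- 2  # Hz; handheld wobble is a low-frequency phenomenon
    pos <- pos + outer(amp * sin(2 * pi * freq * tt + phase), trans1)
    R0 <- if (is.null(base_orientation)) {
      rotation_about(stats::rnorm(3), deg2rad(stats::rnorm(1, 0, 3)))
    } else as.matrix(base_orientation)
    rot_amp <- deg2rad(rot_wander_deg_per_mps * speed)
    rot_axis <- stats::rnorm(3)
    rot_phase <- stats::runif(1, 0, 2 * pi)
    have_wander <- rot_amp > 0
    if (have_wander) rot_axis <- unitize(rot_axis)
    transforms <- lapply(seq_len(n), function(i) {
      R <- if (have_wander) {
        rotation_about(rot_axis,
                       rot_amp * sin(2 * pi * freq * tt[i] + rot_phase)) %*% R0
      } else R0
      rigid_transform(R, pos[i, ], tol = 1e-7)
    })
    list(transforms = transforms, speed = speed, motion = motion,
         frame_rate = frame_rate)
  })
}

#' Emulate model-based (2D-3D registration) tracking
#'
#' The model-based tracking algorithm itself (DRR-based image
#' registration) is outside this package's scope; its error behaviour is
#' emulated by perturbing the true pose of each frame with independent
#' rotation noise (axis uniform on the sphere, angle `|N(0, rot_sd)|`)
#' and per-axis Gaussian translation noise, applied in the bone's CT
#' frame. Frames flagged partially out of the field of view, or drawn as
#' outliers with probability `outlier_frame_prob`, receive noise scaled
#' by `outlier_noise_multiplier` - emulating the edge-of-field frames
#' that dominate the outlier tail of real trials.
#'
#' @param truth list of `rigid_transform` (true poses).
#' @param cfg a `trial_config`.
#' @param partially_out logical flags (one per frame); such frames get
#'   inflated noise deterministically.
#' @param seed RNG seed.
#' @param noise_scale extra multiplier on both noise SDs (per-specimen).
#' @return List with `transforms` and logical `outlier` flags.
#' @export
emulate_model_based <- function(truth, cfg, partially_out = NULL,
                                seed = NULL, noise_scale = 1) {
  n <- length(truth)
  if (n == 0L) stop("truth sequence is empty")
  if (is.null(partially_out)) partially_out <- rep(FALSE, n)
  if (length(partially_out) != n)
    stop("partially_out must have one flag per frame")
  rot_sd <- cfg$model_rot_noise_sd * noise_scale
  trans_sd <- cfg$model_trans_noise_sd * noise_scale
  with_seed(seed, {
    drawn <- stats::runif(n) < cfg$outlier_frame_prob
    outlier <- partially_out | drawn
    mult <- ifelse(outlier, cfg$outlier_noise_multiplier, 1)
    transforms <- lapply(seq_len(n), function(i) {
      axis <- stats::rnorm(3)
      ang <- abs(stats::rnorm(1, 0, 1)) * deg2rad(rot_sd) * mult[i]
      dt <- stats::rnorm(3, 0, 1) * trans_sd * mult[i]
      if (ang == 0 && all(dt == 0)) return(truth[[i]])
      P <- rigid_transform(rotation_about(axis, ang), dt, tol = 1e-7)
      compose(truth[[i]], P)
    })
    list(transforms = transforms, outlier = outlier)
  })
}

#' Simulate one tracked trial
#'
#' Generates the femur trajectory, derives the tibia truth through the
#' frozen relative pose, projects both bead clouds into both views with
#' pixel noise, reconstructs marker-based poses (triangulation + rigid
#' registration), and emulates model-based tracking. A frame is
#' *trackable* when both bones have a marker-based fit (at least 3 beads
#' visible in both views).
#'
#' @param specimen a `specimen_config`.
#' @param geometry a `bvr_geometry`.
#' @param cfg a `trial_config`.
#' @param track run marker-based tracking (set FALSE to defer it to a
#'   separate pipeline stage).
#' @return Object of class `tracked_trial`.
#' @export
generate_trial <- function(specimen, geometry, cfg, track = TRUE) {
  traj <- generate_trajectory(cfg$motion, cfg$mean_speed, cfg$duration,
                              geometry$frame_rate, seed = cfg$seed,
                              speed_sd = cfg$speed_sd)
  femur_truth <- traj$transforms
  tibia_truth <- lapply(femur_truth, compose, b = specimen$frozen_relative_pose)
  n <- length(femur_truth)

  obs <- vector("list", 2L * n)
  fully_in <- list(femur = logical(n), tibia = logical(n))
  bones <- list(femur = list(truth = femur_truth, beads = specimen$femur$beads),
                tibia = list(truth = tibia_truth, beads = specimen$tibia$beads))
  for (bi in seq_along(bones)) {
    bone <- names(bones)[bi]
    beads <- bones[[bi]]$beads
    for (i in seq_len(n)) {
      world <- rt_apply(bones[[bi]]$truth[[i]], beads$coordinates)
      df <- project_beads(geometry, world, labels = beads$labels,
                          pixel_noise_sd = cfg$bead_pixel_noise_sd,
                          seed = derive_seed(cfg$seed, 7L + 2L * i + bi))
      df$frame <- i
      df$bone <- bone
      obs[[(bi - 1L) * n + i]] <- df
      fully_in[[bone]][i] <- all(df$visible)
    }
  }
  observations <- do.call(rbind, obs)
  observations <- observations[, c("frame", "view", "bone", "bead_label",
                                   "u", "v", "visible")]

  model_f <- emulate_model_based(femur_truth, cfg, !fully_in$femur,
                                 seed = derive_seed(cfg$seed, 2L),
                                 noise_scale = specimen$noise_scale)
  model_t <- emulate_model_based(tibia_truth, cfg, !fully_in$tibia,
                                 seed = derive_seed(cfg$seed, 3L),
                                 noise_scale = specimen$noise_scale)

  trial <- structure(list(
    trial_id = cfg$id, specimen_id = specimen$id, motion = cfg$motion,
    frame_rate = geometry$frame_rate, n_frames = n, speed = traj$speed,
    truth = list(femur = femur_truth, tibia = tibia_truth),
    model = list(femur = model_f$transforms, tibia = model_t$transforms),
    model_outlier = list(femur = model_f$outlier, tibia = model_t$outlier),
    marker = NULL, trackable = NULL,
    in_fov = fully_in, observations = observations, config = cfg),
    class = "tracked_trial")
  if (track) trial <- track_trial_markers(trial, specimen, geometry)
  trial
}

#' @export
print.tracked_trial <- function(x, ...) {
  trk <- if (is.null(x$trackable)) "untracked" else
    sprintf("%d trackable", sum(x$trackable))
  cat(sprintf("<tracked_trial> %s (%s, %s): %d frames (%s), speed %.2f m/s\n",
              x$trial_id, x$specimen_id, x$motion, x$n_frames, trk, x$speed))
  invisible(x)
}
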