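#' Triangulate a bead from its two detector observations
#'
#' Back-projects each pixel observation to a ray from the X-ray source
#' through the detector point and returns the least-squares intersection
#' (the point minimising the summed squared perpendicular distance to
#' both rays), together with the RMS reprojection residual in pixels.
#'
#' @param uv1,uv2 length-2 pixel coordinates `(u, v)` in views 1 and 2.
#' @param geometry a `bvr_geometry`.
#' @return List with `point` (lab mm), `residual_px` (RMS reprojection
#'   residual), `ray_angle_deg`.
#' @export
triangulate <- function(uv1, uv2, geometry) {
  rays <- lapply(1:2, function(k) {
    vw <- geometry$views[[k]]
    uv <- if (k == 1) uv1 else uv2
    hit <- vw$center + uv[1] * vw$pixel_pitch * vw$u +
      uv[2] * vw$pixel_pitch * vw$v
    list(origin = vw$source, dir = unitize(hit - vw$source, "ray"))
  })
  ang <- rad2deg(acos(max(-1, min(1, abs(sum(rays[[1]]$dir * rays[[2]]$dir))))))
  if (ang < 1) {
    stop(sprintf("ill-conditioned triangulation: rays nearly parallel (%.3f deg apart)", ang))
  }
  A <- matrix(0, 3, 3); b <- numeric(3)
  for (r in rays) {
    P <- diag(3) - tcrossprod(r$dir)
    A <- A + P
    b <- b + as.numeric(P %*% r$origin)
  }
  p <- as.numeric(solve(A, b))
  # reprojection residual
  reproj <- project_beads(geometry, p, labels = "x")
  res <- sqrt(mean(c((reproj$u[1] - uv1[1])^2 + (reproj$v[1] - uv1[2])^2,
                     (reproj$u[2] - uv2[1])^2 + (reproj$v[2] - uv2[2])^2)))
  list(point = p, residual_px = res, ray_angle_deg = ang)
}

#' Fit a bone pose from triangulated beads
#'
#' Registers the bone's CT-frame bead cloud onto the triangulated
#' lab-frame bead positions with [kabsch_fit()], giving the CT -> lab
#' transform for the frame. Frames with fewer than `min_beads`
#' triangulated beads are untrackable and return NULL.
#'
#' @param bone a `bone_model`.
#' @param lab_points `point_set` of triangulated bead positions (lab
#'   frame), labels matching the bone's beads.
#' @param min_beads minimum beads required (default 3).
#' @return List with `transform` and `rms` (mm), or NULL when the frame
#'   is untrackable.
#' @export
fit_bone_pose <- function(bone, lab_points, min_beads = 3L) {
  if (!inherits(bone, "bone_model")) stop("bone must be a bone_model")
  common <- intersect(bone$beads$labels, lab_points$labels)
  if (length(common) < min_beads) return(NULL)
  kabsch_fit(bone$beads, lab_points, min_points = min_beads)
}

#' Marker-based tracking of one frame's observations
#'
#' Triangulates every bead of a bone visible in both views at one frame.
#'
#' @param obs bead observation data.frame rows for one frame and bone.
#' @param geometry a `bvr_geometry`.
#' @return `point_set` of triangulated lab positions (possibly empty).
#' @keywords internal
triangulate_frame <- function(obs, geometry) {
  o1 <- obs[obs$view == 1 & obs$visible, ]
  o2 <- obs[obs$view == 2 & obs$visible, ]
  labels <- intersect(o1$bead_label, o2$bead_label)
  pts <- matrix(NA_real_, length(labels), 3)
  for (i in seq_along(labels)) {
    a <- o1[o1$bead_label == labels[i], ]
    b <- o2[o2$bead_label == labels[i], ]
    pts[i, ] <- triangulate(c(a$u[1], a$v[1]), c(b$u[1], b$v[1]),
                            geometry)$point
  }
  if (length(labels) == 0L) return(NULL)
  point_set(pts, labels, frame = "lab")
}

#' Reconstruct marker-based poses for a whole trial
#'
#' Runs triangulation and rigid registration for femur and tibia on
#' every frame of a trial's bead observations, filling the `marker` and
#' `trackable` fields of the trial. A frame is trackable when both bones
#' obtained a fit.
#'
#' @param trial a `tracked_trial` (from [generate_trial()]).
#' @param specimen the `specimen_config` the trial was generated from.
#' @param geometry the `bvr_geometry`.
#' @param min_beads minimum beads per bone per frame.
#' @return The trial with `marker`, `marker_rms`, and `trackable` filled.
#' @export
track_trial_markers <- function(trial, specimen, geometry, min_beads = 3L) {
  n <- trial$n_frames
  marker <- list(femur = vector("list", n), tibia = vector("list", n))
  rms <- list(femur = rep(NA_real_, n), tibia = rep(NA_real_, n))
  for (bone in c("femur", "tibia")) {
    bm <- specimen[[bone]]
    for (i in seq_len(n)) {
      obs <- trial$observations[trial$observations$frame == i &
                                  trial$observations$bone == bone, ]
      lab <- triangulate_frame(obs, geometry)
      fit <- if (is.null(lab)) NULL else fit_bone_pose(bm, lab, min_beads)
      if (!is.null(fit)) {
        marker[[bone]][[i]] <- fit$transform
        rms[[bone]][i] <- fit$rms
      }
    }
  }
  trial$marker <- marker
  trial$marker_rms <- rms
  trial$trackable <- vapply(seq_len(n), function(i)
    !is.null(marker$femur[[i]]) && !is.null(marker$tibia[[i]]), logical(1))
  trial
}

#' Read and write bead observation CSV files
#'
#' Columns: `frame`, `view`, `bone`, `bead_label`, `u`, `v`, `visible`.
#'
#' @param observations bead observation data.frame.
#' @param path file path.
#' @export
write_bead_csv <- function(observations, path) {
  df <- observations
  df$u <- ifelse(is.na(df$u), "", sprintf("%.6f", df$u))
  df$v <- ifelse(is.na(df$v), "", sprintf("%.6f", df$v))
  df$visible <- ifelse(df$visible, "TRUE", "FALSE")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bead_csv
#' @export
read_bead_csv <- function(path) {
  df <- utils::read.csv(path)
  needed <- c("frame", "view", "bone", "bead_label", "u", "v", "visible")
  if (!all(needed %in% names(df)))
    stop("malformed bead observation CSV")
  df$visible <- as.logical(df$visible)
  df
}
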