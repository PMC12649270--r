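#' Anatomical coordinate system from bone landmarks
#'
#' Constructs an orthonormal right-handed bone frame: X through the
#' paired condyle/plateau landmarks (the flexion axis, pointing medial),
#' Z along the bone shaft (long axis, superior-positive), Y = Z x X
#' (roughly anterior). The origin is midway between the paired
#' landmarks. Femur landmarks: `medial_epicondyle`, `lateral_epicondyle`,
#' `proximal_shaft`; tibia: `medial_plateau`, `lateral_plateau`,
#' `distal_shaft`. The returned transform maps CT coordinates into the
#' anatomical frame.
#'
#' @param landmarks named list of CT-frame 3-vectors.
#' @param bone `"femur"` or `"tibia"`.
#' @return Object of class `anatomical_frame` with `transform`
#'   (CT -> anatomical), `origin`, and `axes` (rows X, Y, Z in CT).
#' @export
build_anatomical_frame <- function(landmarks, bone = c("femur", "tibia")) {
  bone <- match.arg(bone)
  get_lm <- function(nm) {
    v <- landmarks[[nm]]
    if (is.null(v) || length(v) != 3L || !all(is.finite(v)))
      stop(sprintf("missing or invalid landmark '%s'", nm))
    as.numeric(v)
  }
  if (bone == "femur") {
    med <- get_lm("medial_epicondyle"); lat <- get_lm("lateral_epicondyle")
    shaft <- get_lm("proximal_shaft"); superior_sign <- 1
  } else {
    med <- get_lm("medial_plateau"); lat <- get_lm("lateral_plateau")
    shaft <- get_lm("distal_shaft"); superior_sign <- -1
  }
  origin <- (med + lat) / 2
  x0 <- med - lat
  z0 <- superior_sign * (shaft - origin)
  if (vnorm(x0) < 1 || vnorm(z0) < 1)
    stop("degenerate landmarks: paired or shaft landmarks coincide")
  z <- unitize(z0, "long axis")
  y <- cross3(z, unitize(x0, "flexion axis"))
  if (vnorm(y) < 1e-6)
    stop("degenerate landmarks: shaft parallel to the condylar axis")
  y <- unitize(y)
  x <- cross3(y, z)
  R <- rbind(x, y, z)
  rownames(R) <- c("X", "Y", "Z")
  structure(list(bone = bone,
                 transform = rigid_transform(R, as.numeric(-R %*% origin)),
                 origin = origin, axes = R),
            class = "anatomical_frame")
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat(sprintf("<anatomical_frame> %s, origin (%.1f, %.1f, %.1f) mm (CT)\n",
              x$bone, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

as_acs_transform <- function(acs) {
  if (inherits(acs, "anatomical_frame")) acs$transform
  else if (is_rigid_transform(acs)) acs
  else stop("expected an anatomical_frame or rigid_transform")
}

# -- zero-phase Butterworth filtering ---------------------------------------

# scipy-style steady-state initial filter conditions (direct form II
# transposed), so a constant input passes through exactly.
lfilter_zi <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  n <- length(a)
  A <- rbind(-a[-1], cbind(diag(n - 2), 0))
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(diag(n - 1) - t(A), B))
}

filter_df2t <- function(b, a, x, zi) {
  y <- numeric(length(x))
  z <- zi
  nb <- length(b)
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    for (k in seq_len(nb - 2)) {
      z[k] <- b[k + 1] * x[i] + z[k + 1] - a[k + 1] * y[i]
    }
    z[nb - 1] <- b[nb] * x[i] - a[nb] * y[i]
  }
  y
}

# Zero-phase forward-backward filtering with odd-reflection padding and
# steady-state initial conditions (equivalent to scipy.signal.filtfilt).
filtfilt_padded <- function(b, a, x) {
  n <- length(x)
  padlen <- 3L * (max(length(a), length(b)) - 1L)
  if (n <= padlen)
    stop(sprintf("sequence too short for zero-phase filtering: need more than %d frames, got %d",
                 padlen, n))
  front <- 2 * x[1] - x[(padlen + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - padlen)]
  ext <- c(front, x, back)
  zi <- lfilter_zi(b, a)
  y <- filter_df2t(b, a, ext, zi * ext[1])
  y <- rev(filter_df2t(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

#' Low-pass filter a pose sequence
#'
#' Converts the rotations to quaternions, enforces sign continuity
#' ([hemisphere_align()]), low-pass filters each of the four quaternion
#' components and three translation components with a 2nd-order
#' Butterworth design, renormalises the quaternions, and rebuilds the
#' transforms. The default applies the filter forward and backward for
#' zero phase lag (standard biomechanics practice), with the design
#' cutoff raised to compensate for the double pass so the -3 dB point
#' stays at `cutoff`; set `zero_phase = FALSE` for a causal single pass
#' at the nominal cutoff.
#'
#' @param transforms list of `rigid_transform`, uniformly sampled.
#' @param frame_rate sampling rate (Hz), default 250.
#' @param cutoff -3 dB cutoff frequency (Hz), default 10.
#' @param order filter order, default 2.
#' @param zero_phase forward-backward (default) or single causal pass.
#' @return Filtered list of `rigid_transform`.
#' @export
filter_pose_sequence <- function(transforms, frame_rate = 250, cutoff = 10,
                                 order = 2, zero_phase = TRUE) {
  n <- length(transforms)
  if (n < 3 * order + 1)
    stop(sprintf("pose sequence too short to filter: need at least %d frames, got %d",
                 3 * order + 1, n))
  fc <- cutoff
  if (zero_phase) fc <- cutoff / (sqrt(2) - 1)^(1 / (2 * order))
  W <- fc / (frame_rate / 2)
  if (W >= 1) stop("cutoff too close to the Nyquist frequency")
  coef <- signal::butter(order, W)
  q <- hemisphere_align(t(vapply(transforms, to_quaternion, numeric(4))))
  tr <- t(vapply(transforms, function(x) x$t, numeric(3)))
  run <- function(x) {
    if (zero_phase) filtfilt_padded(coef$b, coef$a, x)
    else filter_df2t(coef$b, coef$a, x, lfilter_zi(coef$b, coef$a) * x[1])
  }
  qf <- apply(q, 2, run)
  tf <- apply(tr, 2, run)
  lapply(seq_len(n), function(i) from_quaternion(qf[i, ], tf[i, ]))
}

# -- joint kinematics --------------------------------------------------------

#' Relative pose of the tibia in the femoral anatomical frame
#'
#' Composes `femur_acs o femur_T^-1 o tibia_T o tibia_acs^-1`, i.e. maps
#' tibia-anatomical coordinates through the tibia's lab pose, back
#' through the femur's lab pose, into the femoral anatomical frame.
#' Identical bone poses with identical anatomical frames give the
#' identity.
#'
#' @param femur_T,tibia_T CT -> lab transforms for the frame.
#' @param femur_acs,tibia_acs `anatomical_frame`s (or CT -> anatomical
#'   transforms).
#' @return `rigid_transform` (tibia anatomical -> femur anatomical).
#' @export
relative_pose <- function(femur_T, tibia_T, femur_acs, tibia_acs) {
  fa <- as_acs_transform(femur_acs)
  ta <- as_acs_transform(tibia_acs)
  compose(fa, compose(rt_invert(femur_T), compose(tibia_T, rt_invert(ta))))
}

#' X-Y-Z Euler decomposition of a relative pose
#'
#' Resolves the rotation as `R = Rx(FE) Ry(AA) Rz(IE)` (flexion/
#' extension, abduction/adduction, internal/external rotation, degrees)
#' and reports the translation components on the femoral anatomical axes
#' as medial/lateral (ML = X), anterior/posterior (AP = Y), and
#' inferior/superior (IS = Z) translations in mm.
#'
#' @param relative a `rigid_transform` from [relative_pose()].
#' @return Named numeric `(FE, AA, IE, ML, AP, IS)`.
#' @export
decompose_xyz <- function(relative) {
  R <- relative$R
  sb <- max(-1, min(1, R[1, 3]))
  AA <- asin(sb)
  if (abs(cos(AA)) < 1e-6)
    stop("gimbal lock: |AA| at 90 degrees, X-Y-Z angles undefined")
  FE <- atan2(-R[2, 3], R[3, 3])
  IE <- atan2(-R[1, 2], R[1, 1])
  c(FE = rad2deg(FE), AA = rad2deg(AA), IE = rad2deg(IE),
    ML = relative$t[1], AP = relative$t[2], IS = relative$t[3])
}

#' Rebuild a transform from X-Y-Z Euler angles
#'
#' Inverse of [decompose_xyz()]; used for round-trip verification.
#'
#' @param dof named numeric `(FE, AA, IE, ML, AP, IS)` (degrees / mm).
#' @return A `rigid_transform`.
#' @export
compose_xyz <- function(dof) {
  rigid_transform(rot_x(dof[["FE"]]) %*% rot_y(dof[["AA"]]) %*% rot_z(dof[["IE"]]),
                  c(dof[["ML"]], dof[["AP"]], dof[["IS"]]))
}

#' Tibial linear speed from rigid-body motion
#'
#' Differentiates the lab-frame position of the tibial anatomical origin
#' with central finite differences (one-sided at the ends) and returns
#' the per-frame speed magnitude in m/s plus the trial mean.
#'
#' @param transforms list of tibia CT -> lab transforms.
#' @param frame_rate sampling rate (Hz).
#' @param origin the tracked point in tibia CT coordinates (mm); the
#'   anatomical origin by convention.
#' @return List with `speed` (per frame, m/s) and `mean`.
#' @export
tibial_speed <- function(transforms, frame_rate, origin = c(0, 0, 0)) {
  n <- length(transforms)
  if (n < 2) stop("need at least 2 frames to differentiate")
  pos <- t(vapply(transforms, function(x) rt_apply(x, origin), numeric(3)))
  vel <- matrix(0, n, 3)
  vel[1, ] <- pos[2, ] - pos[1, ]
  vel[n, ] <- pos[n, ] - pos[n - 1, ]
  if (n > 2) {
    vel[2:(n - 1), ] <- (pos[3:n, , drop = FALSE] -
                           pos[1:(n - 2), , drop = FALSE]) / 2
  }
  speed <- sqrt(rowSums(vel^2)) * frame_rate / 1000
  list(speed = speed, mean = mean(speed))
}

#' Six-DOF kinematics table for one trial
#'
#' Computes the per-frame tibiofemoral kinematics (tibia relative to
#' femur in the anatomical frames) for the chosen tracking method,
#' restricted to trackable frames, optionally low-pass filtered.
#'
#' @param trial a `tracked_trial` with marker tracking completed.
#' @param specimen the matching `specimen_config`.
#' @param method `"marker"`, `"model"`, or `"truth"`.
#' @param filter apply [filter_pose_sequence()] to each bone's poses.
#' @param cutoff filter cutoff (Hz).
#' @param frames frame indices to use; defaults to trackable frames
#'   (all frames for `"truth"` when tracking was skipped).
#' @return data.frame (kinematics table) with columns `frame`, `FE`,
#'   `AA`, `IE`, `ML`, `AP`, `IS`, `speed`, and metadata columns
#'   `method`, `specimen`, `trial`, `motion`.
#' @export
trial_kinematics <- function(trial, specimen, method = c("marker", "model", "truth"),
                             filter = FALSE, cutoff = 10, frames = NULL) {
  method <- match.arg(method)
  if (is.null(frames)) {
    frames <- if (is.null(trial$trackable)) seq_len(trial$n_frames)
      else which(trial$trackable)
  }
  if (length(frames) == 0L) stop("no trackable frames in trial")
  fem <- trial[[method]]$femur[frames]
  tib <- trial[[method]]$tibia[frames]
  if (any(vapply(fem, is.null, logical(1))) ||
      any(vapply(tib, is.null, logical(1))))
    stop(sprintf("missing %s transforms on requested frames", method))
  if (filter) {
    fem <- filter_pose_sequence(fem, trial$frame_rate, cutoff)
    tib <- filter_pose_sequence(tib, trial$frame_rate, cutoff)
  }
  dof <- t(vapply(seq_along(frames), function(i)
    decompose_xyz(relative_pose(fem[[i]], tib[[i]],
                                specimen$femur_acs, specimen$tibia_acs)),
    numeric(6)))
  spd <- tibial_speed(tib, trial$frame_rate,
                      origin = specimen$tibia_acs$origin)$speed
  out <- data.frame(frame = frames, dof, speed = spd,
                    method = method, specimen = trial$specimen_id,
                    trial = trial$trial_id, motion = trial$motion)
  rownames(out) <- NULL
  out
}

#' Time-normalize a kinematics table
#'
#' Linearly interpolates every numeric column onto `n_frames` equally
#' spaced points spanning the trial (first and last values preserved
#' exactly). Hop trials are conventionally normalised to 75 frames,
#' drop trials to 10.
#'
#' @param table a kinematics table (data.frame from
#'   [trial_kinematics()]).
#' @param n_frames number of output frames (>= 2).
#' @return Kinematics table with `n_frames` rows and a `frame` column
#'   running 1..`n_frames`.
#' @export
time_normalize <- function(table, n_frames) {
  if (nrow(table) < 2) stop("need at least 2 input frames")
  if (n_frames < 2) stop("n_frames must be >= 2")
  x <- seq(0, 1, length.out = nrow(table))
  xout <- seq(0, 1, length.out = n_frames)
  num <- vapply(table, is.numeric, logical(1))
  out <- data.frame(frame = seq_len(n_frames))
  for (nm in names(table)[num]) {
    if (nm == "frame") next
    out[[nm]] <- stats::approx(x, table[[nm]], xout = xout)$y
  }
  for (nm in names(table)[!num]) out[[nm]] <- table[[nm]][1]
  out
}
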