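#' Bone model with implanted beads and anatomical landmarks
#'
#' @param name `"femur"` or `"tibia"`.
#' @param beads `point_set` of implanted bead centres in the bone's CT
#'   frame; between 6 and 8 beads.
#' @param landmarks named list of 3-vectors (CT frame) used to construct
#'   the anatomical coordinate system.
#' @param bead_diameter bead diameter (mm), 1 mm tantalum by default.
#' @export
bone_model <- function(name = c("femur", "tibia"), beads, landmarks,
                       bead_diameter = 1) {
  name <- match.arg(name)
  if (!inherits(beads, "point_set")) stop("beads must be a point_set")
  n <- length(beads$labels)
  if (n < 6L || n > 8L)
    stop(sprintf("bead count must be in [6, 8], got %d", n))
  if (bead_diameter <= 0) stop("bead_diameter must be positive")
  required <- if (name == "femur") {
    c("medial_epicondyle", "lateral_epicondyle", "proximal_shaft")
  } else {
    c("medial_plateau", "lateral_plateau", "distal_shaft")
  }
  missing <- setdiff(required, names(landmarks))
  if (length(missing))
    stop(sprintf("missing %s landmarks: %s", name,
                 paste(missing, collapse = ", ")))
  structure(list(name = name, beads = beads, landmarks = landmarks,
                 bead_diameter = bead_diameter),
            class = "bone_model")
}

# Rejection-sample a non-degenerate bead cloud: min pairwise distance
# > 5 mm and RMS out-of-plane thickness > 1 mm.
sample_bead_cloud <- function(n, xlim, ylim, zlim, max_tries = 2000L) {
  for (i in seq_len(max_tries)) {
    P <- cbind(stats::runif(n, xlim[1], xlim[2]),
               stats::runif(n, ylim[1], ylim[2]),
               stats::runif(n, zlim[1], zlim[2]))
    if (min(stats::dist(P)) <= 5) next
    Pc <- sweep(P, 2, colMeans(P))
    if (min(svd(Pc)$d) / sqrt(n) <= 1) next  # coplanar within 1 mm RMS
    return(P)
  }
  stop("failed to sample a non-degenerate bead cloud")
}

#' Generate a synthetic frozen cadaveric specimen
#'
#' Emulates a cadaveric knee prepared for a BVR validation study: femur
#' and tibia each carry 6-8 implanted 1 mm beads (non-collinear,
#' well-separated), anatomical landmarks define the bone coordinate
#' systems, and the tibia is frozen relative to the femur at a flexion
#' angle in the hop-landing range (20-55 degrees). Because the relative
#' pose is frozen, any apparent tibiofemoral motion recovered downstream
#' is tracking error.
#'
#' @param seed RNG seed; identical seeds give bit-identical specimens.
#' @param soft_tissue_volume soft-tissue volume of the specimen (cm^3);
#'   recorded metadata used for specimen-stratified reporting.
#' @param noise_scale per-specimen multiplier applied to emulator noise.
#' @param flexion_deg optional fixed flexion angle; sampled uniformly in
#'   [20, 55] when NULL.
#' @param id specimen identifier.
#' @return Object of class `specimen_config`.
#' @export
generate_specimen <- function(seed, soft_tissue_volume = 3038,
                              noise_scale = 1, flexion_deg = NULL,
                              id = sprintf("specimen_seed%d", seed)) {
  if (soft_tissue_volume <= 0) stop("soft_tissue_volume must be positive")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  with_seed(seed, {
    jit <- function(s) stats::rnorm(3, 0, s)
    femur_lm <- list(
      medial_epicondyle = c(42, 0, 0) + jit(2),
      lateral_epicondyle = c(-42, 0, 0) + jit(2),
      proximal_shaft = c(0, 8, 160) + jit(4))
    tibia_lm <- list(
      medial_plateau = c(38, 0, 0) + jit(2),
      lateral_plateau = c(-38, 0, 0) + jit(2),
      distal_shaft = c(0, -5, -130) + jit(4))
    femur_beads <- point_set(
      sample_bead_cloud(sample(6:8, 1), c(-30, 30), c(-30, 30), c(5, 60)),
      frame = "CT")
    tibia_beads <- point_set(
      sample_bead_cloud(sample(6:8, 1), c(-28, 28), c(-28, 28), c(-60, -5)),
      frame = "CT")
    femur <- bone_model("femur", femur_beads, femur_lm)
    tibia <- bone_model("tibia", tibia_beads, tibia_lm)
    acs_f <- build_anatomical_frame(femur_lm, "femur")
    acs_t <- build_anatomical_frame(tibia_lm, "tibia")
    if (is.null(flexion_deg)) flexion_deg <- stats::runif(1, 20, 55)
    if (flexion_deg < 20 || flexion_deg > 55)
      stop("flexion_deg must lie in [20, 55]")
    # tibia-anatomical -> femur-anatomical pose of the frozen joint
    R_rel <- rot_x(flexion_deg) %*% rot_y(stats::rnorm(1, 0, 1.5)) %*%
      rot_z(stats::rnorm(1, 0, 1.5))
    t_rel <- c(stats::rnorm(1, 0, 1.5), stats::rnorm(1, -3, 1.5),
               -40 + stats::rnorm(1, 0, 3))
    rel_anat <- rigid_transform(R_rel, t_rel)
    frozen <- compose(rt_invert(acs_f$transform),
                      compose(rel_anat, acs_t$transform))
    structure(list(id = id, femur = femur, tibia = tibia,
                   femur_acs = acs_f, tibia_acs = acs_t,
                   frozen_relative_pose = frozen,
                   flexion_deg = flexion_deg,
                   soft_tissue_volume = soft_tissue_volume,
                   noise_scale = noise_scale, seed = seed),
              class = "specimen_config")
  })
}

#' @export
print.specimen_config <- function(x, ...) {
  cat(sprintf("<specimen_config> %s: flexion %.1f deg, soft tissue %g cm^3, %d + %d beads\n",
              x$id, x$flexion_deg, x$soft_tissue_volume,
              length(x$femur$beads$labels), length(x$tibia$beads$labels)))
  invisible(x)
}

#' Three specimen presets spanning the soft-tissue range of the study
#'
#' Soft-tissue volumes 3038, 1203, and 3964 cm^3 for specimens 1-3.
#'
#' @return Named list of three `specimen_config` objects.
#' @export
specimen_presets <- function() {
  vols <- c(specimen1 = 3038, specimen2 = 1203, specimen3 = 3964)
  seeds <- c(101L, 102L, 103L)
  out <- lapply(seq_along(vols), function(i)
    generate_specimen(seeds[i], soft_tissue_volume = vols[[i]],
                      id = names(vols)[i]))
  names(out) <- names(vols)
  out
}

#' Soft-tissue volume from voxel masks
#'
#' Subtracts the union of the bone masks from the whole-specimen mask and
#' converts the remaining voxel count to cm^3.
#'
#' @param total_mask logical array covering the whole specimen.
#' @param bone_masks list of logical arrays (same shape), one per bone.
#' @param voxel_size length-3 voxel edge lengths (mm).
#' @return Soft-tissue volume in cm^3.
#' @export
soft_tissue_volume <- function(total_mask, bone_masks, voxel_size) {
  if (!is.list(bone_masks)) bone_masks <- list(bone_masks)
  for (b in bone_masks) {
    if (!identical(dim(b), dim(total_mask)))
      stop("bone mask shape differs from total mask")
  }
  bones <- Reduce(`|`, bone_masks)
  if (any(bones & !total_mask))
    stop("bone voxels found outside the total specimen mask")
  voxel_mm3 <- prod(as.numeric(voxel_size))
  (sum(total_mask) - sum(bones)) * voxel_mm3 / 1000
}

#' Mask bead silhouettes out of a radiograph
#'
#' Replaces every pixel within `radius` of each bead centre by the median
#' intensity of the surrounding annulus (radius .. 2 x radius), removing
#' the beads' fiducial information while leaving the rest of the image
#' untouched.
#'
#' @param image numeric matrix of pixel intensities.
#' @param bead_centers n x 2 matrix of (row, col) pixel centres.
#' @param radius masking radius in pixels.
#' @return The masked image.
#' @export
mask_beads <- function(image, bead_centers, radius) {
  if (radius <= 0) stop("radius must be positive")
  image <- as.matrix(image)
  if (is.null(bead_centers) || length(bead_centers) == 0L) return(image)
  bead_centers <- if (is.null(dim(bead_centers))) {
    matrix(bead_centers, 1)
  } else as.matrix(bead_centers)
  nr <- nrow(image); nc <- ncol(image)
  if (any(bead_centers[, 1] < 1 | bead_centers[, 1] > nr |
          bead_centers[, 2] < 1 | bead_centers[, 2] > nc))
    stop("bead centre outside image bounds")
  for (i in seq_len(nrow(bead_centers))) {
    cr <- bead_centers[i, 1]; cc <- bead_centers[i, 2]
    rows <- max(1, floor(cr - 2 * radius)):min(nr, ceiling(cr + 2 * radius))
    cols <- max(1, floor(cc - 2 * radius)):min(nc, ceiling(cc + 2 * radius))
    dg <- expand.grid(r = rows, col = cols)
    dist <- sqrt((dg$r - cr)^2 + (dg$col - cc)^2)
    ann <- dist > radius & dist <= 2 * radius
    disk <- dist <= radius
    if (!any(ann)) stop("annulus empty: bead too close to image border")
    fill <- stats::median(image[cbind(dg$r[ann], dg$col[ann])])
    image[cbind(dg$r[disk], dg$col[disk])] <- fill
  }
  image
}
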