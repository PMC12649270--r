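#' Single X-ray view model
#'
#' A pinhole-style model of one X-ray source / image-intensifier pair:
#' point source, flat detector, and an in-plane pixel grid. The principal
#' point (pixel (0, 0)) is the detector centre; `u` runs horizontally,
#' `v` vertically (up) on the detector face.
#'
#' @param source_position,detector_center 3-vectors (mm, lab frame).
#' @param u_axis,v_axis orthonormal in-plane detector axes; both must be
#'   orthogonal to the source-to-centre ray.
#' @param detector_size width x height (mm).
#' @param pixel_pitch mm per pixel.
#' @export
view_model <- function(source_position, detector_center, u_axis, v_axis,
                       detector_size = c(400, 400), pixel_pitch = 0.25) {
  source_position <- as.numeric(source_position)
  detector_center <- as.numeric(detector_center)
  ray <- detector_center - source_position
  sid <- vnorm(ray)
  if (sid < 1e-6) stop("degenerate view: source coincides with detector centre")
  d <- ray / sid
  u_axis <- as.numeric(u_axis); v_axis <- as.numeric(v_axis)
  if (abs(vnorm(u_axis) - 1) > 1e-9 || abs(vnorm(v_axis) - 1) > 1e-9 ||
      abs(sum(u_axis * v_axis)) > 1e-9)
    stop("detector axes must be orthonormal")
  if (abs(sum(u_axis * d)) > 1e-9 || abs(sum(v_axis * d)) > 1e-9)
    stop("detector axes must be orthogonal to the source-centre ray")
  if (any(detector_size <= 0) || pixel_pitch <= 0)
    stop("detector_size and pixel_pitch must be positive")
  structure(list(source = source_position, center = detector_center,
                 u = u_axis, v = v_axis, dir = d, sid = sid,
                 detector_size = as.numeric(detector_size),
                 pixel_pitch = pixel_pitch),
            class = "view_model")
}

#' Biplane videoradiography system geometry
#'
#' Builds a two-view BVR geometry from the quantities a lab reports:
#' source-to-image distance (SID), beam separation angle, and frame rate.
#' Both beams lie in the horizontal lab plane (Z up) and intersect at the
#' lab origin (the isocentre of the shared field of view); the hop travel
#' direction is lab +X.
#'
#' @param sid source-to-image distance (mm); default 1850.
#' @param separation angle between the two source-to-centre beams
#'   (degrees), default 55.
#' @param frame_rate capture rate (Hz), default 250.
#' @param detector_size detector width x height (mm).
#' @param pixel_pitch mm per pixel.
#' @param source_iso_fraction fraction of the SID between source and
#'   isocentre (the rest lies between isocentre and detector).
#' @return Object of class `bvr_geometry` with elements `views` (list of
#'   two `view_model`), `separation_angle`, `frame_rate`.
#' @examples
#' g <- build_geometry()
#' separation_angle(g)  # 55
#' @export
build_geometry <- function(sid = 1850, separation = 55, frame_rate = 250,
                           detector_size = c(400, 400), pixel_pitch = 0.25,
                           source_iso_fraction = 0.6) {
  if (sid <= 0) stop("sid must be positive")
  if (separation <= 0 || separation >= 180)
    stop("separation must lie strictly between 0 and 180 degrees")
  if (frame_rate <= 0) stop("frame_rate must be positive")
  if (source_iso_fraction <= 0 || source_iso_fraction >= 1)
    stop("source_iso_fraction must lie in (0, 1)")
  half <- deg2rad(separation) / 2
  zhat <- c(0, 0, 1)
  views <- lapply(c(-1, 1), function(sgn) {
    d <- c(sin(sgn * half), cos(sgn * half), 0)  # source -> centre beam
    src <- -d * source_iso_fraction * sid
    ctr <- d * (1 - source_iso_fraction) * sid
    u <- unitize(cross3(d, zhat), "detector u axis")
    v <- cross3(u, d)  # = +Z for horizontal beams
    view_model(src, ctr, u, v, detector_size, pixel_pitch)
  })
  if (vnorm(views[[1]]$source - views[[2]]$source) < 1e-6)
    stop("degenerate geometry: the two sources coincide")
  geom <- structure(list(views = views, separation_angle = separation,
                         frame_rate = frame_rate),
                    class = "bvr_geometry")
  meas <- separation_angle(geom)
  if (abs(meas - separation) > 0.01)
    stop("internal error: constructed separation angle off by > 0.01 deg")
  geom
}

#' Measured angle between the two beams of a geometry
#' @param geometry a `bvr_geometry`.
#' @return Angle in degrees between the two source-to-centre rays.
#' @export
separation_angle <- function(geometry) {
  d1 <- geometry$views[[1]]$dir
  d2 <- geometry$views[[2]]$dir
  rad2deg(acos(max(-1, min(1, sum(d1 * d2)))))
}

#' @export
print.bvr_geometry <- function(x, ...) {
  cat(sprintf("<bvr_geometry> SID %.0f mm, separation %.2f deg, %g Hz, detector %g x %g mm @ %g mm/px\n",
              x$views[[1]]$sid, separation_angle(x), x$frame_rate,
              x$views[[1]]$detector_size[1], x$views[[1]]$detector_size[2],
              x$views[[1]]$pixel_pitch))
  invisible(x)
}

#' Project bead positions onto both detectors
#'
#' Perspective projection of 3D lab-frame points from each X-ray source
#' onto its detector plane. Points projecting outside the detector
#' bounds, or lying behind the source relative to the beam, are flagged
#' not visible and carry NA pixel coordinates. Gaussian pixel noise is
#' added to visible points only (visibility is decided on the noise-free
#' projection).
#'
#' @param geometry a `bvr_geometry`.
#' @param points N x 3 matrix of lab coordinates (mm).
#' @param labels point labels (default p1..pN).
#' @param pixel_noise_sd Gaussian noise SD in pixels.
#' @param seed optional RNG seed for the noise.
#' @return data.frame with columns `view`, `bead_label`, `u`, `v`
#'   (pixels, principal point at (0,0)), `visible`.
#' @export
project_beads <- function(geometry, points, labels = NULL,
                          pixel_noise_sd = 0, seed = NULL) {
  points <- if (is.null(dim(points))) matrix(points, 1) else as.matrix(points)
  if (ncol(points) != 3L) stop("points must be N x 3")
  if (pixel_noise_sd < 0) stop("pixel_noise_sd must be >= 0")
  if (is.null(labels)) labels <- sprintf("p%02d", seq_len(nrow(points)))
  with_seed(seed, {
    out <- lapply(seq_along(geometry$views), function(k) {
      vw <- geometry$views[[k]]
      rel <- sweep(points, 2, vw$source)            # source -> point
      depth <- rel %*% vw$dir                       # along-beam component
      lambda <- vw$sid / depth                      # ray scale to detector
      hit <- sweep(rel * as.numeric(lambda), 2, vw$source, "+")
      off <- sweep(hit, 2, vw$center)
      u <- (off %*% vw$u) / vw$pixel_pitch
      v <- (off %*% vw$v) / vw$pixel_pitch
      half_px <- vw$detector_size / (2 * vw$pixel_pitch)
      visible <- as.numeric(depth) > 1e-9 &
        abs(as.numeric(u)) <= half_px[1] & abs(as.numeric(v)) <= half_px[2]
      u <- as.numeric(u); v <- as.numeric(v)
      if (pixel_noise_sd > 0) {
        u[visible] <- u[visible] + stats::rnorm(sum(visible), 0, pixel_noise_sd)
        v[visible] <- v[visible] + stats::rnorm(sum(visible), 0, pixel_noise_sd)
      }
      u[!visible] <- NA_real_; v[!visible] <- NA_real_
      data.frame(view = k, bead_label = labels, u = u, v = v,
                 visible = visible)
    })
    do.call(rbind, out)
  })
}
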