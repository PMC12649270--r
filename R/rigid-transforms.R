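#' Rigid-body transform
#'
#' A rigid transform maps points from one coordinate system to another
#' (typically bone CT coordinates to the BVR lab frame) as
#' `p' = R p + t`, with `R` a proper rotation and `t` in millimetres.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector (mm).
#' @param tol orthonormality tolerance checked on construction.
#' @return An object of class `rigid_transform` with elements `R` and `t`.
#' @examples
#' T1 <- rigid_transform(rot_x(30), c(1, 2, 3))
#' compose(T1, rt_invert(T1))  # identity
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0), tol = 1e-9) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("rotation must be a 3x3 matrix")
  translation <- as.numeric(translation)
  if (length(translation) != 3L)
    stop("translation must have length 3")
  stopifnot_finite(rotation, "rotation")
  stopifnot_finite(translation, "translation")
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > tol)
    stop(sprintf("rotation is not orthonormal (max |R'R - I| = %.3g > %.1g)",
                 err, tol))
  if (abs(det(rotation) - 1) > max(tol, 1e-8))
    stop("rotation determinant is not +1 (improper rotation / reflection)")
  structure(list(R = rotation, t = translation), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle(x$R)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              rad2deg(ang), x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

is_rigid_transform <- function(x) inherits(x, "rigid_transform")

#' Identity transform
#' @return The identity `rigid_transform`.
#' @export
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Elementary rotations
#'
#' Rotation matrices about the coordinate axes. Angles are accepted in
#' degrees at the interface; radians are used internally throughout.
#'
#' @param angle rotation angle.
#' @param unit `"deg"` (default) or `"rad"`.
#' @return 3x3 rotation matrix.
#' @export
rot_x <- function(angle, unit = c("deg", "rad")) {
  a <- if (match.arg(unit) == "deg") deg2rad(angle) else angle
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(angle, unit = c("deg", "rad")) {
  a <- if (match.arg(unit) == "deg") deg2rad(angle) else angle
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(angle, unit = c("deg", "rad")) {
  a <- if (match.arg(unit) == "deg") deg2rad(angle) else angle
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

# Rodrigues rotation about a unit axis, angle in radians.
rotation_about <- function(axis, angle) {
  axis <- unitize(axis, "rotation axis")
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

#' Compose and invert rigid transforms
#'
#' `compose(a, b)` returns the transform applying `b` first, then `a`
#' (`compose(a, b)$apply(p) == a(b(p))`). `rt_invert` returns the inverse.
#'
#' @param a,b,x `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose <- function(a, b) {
  if (!is_rigid_transform(a) || !is_rigid_transform(b))
    stop("compose() expects rigid_transform inputs")
  structure(list(R = a$R %*% b$R,
                 t = as.numeric(a$R %*% b$t) + a$t),
            class = "rigid_transform")
}

#' @rdname compose
#' @export
rt_invert <- function(x) {
  if (!is_rigid_transform(x)) stop("rt_invert() expects a rigid_transform")
  Rt <- t(x$R)
  structure(list(R = Rt, t = as.numeric(-Rt %*% x$t)),
            class = "rigid_transform")
}

#' Apply a transform to points
#'
#' @param x a `rigid_transform`.
#' @param points length-3 vector or N x 3 matrix of coordinates (mm).
#' @return Transformed coordinates, same shape as the input.
#' @export
rt_apply <- function(x, points) {
  if (!is_rigid_transform(x)) stop("rt_apply() expects a rigid_transform")
  if (is.null(dim(points))) {
    as.numeric(x$R %*% points) + x$t
  } else {
    sweep(points %*% t(x$R), 2, x$t, "+")
  }
}

#' Labelled 3D point set
#'
#' Bead coordinates tagged with the coordinate system they live in
#' (`"CT"` for the CT scan frame, `"lab"` for the BVR global frame).
#'
#' @param coordinates N x 3 matrix (mm).
#' @param labels character vector of unique bead identifiers.
#' @param frame `"CT"` or `"lab"`.
#' @export
point_set <- function(coordinates, labels = NULL, frame = c("CT", "lab")) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3L) stop("coordinates must be N x 3")
  frame <- match.arg(frame)
  if (is.null(labels)) labels <- sprintf("b%02d", seq_len(nrow(coordinates)))
  labels <- as.character(labels)
  if (length(labels) != nrow(coordinates))
    stop("one label per point required")
  if (anyDuplicated(labels)) stop("duplicate bead labels")
  stopifnot_finite(coordinates, "coordinates")
  rownames(coordinates) <- labels
  structure(list(labels = labels, coordinates = coordinates, frame = frame),
            class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d points in %s frame\n", length(x$labels), x$frame))
  invisible(x)
}

#' Least-squares rigid registration (Kabsch)
#'
#' Finds the rigid transform minimising the sum of squared distances from
#' transformed `source` points to matched `target` points, using the SVD
#' (Kabsch) solution with determinant-sign correction to exclude
#' reflections. Points are matched by label.
#'
#' @param source,target `point_set` objects sharing at least 3 labels.
#' @param min_points minimum number of matched points.
#' @return List with `transform` (source frame -> target frame), `rms`
#'   residual (mm), and `n` points used.
#' @export
kabsch_fit <- function(source, target, min_points = 3L) {
  if (!inherits(source, "point_set") || !inherits(target, "point_set"))
    stop("kabsch_fit() expects point_set inputs")
  common <- intersect(source$labels, target$labels)
  if (length(common) < length(source$labels) &&
      length(common) < length(target$labels) && length(common) == 0L)
    stop("label mismatch: no common bead labels between source and target")
  if (length(common) < min_points)
    stop(sprintf("need at least %d matched points, got %d",
                 min_points, length(common)))
  S <- source$coordinates[common, , drop = FALSE]
  Tm <- target$coordinates[common, , drop = FALSE]
  sbar <- colMeans(S); tbar <- colMeans(Tm)
  Sc <- sweep(S, 2, sbar); Tc <- sweep(Tm, 2, tbar)
  sv <- svd(Sc)$d
  if (sv[2] < 1e-6 * max(sv[1], 1))
    stop("degenerate point configuration: points are collinear")
  C <- t(Sc) %*% Tc
  dec <- svd(C)
  d <- sign(det(dec$v %*% t(dec$u)))
  R <- dec$v %*% diag(c(1, 1, d)) %*% t(dec$u)
  tr <- tbar - as.numeric(R %*% sbar)
  fitted <- sweep(S %*% t(R), 2, tr, "+")
  rms <- sqrt(mean(rowSums((fitted - Tm)^2)))
  list(transform = rigid_transform(R, tr), rms = rms, n = length(common))
}

#' Quaternion conversions
#'
#' `to_quaternion` converts the rotation part of a transform (or a bare
#' rotation matrix) to a unit quaternion `(w, x, y, z)`;
#' `from_quaternion` rebuilds a `rigid_transform`. Quaternions `q` and
#' `-q` represent the same rotation (double cover).
#'
#' @param x a `rigid_transform` or 3x3 rotation matrix.
#' @return `to_quaternion`: named numeric `(w, x, y, z)` with unit norm.
#' @export
to_quaternion <- function(x) {
  R <- if (is_rigid_transform(x)) x$R else as.matrix(x)
  # Shepperd's method: pick the largest diagonal pivot for stability
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr >= R[1, 1] && tr >= R[2, 2] && tr >= R[3, 3]) {
    s <- sqrt(1 + tr) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  q <- q / vnorm(q)
  names(q) <- c("w", "x", "y", "z")
  q
}

#' @rdname to_quaternion
#' @param q numeric quaternion `(w, x, y, z)`; need not be normalised but
#'   must have non-zero norm.
#' @param translation length-3 translation (mm).
#' @export
from_quaternion <- function(q, translation = c(0, 0, 0)) {
  q <- as.numeric(q)
  if (length(q) != 4L) stop("quaternion must have 4 components")
  n <- vnorm(q)
  if (n < 1e-12) stop("zero-norm quaternion cannot represent a rotation")
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
  rigid_transform(R, translation, tol = 1e-7)
}

#' Enforce quaternion sign continuity along a trajectory
#'
#' Flips quaternion signs so consecutive samples have a non-negative dot
#' product. The represented rotations are unchanged; this is required
#' before filtering quaternion components as ordinary time series.
#'
#' @param q n x 4 matrix of quaternions (rows `(w, x, y, z)`).
#' @return n x 4 matrix with consecutive dot products >= 0.
#' @export
hemisphere_align <- function(q) {
  q <- as.matrix(q)
  if (ncol(q) != 4L) stop("expected an n x 4 quaternion matrix")
  if (nrow(q) == 0L) stop("empty quaternion sequence")
  for (i in seq_len(nrow(q))[-1]) {
    if (sum(q[i, ] * q[i - 1, ]) < 0) q[i, ] <- -q[i, ]
  }
  q
}

#' Read and write per-frame transform CSV files
#'
#' The interchange format between pipeline stages: one row per frame with
#' a `frame_index` column followed by the 16 row-major entries of the 4x4
#' homogeneous matrix (`m11`, `m12`, ..., `m44`). A header line is
#' required.
#'
#' @param transforms list of `rigid_transform`.
#' @param path file path.
#' @param frame_index integer frame indices (defaults to 1..n).
#' @export
write_transform_csv <- function(transforms, path, frame_index = NULL) {
  if (is.null(frame_index)) frame_index <- seq_along(transforms)
  if (length(frame_index) != length(transforms))
    stop("frame_index length must match transforms")
  header <- paste(c("frame_index",
                    paste0("m", rep(1:4, each = 4), rep(1:4, times = 4))),
                  collapse = ",")
  rows <- vapply(seq_along(transforms), function(i) {
    x <- transforms[[i]]
    M <- rbind(cbind(x$R, x$t), c(0, 0, 0, 1))
    paste(c(format(frame_index[i]),
            sprintf("%.12g", as.numeric(t(M)))), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_transform_csv
#' @return `read_transform_csv`: list with `frame_index` and `transforms`.
#' @export
read_transform_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "frame_index" || ncol(df) != 17L)
    stop("malformed transform CSV: expected frame_index + 16 matrix columns")
  transforms <- lapply(seq_len(nrow(df)), function(i) {
    M <- matrix(as.numeric(df[i, -1]), 4, 4, byrow = TRUE)
    if (max(abs(M[4, ] - c(0, 0, 0, 1))) > 1e-9)
      stop("malformed homogeneous matrix: bottom row is not (0,0,0,1)")
    R <- M[1:3, 1:3]
    # text round-trip can leave ~1e-12 orthonormality error; project back
    if (max(abs(crossprod(R) - diag(3))) > 1e-9) {
      dec <- svd(R)
      R <- dec$u %*% t(dec$v)
      if (det(R) < 0) stop("stored rotation is improper")
    }
    rigid_transform(R, M[1:3, 4])
  })
  list(frame_index = as.integer(df$frame_index), transforms = transforms)
}
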