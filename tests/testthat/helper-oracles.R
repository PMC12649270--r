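# Independent oracles used to cross-check the implementation.

# Horn's closed-form absolute-orientation solution (quaternion eigenvector
# method) -- independent of the SVD/Kabsch route in the package.
horn_fit <- function(source, target) {
  S <- source$coordinates[source$labels, , drop = FALSE]
  Tm <- target$coordinates[source$labels, , drop = FALSE]
  sbar <- colMeans(S); tbar <- colMeans(Tm)
  Sc <- sweep(S, 2, sbar); Tc <- sweep(Tm, 2, tbar)
  M <- t(Sc) %*% Tc
  N <- matrix(c(
    M[1,1]+M[2,2]+M[3,3], M[2,3]-M[3,2],        M[3,1]-M[1,3],        M[1,2]-M[2,1],
    M[2,3]-M[3,2],        M[1,1]-M[2,2]-M[3,3], M[1,2]+M[2,1],        M[3,1]+M[1,3],
    M[3,1]-M[1,3],        M[1,2]+M[2,1],       -M[1,1]+M[2,2]-M[3,3], M[2,3]+M[3,2],
    M[1,2]-M[2,1],        M[3,1]+M[1,3],        M[2,3]+M[3,2],       -M[1,1]-M[2,2]+M[3,3]),
    4, 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  R <- bvrkin::from_quaternion(q)$R
  tr <- tbar - as.numeric(R %*% sbar)
  fitted <- sweep(S %*% t(R), 2, tr, "+")
  list(R = R, t = tr, rms = sqrt(mean(rowSums((fitted - Tm)^2))))
}

# Midpoint of the common perpendicular of two skew rays (closed form).
ray_midpoint <- function(o1, d1, o2, d2) {
  d1 <- d1 / sqrt(sum(d1^2)); d2 <- d2 / sqrt(sum(d2^2))
  w <- o1 - o2
  a <- sum(d1 * d1); b <- sum(d1 * d2); cc <- sum(d2 * d2)
  d <- sum(d1 * w); e <- sum(d2 * w)
  den <- a * cc - b * b
  s <- (b * e - cc * d) / den
  t <- (a * e - b * d) / den
  (o1 + s * d1 + o2 + t * d2) / 2
}

# Rodrigues rotation matrix about an axis, angle in degrees.
rotation_about_deg <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# Uniform random rotation matrix (quaternion from 4 normals).
random_rotation <- function() {
  q <- stats::rnorm(4)
  bvrkin::from_quaternion(q / sqrt(sum(q^2)))$R
}

random_transform <- function(trans_scale = 100) {
  bvrkin::rigid_transform(random_rotation(), stats::rnorm(3, 0, trans_scale))
}

# Analytic squared-magnitude response of the zero-phase (dual-pass)
# digital Butterworth used by filter_pose_sequence: bilinear-transform
# prewarped analog prototype, squared for the double pass.
butter_zero_phase_gain <- function(f, fs, cutoff, order = 2) {
  fd <- cutoff / (sqrt(2) - 1)^(1 / (2 * order))  # single-pass design cutoff
  warp <- function(x) tan(pi * x / fs)
  (1 / (1 + (warp(f) / warp(fd))^(2 * order)))
}

# Amplitude of a sinusoid at known frequency via least-squares fit on the
# central portion of a series (avoids edge transients).
fitted_amplitude <- function(x, f, fs, trim = 0.25) {
  n <- length(x)
  idx <- seq(floor(n * trim) + 1, ceiling(n * (1 - trim)))
  tt <- (idx - 1) / fs
  X <- cbind(1, sin(2 * pi * f * tt), cos(2 * pi * f * tt))
  cf <- qr.solve(X, x[idx])
  sqrt(cf[2]^2 + cf[3]^2)
}

transforms_equal <- function(a, b, tol = 1e-9) {
  max(max(abs(a$R - b$R)), max(abs(a$t - b$t))) < tol
}

# Small test scene: preset specimen 2, default geometry.
test_specimen <- function() bvrkin::generate_specimen(102L, 1203, id = "specimen2")
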