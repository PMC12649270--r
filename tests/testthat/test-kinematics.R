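test_that("anatomical frames are right-handed for canonical and mirrored limbs", {
  canon <- list(medial_epicondyle = c(40, 0, 0),
                lateral_epicondyle = c(-40, 0, 0),
                proximal_shaft = c(0, 0, 150))
  acs <- build_anatomical_frame(canon, "femur")
  expect_true(transforms_equal(acs$transform, rt_identity(), 1e-9))

  mirrored <- canon
  mirrored$medial_epicondyle <- c(-40, 0, 0)
  mirrored$lateral_epicondyle <- c(40, 0, 0)
  acs_m <- build_anatomical_frame(mirrored, "femur")
  expect_equal(det(acs_m$transform$R), 1, tolerance = 1e-9)

  tib <- list(medial_plateau = c(38, 0, 0), lateral_plateau = c(-38, 0, 0),
              distal_shaft = c(0, 0, -130))
  acs_t <- build_anatomical_frame(tib, "tibia")
  expect_true(transforms_equal(acs_t$transform, rt_identity(), 1e-9))

  expect_error(build_anatomical_frame(canon[-1], "femur"), "landmark")
  expect_error(build_anatomical_frame(
    list(medial_epicondyle = c(1, 0, 0), lateral_epicondyle = c(1, 0, 0),
         proximal_shaft = c(0, 0, 100)), "femur"), "degenerate")
})

test_that("frozen specimens decompose to their configured flexion", {
  for (seed in c(7L, 8L, 9L)) {
    sp <- generate_specimen(seed, 2500)
    rel <- relative_pose(rt_identity(), sp$frozen_relative_pose,
                         sp$femur_acs, sp$tibia_acs)
    dof <- decompose_xyz(rel)
    expect_equal(unname(dof["FE"]), sp$flexion_deg, tolerance = 1e-9)
    expect_true(dof["FE"] >= 20 && dof["FE"] <= 55)
  }
})

test_that("relative pose composes as documented", {
  sp <- test_specimen()
  Tpose <- rigid_transform(rot_y(12), c(30, -10, 5))
  # identical bone poses with identical anatomical frames -> identity
  expect_true(transforms_equal(
    relative_pose(Tpose, Tpose, sp$femur_acs, sp$femur_acs), rt_identity(), 1e-9))

  # hand-computed example: identity ACS, tibia offset from femur by Rx(30)+t
  femur_T <- rigid_transform(rot_z(40), c(5, 6, 7))
  offset <- rigid_transform(rot_x(30), c(1, 2, 3))
  tibia_T <- compose(femur_T, offset)
  rel <- relative_pose(femur_T, tibia_T, rt_identity(), rt_identity())
  expect_true(transforms_equal(rel, offset, 1e-9))
  manual <- t(rot_z(40)) %*% (rot_z(40) %*% rot_x(30))  # femur^-1 tibia rotation
  expect_equal(rel$R, manual, tolerance = 1e-12)
})

test_that("X-Y-Z Euler decomposition round-trips and flags gimbal lock", {
  expect_equal(unname(decompose_xyz(rt_identity())), rep(0, 6))
  dof <- decompose_xyz(rigid_transform(rot_x(30)))
  expect_equal(unname(dof), c(30, 0, 0, 0, 0, 0), tolerance = 1e-9)

  set.seed(91)
  for (rep in 1:1000) {
    # sample away from gimbal lock (|AA| < 90)
    dof_in <- c(FE = runif(1, -170, 170), AA = runif(1, -80, 80),
                IE = runif(1, -170, 170), ML = rnorm(1, 0, 20),
                AP = rnorm(1, 0, 20), IS = rnorm(1, 0, 20))
    Tt <- compose_xyz(dof_in)
    back <- compose_xyz(decompose_xyz(Tt))
    expect_true(transforms_equal(back, Tt, 1e-9))
  }
  expect_error(decompose_xyz(rigid_transform(rot_y(90))), "gimbal")
})

test_that("constant pose sequences pass through the filter unchanged", {
  Tt <- rigid_transform(rot_x(25) %*% rot_z(10), c(4, 5, 6))
  seqs <- rep(list(Tt), 30)
  out <- filter_pose_sequence(seqs)
  for (x in out) expect_true(transforms_equal(x, Tt, 1e-9))
  # filtering does not bias a constant
  expect_equal(mean(vapply(out, function(x) x$t[1], numeric(1))) - Tt$t[1], 0,
               tolerance = 1e-9)
  expect_error(filter_pose_sequence(rep(list(Tt), 5)), "at least 7")
})

test_that("filter attenuation matches the analytic Butterworth response", {
  fs <- 250; n <- 500
  tt <- (0:(n - 1)) / fs
  base <- rigid_transform(diag(3), c(0, 0, 0))
  for (f in c(1, 50)) {
    seqs <- lapply(seq_len(n), function(i)
      rigid_transform(diag(3), c(10 * sin(2 * pi * f * tt[i]), 0, 0)))
    out <- filter_pose_sequence(seqs, frame_rate = fs, cutoff = 10)
    amp <- fitted_amplitude(vapply(out, function(x) x$t[1], numeric(1)), f, fs)
    expected <- 10 * butter_zero_phase_gain(f, fs, 10)
    if (f == 1) {
      expect_gt(amp, 10 * 0.99)                    # passband: < 1% attenuation
      expect_equal(amp, expected, tolerance = 0.02)
    } else {
      expect_lt(amp, 10 * 0.02)                    # stopband: < 2% leakage
      expect_lt(abs(amp - expected), 0.01 * 10)
    }
  }
})

test_that("rotational oscillations are filtered like translations", {
  fs <- 250; n <- 500
  tt <- (0:(n - 1)) / fs
  seqs <- lapply(seq_len(n), function(i)
    rigid_transform(rot_x(5 * sin(2 * pi * 1 * tt[i]))))
  out <- filter_pose_sequence(seqs, frame_rate = fs, cutoff = 10)
  ang <- vapply(out, function(x) decompose_xyz(x)[["FE"]], numeric(1))
  amp <- fitted_amplitude(ang, 1, fs)
  expect_gt(amp, 5 * 0.99)
  # renormalisation after component filtering introduces negligible error
  for (x in out) expect_lt(abs(sqrt(sum(to_quaternion(x)^2)) - 1), 1e-12)
})

test_that("tibial speed recovers constant-velocity set-points exactly", {
  still <- rep(list(rigid_transform(rot_x(10), c(3, 2, 1))), 20)
  expect_equal(tibial_speed(still, 250)$speed, rep(0, 20))
  for (v in c(1.8, 0.9)) {
    tr <- generate_trajectory("drop", v, 0.1, 250, seed = 2, speed_sd = 0,
                              pos_wander_mm_per_mps = 0,
                              rot_wander_deg_per_mps = 0)
    expect_equal(tibial_speed(tr$transforms, 250)$mean, v, tolerance = 1e-9)
  }
  expect_error(tibial_speed(still[1], 250), "at least 2")
})

test_that("time normalization yields the conventional frame counts", {
  sp <- test_specimen(); g <- build_geometry()
  hop <- generate_trial(sp, g, trial_config("hop", seed = 31L))
  drop <- generate_trial(sp, g, trial_config("drop", seed = 32L))
  kh <- trial_kinematics(hop, sp, "marker")
  kd <- trial_kinematics(drop, sp, "marker")
  expect_identical(nrow(time_normalize(kh, 75)), 75L)
  expect_identical(nrow(time_normalize(kd, 10)), 10L)
  # endpoints preserved exactly
  nh <- time_normalize(kh, 75)
  expect_equal(nh$FE[c(1, 75)], kh$FE[c(1, nrow(kh))])
  # a linear ramp stays on the ramp
  ramp <- data.frame(frame = 1:11, FE = seq(0, 10, 1), AA = 0, IE = 0,
                     ML = 0, AP = 0, IS = 0)
  out <- time_normalize(ramp, 6)
  expect_equal(out$FE, seq(0, 10, 2))
})

test_that("zero-noise marker and model kinematics agree to 1e-6", {
  sp <- test_specimen(); g <- build_geometry()
  cfg <- trial_config("hop", seed = 33L, duration = 0.1,
                      bead_pixel_noise_sd = 0, model_rot_noise_sd = 0,
                      model_trans_noise_sd = 0, outlier_frame_prob = 0)
  tr <- generate_trial(sp, g, cfg)
  km <- trial_kinematics(tr, sp, "marker")
  ko <- trial_kinematics(tr, sp, "model")
  for (d in c("FE", "AA", "IE", "ML", "AP", "IS")) {
    expect_lt(max(abs(km[[d]] - ko[[d]])), 1e-6)
  }
  # frozen-specimen constancy: truth kinematics have zero SD
  kt <- trial_kinematics(tr, sp, "truth")
  for (d in c("FE", "AA", "IE", "ML", "AP", "IS")) {
    expect_lt(stats::sd(kt[[d]]), 1e-9)
  }
})

test_that("difference-transform magnitude is invariant to the ACS convention", {
  sp <- test_specimen(); g <- build_geometry()
  tr <- generate_trial(sp, g, trial_config("hop", seed = 34L, duration = 0.1))
  frames <- which(tr$trackable)
  # alternative anatomical convention: axes tilted by a fixed rotation
  tilt_f <- compose(rigid_transform(rot_z(15) %*% rot_y(5)), sp$femur_acs$transform)
  tilt_t <- compose(rigid_transform(rot_x(-10)), sp$tibia_acs$transform)
  ang_for <- function(fa, ta) {
    vapply(frames, function(i) {
      rm_ <- relative_pose(tr$marker$femur[[i]], tr$marker$tibia[[i]], fa, ta)
      ro <- relative_pose(tr$model$femur[[i]], tr$model$tibia[[i]], fa, ta)
      D <- compose(ro, rt_invert(rm_))
      acos(pmin(1, (sum(diag(D$R)) - 1) / 2)) * 180 / pi
    }, numeric(1))
  }
  a1 <- ang_for(sp$femur_acs$transform, sp$tibia_acs$transform)
  a2 <- ang_for(tilt_f, tilt_t)
  expect_equal(a1, a2, tolerance = 1e-9)
  # pooled per-DOF RMS is approximately stable under a small ACS change
  rms_for <- function(fa, ta) {
    d <- t(vapply(frames, function(i) {
      rm_ <- relative_pose(tr$marker$femur[[i]], tr$marker$tibia[[i]], fa, ta)
      ro <- relative_pose(tr$model$femur[[i]], tr$model$tibia[[i]], fa, ta)
      decompose_xyz(ro) - decompose_xyz(rm_)
    }, numeric(6)))
    sqrt(mean(d[, 1:3]^2))
  }
  expect_equal(rms_for(sp$femur_acs$transform, sp$tibia_acs$transform),
               rms_for(compose(rigid_transform(rot_z(2)), sp$femur_acs$transform),
                       sp$tibia_acs$transform),
               tolerance = 0.05)
})
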