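test_that("default geometry reproduces the configured system", {
  g <- build_geometry()
  expect_equal(separation_angle(g), 55, tolerance = 1e-6)
  expect_equal(g$frame_rate, 250)
  for (vw in g$views) {
    # SID recomputed from the stored fields matches the input
    expect_equal(sqrt(sum((vw$center - vw$source)^2)), 1850, tolerance = 1e-6)
    expect_equal(sum(vw$u * vw$v), 0, tolerance = 1e-9)
    expect_equal(sum(vw$u * vw$dir), 0, tolerance = 1e-9)
    expect_equal(sum(vw$v * vw$dir), 0, tolerance = 1e-9)
    expect_equal(sqrt(sum(vw$u^2)), 1, tolerance = 1e-9)
  }
})

test_that("geometry handles alternative separations and rejects bad input", {
  g90 <- build_geometry(separation = 90)
  expect_equal(sum(g90$views[[1]]$dir * g90$views[[2]]$dir), 0,
               tolerance = 1e-9)
  g <- build_geometry(sid = 1400, separation = 45, frame_rate = 500)
  expect_equal(g$views[[1]]$sid, 1400, tolerance = 1e-6)
  expect_equal(separation_angle(g), 45, tolerance = 0.01)
  expect_error(build_geometry(sid = -1), "positive")
  expect_error(build_geometry(separation = 0), "between 0 and 180")
  expect_error(build_geometry(separation = 180), "between 0 and 180")
})

test_that("specimen generation is deterministic and non-degenerate", {
  a <- generate_specimen(1, 3038)
  b <- generate_specimen(1, 3038)
  expect_identical(a, b)

  presets <- specimen_presets()
  expect_equal(vapply(presets, function(s) s$soft_tissue_volume, numeric(1)),
               c(specimen1 = 3038, specimen2 = 1203, specimen3 = 3964))

  for (sp in presets) {
    for (bone in c("femur", "tibia")) {
      beads <- sp[[bone]]$beads
      n <- length(beads$labels)
      expect_true(n >= 6 && n <= 8)
      expect_gt(min(dist(beads$coordinates)), 5)
      # registration self-test: the cloud supports a clean rigid fit
      Tt <- rigid_transform(rot_x(30) %*% rot_y(10), c(4, 5, 6))
      fit <- kabsch_fit(beads, point_set(rt_apply(Tt, beads$coordinates),
                                         beads$labels, "lab"))
      expect_true(transforms_equal(fit$transform, Tt, 1e-9))
    }
    expect_true(sp$flexion_deg >= 20 && sp$flexion_deg <= 55)
  }
})

test_that("frozen relative pose is constant across all frames of all trials", {
  sp <- test_specimen()
  g <- build_geometry()
  for (motion in c("hop", "drop")) {
    tr <- generate_trial(sp, g, trial_config(motion, seed = 3L), track = FALSE)
    rels <- lapply(seq_len(tr$n_frames), function(i)
      compose(rt_invert(tr$truth$femur[[i]]), tr$truth$tibia[[i]]))
    for (r in rels) {
      expect_true(transforms_equal(r, sp$frozen_relative_pose, 1e-12))
    }
  }
})

test_that("trajectories honour speed set-points", {
  # zero speed: exactly stationary
  tr0 <- generate_trajectory("hop", 0, 0.1, 250, seed = 1)
  expect_equal(tr0$speed, 0)
  for (x in tr0$transforms) expect_identical(x, tr0$transforms[[1]])

  # constant-velocity segment: finite differences recover the set speed
  tr1 <- generate_trajectory("drop", 1.8, 0.1, 250, seed = 2, speed_sd = 0,
                             pos_wander_mm_per_mps = 0,
                             rot_wander_deg_per_mps = 0)
  spd <- tibial_speed(tr1$transforms, 250)
  expect_equal(spd$mean, 1.8, tolerance = 1e-9)
  expect_equal(max(abs(spd$speed - 1.8)), 0, tolerance = 1e-9)

  # hop: displacement predominantly horizontal, orientation wander small
  trh <- generate_trajectory("hop", 0.9, 0.3, 250, seed = 3)
  pos <- t(vapply(trh$transforms, function(x) x$t, numeric(3)))
  disp <- pos[nrow(pos), ] - pos[1, ]
  expect_gt(abs(disp[1]), 10 * max(abs(disp[2]), abs(disp[3])))
  angs <- vapply(trh$transforms, function(x)
    acos(pmin(1, (sum(diag(t(trh$transforms[[1]]$R) %*% x$R)) - 1) / 2)),
    numeric(1)) * 180 / pi
  expect_lt(max(angs), 5)

  # drop: predominantly vertical
  trd <- generate_trajectory("drop", 1.8, 0.04, 250, seed = 4)
  pos <- t(vapply(trd$transforms, function(x) x$t, numeric(3)))
  disp <- pos[nrow(pos), ] - pos[1, ]
  expect_gt(abs(disp[3]), 10 * max(abs(disp[1]), abs(disp[2])))
})

test_that("drop trials average to the configured mean speed", {
  means <- vapply(1:40, function(i) {
    tr <- generate_trajectory("drop", 1.8, 0.04, 250, seed = 1000 + i,
                              speed_sd = 0.4)
    tibial_speed(tr$transforms, 250)$mean
  }, numeric(1))
  se <- 0.4 / sqrt(40)
  expect_lt(abs(mean(means) - 1.8), 2 * se + 0.01)
})

test_that("bead projection behaves geometrically", {
  g <- build_geometry()
  # the isocentre lies on both centre rays -> principal point in both views
  prj <- project_beads(g, c(0, 0, 0))
  expect_equal(prj$u, c(0, 0), tolerance = 1e-9)
  expect_equal(prj$v, c(0, 0), tolerance = 1e-9)
  expect_true(all(prj$visible))

  # out-of-field point: invisible, no coordinates
  far <- project_beads(g, c(0, 0, 5000))
  expect_false(any(far$visible))
  expect_true(all(is.na(far$u)))

  # behind-source point: flagged invisible
  behind <- project_beads(g, g$views[[1]]$source - 100 * g$views[[1]]$dir)
  expect_false(behind$visible[behind$view == 1])

  # enlarging the detector never hides a visible bead
  set.seed(61)
  pts <- matrix(runif(60, -150, 150), 20)
  small <- project_beads(g, pts)
  big <- project_beads(build_geometry(detector_size = c(800, 800)), pts)
  expect_true(all(big$visible[small$visible]))
})

test_that("zero-noise projection triangulates back to the source point", {
  g <- build_geometry()
  set.seed(62)
  for (rep in 1:25) {
    p <- runif(3, -60, 60)
    prj <- project_beads(g, p)
    got <- triangulate(c(prj$u[1], prj$v[1]), c(prj$u[2], prj$v[2]), g)
    expect_lt(sqrt(sum((got$point - p)^2)), 1e-6)
  }
})

test_that("model-based emulator reproduces its configured noise law", {
  sp <- test_specimen()
  truth <- lapply(1:50, function(i) random_transform())
  cfg0 <- trial_config("hop", seed = 1, model_rot_noise_sd = 0,
                       model_trans_noise_sd = 0, outlier_frame_prob = 0)
  out0 <- emulate_model_based(truth, cfg0, seed = 5)
  for (i in seq_along(truth)) expect_identical(out0$transforms[[i]], truth[[i]])

  # half-normal rotation error: mean |angle| = sd * sqrt(2/pi)
  n <- 10000
  truthc <- rep(list(rt_identity()), n)
  cfg <- trial_config("hop", seed = 1, model_rot_noise_sd = 0.3,
                      model_trans_noise_sd = 0, outlier_frame_prob = 0)
  out <- emulate_model_based(truthc, cfg, seed = 6)
  angs <- vapply(out$transforms, function(x)
    acos(pmin(1, (sum(diag(x$R)) - 1) / 2)), numeric(1)) * 180 / pi
  expect_lt(abs(mean(angs) - 0.3 * sqrt(2 / pi)), 0.05 * 0.3 * sqrt(2 / pi))

  # outlier frames follow the configured binomial rate
  cfg2 <- trial_config("hop", seed = 1, outlier_frame_prob = 0.05)
  out2 <- emulate_model_based(truthc, cfg2, seed = 7)
  expect_lt(abs(sum(out2$outlier) - n * 0.05),
            3 * sqrt(n * 0.05 * 0.95))

  # determinism
  outa <- emulate_model_based(truth, cfg, seed = 8)
  outb <- emulate_model_based(truth, cfg, seed = 8)
  expect_identical(outa, outb)
})

test_that("identical trial config and seed give bit-identical trials", {
  sp <- test_specimen()
  g <- build_geometry()
  cfg <- trial_config("drop", seed = 12L)
  t1 <- generate_trial(sp, g, cfg)
  t2 <- generate_trial(sp, g, cfg)
  expect_identical(t1, t2)
})

test_that("soft-tissue volume subtracts bone from total", {
  total <- array(FALSE, c(20, 10, 10))
  total[1:10, , ] <- TRUE                      # 1000 voxels
  bones <- array(FALSE, c(20, 10, 10))
  bones[1:2, , ] <- TRUE                       # 200 voxels
  expect_equal(soft_tissue_volume(total, list(bones), c(1, 1, 1)), 0.8)
  empty <- array(FALSE, c(20, 10, 10))
  expect_equal(soft_tissue_volume(total, list(empty), c(1, 1, 1)), 1.0)

  # random nested masks against a brute-force voxel count
  set.seed(71)
  tot <- array(runif(8000) < 0.6, c(20, 20, 20))
  b1 <- tot & array(runif(8000) < 0.3, c(20, 20, 20))
  b2 <- tot & array(runif(8000) < 0.2, c(20, 20, 20))
  vx <- c(0.49, 0.49, 0.625)
  brute <- sum(tot & !(b1 | b2)) * prod(vx) / 1000
  expect_equal(soft_tissue_volume(tot, list(b1, b2), vx), brute)

  bad <- array(FALSE, c(20, 20, 20)); bad[1] <- TRUE
  bad_total <- array(FALSE, c(20, 20, 20))
  expect_error(soft_tissue_volume(bad_total, list(bad), vx), "outside")
  expect_error(soft_tissue_volume(tot, list(array(FALSE, c(2, 2, 2))), vx),
               "shape")
})

test_that("bead masking removes bead contrast and nothing else", {
  img <- matrix(100, 80, 80)
  disk_at <- function(img, cr, cc, r, val) {
    for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img)))
      if ((i - cr)^2 + (j - cc)^2 <= r^2) img[i, j] <- val
    img
  }
  one <- disk_at(img, 40, 40, 3, 400)
  masked <- mask_beads(one, c(40, 40), radius = 5)
  expect_equal(max(abs(masked - 100)), 0)

  expect_identical(mask_beads(img, NULL, 5), img)
  expect_error(mask_beads(img, c(40, 40), 0), "positive")
  expect_error(mask_beads(img, c(500, 40), 5), "bounds")

  # synthetic radiograph: 6 beads on a smooth background gradient
  bg <- outer(seq(80, 140, length.out = 80), seq(90, 110, length.out = 80),
              function(a, b) (a + b) / 2)
  centers <- cbind(c(15, 25, 40, 55, 65, 30), c(20, 60, 35, 15, 65, 45))
  contrast <- 300
  rad <- with_beads <- bg
  for (k in 1:6)
    with_beads <- disk_at(with_beads, centers[k, 1], centers[k, 2], 3,
                          bg[centers[k, 1], centers[k, 2]] + contrast)
  masked <- mask_beads(with_beads, centers, radius = 5)
  resid <- 0
  for (k in 1:6) {
    for (i in -5:5) for (j in -5:5) if (i^2 + j^2 <= 25) {
      r <- centers[k, 1] + i; cc <- centers[k, 2] + j
      resid <- max(resid, abs(masked[r, cc] - bg[r, cc]))
    }
  }
  expect_lt(resid, contrast / 10)
})
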