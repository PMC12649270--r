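#' Default pipeline configuration
#'
#' The study-scale demo: three specimens spanning the soft-tissue range
#' (3038, 1203, 3964 cm^3), 33 trials in total (7 hop + 4 drop per
#' specimen), default BVR geometry (SID 1850 mm, 55 degree separation,
#' 250 Hz), and default noise parameters. Hop tables normalise to 75
#' frames, drop tables to 10.
#'
#' @param n_hop,n_drop trials per specimen.
#' @param base_seed seed from which every trial seed is derived.
#' @return Config list consumable by [run_pipeline()].
#' @export
default_config <- function(n_hop = 7L, n_drop = 4L, base_seed = 20L) {
  specimens <- list(
    list(id = "specimen1", seed = 101L, soft_tissue_cm3 = 3038, noise_scale = 1),
    list(id = "specimen2", seed = 102L, soft_tissue_cm3 = 1203, noise_scale = 1),
    list(id = "specimen3", seed = 103L, soft_tissue_cm3 = 3964, noise_scale = 1))
  trials <- list()
  k <- 0L
  for (sp in specimens) {
    for (motion in c(rep("hop", n_hop), rep("drop", n_drop))) {
      k <- k + 1L
      trials[[k]] <- list(id = sprintf("%s_%s_%02d", sp$id, motion, k),
                          specimen = sp$id, motion = motion,
                          seed = derive_seed(base_seed, 100L + k))
    }
  }
  list(
    geometry = list(sid_mm = 1850, separation_deg = 55, frame_rate_hz = 250,
                    detector_mm = c(400, 400), pixel_pitch_mm = 0.25),
    noise = list(bead_pixel_noise_sd = 0.5, model_rot_noise_sd = 0.45,
                 model_trans_noise_sd = 0.40, outlier_frame_prob = 0.05,
                 outlier_noise_multiplier = 4),
    specimens = specimens,
    trials = trials,
    normalize = list(hop = 75L, drop = 10L))
}

#' Validate a pipeline configuration
#'
#' Checks the structure and value ranges of a config list (or JSON
#' file); errors describe the offending field.
#'
#' @param config config list or path to a JSON config file.
#' @return The validated config list, invisibly usable downstream.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  need <- function(ok, msg) if (!ok) stop(sprintf("invalid config: %s", msg))
  need(is.list(config$geometry), "missing geometry block")
  g <- config$geometry
  need(is.numeric(g$sid_mm) && g$sid_mm > 0, "geometry$sid_mm must be > 0")
  need(g$separation_deg > 0 && g$separation_deg < 180,
       "geometry$separation_deg must lie in (0, 180)")
  need(g$frame_rate_hz > 0, "geometry$frame_rate_hz must be > 0")
  no <- config$noise
  need(is.list(no), "missing noise block")
  need(all(unlist(no[c("bead_pixel_noise_sd", "model_rot_noise_sd",
                       "model_trans_noise_sd", "outlier_noise_multiplier")]) >= 0),
       "noise SDs and multiplier must be >= 0")
  need(no$outlier_frame_prob >= 0 && no$outlier_frame_prob <= 1,
       "noise$outlier_frame_prob must lie in [0, 1]")
  sps <- config$specimens
  if (is.data.frame(sps)) sps <- split(sps, seq_len(nrow(sps)))
  need(length(sps) >= 1, "at least one specimen required")
  ids <- vapply(sps, function(s) as.character(s$id), character(1))
  need(!anyDuplicated(ids), "duplicate specimen ids")
  trs <- config$trials
  if (is.data.frame(trs)) trs <- split(trs, seq_len(nrow(trs)))
  need(length(trs) >= 1, "at least one trial required")
  for (tr in trs) {
    need(tr$specimen %in% ids,
         sprintf("trial '%s' references unknown specimen '%s'", tr$id, tr$specimen))
    need(tr$motion %in% c("hop", "drop"),
         sprintf("trial '%s' has invalid motion", tr$id))
  }
  config$specimens <- sps
  config$trials <- trs
  config
}

config_geometry <- function(config) {
  g <- config$geometry
  build_geometry(sid = g$sid_mm, separation = g$separation_deg,
                 frame_rate = g$frame_rate_hz,
                 detector_size = as.numeric(g$detector_mm %||% c(400, 400)),
                 pixel_pitch = g$pixel_pitch_mm %||% 0.25)
}

config_specimens <- function(config) {
  out <- lapply(config$specimens, function(s)
    generate_specimen(as.integer(s$seed),
                      soft_tissue_volume = s$soft_tissue_cm3,
                      noise_scale = s$noise_scale %||% 1,
                      id = as.character(s$id)))
  names(out) <- vapply(out, function(s) s$id, character(1))
  out
}

config_trial_cfg <- function(tr, config) {
  no <- config$noise
  trial_config(motion = tr$motion, seed = as.integer(tr$seed),
               mean_speed = tr$mean_speed %||% NULL,
               speed_sd = tr$speed_sd %||% NULL,
               duration = tr$duration %||% NULL,
               bead_pixel_noise_sd = no$bead_pixel_noise_sd,
               model_rot_noise_sd = no$model_rot_noise_sd,
               model_trans_noise_sd = no$model_trans_noise_sd,
               outlier_frame_prob = no$outlier_frame_prob,
               outlier_noise_multiplier = no$outlier_noise_multiplier,
               id = as.character(tr$id))
}

PIPELINE_STAGES <- c("simulate", "track-markers", "kinematics", "agreement")

#' Run the full validation pipeline
#'
#' Orchestrates simulate -> track-markers -> kinematics -> agreement.
#' Every stage reads and writes only the documented CSV/JSON interchange
#' formats under `out_dir`, so stages can be re-run independently:
#'
#' * `simulate`: writes `geometry.json`, `config.json`, and per trial
#'   `truth_<bone>.csv`, `model_<bone>.csv`, `beads.csv`, `trial.json`.
#' * `track-markers`: reads `beads.csv` + geometry + specimen beads,
#'   writes `marker_<bone>.csv` (trackable frames only).
#' * `kinematics`: writes per trial `kinematics_marker.csv` /
#'   `kinematics_model.csv` and time-normalised versions (75 frames hop,
#'   10 drop).
#' * `agreement`: writes `report.csv` / `report.json` with the pooled,
#'   per-bone, per-specimen and per-motion analyses.
#'
#' Reruns with the same config are byte-identical. Per-stage frame
#' accounting is logged to stderr.
#'
#' @param config config list (see [default_config()]) or JSON path.
#' @param out_dir output directory (created if needed).
#' @param stages subset of the stage names, or `"all"`. Later stages
#'   error if an upstream output is missing.
#' @param normalize `"on"` (default; 75/10 frames by motion) or `"off"`.
#' @return A run manifest (list): config hash, seeds, file paths, and
#'   per-stage frame counts. Written to `manifest.json`.
#' @export
run_pipeline <- function(config = default_config(), out_dir, stages = "all",
                         normalize = c("on", "off")) {
  normalize <- match.arg(normalize)
  config <- validate_config(config)
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message(sprintf(...))
  config_path <- file.path(out_dir, "config.json")
  geometry <- config_geometry(config)
  specimens <- config_specimens(config)
  trial_dir <- function(id) file.path(out_dir, "trials", id)
  manifest <- list(seeds = list(
    specimens = vapply(config$specimens, function(s) as.integer(s$seed), integer(1)),
    trials = vapply(config$trials, function(t) as.integer(t$seed), integer(1))),
    counts = list(trials = length(config$trials)), files = character(0))
  # manifest paths are stored relative to out_dir so reruns are identical
  add_file <- function(p) {
    rel <- sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", out_dir), "/?"),
               "", p)
    manifest$files <<- c(manifest$files, rel)
  }

  if ("simulate" %in% stages) {
    jsonlite::write_json(config, config_path, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    jsonlite::write_json(config$geometry, file.path(out_dir, "geometry.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    add_file(config_path); add_file(file.path(out_dir, "geometry.json"))
    frames_total <- 0L
    for (tr in config$trials) {
      cfg <- config_trial_cfg(tr, config)
      trial <- generate_trial(specimens[[tr$specimen]], geometry, cfg,
                              track = FALSE)
      d <- trial_dir(tr$id)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (bone in c("femur", "tibia")) {
        write_transform_csv(trial$truth[[bone]],
                            file.path(d, sprintf("truth_%s.csv", bone)))
        write_transform_csv(trial$model[[bone]],
                            file.path(d, sprintf("model_%s.csv", bone)))
        add_file(file.path(d, sprintf("truth_%s.csv", bone)))
        add_file(file.path(d, sprintf("model_%s.csv", bone)))
      }
      write_bead_csv(trial$observations, file.path(d, "beads.csv"))
      add_file(file.path(d, "beads.csv"))
      jsonlite::write_json(
        list(id = tr$id, specimen = tr$specimen, motion = tr$motion,
             seed = as.integer(tr$seed), n_frames = trial$n_frames,
             speed_mps = trial$speed,
             model_outlier_femur = trial$model_outlier$femur,
             model_outlier_tibia = trial$model_outlier$tibia,
             in_fov_femur = trial$in_fov$femur,
             in_fov_tibia = trial$in_fov$tibia),
        file.path(d, "trial.json"), auto_unbox = TRUE, digits = 10)
      add_file(file.path(d, "trial.json"))
      frames_total <- frames_total + trial$n_frames
    }
    manifest$counts$frames_generated <- frames_total
    log_msg("simulate: %d trials, %d frames generated",
            length(config$trials), frames_total)
  }

  if ("track-markers" %in% stages) {
    trackable_total <- 0L
    for (tr in config$trials) {
      d <- trial_dir(tr$id)
      bead_path <- file.path(d, "beads.csv")
      if (!file.exists(bead_path))
        stop("missing simulate output for trial '", tr$id,
             "': run the simulate stage first")
      obs <- read_bead_csv(bead_path)
      sp <- specimens[[tr$specimen]]
      meta <- jsonlite::read_json(file.path(d, "trial.json"), simplifyVector = TRUE)
      stub <- list(n_frames = meta$n_frames, observations = obs)
      tracked <- track_trial_markers(stub, sp, geometry)
      for (bone in c("femur", "tibia")) {
        idx <- which(!vapply(tracked$marker[[bone]], is.null, logical(1)))
        write_transform_csv(tracked$marker[[bone]][idx],
                            file.path(d, sprintf("marker_%s.csv", bone)),
                            frame_index = idx)
        add_file(file.path(d, sprintf("marker_%s.csv", bone)))
      }
      trackable_total <- trackable_total + sum(tracked$trackable)
      log_msg("track-markers %s: %d / %d frames trackable", tr$id,
              sum(tracked$trackable), meta$n_frames)
    }
    manifest$counts$frames_trackable <- trackable_total
  }

  if ("kinematics" %in% stages || "agreement" %in% stages) {
    trials <- lapply(config$trials, function(tr) {
      d <- trial_dir(tr$id)
      if (!file.exists(file.path(d, "marker_femur.csv")))
        stop("missing track-markers output for trial '", tr$id,
             "': run the track-markers stage first")
      meta <- jsonlite::read_json(file.path(d, "trial.json"), simplifyVector = TRUE)
      n <- meta$n_frames
      rd <- function(name) {
        got <- read_transform_csv(file.path(d, name))
        out <- vector("list", n)
        out[got$frame_index] <- got$transforms
        out
      }
      marker <- list(femur = rd("marker_femur.csv"), tibia = rd("marker_tibia.csv"))
      trackable <- vapply(seq_len(n), function(i)
        !is.null(marker$femur[[i]]) && !is.null(marker$tibia[[i]]), logical(1))
      structure(list(trial_id = tr$id, specimen_id = tr$specimen,
                     motion = tr$motion, frame_rate = geometry$frame_rate,
                     n_frames = n, speed = meta$speed_mps,
                     truth = list(femur = rd("truth_femur.csv"),
                                  tibia = rd("truth_tibia.csv")),
                     model = list(femur = rd("model_femur.csv"),
                                  tibia = rd("model_tibia.csv")),
                     marker = marker, trackable = trackable),
                class = "tracked_trial")
    })
    names(trials) <- vapply(config$trials, function(t) as.character(t$id),
                            character(1))
  }

  if ("kinematics" %in% stages) {
    analyzed <- 0L
    for (tr in trials) {
      d <- trial_dir(tr$trial_id)
      for (method in c("marker", "model")) {
        kin <- trial_kinematics(tr, specimens[[tr$specimen_id]], method,
                                filter = sum(tr$trackable) >= 7)
        p <- file.path(d, sprintf("kinematics_%s.csv", method))
        utils::write.csv(format(kin, digits = 10, trim = TRUE, scientific = FALSE),
                         p, row.names = FALSE, quote = FALSE)
        add_file(p)
        if (normalize == "on") {
          nf <- if (tr$motion == "hop") config$normalize$hop %||% 75L
                else config$normalize$drop %||% 10L
          pn <- file.path(d, sprintf("kinematics_%s_norm.csv", method))
          utils::write.csv(format(time_normalize(kin, nf), digits = 10,
                                  trim = TRUE, scientific = FALSE),
                           pn, row.names = FALSE, quote = FALSE)
          add_file(pn)
        }
      }
      analyzed <- analyzed + sum(tr$trackable)
    }
    manifest$counts$frames_analyzed <- analyzed
    log_msg("kinematics: %d frames analyzed across %d trials", analyzed,
            length(trials))
  }

  if ("agreement" %in% stages) {
    report <- stratified_report(trials, specimens)
    write_agreement_report(report, file.path(out_dir, "report.csv"),
                           file.path(out_dir, "report.json"))
    add_file(file.path(out_dir, "report.csv"))
    add_file(file.path(out_dir, "report.json"))
    manifest$counts$report_rows <- nrow(report)
    manifest$counts$frames_pooled <- report$n[report$analysis == "pooled"][1]
    log_msg("agreement: %d pooled frames, %d report rows",
            manifest$counts$frames_pooled, nrow(report))
  }

  if (file.exists(config_path)) {
    manifest$config_hash <- unname(tools::md5sum(config_path))
  }
  manifest$package_version <- as.character(utils::packageVersion("bvrkin"))
  manifest$stages <- stages
  abs_files <- file.path(out_dir, manifest$files)
  bad <- manifest$files[!file.exists(abs_files) | file.size(abs_files) == 0]
  if (length(bad))
    stop("pipeline outputs missing or empty: ", paste(bad, collapse = ", "))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}

#' Build the miniature bundled dataset
#'
#' Generates a deterministic 2-trial (one hop, one drop) single-specimen
#' dataset through the full pipeline; used as a small fixture that can
#' be regenerated bit-identically from its seed.
#'
#' @param dir output directory.
#' @param seed base seed.
#' @return The run manifest, invisibly.
#' @export
make_fixtures <- function(dir, seed = 77L) {
  config <- default_config(n_hop = 1L, n_drop = 1L, base_seed = seed)
  config$specimens <- config$specimens[2]
  config$trials <- Filter(function(t) t$specimen == "specimen2", config$trials)
  for (i in seq_along(config$trials)) {
    config$trials[[i]]$id <- sprintf("mini_%s", config$trials[[i]]$motion)
    if (config$trials[[i]]$motion == "hop") config$trials[[i]]$duration <- 0.08
  }
  run_pipeline(config, dir)
}
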