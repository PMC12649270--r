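DOF_NAMES <- c("FE", "AA", "IE", "ML", "AP", "IS")

#' Per-frame, per-DOF differences between two kinematics tables
#'
#' Computes the signed difference `test - reference` (Bland-Altman
#' convention: model minus marker) and the pair mean for each DOF at
#' each frame.
#'
#' @param reference,test kinematics tables covering identical frames
#'   (reference is conventionally the marker-based table).
#' @return Long data.frame with columns `frame`, `dof`, `diff`,
#'   `pair_mean`, plus the `specimen`, `trial`, `motion` metadata of the
#'   reference table.
#' @export
frame_differences <- function(reference, test) {
  if (nrow(reference) != nrow(test) ||
      !all(reference$frame == test$frame)) {
    missing <- union(setdiff(reference$frame, test$frame),
                     setdiff(test$frame, reference$frame))
    stop(sprintf("frame mismatch between tables (frames %s)",
                 paste(utils::head(missing, 10), collapse = ", ")))
  }
  out <- lapply(DOF_NAMES, function(d) {
    data.frame(frame = reference$frame, dof = d,
               diff = test[[d]] - reference[[d]],
               pair_mean = (test[[d]] + reference[[d]]) / 2)
  })
  out <- do.call(rbind, out)
  for (m in c("specimen", "trial", "motion")) {
    if (!is.null(reference[[m]])) out[[m]] <- reference[[m]][1]
  }
  out$dof <- factor(out$dof, levels = DOF_NAMES)
  out
}

#' Tracking accuracy: mean absolute difference
#'
#' @param diffs numeric vector of signed per-frame differences.
#' @return List with `mad` (mean of |diff|), `sd` (SD of |diff|), `n`.
#' @export
accuracy_mad <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2) stop("need at least 2 differences")
  a <- abs(diffs)
  list(mad = mean(a), sd = stats::sd(a), n = length(diffs))
}

#' Bland-Altman bias and limits of agreement
#'
#' Bias is the mean signed difference; the limits of agreement are
#' `bias +/- 1.96 x SD` of the differences (sample SD, n - 1
#' denominator), tabulated as the half-width. Outliers are frames whose
#' deviation from the bias exceeds the LoA half-width by more than a
#' 1e-9 numerical guard (degrees/mm), so two methods that agree to
#' machine precision report a zero outlier fraction.
#'
#' @param diffs numeric vector of signed per-frame differences.
#' @return List with `bias`, `loa` (half-width), `sd_diff`,
#'   `outlier_fraction`, `n`.
#' @export
bland_altman <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2) stop("need at least 2 differences")
  bias <- mean(diffs)
  sd_diff <- stats::sd(diffs)
  loa <- 1.96 * sd_diff
  out <- abs(diffs - bias) - loa > 1e-9
  list(bias = bias, loa = loa, sd_diff = sd_diff,
       outlier_fraction = mean(out), n = length(diffs))
}

#' Confidence interval half-width for the limits of agreement
#'
#' Large-sample Bland-Altman approximation:
#' `1.96 x sqrt(3 / n) x SD`.
#'
#' @param sd_diff SD of the differences.
#' @param n number of frames.
#' @return CI half-width in the units of the differences.
#' @export
loa_confidence_interval <- function(sd_diff, n) {
  if (n < 2) stop("need n >= 2")
  if (any(sd_diff < 0)) stop("sd_diff must be >= 0")
  1.96 * sqrt(3 / n) * sd_diff
}

#' Per-bone differences between tracking methods
#'
#' For each frame, forms the difference transform
#' `marker^-1 o model` (how far the model-based pose is from the
#' marker-based pose, in the bone's CT frame), expresses it in the
#' bone's anatomical frame by conjugation, and decomposes it into the
#' six DOFs.
#'
#' @param marker,model lists of CT -> lab transforms (NULL entries are
#'   untrackable frames and are skipped in both).
#' @param acs the bone's `anatomical_frame`.
#' @param frames optional frame indices.
#' @return Long data.frame with `frame`, `dof`, `diff`, `pair_mean`
#'   (zero by construction for per-bone differences, kept for format
#'   compatibility).
#' @export
per_bone_differences <- function(marker, model, acs, frames = NULL) {
  if (length(marker) != length(model))
    stop(sprintf("frame mismatch: %d marker vs %d model frames",
                 length(marker), length(model)))
  if (is.null(frames)) {
    frames <- which(!vapply(marker, is.null, logical(1)) &
                      !vapply(model, is.null, logical(1)))
  }
  a <- as_acs_transform(acs)
  ainv <- rt_invert(a)
  dof <- t(vapply(frames, function(i) {
    D <- compose(rt_invert(marker[[i]]), model[[i]])
    decompose_xyz(compose(a, compose(D, ainv)))
  }, numeric(6)))
  out <- do.call(rbind, lapply(seq_along(DOF_NAMES), function(j)
    data.frame(frame = frames, dof = DOF_NAMES[j], diff = dof[, j],
               pair_mean = 0)))
  out$dof <- factor(out$dof, levels = DOF_NAMES)
  out
}

summarise_diffs <- function(d, with_ci = FALSE) {
  rows <- lapply(levels(d$dof), function(dd) {
    x <- d$diff[d$dof == dd]
    acc <- accuracy_mad(x)
    ba <- bland_altman(x)
    data.frame(dof = dd, n = ba$n, mad = acc$mad, mad_sd = acc$sd,
               bias = ba$bias, loa = ba$loa,
               loa_ci = if (with_ci) loa_confidence_interval(ba$sd_diff, ba$n)
                        else NA_real_,
               outlier_frac = ba$outlier_fraction)
  })
  do.call(rbind, rows)
}

#' Stratified agreement report
#'
#' Runs the four agreement analyses of the validation design: (1) all
#' trial data pooled; (2) femur and tibia analysed separately from the
#' per-bone CT -> lab transforms; (3) data separated by specimen (soft
#' tissue effect); (4) data separated by motion type (velocity effect).
#' Accuracy is the mean absolute difference (+/- SD), bias and precision
#' come from Bland-Altman analysis, and LoA confidence intervals are
#' reported for the pooled analysis only.
#'
#' @param trials list of `tracked_trial` objects (marker tracking done).
#' @param specimens named list of `specimen_config`s keyed by specimen
#'   id.
#' @param strata subset of `c("pooled", "bone", "specimen", "motion")`.
#' @param filter low-pass filter the pose sequences before comparing
#'   (default FALSE: the emulated tracking noise is frame-independent,
#'   so agreement is assessed on the unfiltered per-frame poses; see the
#'   methods vignette).
#' @param cutoff filter cutoff (Hz) when `filter = TRUE`.
#' @return data.frame with one row per stratum level x DOF: `analysis`,
#'   `level`, `dof`, `n`, `mad`, `mad_sd`, `bias`, `loa`, `loa_ci`,
#'   `outlier_frac`. The underlying per-frame differences are attached
#'   as attributes `joint_diffs` and `bone_diffs`.
#' @export
stratified_report <- function(trials, specimens,
                              strata = c("pooled", "bone", "specimen", "motion"),
                              filter = FALSE, cutoff = 10) {
  strata <- match.arg(strata, several.ok = TRUE)
  if (length(trials) == 0L) stop("need at least one trial")
  joint <- list(); bone <- list()
  for (tr in trials) {
    sp <- specimens[[tr$specimen_id]]
    if (is.null(sp)) stop(sprintf("no specimen config for '%s'", tr$specimen_id))
    km <- trial_kinematics(tr, sp, "marker", filter = filter, cutoff = cutoff)
    ko <- trial_kinematics(tr, sp, "model", filter = filter, cutoff = cutoff)
    joint[[length(joint) + 1L]] <- frame_differences(km, ko)
    frames <- which(tr$trackable)
    for (b in c("femur", "tibia")) {
      bd <- per_bone_differences(tr$marker[[b]], tr$model[[b]],
                                 sp[[paste0(b, "_acs")]], frames = frames)
      bd$bone <- b
      bd$specimen <- tr$specimen_id
      bd$trial <- tr$trial_id
      bd$motion <- tr$motion
      bone[[length(bone) + 1L]] <- bd
    }
  }
  joint <- do.call(rbind, joint)
  bone <- do.call(rbind, bone)

  out <- list()
  if ("pooled" %in% strata) {
    s <- summarise_diffs(joint, with_ci = TRUE)
    out[[length(out) + 1L]] <- cbind(analysis = "pooled", level = "all", s)
  }
  if ("bone" %in% strata) {
    for (b in c("femur", "tibia")) {
      s <- summarise_diffs(bone[bone$bone == b, ])
      out[[length(out) + 1L]] <- cbind(analysis = "bone", level = b, s)
    }
  }
  if ("specimen" %in% strata) {
    for (sp in unique(joint$specimen)) {
      d <- joint[joint$specimen == sp, ]
      if (nrow(d) == 0L) { warning(sprintf("empty specimen stratum '%s'", sp)); next }
      out[[length(out) + 1L]] <- cbind(analysis = "specimen", level = sp,
                                       summarise_diffs(d))
    }
  }
  if ("motion" %in% strata) {
    for (mo in unique(joint$motion)) {
      d <- joint[joint$motion == mo, ]
      if (nrow(d) == 0L) { warning(sprintf("empty motion stratum '%s'", mo)); next }
      out[[length(out) + 1L]] <- cbind(analysis = "motion", level = mo,
                                       summarise_diffs(d))
    }
  }
  report <- do.call(rbind, out)
  rownames(report) <- NULL
  attr(report, "joint_diffs") <- joint
  attr(report, "bone_diffs") <- bone
  class(report) <- c("agreement_report", "data.frame")
  report
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Agreement report (model-based minus marker-based):\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an agreement report to CSV and JSON
#'
#' @param report an `agreement_report`.
#' @param csv_path,json_path output paths (NULL to skip either).
#' @export
write_agreement_report <- function(report, csv_path = NULL, json_path = NULL) {
  df <- as.data.frame(report)
  if (!is.null(csv_path))
    utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(df, json_path, dataframe = "rows", auto_unbox = TRUE,
                         digits = 10, na = "null")
  invisible(report)
}

#' Bland-Altman plot for one DOF
#'
#' Difference against pair mean with the bias and +/- LoA reference
#' lines, optionally faceted by specimen. Requires ggplot2.
#'
#' @param diffs long differences data.frame (e.g. attribute
#'   `joint_diffs` of a report).
#' @param dof which DOF to plot.
#' @param by_specimen facet by specimen.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(diffs, dof = "AP", by_specimen = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- diffs[diffs$dof == dof, ]
  ba <- bland_altman(d$diff)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = pair_mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = ba$bias + c(-1, 1) * ba$loa,
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods", y = "Model - marker",
                  title = sprintf("%s: bias %.2f, LoA %.2f", dof, ba$bias, ba$loa))
  if (by_specimen && !is.null(d$specimen))
    p <- p + ggplot2::facet_wrap(~specimen)
  p
}
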