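# Whole-trial orchestration: artifact detection splits the recording into
# the left- and right-rotation manoeuvres, each analyzed with its own
# baseline (re-baselined after the position change); marker metrics are
# computed over windows anchored to the force-phase points.

#' Analysis configuration
#'
#' All tunable thresholds of the pipeline with their defaults. Can be read
#' from / written to YAML ([read_analysis_config()]).
#'
#' @param ... overrides of the defaults (see source for the full set).
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(...) {
  cfg <- utils::modifyList(list(
    force_cutoff = 50, marker_cutoff = 10, filter_order = 4,
    onset_min_n = 10, onset_frac = 0.05, sustain_s = 0.05,
    min_event_n = 50, b_rule = "local_min",
    baseline_dur = 0.5, quiet_sd = 5,
    drop_threshold = 20, rise_threshold = 50, coincide_s = 0.5,
    ref_dur = 0.5, convention = "twist_z",
    onset_velocity_frac = 0.05, onset_sustain_s = 0.025,
    active_acromion = c(left_rotation = "op_shoulder_peak_right",
                        right_rotation = "op_shoulder_peak_left"),
    alias_map = NULL), list(...))
  structure(cfg, class = "analysis_config")
}

#' Read / write an analysis configuration as YAML
#' @param path YAML file path.
#' @return an [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}

#' @rdname read_analysis_config
#' @param config an [analysis_config()].
#' @export
write_analysis_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

analyze_side <- function(fz1, window, side, trial, series, vps, config) {
  base_w <- c(window[1], window[1] + config$baseline_dur)
  baseline <- estimate_baseline(fz1, base_w, quiet_sd = config$quiet_sd)
  pts <- segment_phases(fz1, baseline, window = window,
                        onset_min_n = config$onset_min_n,
                        onset_frac = config$onset_frac,
                        sustain_s = config$sustain_s,
                        min_event_n = config$min_event_n,
                        b_rule = config$b_rule)
  lf <- loaded_forces(fz1, pts, baseline)

  res <- list(side = side, phase_points = pts, baseline = baseline,
              stretch_loaded_max = lf$stretch_loaded_max,
              trigger_loaded_max = lf$trigger_loaded_max,
              phase_durations = lf$phase_durations,
              missing = character(0))

  acromion <- config$active_acromion[[side]]
  res$trigger_time <- tryCatch({
    m <- get_marker(trial, acromion)
    tw <- c(pts$B - 0.15, pts$C + 0.1)
    as.numeric(trigger_time(m$positions[, 3], m$rate, tw,
                            onset_frac = config$onset_velocity_frac,
                            sustain_s = config$onset_sustain_s,
                            cutoff = NULL))  # markers pre-filtered upstream
  }, error = function(e) {
    warning("trigger_time (", side, "): ", conditionMessage(e),
            call. = FALSE)
    res$missing <<- c(res$missing, "trigger_time")
    NA_real_
  })

  res$extension_amplitude <- tryCatch({
    extension_amplitude(vps$head_vertex, vps$mid_shoulder,
                        trial$markers[[1]]$rate,
                        baseline_window = c(pts$A - 0.5, pts$A),
                        stretch_window = c(pts$A, pts$B))
  }, error = function(e) {
    warning("extension_amplitude (", side, "): ", conditionMessage(e),
            call. = FALSE)
    res$missing <<- c(res$missing, "extension_amplitude")
    NA_real_
  })

  # rotation toward the manoeuvre side: the right-rotation excursion is
  # negative under the left-positive convention, so its magnitude is -min
  rot_toward <- function(window) {
    if (side == "right_rotation") {
      sel <- series$times >= window[1] & series$times <= window[2] &
        !series$masked
      if (!any(sel)) stop("empty rotation window", call. = FALSE)
      -min(series$axial_angle[sel])
    } else {
      max_rotation_angle(series, window)
    }
  }
  res$max_rotation_pre <- tryCatch(rot_toward(c(window[1], pts$B)),
                                   error = function(e) NA_real_)
  res$max_rotation_post <- tryCatch(rot_toward(c(pts$B, pts$D)),
                                    error = function(e) NA_real_)
  res
}

#' Analyze a full manipulation trial
#'
#' Runs the complete pipeline: vertical-GRF extraction and filtering,
#' position-change artifact detection (the artifact window is excluded and
#' the two manoeuvres are analyzed separately, each re-baselined), phase
#' segmentation, loaded forces, trigger time, extension amplitude, and
#' pre/post maximum axial rotation. Component failures yield partial
#' records with the missing fields named.
#'
#' @param trial a [trial()].
#' @param config an [analysis_config()].
#' @return a `manipulation_metrics` list: per-side records plus the
#'   artifact event and provenance.
#' @export
analyze_trial <- function(trial, config = analysis_config()) {
  fz1 <- vertical_grf(trial$plates[[1]], cutoff = config$force_cutoff,
                      order = config$filter_order)
  fz2 <- vertical_grf(trial$plates[[2]], cutoff = config$force_cutoff,
                      order = config$filter_order)
  art <- detect_position_change(fz1, fz2,
                                drop_threshold = config$drop_threshold,
                                rise_threshold = config$rise_threshold,
                                coincide_s = config$coincide_s)
  t_end <- max(fz1$times)
  windows <- if (!is.null(art)) {
    list(left_rotation = c(0, art$window[1]),
         right_rotation = c(art$window[2], t_end))
  } else {
    side <- trial$meta$side
    if (is.null(side) || side == "both") side <- "left_rotation"
    stats::setNames(list(c(0, t_end)), side)
  }

  trial <- filter_trial_markers(trial, cutoff = config$marker_cutoff,
                                order = config$filter_order)
  series <- angle_series(trial, convention = config$convention)
  vps <- virtual_points(trial)
  sides <- lapply(names(windows), function(s) {
    tryCatch(analyze_side(fz1, windows[[s]], s, trial, series, vps, config),
             error = function(e) {
               warning("side ", s, " failed: ", conditionMessage(e),
                       call. = FALSE)
               list(side = s, missing = "all",
                    error = conditionMessage(e))
             })
  })
  names(sides) <- names(windows)
  structure(list(sides = sides, artifact = art,
                 subject_id = trial$meta$subject_id,
                 convention = config$convention,
                 version = as.character(utils::packageVersion("manipkin"))),
            class = "manipulation_metrics")
}

#' Flatten metrics into a one-row-per-side data frame
#'
#' @param metrics a `manipulation_metrics` (or list of them).
#' @return data.frame with columns side, A, B, C, D, baseline_N,
#'   stretch_loaded_max_N, trigger_loaded_max_N, trigger_time_s,
#'   extension_amplitude_mm, max_rotation_pre_deg, max_rotation_post_deg.
#' @export
metrics_table <- function(metrics) {
  if (inherits(metrics, "manipulation_metrics")) metrics <- list(metrics)
  rows <- list()
  for (m in metrics) {
    for (s in m$sides) {
      if (identical(s$missing, "all")) next
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = if (is.null(m$subject_id)) NA else m$subject_id,
        side = s$side,
        A = s$phase_points$A, B = s$phase_points$B,
        C = s$phase_points$C, D = s$phase_points$D,
        baseline_N = s$baseline$value,
        stretch_loaded_max_N = s$stretch_loaded_max,
        trigger_loaded_max_N = s$trigger_loaded_max,
        trigger_time_s = s$trigger_time,
        extension_amplitude_mm = s$extension_amplitude,
        max_rotation_pre_deg = s$max_rotation_pre,
        max_rotation_post_deg = s$max_rotation_post)
    }
  }
  do.call(rbind, rows)
}
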