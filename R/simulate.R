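# Synthetic manipulation trials with full ground truth. A trial emulates the
# recorded structure: quiet prone baseline, slow stretch ramp, a small
# pre-thrust dip, a brief raised-cosine HVLA thrust, return to baseline, a
# mid-trial position-change artifact on both plates (subject lifts the head
# to turn it), then the mirrored right-rotation manoeuvre. Head markers move
# as a rigid body twisting about the vertical axis through the mid-shoulder
# point and translating cranially by the extension amplitude; the operator's
# active acromion executes a half-cosine vertical thrust excursion.

half_rise <- function(t, t0, t1) {
  x <- pmin(1, pmax(0, (t - t0) / (t1 - t0)))
  0.5 * (1 - cos(pi * x))
}

cos_bump <- function(t, t0, tm, t1) {
  half_rise(t, t0, tm) - half_rise(t, tm, t1)
}

#' Ground-truth parameters of one synthetic trial
#'
#' Defaults are the cohort-level reported values: pooled triggering-phase
#' loaded force 476.75 N, stretching-phase 274.79 N, trigger time 0.35 s,
#' extension 4.39 mm, rotation 68.6 deg before and 73.7 deg at the thrust,
#' position-change plate-2 peak 514.1 N at 5.68 s. Loaded forces and
#' extension accept length-2 vectors (left, right).
#'
#' @param trigger_loaded triggering-phase loaded force (N), scalar or
#'   c(left, right).
#' @param stretch_loaded stretching-phase loaded force (N), scalar or
#'   c(left, right).
#' @param trigger_duration thrust rise time I->II (s).
#' @param extension neck extension amplitude (mm), scalar or c(left, right).
#' @param rot_pre,rot_post maximum left-rotation angle before / at the
#'   thrust (degrees).
#' @param baseline1,baseline2 resting plate loads: head on plate 1, chest on
#'   plate 2 (N).
#' @param artifact_time centre of the position-change artifact (s); NA
#'   disables it.
#' @param artifact_peak2 absolute plate-2 peak during the artifact (N).
#' @param noise_sd_marker marker Gaussian noise SD (mm).
#' @param noise_sd_force force Gaussian noise SD (N).
#' @param seed RNG seed for the noise draws.
#' @param timeline named list overriding timeline defaults (see source).
#' @return a `subject_params` list.
#' @export
subject_params <- function(trigger_loaded = 476.75,
                           stretch_loaded = 274.79,
                           trigger_duration = 0.35,
                           extension = 4.39,
                           rot_pre = 68.6, rot_post = 73.7,
                           baseline1 = 50, baseline2 = 350,
                           artifact_time = 5.68, artifact_peak2 = 514.1,
                           noise_sd_marker = 0.5, noise_sd_force = 2,
                           seed = 1L, timeline = list()) {
  tl <- utils::modifyList(list(
    t_total = 12, ref_dur = 0.5,
    rot_ramp = c(0.5, 0.95),
    A = 1.0, stretch_dur = 2.0, dip_dur = 0.1, ext_ramp_dur = 1.5,
    return_dur = 1.0, right_offset = 6.0,
    artifact_halfwidth = 0.4,
    marker_rate = 200, force_rate = 1000,
    dip_frac = 0.08, couple_frac = 0.05, lift_frac = 0.85,
    thrust_marker_depth = 0.05), timeline)
  p <- list(trigger_loaded = rep(trigger_loaded, length.out = 2),
            stretch_loaded = rep(stretch_loaded, length.out = 2),
            trigger_duration = trigger_duration,
            extension = rep(extension, length.out = 2),
            rot_pre = rot_pre, rot_post = rot_post,
            baseline1 = baseline1, baseline2 = baseline2,
            artifact_time = artifact_time, artifact_peak2 = artifact_peak2,
            noise_sd_marker = noise_sd_marker,
            noise_sd_force = noise_sd_force,
            seed = as.integer(seed), timeline = tl)
  num <- unlist(p[c("trigger_loaded", "stretch_loaded", "trigger_duration",
                    "extension", "rot_pre", "rot_post", "baseline1",
                    "baseline2", "noise_sd_marker", "noise_sd_force")])
  if (any(num < 0)) stop("negative physical parameter", call. = FALSE)
  structure(p, class = "subject_params")
}

# per-side phase-point ground truth from a timeline
side_times <- function(tl, Td, offset = 0) {
  A <- tl$A + offset
  B <- A + tl$stretch_dur + tl$dip_dur
  C <- B + Td
  D <- C + Td + tl$return_dur
  list(A = A, B = B, C = C, D = D,
       plateau = A + tl$stretch_dur, dip0 = A + tl$stretch_dur,
       fall_end = C + Td)
}

# loaded vertical-force waveform of one manoeuvre (zero outside the event)
side_loaded_curve <- function(t, st, S, Tl, dip_frac) {
  d <- dip_frac * S
  ramp <- S * half_rise(t, st$A, st$plateau)
  dip <- -d * half_rise(t, st$dip0, st$B)
  thrust <- (Tl - (S - d)) * cos_bump(t, st$B, st$C, st$fall_end)
  ret <- -(S - d) * half_rise(t, st$fall_end, st$D)
  ramp + dip + thrust + ret
}

subject_geometry <- function() {
  static <- rbind(
    shoulder_peak_left = c(-0.18, 0.00, 0.25),
    shoulder_peak_right = c(0.18, 0.00, 0.25),
    subscapular_left = c(-0.10, -0.15, 0.27),
    subscapular_right = c(0.10, -0.15, 0.27),
    t10_spinous = c(0.00, -0.30, 0.25),  # level with the acromions: the
    # anatomical vertical coincides with lab Z in the simulated world
    c5_spinous = c(0.00, 0.05, 0.30),
    humerus_med_epi_left = c(-0.28, -0.10, 0.15),
    humerus_med_epi_right = c(0.28, -0.10, 0.15),
    humerus_lat_epi_left = c(-0.33, -0.12, 0.15),
    humerus_lat_epi_right = c(0.33, -0.12, 0.15),
    forearm_mid_left = c(-0.30, 0.10, 0.12),
    forearm_mid_right = c(0.30, 0.10, 0.12),
    psis_left = c(-0.08, -0.75, 0.22),
    psis_right = c(0.08, -0.75, 0.22))
  head <- rbind(
    head_crown = c(0.00, 0.36, 0.30),
    temporal_left = c(-0.07, 0.22, 0.30),
    temporal_right = c(0.07, 0.22, 0.30),
    occipital_bulge = c(0.00, 0.15, 0.33),
    mastoid_left = c(-0.06, 0.17, 0.26),
    mastoid_right = c(0.06, 0.17, 0.26))
  list(static = static, head = head, pivot = c(0, 0, 0.25))
}

operator_geometry <- function() {
  g <- rbind(
    op_c7_spinous = c(0.45, 0.10, 0.55),
    op_sternum = c(0.40, 0.18, 0.50),
    op_shoulder_peak_left = c(0.30, 0.32, 0.46),
    op_shoulder_peak_right = c(0.55, 0.30, 0.46),
    op_subscapular_left = c(0.34, 0.05, 0.50),
    op_subscapular_right = c(0.52, 0.05, 0.50),
    op_humerus_med_epi_left = c(0.25, 0.35, 0.35),
    op_humerus_med_epi_right = c(0.58, 0.33, 0.35),
    op_humerus_lat_epi_left = c(0.22, 0.38, 0.35),
    op_humerus_lat_epi_right = c(0.62, 0.36, 0.35),
    op_radius_styloid_left = c(0.20, 0.40, 0.28),
    op_radius_styloid_right = c(0.60, 0.38, 0.28),
    op_ulna_styloid_left = c(0.18, 0.42, 0.28),
    op_ulna_styloid_right = c(0.63, 0.40, 0.28),
    op_mcp3_left = c(0.15, 0.44, 0.26),
    op_mcp3_right = c(0.66, 0.42, 0.26),
    op_palm_heel_left_1 = c(0.16, 0.41, 0.27),
    op_palm_heel_left_2 = c(0.17, 0.43, 0.27),
    op_palm_heel_right_1 = c(0.64, 0.39, 0.27),
    op_palm_heel_right_2 = c(0.65, 0.41, 0.27),
    op_upperarm_track_left = c(0.27, 0.34, 0.40),
    op_upperarm_track_right = c(0.56, 0.32, 0.40),
    op_forearm_track_left = c(0.21, 0.39, 0.31),
    op_forearm_track_right = c(0.61, 0.37, 0.31))
  g
}

#' Simulate one manipulation trial
#'
#' Builds markers (200 Hz) and two force plates (1000 Hz) from a
#' [subject_params()] description and returns the trial together with the
#' full ground truth every pipeline metric can be checked against.
#'
#' @param params a [subject_params()].
#' @return list(trial = [trial()], truth = ground-truth list).
#' @export
simulate_trial <- function(params) {
  stopifnot(inherits(params, "subject_params"))
  tl <- params$timeline
  Td <- params$trigger_duration
  stL <- side_times(tl, Td, 0)
  stR <- side_times(tl, Td, tl$right_offset)
  if (stL$D >= stR$A) stop("timeline segments overlap: left return ends at ",
                           stL$D, " s but right stretch starts at ", stR$A,
                           " s", call. = FALSE)
  has_art <- is.finite(params$artifact_time)
  if (has_art) {
    aw <- params$artifact_time + c(-1, 1) * tl$artifact_halfwidth
    if (aw[1] <= stL$D || aw[2] >= stR$A) {
      stop("artifact window overlaps a manoeuvre", call. = FALSE)
    }
  }
  set.seed(params$seed)

  ## ---- force plates
  tf <- seq(0, tl$t_total - 1 / tl$force_rate, by = 1 / tl$force_rate)
  gL <- side_loaded_curve(tf, stL, params$stretch_loaded[1],
                          params$trigger_loaded[1], tl$dip_frac)
  gR <- side_loaded_curve(tf, stR, params$stretch_loaded[2],
                          params$trigger_loaded[2], tl$dip_frac)
  fz1 <- params$baseline1 + gL + gR
  thrL <- (params$trigger_loaded[1] -
             (1 - tl$dip_frac) * params$stretch_loaded[1]) *
    cos_bump(tf, stL$B, stL$C, stL$fall_end)
  thrR <- (params$trigger_loaded[2] -
             (1 - tl$dip_frac) * params$stretch_loaded[2]) *
    cos_bump(tf, stR$B, stR$C, stR$fall_end)
  fz2 <- params$baseline2 + tl$couple_frac * (thrL + thrR)
  if (has_art) {
    art <- cos_bump(tf, aw[1], params$artifact_time, aw[2])
    fz1 <- fz1 - tl$lift_frac * params$baseline1 * art
    fz2 <- fz2 + (params$artifact_peak2 - params$baseline2) * art
  }
  fx1 <- 0.10 * (gL + gR); fy1 <- 0.12 * (gL + gR)
  fx2 <- 0.10 * (fz2 - params$baseline2); fy2 <- 0.05 * (fz2 - params$baseline2)
  nse <- function(v) v + stats::rnorm(length(v), 0, params$noise_sd_force)
  plates <- list(force_channel(1, nse(fx1), nse(fy1), nse(fz1), tl$force_rate),
                 force_channel(2, nse(fx2), nse(fy2), nse(fz2), tl$force_rate))

  ## ---- markers
  tm <- seq(0, tl$t_total - 1 / tl$marker_rate, by = 1 / tl$marker_rate)
  nm <- length(tm)
  theta <- params$rot_pre * half_rise(tm, tl$rot_ramp[1], tl$rot_ramp[2]) +
    (params$rot_post - params$rot_pre) *
      (cos_bump(tm, stL$B, stL$C, stL$fall_end) -
         cos_bump(tm, stR$B, stR$C, stR$fall_end)) -
    2 * params$rot_pre * half_rise(tm, if (has_art) aw[1] else stL$D + 0.3,
                                   if (has_art) aw[2] else stR$A - 0.3) +
    params$rot_pre * half_rise(tm, tl$t_total - 1.0, tl$t_total - 0.2)
  ext_m <- (params$extension[1] / 1000) *
    (half_rise(tm, stL$A, stL$A + tl$ext_ramp_dur) -
       half_rise(tm, stL$fall_end, stL$D)) +
    (params$extension[2] / 1000) *
    (half_rise(tm, stR$A, stR$A + tl$ext_ramp_dur) -
       half_rise(tm, stR$fall_end, stR$D))

  geo <- subject_geometry()
  p0 <- geo$pivot
  u0 <- geo$head["head_crown", ] - p0
  base_dist <- sqrt(sum(u0^2))
  u0 <- u0 / base_dist
  cs <- cos(theta * pi / 180); sn <- sin(theta * pi / 180)
  sdm <- params$noise_sd_marker / 1000
  markers <- list()
  for (lab in rownames(geo$static)) {
    pos <- matrix(geo$static[lab, ], nm, 3, byrow = TRUE)
    markers[[lab]] <- marker_trajectory(lab, pos + stats::rnorm(3 * nm, 0, sdm),
                                        tl$marker_rate)
  }
  for (lab in rownames(geo$head)) {
    v0 <- geo$head[lab, ] - p0
    vx <- v0[1] + ext_m * u0[1]
    vy <- v0[2] + ext_m * u0[2]
    vz <- v0[3] + ext_m * u0[3]
    pos <- cbind(p0[1] + cs * vx - sn * vy,
                 p0[2] + sn * vx + cs * vy,
                 p0[3] + vz)
    markers[[lab]] <- marker_trajectory(lab, pos + stats::rnorm(3 * nm, 0, sdm),
                                        tl$marker_rate)
  }
  og <- operator_geometry()
  dzL <- -tl$thrust_marker_depth * cos_bump(tm, stL$B, stL$C, stL$fall_end)
  dzR <- -tl$thrust_marker_depth * cos_bump(tm, stR$B, stR$C, stR$fall_end)
  for (lab in rownames(og)) {
    pos <- matrix(og[lab, ], nm, 3, byrow = TRUE)
    if (lab == "op_shoulder_peak_right") pos[, 3] <- pos[, 3] + dzL
    if (lab == "op_shoulder_peak_left") pos[, 3] <- pos[, 3] + dzR
    markers[[lab]] <- marker_trajectory(lab, pos + stats::rnorm(3 * nm, 0, sdm),
                                        tl$marker_rate)
  }

  tr <- align_clocks(trial(markers, plates,
                           meta = list(side = "both", seed = params$seed)))
  truth <- list(
    left = list(A = stL$A, B = stL$B, C = stL$C, D = stL$D,
                stretch_loaded = params$stretch_loaded[1],
                trigger_loaded = params$trigger_loaded[1],
                extension = params$extension[1]),
    right = list(A = stR$A, B = stR$B, C = stR$C, D = stR$D,
                 stretch_loaded = params$stretch_loaded[2],
                 trigger_loaded = params$trigger_loaded[2],
                 extension = params$extension[2]),
    trigger_time = Td,
    rot_pre = params$rot_pre, rot_post = params$rot_post,
    baseline1 = params$baseline1, baseline2 = params$baseline2,
    artifact_time = if (has_art) params$artifact_time else NA_real_,
    artifact_peak2 = if (has_art) params$artifact_peak2 else NA_real_,
    artifact_window = if (has_art) aw else NULL,
    base_distance_m = base_dist,
    params = params)
  list(trial = tr, truth = truth)
}

#' Cohort simulation configuration
#'
#' Per-parameter truncated-normal (at zero) distributions; defaults are the
#' reported cohort statistics: triggering 476.75 +/- 33.11 N, stretching
#' 274.79 +/- 52.08 N (pooled left/right), trigger time 0.35 +/- 0.03 s,
#' extension 4.39 +/- 1.02 mm, rotation 68.6 +/- 2.37 deg pre and
#' 73.7 +/- 1.34 deg post, n = 10 subjects.
#'
#' @param n_subjects number of subjects (default 10).
#' @param dists named list of c(mean, sd) pairs overriding defaults; names
#'   as in [subject_params()].
#' @param master_seed integer master seed; per-subject seeds derive from it.
#' @param noise_sd_marker,noise_sd_force noise levels passed through.
#' @param timeline timeline overrides passed to [subject_params()].
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 10, dists = list(), master_seed = 42,
                          noise_sd_marker = 0.5, noise_sd_force = 2,
                          timeline = list()) {
  d <- utils::modifyList(list(
    trigger_loaded = c(476.75, 33.11),
    stretch_loaded = c(274.79, 52.08),
    trigger_duration = c(0.35, 0.03),
    extension = c(4.39, 1.02),
    rot_pre = c(68.6, 2.37),
    rot_post = c(73.7, 1.34),
    baseline1 = c(50, 5),
    baseline2 = c(350, 30),
    artifact_peak2 = c(514.1, 20)), dists)
  structure(list(n_subjects = n_subjects, dists = d,
                 master_seed = as.integer(master_seed),
                 noise_sd_marker = noise_sd_marker,
                 noise_sd_force = noise_sd_force,
                 timeline = timeline),
            class = "cohort_config")
}

rtruncnorm0 <- function(n, mean, sd) {
  v <- stats::rnorm(n, mean, sd)
  while (any(v <= 0)) v[v <= 0] <- stats::rnorm(sum(v <= 0), mean, sd)
  v
}

#' Draw per-subject ground-truth parameters
#'
#' The sampling layer of [simulate_cohort()], exposed so statistical
#' calibration can run on realized parameter draws directly. Loaded forces
#' and extension get independent left/right draws from the same (pooled)
#' distribution; each subject's seed derives deterministically from the
#' master seed.
#'
#' @param config a [cohort_config()].
#' @return list of [subject_params()], length `n_subjects`, with the
#'   realized draws recorded in attribute "draws" (a data.frame).
#' @export
draw_cohort_params <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  d <- config$dists
  out <- vector("list", config$n_subjects)
  rows <- list()
  for (i in seq_len(config$n_subjects)) {
    seed_i <- (config$master_seed %% 1000000L) * 1000L + i
    set.seed(seed_i)
    draw2 <- function(nm) rtruncnorm0(2, d[[nm]][1], d[[nm]][2])
    draw1 <- function(nm) rtruncnorm0(1, d[[nm]][1], d[[nm]][2])
    trig <- draw2("trigger_loaded")
    str <- draw2("stretch_loaded")
    # stretch level must stay below the trigger peak for a valid event shape
    str <- pmin(str, 0.9 * trig)
    td <- draw1("trigger_duration")
    ext <- draw2("extension")
    rpre <- draw1("rot_pre")
    rpost <- max(draw1("rot_post"), rpre + 0.5)
    out[[i]] <- subject_params(
      trigger_loaded = trig, stretch_loaded = str, trigger_duration = td,
      extension = ext, rot_pre = rpre, rot_post = rpost,
      baseline1 = draw1("baseline1"), baseline2 = draw1("baseline2"),
      artifact_peak2 = draw1("artifact_peak2"),
      noise_sd_marker = config$noise_sd_marker,
      noise_sd_force = config$noise_sd_force,
      seed = seed_i, timeline = config$timeline)
    rows[[i]] <- data.frame(
      subject = i, seed = seed_i,
      trigger_loaded_left = trig[1], trigger_loaded_right = trig[2],
      stretch_loaded_left = str[1], stretch_loaded_right = str[2],
      trigger_duration = td,
      extension_left = ext[1], extension_right = ext[2],
      rot_pre = rpre, rot_post = rpost)
  }
  attr(out, "draws") <- do.call(rbind, rows)
  out
}

#' Simulate a cohort of trials
#'
#' @param config a [cohort_config()].
#' @return list with `trials` (list of simulate_trial results) and `draws`
#'   (data.frame of realized per-subject parameters).
#' @export
simulate_cohort <- function(config) {
  ps <- draw_cohort_params(config)
  list(trials = lapply(ps, simulate_trial), draws = attr(ps, "draws"))
}
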