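#' Laboratory frame convention
#'
#' The shared axis convention for markers and force plates: X is the frontal
#' axis (subject left negative, right positive), Y the sagittal axis (back
#' negative, front positive), Z the vertical axis (up positive). Positions in
#' metres, forces in newtons, time in seconds from trial start.
#'
#' @return a `lab_frame` object.
#' @export
lab_frame <- function() {
  structure(
    list(axes = c(X = "frontal (left-/right+)",
                  Y = "sagittal (back-/front+)",
                  Z = "vertical (down-/up+)"),
         units = c(position = "m", force = "N", time = "s")),
    class = "lab_frame")
}

#' Marker trajectory
#'
#' @param label marker name (canonical vocabulary, see [marker_vocabulary()]).
#' @param positions n x 3 numeric matrix of positions (m), columns X,Y,Z.
#' @param rate sampling rate (Hz).
#' @param occluded logical vector, length n; TRUE where the marker was lost.
#' @return a `marker_trajectory` object.
#' @export
marker_trajectory <- function(label, positions, rate, occluded = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, rate > 0)
  n <- nrow(positions)
  if (is.null(occluded)) occluded <- rep(FALSE, n)
  stopifnot(length(occluded) == n)
  if (any(!is.finite(positions[!occluded, , drop = FALSE]))) {
    stop("non-finite position in non-occluded frames of marker '", label, "'",
         call. = FALSE)
  }
  structure(list(label = label, positions = positions, rate = rate,
                 occluded = as.logical(occluded)),
            class = "marker_trajectory")
}

#' Force-plate channel
#'
#' @param plate_id 1 or 2 (plate 1 under the head / active hand, plate 2
#'   under the chest / auxiliary hand).
#' @param fx,fy,fz per-sample force components (N), equal lengths.
#' @param rate sampling rate (Hz).
#' @return a `force_channel` object.
#' @export
force_channel <- function(plate_id, fx, fy, fz, rate) {
  stopifnot(plate_id %in% c(1L, 2L), rate > 0,
            length(fx) == length(fy), length(fy) == length(fz))
  structure(list(plate_id = as.integer(plate_id),
                 fx = as.numeric(fx), fy = as.numeric(fy),
                 fz = as.numeric(fz), rate = rate),
            class = "force_channel")
}

#' Manipulation trial
#'
#' One synchronized recording: marker trajectories plus two force plates on a
#' common clock (time zero at trial start for both streams unless a trigger
#' offset is declared through [align_clocks()]).
#'
#' @param markers named list of [marker_trajectory()] objects.
#' @param plates list of two [force_channel()] objects (plate ids 1 and 2).
#' @param meta list; recognized fields: `subject_id`, `side`
#'   ("left_rotation"/"right_rotation"/"both"), `notes`, `force_offset`
#'   (seconds the force clock starts after the marker clock).
#' @return a `trial` object.
#' @export
trial <- function(markers, plates, meta = list()) {
  stopifnot(is.list(markers), length(plates) == 2)
  labs <- vapply(markers, function(m) m$label, character(1))
  names(markers) <- labs
  ids <- vapply(plates, function(p) p$plate_id, integer(1))
  stopifnot(setequal(ids, c(1L, 2L)))
  plates <- plates[order(ids)]
  if (is.null(meta$force_offset)) meta$force_offset <- 0
  structure(list(markers = markers, plates = plates,
                 frame = lab_frame(), meta = meta),
            class = "trial")
}

#' @export
print.trial <- function(x, ...) {
  nm <- length(x$markers)
  nf <- if (nm > 0) nrow(x$markers[[1]]$positions) else 0
  cat("<trial>", nm, "markers x", nf, "frames @",
      if (nm > 0) x$markers[[1]]$rate else NA, "Hz;",
      "2 plates x", length(x$plates[[1]]$fz), "samples @",
      x$plates[[1]]$rate, "Hz\n")
  if (!is.null(x$meta$subject_id)) cat("  subject:", x$meta$subject_id, "\n")
  if (!is.null(x$meta$side)) cat("  side:", x$meta$side, "\n")
  invisible(x)
}

#' Canonical marker vocabulary
#'
#' Subject (20 markers) and operator (24 markers, `op_` prefix) label sets.
#' Tracking-only points carry no anatomical meaning beyond rigid-body support.
#'
#' @return named list with `subject` and `operator` character vectors.
#' @export
marker_vocabulary <- function() {
  list(
    subject = c(
      "head_crown", "temporal_left", "temporal_right", "occipital_bulge",
      "mastoid_left", "mastoid_right", "c5_spinous",
      "shoulder_peak_left", "shoulder_peak_right",
      "subscapular_left", "subscapular_right", "t10_spinous",
      "humerus_med_epi_left", "humerus_med_epi_right",
      "humerus_lat_epi_left", "humerus_lat_epi_right",
      "forearm_mid_left", "forearm_mid_right",
      "psis_left", "psis_right"),
    operator = c(
      "op_c7_spinous", "op_sternum",
      "op_shoulder_peak_left", "op_shoulder_peak_right",
      "op_subscapular_left", "op_subscapular_right",
      "op_humerus_med_epi_left", "op_humerus_med_epi_right",
      "op_humerus_lat_epi_left", "op_humerus_lat_epi_right",
      "op_radius_styloid_left", "op_radius_styloid_right",
      "op_ulna_styloid_left", "op_ulna_styloid_right",
      "op_mcp3_left", "op_mcp3_right",
      "op_palm_heel_left_1", "op_palm_heel_left_2",
      "op_palm_heel_right_1", "op_palm_heel_right_2",
      "op_upperarm_track_left", "op_upperarm_track_right",
      "op_forearm_track_left", "op_forearm_track_right"))
}

#' Fetch a marker or fail with its name
#'
#' @param trial a [trial()].
#' @param label canonical marker label.
#' @return the [marker_trajectory()].
#' @export
get_marker <- function(trial, label) {
  m <- trial$markers[[label]]
  if (is.null(m)) {
    stop("missing required marker '", label, "'; trial has: ",
         paste(names(trial$markers), collapse = ", "), call. = FALSE)
  }
  m
}

marker_times <- function(trial) {
  n <- nrow(trial$markers[[1]]$positions)
  (seq_len(n) - 1) / trial$markers[[1]]$rate
}

# force sample times on the marker clock: a positive force_offset means the
# force recording started that many seconds before marker time zero
force_times <- function(trial, plate = 1) {
  n <- length(trial$plates[[plate]]$fz)
  (seq_len(n) - 1) / trial$plates[[plate]]$rate - trial$meta$force_offset
}

#' Align marker and force clocks
#'
#' Establishes the common time base. Raw samples are never modified: the
#' alignment is a pure relabeling through per-stream index-to-seconds maps
#' (`marker_times()` / `force_times()`); downstream analyses query by time.
#' If the two streams' durations differ by more than 10% a warning is issued
#' and analyses use the overlap window.
#'
#' @param trial a [trial()].
#' @param force_offset seconds the force recording started before marker
#'   frame 0 (a declared trigger offset); 0 means simultaneous start.
#' @return the trial with alignment metadata set.
#' @export
align_clocks <- function(trial, force_offset = trial$meta$force_offset) {
  trial$meta$force_offset <- force_offset
  dm <- nrow(trial$markers[[1]]$positions) / trial$markers[[1]]$rate
  df <- length(trial$plates[[1]]$fz) / trial$plates[[1]]$rate
  if (abs(dm - df) > 0.1 * max(dm, df)) {
    warning(sprintf(paste0("marker (%.2f s) and force (%.2f s) durations ",
                           "differ by >10%%; truncating analyses to overlap"),
                    dm, df), call. = FALSE)
  }
  trial$meta$overlap <- c(max(0, -force_offset), min(dm, df - force_offset))
  trial
}

#' Low-pass filter all marker trajectories of a trial
#'
#' Fills short occlusion gaps ([fill_gaps()]) then zero-phase low-pass
#' filters each coordinate. Markers still carrying long occlusions are left
#' unfiltered (filtering across a gap would smear invalid samples) and a
#' warning names them.
#'
#' @param trial a [trial()].
#' @param cutoff marker low-pass cutoff in Hz (default 10).
#' @param order filter order (default 4).
#' @param max_gap longest occlusion gap (frames) to interpolate first.
#' @return the trial with filtered marker positions.
#' @export
filter_trial_markers <- function(trial, cutoff = 10, order = 4,
                                 max_gap = 10) {
  skipped <- character(0)
  for (lab in names(trial$markers)) {
    m <- fill_gaps(trial$markers[[lab]], max_gap)
    if (any(m$occluded)) {
      skipped <- c(skipped, lab)
    } else {
      for (j in 1:3) {
        m$positions[, j] <- lowpass_filter(m$positions[, j], cutoff,
                                           m$rate, order)
      }
    }
    trial$markers[[lab]] <- m
  }
  if (length(skipped) > 0) {
    warning("left unfiltered (long occlusions): ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  trial
}

#' Fill short marker occlusions
#'
#' Gaps of at most `max_gap` frames are filled by cubic-spline interpolation
#' per coordinate and unmasked; longer gaps are left occluded so that any
#' metric over them fails loudly.
#'
#' @param m a [marker_trajectory()].
#' @param max_gap longest gap (frames) to interpolate; default 10.
#' @return the trajectory with short gaps filled.
#' @export
fill_gaps <- function(m, max_gap = 10) {
  occ <- m$occluded
  if (!any(occ)) return(m)
  r <- rle(occ)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  good <- which(!occ)
  if (length(good) < 4) return(m)
  for (k in which(r$values)) {
    len <- r$lengths[k]
    idx <- starts[k]:ends[k]
    interior <- starts[k] > 1 && ends[k] < length(occ)
    if (len <= max_gap && interior) {
      for (j in 1:3) {
        m$positions[idx, j] <- stats::spline(good, m$positions[good, j],
                                             xout = idx, method = "natural")$y
      }
      m$occluded[idx] <- FALSE
    }
  }
  m
}
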