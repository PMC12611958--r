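# Vertical-GRF phase analysis: the manipulation event is segmented by four
# turning points A (stretch onset), B (end of stretch / thrust onset, the
# last pre-thrust local minimum), C (thrust force peak) and D (return to
# baseline), giving the stretching (A-B), triggering (B-C) and return (C-D)
# phases. "Loaded" forces are peak minus the pre-manipulation baseline
# attributable to resting segment weight.

#' Vertical ground-reaction-force series
#'
#' Extracts, sign-normalizes (pressing harder on the plate increases the
#' value) and zero-phase low-pass filters the Fz channel.
#'
#' @param channel a [force_channel()].
#' @param cutoff low-pass cutoff in Hz (default 50).
#' @param order filter order (default 4).
#' @param flip set TRUE if the plate reports compression as negative Fz.
#' @return a `grf_series`: list(times, values (N), rate, plate_id).
#' @export
vertical_grf <- function(channel, cutoff = 50, order = 4, flip = FALSE) {
  v <- if (flip) -channel$fz else channel$fz
  v <- lowpass_filter(v, cutoff, channel$rate, order)
  structure(list(times = (seq_along(v) - 1) / channel$rate, values = v,
                 rate = channel$rate, plate_id = channel$plate_id),
            class = "grf_series")
}

#' Combined (resultant) force magnitude
#'
#' Per-sample Euclidean norm sqrt(Fx^2 + Fy^2 + Fz^2); diagnostic used to
#' confirm the active hand's plate shows the larger excursion.
#'
#' @param channel a [force_channel()].
#' @return a `grf_series` of the resultant magnitude.
#' @export
combined_force <- function(channel) {
  v <- sqrt(channel$fx^2 + channel$fy^2 + channel$fz^2)
  structure(list(times = (seq_along(v) - 1) / channel$rate, values = v,
                 rate = channel$rate, plate_id = channel$plate_id),
            class = "grf_series")
}

grf_window <- function(series, window) {
  sel <- series$times >= window[1] & series$times <= window[2]
  if (!any(sel)) stop("empty window [", window[1], ", ", window[2], "] s",
                      call. = FALSE)
  sel
}

#' Baseline (initial force value) estimate
#'
#' Median of the vertical GRF over a quiet pre-manipulation window. The
#' baseline reflects resting head/chest weight and differs between subjects.
#'
#' @param fz a `grf_series` from [vertical_grf()].
#' @param pre_window c(start, end) seconds, at least 0.25 s long, preceding
#'   the manipulation onset.
#' @param quiet_sd warn if the window's SD exceeds this (N; default 5).
#' @return list(value (N), window, sd).
#' @export
estimate_baseline <- function(fz, pre_window, quiet_sd = 5) {
  if (diff(pre_window) < 0.25) {
    stop("baseline window must span at least 0.25 s", call. = FALSE)
  }
  sel <- grf_window(fz, pre_window)
  v <- fz$values[sel]
  s <- stats::sd(v)
  if (s > quiet_sd) {
    warning(sprintf("baseline window not quiet (SD %.1f N > %.1f N)", s,
                    quiet_sd), call. = FALSE)
  }
  list(value = stats::median(v), window = pre_window, sd = s)
}

# first index of a run of at least len samples satisfying cond, NA if none
first_sustained <- function(cond, len) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= len)
  if (length(hit) == 0) return(NA_integer_)
  ends[hit[1]] - r$lengths[hit[1]] + 1L
}

#' Segment the manipulation event into phases
#'
#' Locates the four turning points on a vertical-GRF series containing one
#' dominant thrust peak. A: first sustained rise above
#' `baseline + max(onset_min_n, onset_frac * amplitude)`, refined backward
#' along the rising flank to the baseline plateau. C: global maximum
#' (earliest sample on exact ties, logged). B: the last local minimum in
#' (A, C) before the final monotone rise to C (`b_rule = "local_min"`,
#' default), or the last non-positive-to-positive crossing of dF/dt
#' (`b_rule = "dfdt"`). D: first sustained return within the onset threshold
#' of baseline after C, refined forward along the falling flank.
#'
#' @param fz a `grf_series`.
#' @param baseline result of [estimate_baseline()] (or a number).
#' @param window optional c(start, end) seconds restricting the search.
#' @param onset_min_n absolute onset threshold floor in N (default 10).
#' @param onset_frac onset threshold as a fraction of event amplitude
#'   (default 0.05).
#' @param sustain_s minimum time above/below threshold (default 0.05 s).
#' @param min_event_n smallest peak-above-baseline accepted as an event
#'   (default 50 N).
#' @param b_rule "local_min" or "dfdt".
#' @return a `phase_points` list: A, B, C, D (seconds), plus the threshold
#'   used.
#' @export
segment_phases <- function(fz, baseline, window = NULL,
                           onset_min_n = 10, onset_frac = 0.05,
                           sustain_s = 0.05, min_event_n = 50,
                           b_rule = c("local_min", "dfdt")) {
  b_rule <- match.arg(b_rule)
  base <- if (is.list(baseline)) baseline$value else baseline
  sel <- if (is.null(window)) rep(TRUE, length(fz$values)) else
    grf_window(fz, window)
  idx <- which(sel)
  v <- fz$values[idx]
  tt <- fz$times[idx]
  amp <- max(v) - base
  if (amp < min_event_n) {
    stop(sprintf("no manipulation event: peak %.1f N above baseline < %.0f N",
                 amp, min_event_n), call. = FALSE)
  }
  thr <- max(onset_min_n, onset_frac * amp)
  nsus <- max(1L, round(sustain_s * fz$rate))

  iC <- which.max(v)  # earliest maximal sample on ties (which.max contract)

  iA <- first_sustained(v > base + thr, nsus)
  if (is.na(iA) || iA > iC) {
    stop("could not locate sustained onset before the peak", call. = FALSE)
  }
  while (iA > 1 && v[iA - 1] < v[iA]) iA <- iA - 1L  # walk down the flank

  if (b_rule == "local_min") {
    # walk back from the peak on a heavily smoothed copy (noise wiggles on
    # the steep thrust rise would stop the walk prematurely), then refine to
    # the true local minimum nearby on the analysis series
    vs <- tryCatch(lowpass_filter(v, min(10, fz$rate / 4), fz$rate),
                   error = function(e) v)
    iB <- which.max(vs)  # smoothed peak, may sit a few ms off argmax(v)
    while (iB > iA + 1 && vs[iB - 1] <= vs[iB]) iB <- iB - 1L
    nb <- round(0.025 * fz$rate)
    nb_win <- max(iA + 1, iB - nb):min(iC, iB + nb)
    iB <- nb_win[which.min(v[nb_win])]
  } else {
    dv <- diff(v[1:iC])
    cross <- which(dv[-1] > 0 & dv[-length(dv)] <= 0) + 1L
    cross <- cross[cross > iA]
    iB <- if (length(cross) > 0) cross[length(cross)] else iA
  }
  if (iB <= iA) {
    stop("no pre-thrust turning point found between onset and peak",
         call. = FALSE)
  }

  after <- v[iC:length(v)]
  iDrel <- first_sustained(after < base + thr, nsus)
  if (is.na(iDrel)) {
    stop("signal never returns to baseline after the peak", call. = FALSE)
  }
  iD <- iC + iDrel - 1L
  while (iD < length(v) && v[iD + 1] < v[iD]) iD <- iD + 1L

  pts <- list(A = tt[iA], B = tt[iB], C = tt[iC], D = tt[iD],
              threshold = thr)
  if (!(pts$A < pts$B && pts$B < pts$C && pts$C < pts$D)) {
    stop(sprintf("phase ordering violated: A=%.3f B=%.3f C=%.3f D=%.3f",
                 pts$A, pts$B, pts$C, pts$D), call. = FALSE)
  }
  structure(pts, class = "phase_points")
}

#' Loaded-force metrics from phase points
#'
#' Loaded force = raw force peak minus the initial (baseline) force value.
#' `stretch_loaded_max` is the maximum over the stretching phase A-B;
#' `trigger_loaded_max` is the value at the thrust peak C.
#'
#' @param fz a `grf_series`.
#' @param points a `phase_points` from [segment_phases()].
#' @param baseline result of [estimate_baseline()] (or a number).
#' @return a `phase_metrics` list: baseline, stretch_loaded_max,
#'   trigger_loaded_max (N), phase_durations (stretch, trigger, return; s).
#' @export
loaded_forces <- function(fz, points, baseline) {
  base <- if (is.list(baseline)) baseline$value else baseline
  selAB <- fz$times >= points$A & fz$times <= points$B
  stretch <- max(fz$values[selAB]) - base
  trig <- fz$values[which.min(abs(fz$times - points$C))] - base
  if (stretch < 0 || trig < 0) {
    stop(sprintf(paste0("negative loaded force (stretch %.1f, trigger %.1f N)",
                        ": baseline above peak suggests mis-segmentation"),
                 stretch, trig), call. = FALSE)
  }
  structure(list(baseline = base,
                 stretch_loaded_max = stretch,
                 trigger_loaded_max = trig,
                 phase_durations = c(stretch = points$B - points$A,
                                     trigger = points$C - points$B,
                                     return = points$D - points$C)),
            class = "phase_metrics")
}

#' Detect the mid-trial position-change artifact
#'
#' Between the left- and right-rotation manoeuvres the subject lifts and
#' turns the head: plate 1 (head) shows a trough below its baseline while
#' plate 2 (chest) shows a coincident peak above its baseline. Both
#' excursions must occur within `coincide_s` of each other; the window is
#' then excluded from phase analysis.
#'
#' @param plate1_fz,plate2_fz `grf_series` on a common clock.
#' @param base1,base2 per-plate baselines (N); if NULL, the median of the
#'   first 0.5 s.
#' @param drop_threshold plate-1 must fall below `base1 - drop_threshold`
#'   (default 20 N).
#' @param rise_threshold plate-2 must rise above `base2 + rise_threshold`
#'   (default 50 N).
#' @param coincide_s maximum separation between the trough and the peak
#'   (default 0.5 s).
#' @param search optional c(start, end) window to search (seconds).
#' @return an `artifact_event` list(time, plate1_trough, plate2_peak,
#'   window) or NULL if no coincident trough/peak exists.
#' @export
detect_position_change <- function(plate1_fz, plate2_fz,
                                   base1 = NULL, base2 = NULL,
                                   drop_threshold = 20, rise_threshold = 50,
                                   coincide_s = 0.5, search = NULL) {
  if (is.null(base1)) {
    base1 <- stats::median(plate1_fz$values[plate1_fz$times <= 0.5])
  }
  if (is.null(base2)) {
    base2 <- stats::median(plate2_fz$values[plate2_fz$times <= 0.5])
  }
  sel <- if (is.null(search)) rep(TRUE, length(plate2_fz$values)) else
    grf_window(plate2_fz, search)
  high2 <- plate2_fz$values > base2 + rise_threshold & sel
  if (!any(high2)) return(NULL)
  r <- rle(high2)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    seg <- starts[k]:ends[k]
    ipk <- seg[which.max(plate2_fz$values[seg])]
    tpk <- plate2_fz$times[ipk]
    near1 <- plate1_fz$times >= tpk - coincide_s &
      plate1_fz$times <= tpk + coincide_s
    if (!any(near1)) next
    trough <- min(plate1_fz$values[near1])
    if (trough < base1 - drop_threshold) {
      pad <- 0.1
      return(structure(
        list(time = tpk,
             plate1_trough = trough,
             plate2_peak = plate2_fz$values[ipk],
             window = c(plate2_fz$times[seg[1]] - pad,
                        plate2_fz$times[seg[length(seg)]] + pad)),
        class = "artifact_event"))
    }
  }
  NULL
}
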