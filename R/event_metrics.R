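# Marker-derived headline metrics. Trigger time is the interval from the
# active acromion's movement onset (point I) to its peak vertical
# displacement (point II) during the thrust; neck extension is the increase
# of the head-vertex-to-mid-shoulder distance during stretching.

#' Operator trigger time from acromion vertical displacement
#'
#' Point II is the extremum of largest absolute vertical excursion inside
#' `thrust_window`; point I is the movement onset: searching backward from
#' the peak-speed instant, the last sustained (>= `sustain_s`) time at which
#' |velocity| stays below `onset_frac` of the peak speed, refined backward
#' along strictly decreasing |velocity| until it falls under `floor_frac`
#' of the peak speed (below that, motion has ceased and further backtracking
#' would chase filter ripple or noise). The trigger time is t(II) - t(I).
#'
#' @param z vertical displacement (m), uniformly sampled.
#' @param rate sampling rate (Hz).
#' @param thrust_window c(start, end) seconds (times measured from the
#'   signal's own clock, sample 1 at t = 0) containing one thrust.
#' @param onset_frac velocity threshold as fraction of peak speed
#'   (default 0.05).
#' @param sustain_s sustained-quiet requirement (default 0.025 s).
#' @param floor_frac backtracking stops once |velocity| drops below this
#'   fraction of peak speed (default 0.01).
#' @param cutoff displacement low-pass cutoff in Hz before differentiation
#'   (default 10); NULL skips filtering.
#' @param min_excursion smallest peak excursion treated as a thrust
#'   (default 0.005 m).
#' @return trigger time in seconds, with attributes `t_onset`, `t_peak`.
#' @export
trigger_time <- function(z, rate, thrust_window, onset_frac = 0.05,
                         sustain_s = 0.025, floor_frac = 0.01, cutoff = 10,
                         min_excursion = 0.005) {
  if (!is.null(cutoff)) z <- lowpass_filter(z, cutoff, rate)
  tt <- (seq_along(z) - 1) / rate
  sel <- which(tt >= thrust_window[1] & tt <= thrust_window[2])
  if (length(sel) < 5) stop("thrust window too short", call. = FALSE)
  zs <- z[sel]
  exc <- zs - zs[1]
  if (max(abs(exc)) < min_excursion) {
    stop(sprintf("no thrust: peak excursion %.2f mm below noise floor",
                 1000 * max(abs(exc))), call. = FALSE)
  }
  i2 <- which.max(abs(exc))
  n <- length(zs)
  hi <- pmin(n, seq_len(n) + 1L); lo <- pmax(1L, seq_len(n) - 1L)
  v <- (zs[hi] - zs[lo]) / ((hi - lo) / rate)  # central difference
  ipkv <- which.max(abs(v[1:i2]))
  thr <- onset_frac * abs(v[ipkv])
  nsus <- max(1L, round(sustain_s * rate))
  quiet <- abs(v[1:ipkv]) < thr
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= nsus)
  i1 <- if (length(ok) > 0) ends[ok[length(ok)]] else 1L
  floor_v <- floor_frac * abs(v[ipkv])
  while (i1 > 1 && abs(v[i1 - 1]) < abs(v[i1]) &&
         abs(v[i1 - 1]) >= floor_v) i1 <- i1 - 1L
  structure(tt[sel[i2]] - tt[sel[i1]],
            t_onset = tt[sel[i1]], t_peak = tt[sel[i2]])
}

#' Neck extension (retraction) amplitude
#'
#' Maximum head-vertex-to-mid-shoulder distance over the stretch window
#' minus the mean distance over the baseline window, in millimetres. Being a
#' distance, the metric is invariant under any common rigid transform of all
#' markers.
#'
#' @param head_vertex,mid_shoulder `virtual_point` objects from
#'   [virtual_points()].
#' @param rate marker rate (Hz).
#' @param baseline_window,stretch_window c(start, end) seconds.
#' @return amplitude in mm (negative with a warning if the stretch maximum
#'   falls below baseline, flagging mis-windowing).
#' @export
extension_amplitude <- function(head_vertex, mid_shoulder, rate,
                                baseline_window, stretch_window) {
  d <- sqrt(rowSums((head_vertex$positions - mid_shoulder$positions)^2))
  masked <- head_vertex$masked | mid_shoulder$masked
  tt <- (seq_along(d) - 1) / rate
  pick <- function(w) {
    s <- tt >= w[1] & tt <= w[2] & !masked
    if (!any(s)) stop("window [", w[1], ", ", w[2],
                      "] s fully masked or empty", call. = FALSE)
    d[s]
  }
  amp <- 1000 * (max(pick(stretch_window)) - mean(pick(baseline_window)))
  if (amp < 0) {
    warning(sprintf("extension amplitude negative (%.2f mm): check windows",
                    amp), call. = FALSE)
  }
  amp
}
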