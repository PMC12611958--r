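# Piecewise-linear toy from the segmentation contract: baseline 80 N, ramp
# to 350 N over [1,3] s, dip to 330 N at 3.1 s, spike to 630 N at 3.3 s,
# return to 80 N by 4.0 s.
toy_series <- function(rate = 1000, filtered = TRUE) {
  tt <- seq(0, 5, by = 1 / rate)
  v <- approx(x = c(0, 1, 3, 3.1, 3.3, 4.0, 5),
              y = c(80, 80, 350, 330, 630, 80, 80), xout = tt)$y
  if (filtered) v <- lowpass_filter(v, 50, rate)
  structure(list(times = tt, values = v, rate = rate, plate_id = 1L),
            class = "grf_series")
}

test_that("vertical_grf preserves constants and selects the Z axis", {
  ch <- force_channel(1, fx = rep(30, 600), fy = rep(-40, 600),
                      fz = rep(80, 600), rate = 1000)
  g <- vertical_grf(ch)
  expect_equal(g$values, rep(80, 600), tolerance = 1e-9)
  ch0 <- force_channel(1, fx = rnorm(600), fy = rnorm(600),
                       fz = rep(0, 600), rate = 1000)
  expect_lt(max(abs(vertical_grf(ch0)$values)), 1e-9)
  # raw Kistler sign convention handled by flip
  chn <- force_channel(1, 0 * 1:600, 0 * 1:600, rep(-80, 600), 1000)
  expect_equal(vertical_grf(chn, flip = TRUE)$values, rep(80, 600),
               tolerance = 1e-9)
})

test_that("combined_force is the Euclidean norm", {
  ch <- force_channel(1, fx = c(3, 0), fy = c(4, 0), fz = c(0, -120), 1000)
  expect_equal(combined_force(ch)$values, c(5, 120))
})

test_that("plate 1 combined-force range exceeds plate 2's on generator trials", {
  st <- quiet_trial(seed = 6)
  r1 <- diff(range(combined_force(st$trial$plates[[1]])$values))
  r2 <- diff(range(combined_force(st$trial$plates[[2]])$values))
  expect_gt(r1, r2)
})

test_that("baseline is a robust median", {
  g <- toy_series()
  b <- estimate_baseline(g, c(0.2, 0.8))
  expect_equal(b$value, 80, tolerance = 0.01)
  # one 500 N spike sample does not move the median
  g2 <- toy_series(filtered = FALSE)
  g2$values[500] <- 500
  expect_warning(b2 <- estimate_baseline(g2, c(0.2, 0.8)), "not quiet")
  expect_equal(b2$value, 80)
  expect_error(estimate_baseline(g, c(0.2, 0.3)), "0.25 s")
  # generator baseline recovered within 0.5 N
  st <- quiet_trial(seed = 6)
  fz1 <- vertical_grf(st$trial$plates[[1]])
  expect_lt(abs(estimate_baseline(fz1, c(0.2, 0.9))$value - 50), 0.5)
})

test_that("segmentation matches the exhaustive scan on the toy", {
  g <- toy_series()
  base <- estimate_baseline(g, c(0.2, 0.8))
  pts <- segment_phases(g, base)
  raw <- toy_series(filtered = FALSE)
  oracle <- scan_phases(raw$values, raw$times, 80,
                        max(10, 0.05 * (630 - 80)))
  # each point within one filter transient (~30 ms at 50 Hz) of the oracle
  expect_lt(abs(pts$A - oracle["A"]), 0.03)
  expect_lt(abs(pts$B - oracle["B"]), 0.03)
  expect_lt(abs(pts$C - oracle["C"]), 0.03)
  expect_lt(abs(pts$D - oracle["D"]), 0.03)
  expect_true(pts$A < pts$B && pts$B < pts$C && pts$C < pts$D)
})

test_that("flat signal yields a no-event error", {
  g <- structure(list(times = seq(0, 3, 1e-3),
                      values = rep(80, 3001) + rnorm(3001, 0, 0.5),
                      rate = 1000, plate_id = 1L), class = "grf_series")
  expect_error(segment_phases(g, 80), "no manipulation event")
})

test_that("loaded forces follow the peak-minus-baseline definition", {
  g <- toy_series()
  base <- estimate_baseline(g, c(0.2, 0.8))
  pts <- segment_phases(g, base)
  lf <- loaded_forces(g, pts, base)
  expect_equal(lf$stretch_loaded_max, 270, tolerance = 0.02)
  expect_equal(lf$trigger_loaded_max, 550, tolerance = 0.02)
  # zero baseline: loaded values equal raw maxima
  lf0 <- loaded_forces(g, pts, 0)
  expect_equal(lf0$trigger_loaded_max, 630, tolerance = 0.2)
  # baseline above peak flags mis-segmentation
  expect_error(loaded_forces(g, pts, 700), "mis-segmentation")
})

test_that("segmentation is idempotent and equivariant", {
  g <- toy_series()
  base <- estimate_baseline(g, c(0.2, 0.8))
  p1 <- segment_phases(g, base)
  p2 <- segment_phases(g, base)
  expect_identical(p1, p2)
  # amplitude equivariance: scale (fz - baseline) by k
  for (k in c(2, 5)) {
    gk <- g
    gk$values <- 80 + k * (g$values - 80)
    pk <- segment_phases(gk, 80)
    expect_equal(pk$A, p1$A, tolerance = 1e-6)
    expect_equal(pk$B, p1$B, tolerance = 1e-6)
    expect_equal(pk$C, p1$C, tolerance = 1e-6)
    expect_equal(pk$D, p1$D, tolerance = 1e-6)
    lk <- loaded_forces(gk, pk, 80)
    expect_equal(lk$trigger_loaded_max, k * 550, tolerance = k * 0.1)
    expect_equal(lk$stretch_loaded_max, k * 270, tolerance = k * 0.1)
  }
  # time-shift equivariance: delay by 0.5 s shifts every point by 0.5 s
  gs <- g
  gs$times <- g$times + 0.5
  ps <- segment_phases(gs, 80)
  for (pt in c("A", "B", "C", "D")) {
    expect_equal(ps[[pt]], p1[[pt]] + 0.5, tolerance = 1e-9)
  }
})

test_that("noise-free generator phase points are recovered within 0.02 s", {
  st <- quiet_trial(seed = 5)
  m <- analyze_trial(st$trial)
  for (side in c("left", "right")) {
    s <- m$sides[[paste0(side, "_rotation")]]
    tru <- st$truth[[side]]
    for (pt in c("A", "B", "C", "D")) {
      expect_lt(abs(s$phase_points[[pt]] - tru[[pt]]), 0.02)
    }
  }
})

test_that("trigger exceeds stretch whenever the generator says so", {
  # randomized-parameter sign-convention sweep (sampling layer + extraction
  # on a thinned subset to keep runtime in budget)
  set.seed(60)
  cfg <- cohort_config(n_subjects = 4, master_seed = 60,
                       noise_sd_marker = 0, noise_sd_force = 0)
  sim <- simulate_cohort(cfg)
  for (st in sim$trials) {
    fz1 <- vertical_grf(st$trial$plates[[1]])
    fz2 <- vertical_grf(st$trial$plates[[2]])
    art <- detect_position_change(fz1, fz2)
    for (side in c("left", "right")) {
      win <- if (side == "left") c(0, art$window[1]) else
        c(art$window[2], max(fz1$times))
      base <- estimate_baseline(fz1, c(win[1], win[1] + 0.5))
      pts <- segment_phases(fz1, base, window = win)
      lf <- loaded_forces(fz1, pts, base)
      if (st$truth[[side]]$trigger_loaded > st$truth[[side]]$stretch_loaded) {
        expect_gt(lf$trigger_loaded_max, lf$stretch_loaded_max)
      }
    }
  }
})

test_that("position-change artifact detection requires coincidence", {
  st <- quiet_trial(seed = 8)
  fz1 <- vertical_grf(st$trial$plates[[1]])
  fz2 <- vertical_grf(st$trial$plates[[2]])
  ev <- detect_position_change(fz1, fz2)
  expect_false(is.null(ev))
  expect_lt(abs(ev$time - 5.68), 0.05)
  expect_lt(abs(ev$plate2_peak - 514.1), 0.01 * 514.1)
  expect_lt(ev$plate1_trough, 50 - 20)
  # no artifact configured -> none
  st0 <- quiet_trial(artifact_time = NA, seed = 8)
  expect_null(detect_position_change(vertical_grf(st0$trial$plates[[1]]),
                                     vertical_grf(st0$trial$plates[[2]])))
  # plate-2 peak without a plate-1 trough -> none
  fz1_flat <- fz1
  fz1_flat$values <- rep(50, length(fz1$values))
  expect_null(detect_position_change(fz1_flat, fz2))
})
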