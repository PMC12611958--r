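# Small marker bodies used throughout
ref_body <- function(pts = NULL) {
  if (is.null(pts)) {
    pts <- rbind(c(0, 0.1, 0.05), c(-0.07, 0, 0.02), c(0.07, 0, 0.02),
                 c(0, -0.08, 0.08), c(0, 0, -0.05))
  }
  rownames(pts) <- paste0("m", seq_len(nrow(pts)))
  structure(list(name = "test", marker_labels = rownames(pts),
                 reference_shape = sweep(pts, 2, colMeans(pts))),
            class = "rigid_body_def")
}

as_frame <- function(pts) {
  stats::setNames(lapply(seq_len(nrow(pts)), function(i) pts[i, ]),
                  rownames(pts))
}

test_that("identity observation gives identity pose with zero residual", {
  b <- ref_body()
  p <- estimate_pose(b, as_frame(b$reference_shape))
  expect_equal(p$rotation, diag(3), tolerance = 1e-12)
  expect_equal(p$translation, c(0, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(p$residual_rmsd, 1e-12)
})

test_that("a known transform is recovered to numerical precision", {
  b <- ref_body()
  R <- rot_z(30)
  obs <- sweep(b$reference_shape %*% t(R), 2, c(0.1, 0, 0), "+")
  rownames(obs) <- b$marker_labels
  p <- estimate_pose(b, as_frame(obs))
  ang_err <- acos((sum(diag(t(p$rotation) %*% R)) - 1) / 2) * 180 / pi
  expect_lt(ang_err, 1e-9)
  expect_equal(p$translation, c(0.1, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("axial angle noise matches first-order Procrustes theory", {
  # the twist-angle SD of a Kabsch fit under isotropic marker noise sigma is
  # sigma / sqrt(sum of squared in-plane marker radii); the Monte-Carlo 99th
  # percentile must stay within the implied 2.9-sigma envelope (and well
  # above half of it, i.e. the estimator adds no slack of its own)
  set.seed(42)
  hb <- ref_body(rbind(c(0, 0.145, 0.05), c(-0.07, 0.005, 0.04),
                       c(0.07, 0.005, 0.04), c(0, -0.065, 0.08),
                       c(-0.06, -0.045, -0.02), c(0.06, -0.045, -0.02)))
  sigma <- 1e-3
  sd_theory <- sigma / sqrt(sum(hb$reference_shape[, 1]^2 +
                                  hb$reference_shape[, 2]^2)) * 180 / pi
  errs <- replicate(1000, {
    a_true <- runif(1, -90, 90)
    obs <- hb$reference_shape %*% t(rot_z(a_true)) +
      matrix(rnorm(18, 0, sigma), 6, 3)
    rownames(obs) <- hb$marker_labels
    p <- estimate_pose(hb, as_frame(obs))
    thorax <- list(rotation = diag(3), translation = c(0, 0, 0))
    abs(axial_rotation_angle(p, thorax) - a_true)
  })
  q99 <- stats::quantile(errs, 0.99)
  expect_lt(q99, 2.9 * sd_theory)
  expect_gt(q99, 1.5 * sd_theory)
})

test_that("degenerate frames fail with named errors", {
  b <- ref_body()
  expect_error(estimate_pose(b, as_frame(b$reference_shape[1:2, ])),
               "only 2")
  line <- cbind(seq(0, 0.1, length.out = 5), 0, 0)
  rownames(line) <- b$marker_labels
  expect_error(estimate_pose(b, as_frame(line)), "collinear")
})

test_that("Kabsch agrees with a 0.1-degree brute-force rotation search", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    pts <- matrix(runif(n * 3, -0.1, 0.1), n, 3)
    b <- ref_body(pts)
    a_true <- runif(1, -170, 170)
    obs <- b$reference_shape %*% t(rot_z(a_true))
    rownames(obs) <- b$marker_labels
    p <- estimate_pose(b, as_frame(obs))
    a_grid <- grid_fit_z(b$reference_shape, obs, res = 0.1)
    thorax <- list(rotation = diag(3), translation = c(0, 0, 0))
    a_kabsch <- axial_rotation_angle(p, thorax)
    expect_lt(abs(a_kabsch - a_grid), 0.1)
    expect_lt(abs(a_kabsch - a_true), 1e-6)
  }
})

test_that("swing-twist decomposition matches constructions and the oracle", {
  thorax <- list(rotation = diag(3), translation = c(0, 0, 0))
  head_eq <- list(rotation = diag(3), translation = c(0, 0, 0))
  expect_equal(axial_rotation_angle(head_eq, thorax), 0)
  # pure axial rotation at the reported post-manipulation maximum
  head_737 <- list(rotation = rot_z(73.7), translation = c(0, 0, 0))
  expect_equal(axial_rotation_angle(head_737, thorax), 73.7,
               tolerance = 1e-9)
  # 45 deg about Z then 5 deg about X: twist component within 0.2 deg of 45
  head_mix <- list(rotation = rot_x(5) %*% rot_z(45),
                   translation = c(0, 0, 0))
  tw <- axial_rotation_angle(head_mix, thorax)
  expect_lt(abs(tw - 45), 0.2)
  expect_equal(tw, twist_about_z_oracle(head_mix$rotation), tolerance = 1e-9)
})

test_that("relative angle is invariant to a common rigid transform", {
  set.seed(3)
  thorax <- list(rotation = rot_z(12), translation = c(0, 0, 0))
  head <- list(rotation = rot_z(60) %*% rot_x(4), translation = c(0, 0, 0))
  a0 <- axial_rotation_angle(head, thorax)
  for (rep in 1:20) {
    G <- rot_z(runif(1, -180, 180)) %*% rot_x(runif(1, -60, 60)) %*%
      rot_y(runif(1, -60, 60))
    a1 <- axial_rotation_angle(
      list(rotation = G %*% head$rotation, translation = c(0, 0, 0)),
      list(rotation = G %*% thorax$rotation, translation = c(0, 0, 0)))
    expect_lt(abs(a1 - a0), 1e-6)
  }
})

test_that("axial rotations compose additively (mod 360)", {
  thorax <- list(rotation = diag(3), translation = c(0, 0, 0))
  set.seed(4)
  for (rep in 1:20) {
    a <- runif(1, -170, 170); b <- runif(1, -170, 170)
    h <- list(rotation = rot_z(b) %*% rot_z(a), translation = c(0, 0, 0))
    got <- axial_rotation_angle(h, thorax)
    want <- ((a + b + 180) %% 360) - 180
    expect_lt(min(abs(got - want), abs(abs(got - want) - 360)), 1e-6)
  }
})

test_that("residual rmsd is zero noise-free and grows with noise", {
  set.seed(5)
  b <- ref_body()
  obs0 <- b$reference_shape %*% t(rot_z(25))
  rownames(obs0) <- b$marker_labels
  expect_lt(estimate_pose(b, as_frame(obs0))$residual_rmsd, 1e-9)
  med_rmsd <- vapply(c(5e-4, 1e-3, 2e-3), function(s) {
    stats::median(replicate(200, {
      obs <- obs0 + matrix(rnorm(15, 0, s), 5, 3)
      rownames(obs) <- b$marker_labels
      estimate_pose(b, as_frame(obs))$residual_rmsd
    }))
  }, numeric(1))
  expect_true(all(diff(med_rmsd) > 0))
})

test_that("angle series recovers a generator rotation ramp and masks gaps", {
  st <- quiet_trial(rot_pre = 70, seed = 3)
  s <- angle_series(st$trial)
  pre <- s$times < st$truth$left$B
  expect_lt(abs(max(s$axial_angle[pre & !s$masked]) - 70), 0.1)
  # occlude all head markers over frames 100-120: exactly those masked
  tr <- st$trial
  for (lab in head_marker_set()) {
    tr$markers[[lab]]$occluded[100:120] <- TRUE
  }
  expect_warning(s2 <- angle_series(tr), "masked")
  expect_true(all(s2$masked[100:120]))
  expect_false(any(s2$masked[-(100:120)]))
})

test_that("a static trial gives zero angle throughout", {
  st <- quiet_trial(rot_pre = 0, rot_post = 0.001, extension = 0,
                    artifact_time = NA, seed = 2)
  s <- angle_series(st$trial)
  expect_lt(max(abs(s$axial_angle[!s$masked])), 0.01)
})

test_that("max_rotation_angle handles monotone ramps and tiny windows", {
  s <- structure(list(times = seq(0, 1, by = 0.01),
                      axial_angle = seq(0, 50, length.out = 101),
                      masked = rep(FALSE, 101), convention_tag = "twist_z"),
                 class = "angle_series")
  expect_equal(max_rotation_angle(s, c(0, 0.5)), 25)
  expect_equal(max_rotation_angle(s, c(0.5, 0.5)), 25)
  s$masked[] <- TRUE
  expect_error(max_rotation_angle(s, c(0, 1)), "no unmasked")
})

test_that("virtual points: midpoint arithmetic, symmetry, generator truth", {
  nm <- 10
  mk <- list(
    marker_trajectory("shoulder_peak_left",
                      matrix(rep(c(-0.2, 0, 1.4), each = nm), nm), 200),
    marker_trajectory("shoulder_peak_right",
                      matrix(rep(c(0.2, 0, 1.4), each = nm), nm), 200),
    marker_trajectory("head_crown",
                      matrix(rep(c(0, 0.3, 1.5), each = nm), nm), 200))
  pl <- lapply(1:2, function(i) force_channel(i, 0, 0, 0, 1000))
  tr <- trial(mk, pl)
  vp <- virtual_points(tr)
  expect_equal(vp$mid_shoulder$positions[1, ], c(0, 0, 1.4),
               ignore_attr = TRUE)
  # symmetric perturbation leaves the midpoint unchanged
  d <- c(0.01, -0.02, 0.03)
  tr$markers[["shoulder_peak_left"]]$positions <-
    sweep(tr$markers[["shoulder_peak_left"]]$positions, 2, d, "+")
  tr$markers[["shoulder_peak_right"]]$positions <-
    sweep(tr$markers[["shoulder_peak_right"]]$positions, 2, d, "-")
  expect_equal(virtual_points(tr)$mid_shoulder$positions[1, ], c(0, 0, 1.4),
               ignore_attr = TRUE)
  # generator: mid-shoulder equals the internal T1 proxy (pivot) exactly
  st <- quiet_trial(seed = 4)
  vps <- virtual_points(st$trial)
  pivot <- manipkin:::subject_geometry()$pivot
  expect_lt(max(abs(sweep(vps$mid_shoulder$positions, 2, pivot))), 1e-9)
})
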