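#' Rigid-body definition from trial markers
#'
#' Captures a body-fixed reference shape: the marker coordinates averaged
#' over `ref_window` (default the first 0.5 s, when the subject lies still),
#' re-expressed about their centroid. At least three non-collinear markers
#' are required.
#'
#' @param trial a [trial()].
#' @param name body name, e.g. "head" or "thorax".
#' @param marker_labels the body's marker labels.
#' @param ref_window c(start, end) seconds used as the neutral reference.
#' @return a `rigid_body_def` object.
#' @export
rigid_body_def <- function(trial, name, marker_labels,
                           ref_window = c(0, 0.5)) {
  if (length(marker_labels) < 3) {
    stop("rigid body '", name, "' needs >= 3 markers", call. = FALSE)
  }
  t_m <- marker_times(trial)
  sel <- t_m >= ref_window[1] & t_m <= ref_window[2]
  shape <- t(vapply(marker_labels, function(lab) {
    m <- get_marker(trial, lab)
    ok <- sel & !m$occluded
    if (!any(ok)) {
      stop("marker '", lab, "' fully occluded in reference window",
           call. = FALSE)
    }
    colMeans(m$positions[ok, , drop = FALSE])
  }, numeric(3)))
  check_noncollinear(shape, name)
  shape <- sweep(shape, 2, colMeans(shape))
  structure(list(name = name, marker_labels = marker_labels,
                 reference_shape = shape),
            class = "rigid_body_def")
}

check_noncollinear <- function(pts, what) {
  c0 <- sweep(pts, 2, colMeans(pts))
  if (qr(c0)$rank < 2) {
    stop("markers of '", what, "' are collinear (rank-deficient shape)",
         call. = FALSE)
  }
}

#' Least-squares pose of a rigid body (Kabsch / orthogonal Procrustes)
#'
#' Finds the proper rotation R and translation t minimizing
#' sum_i ||R s_i + t - x_i||^2 between the body's reference shape s and the
#' observed markers x, via SVD of the cross-covariance with a reflection
#' guard (det(R) = +1 always).
#'
#' @param body a [rigid_body_def()].
#' @param frame_markers named list/rows of observed 3-vectors for this frame
#'   (named by marker label; may omit occluded markers).
#' @return a `pose`: list(rotation 3x3, translation length-3,
#'   residual_rmsd in metres, n_markers used).
#' @export
estimate_pose <- function(body, frame_markers) {
  have <- intersect(body$marker_labels, names(frame_markers))
  if (length(have) < 3) {
    stop("degenerate frame for body '", body$name, "': only ",
         length(have), " of its markers visible (",
         paste(have, collapse = ", "), ")", call. = FALSE)
  }
  obs <- t(vapply(have, function(l) as.numeric(frame_markers[[l]]),
                  numeric(3)))
  ref <- body$reference_shape[match(have, body$marker_labels), , drop = FALSE]
  check_noncollinear(obs, body$name)
  mu_o <- colMeans(obs); mu_r <- colMeans(ref)
  H <- t(sweep(ref, 2, mu_r)) %*% sweep(obs, 2, mu_o)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- mu_o - as.numeric(R %*% mu_r)
  fit <- sweep(ref %*% t(R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fit - obs)^2)))
  structure(list(rotation = R, translation = tr, residual_rmsd = rmsd,
                 n_markers = length(have)),
            class = "pose")
}

rotmat_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

#' Axial rotation of the head relative to the thorax
#'
#' Decomposes the relative rotation `thorax^-1 o head` and returns its
#' component about the thorax vertical (Z) axis in degrees, positive for
#' left rotation. Default decomposition is the swing-twist split about Z
#' (`"twist_z"`); a Cardan X-Y-Z sequence (`"cardan_xyz"`, Z angle reported)
#' is available for comparison with Euler-based pipelines. Near the Cardan
#' gimbal lock (|Y| within 1 degree of 90) the value is still returned with
#' attribute `gimbal = TRUE`.
#'
#' @param head,thorax `pose` objects from [estimate_pose()].
#' @param convention "twist_z" (default) or "cardan_xyz".
#' @return angle in degrees in (-180, 180].
#' @export
axial_rotation_angle <- function(head, thorax, convention = "twist_z") {
  Rrel <- t(thorax$rotation) %*% head$rotation
  if (convention == "twist_z") {
    q <- rotmat_to_quat(Rrel)
    ang <- 2 * atan2(q[4], q[1]) * 180 / pi
    if (ang > 180) ang <- ang - 360
    if (ang <= -180) ang <- ang + 360
    return(ang)
  }
  if (convention == "cardan_xyz") {
    # R = Rx(a) Ry(b) Rz(c); report c
    b <- asin(max(-1, min(1, -Rrel[3, 1])))
    gimbal <- abs(abs(b) - pi / 2) < pi / 180
    c_ang <- atan2(Rrel[2, 1], Rrel[1, 1]) * 180 / pi
    return(structure(c_ang, gimbal = gimbal))
  }
  stop("unknown convention '", convention, "'", call. = FALSE)
}

#' Anatomical thorax axes from reference-window markers
#'
#' Builds the thorax segment frame the axial angle is decomposed in:
#' X along the acromion line (left -> right shoulder peak), the cranial
#' direction from T10 to the mid-shoulder point, Z their cross product
#' (the body's vertical), re-orthogonalized. Because the frame is built
#' from the markers themselves, angles decomposed in it are invariant to
#' any common rigid transform of the laboratory.
#'
#' @param trial a [trial()].
#' @param ref_window averaging window, seconds.
#' @return 3x3 rotation matrix with the axes as columns.
#' @export
anatomical_axes <- function(trial, ref_window = c(0, 0.5)) {
  t_m <- marker_times(trial)
  sel <- t_m >= ref_window[1] & t_m <= ref_window[2]
  avg <- function(lab) {
    m <- get_marker(trial, lab)
    ok <- sel & !m$occluded
    colMeans(m$positions[ok, , drop = FALSE])
  }
  sl <- avg("shoulder_peak_left"); sr <- avg("shoulder_peak_right")
  t10 <- avg("t10_spinous")
  xhat <- sr - sl; xhat <- xhat / sqrt(sum(xhat^2))
  cranial <- (sl + sr) / 2 - t10
  zhat <- c(xhat[2] * cranial[3] - xhat[3] * cranial[2],
            xhat[3] * cranial[1] - xhat[1] * cranial[3],
            xhat[1] * cranial[2] - xhat[2] * cranial[1])
  zhat <- zhat / sqrt(sum(zhat^2))
  yhat <- c(zhat[2] * xhat[3] - zhat[3] * xhat[2],
            zhat[3] * xhat[1] - zhat[1] * xhat[3],
            zhat[1] * xhat[2] - zhat[2] * xhat[1])
  cbind(xhat, yhat, zhat)
}

#' Per-frame axial rotation series
#'
#' Estimates head and thorax poses for every frame, both expressed in the
#' anatomical thorax frame captured over the reference window
#' ([anatomical_axes()]), and returns the axial angle over time. Frames
#' where either pose cannot be estimated (occlusion, collinearity) are
#' masked, never interpolated.
#'
#' @param trial a [trial()].
#' @param head_def,thorax_def [rigid_body_def()] objects (defaults built
#'   from the canonical subject marker sets).
#' @param convention see [axial_rotation_angle()].
#' @return an `angle_series`: list(times, axial_angle degrees, masked,
#'   convention_tag).
#' @export
angle_series <- function(trial,
                         head_def = NULL, thorax_def = NULL,
                         convention = "twist_z") {
  if (is.null(head_def)) {
    head_def <- rigid_body_def(trial, "head", head_marker_set())
  }
  if (is.null(thorax_def)) {
    thorax_def <- rigid_body_def(trial, "thorax", thorax_marker_set())
  }
  t_m <- marker_times(trial)
  n <- length(t_m)
  ang <- rep(NA_real_, n)
  masked <- rep(FALSE, n)
  bodies <- list(head_def, thorax_def)
  # rotate reference shapes into the anatomical thorax frame so the twist
  # axis is the subject's own vertical, not the laboratory's
  axes <- tryCatch(anatomical_axes(trial), error = function(e) diag(3))
  bodies <- lapply(bodies, function(b) {
    b$reference_shape <- b$reference_shape %*% axes
    b
  })
  rots <- list()
  partial <- rep(FALSE, n)  # frames needing the per-marker fallback
  for (bi in 1:2) {
    b <- bodies[[bi]]
    mks <- lapply(b$marker_labels, get_marker, trial = trial)
    occ <- Reduce(`|`, lapply(mks, `[[`, "occluded"))
    partial <- partial | occ
    m <- length(mks)
    obs_all <- do.call(cbind, lapply(mks, `[[`, "positions"))  # n x 3m
    ref <- b$reference_shape
    Rf <- vector("list", n)
    for (f in which(!occ)) {
      obs <- matrix(obs_all[f, ], ncol = 3, byrow = TRUE)
      obs <- obs - rep(colMeans(obs), each = m)
      sv <- svd(crossprod(ref, obs))
      d <- sign(det(sv$v %*% t(sv$u)))
      Rf[[f]] <- sv$v %*% (c(1, 1, d) * t(sv$u))
    }
    rots[[bi]] <- Rf
  }
  # fallback for frames with occlusions: full estimate_pose on visible subset
  for (f in which(partial)) {
    for (bi in 1:2) {
      if (!is.null(rots[[bi]][[f]])) next
      b <- bodies[[bi]]
      vis <- list()
      for (l in b$marker_labels) {
        mm <- get_marker(trial, l)
        if (!mm$occluded[f]) vis[[l]] <- mm$positions[f, ]
      }
      p <- tryCatch(estimate_pose(b, vis), error = function(e) NULL)
      if (!is.null(p)) rots[[bi]][[f]] <- p$rotation
    }
  }
  for (f in seq_len(n)) {
    if (is.null(rots[[1]][[f]]) || is.null(rots[[2]][[f]])) {
      masked[f] <- TRUE
    } else {
      ang[f] <- as.numeric(axial_rotation_angle(
        list(rotation = rots[[1]][[f]]), list(rotation = rots[[2]][[f]]),
        convention))
    }
  }
  if (any(masked)) {
    warning(sum(masked), " of ", n, " frames masked (pose estimation failed)",
            call. = FALSE)
  }
  structure(list(times = t_m, axial_angle = ang, masked = masked,
                 convention_tag = convention),
            class = "angle_series")
}

#' Default head / thorax marker sets
#' @return character vector of canonical labels.
#' @export
head_marker_set <- function() {
  c("head_crown", "temporal_left", "temporal_right", "occipital_bulge",
    "mastoid_left", "mastoid_right")
}

#' @rdname head_marker_set
#' @export
thorax_marker_set <- function() {
  c("shoulder_peak_left", "shoulder_peak_right",
    "subscapular_left", "subscapular_right", "t10_spinous")
}

#' Maximum axial rotation over a window
#'
#' @param series an [angle_series()].
#' @param window c(start, end) seconds.
#' @return maximum angle (degrees, left-rotation positive) over unmasked
#'   frames in the window.
#' @export
max_rotation_angle <- function(series, window) {
  sel <- series$times >= window[1] & series$times <= window[2] &
    !series$masked
  if (!any(sel)) {
    stop("no unmasked frames in window [", window[1], ", ", window[2], "] s",
         call. = FALSE)
  }
  max(series$axial_angle[sel])
}

#' Virtual landmark points
#'
#' `mid_shoulder`: per-frame midpoint of the left and right acromion
#' ("shoulder peak") markers, the T1 proxy. `head_vertex`: the crown marker.
#' Frames with either acromion occluded are masked.
#'
#' @param trial a [trial()].
#' @return list of two `virtual_point`s (label, positions n x 3, masked).
#' @export
virtual_points <- function(trial) {
  sl <- get_marker(trial, "shoulder_peak_left")
  sr <- get_marker(trial, "shoulder_peak_right")
  cr <- get_marker(trial, "head_crown")
  mid <- (sl$positions + sr$positions) / 2
  mid_mask <- sl$occluded | sr$occluded
  list(
    mid_shoulder = structure(list(label = "mid_shoulder", positions = mid,
                                  masked = mid_mask),
                             class = "virtual_point"),
    head_vertex = structure(list(label = "head_vertex",
                                 positions = cr$positions,
                                 masked = cr$occluded),
                            class = "virtual_point"))
}
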