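# Independent oracles used to freeze expected values. Each deliberately
# avoids the code path it checks.

# rotation matrix about Z, degrees
rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(deg) {
  r <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(r), sin(r), 0, -sin(r), cos(r)), 3, 3)
}

rot_y <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), 0, -sin(r), 0, 1, 0, sin(r), 0, cos(r)), 3, 3)
}

# brute-force rigid fit: grid search over Z rotation only (bodies used with
# it are constructed from pure Z rotations), resolution in degrees
grid_fit_z <- function(ref, obs, res = 0.1) {
  angs <- seq(-180, 180 - res, by = res)
  best <- Inf; best_a <- NA
  rc <- sweep(ref, 2, colMeans(ref))
  oc <- sweep(obs, 2, colMeans(obs))
  for (a in angs) {
    e <- sum((rc %*% t(rot_z(a)) - oc)^2)
    if (e < best) { best <- e; best_a <- a }
  }
  best_a
}

# swing-twist oracle via explicit axis projection: twist of rotation R about
# unit axis n, from the quaternion projected onto n
twist_about_z_oracle <- function(R) {
  # quaternion from trace (independent implementation)
  qw <- sqrt(max(0, 1 + R[1, 1] + R[2, 2] + R[3, 3])) / 2
  qz <- (R[2, 1] - R[1, 2]) / (4 * qw)
  a <- 2 * atan2(qz, qw) * 180 / pi
  if (a > 180) a <- a - 360
  if (a <= -180) a <- a + 360
  a
}

# exhaustive phase scan on a sampled signal: definitions applied literally,
# no sustained/backtracking machinery (valid for clean piecewise signals)
scan_phases <- function(v, tt, base, thr) {
  iC <- which.max(v)
  above <- which(v > base + thr)
  iA <- min(above[above < iC])
  while (iA > 1 && v[iA - 1] < v[iA]) iA <- iA - 1
  iB <- iC
  while (iB > iA + 1 && v[iB - 1] <= v[iB]) iB <- iB - 1
  after <- which(v < base + thr)
  iD <- min(after[after > iC])
  while (iD < length(v) && v[iD + 1] < v[iD]) iD <- iD + 1
  c(A = tt[iA], B = tt[iB], C = tt[iC], D = tt[iD])
}

# direct paired-t formula
paired_t_oracle <- function(x, y) {
  d <- x - y
  mean(d) * sqrt(length(d)) / stats::sd(d)
}

# quick noise-free trial + pipeline shorthand used by several files
quiet_trial <- function(...) {
  simulate_trial(subject_params(noise_sd_marker = 0, noise_sd_force = 0, ...))
}

# rigid transform applied to every marker of a trial
transform_trial <- function(trial, R, tvec) {
  for (lab in names(trial$markers)) {
    p <- trial$markers[[lab]]$positions
    trial$markers[[lab]]$positions <- sweep(p %*% t(R), 2, tvec, "+")
  }
  trial
}
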