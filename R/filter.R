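#' Butterworth low-pass coefficients
#'
#' Designs a digital low-pass Butterworth filter by the bilinear transform
#' of the analog prototype (poles on the unit semicircle), pre-warping the
#' cutoff. Returns transfer-function coefficients normalized so `a[1] == 1`.
#'
#' @param order filter order (positive integer; zero-phase use doubles the
#'   effective order).
#' @param cutoff cutoff frequency in Hz (-3 dB point of a single pass).
#' @param rate sampling rate in Hz.
#' @return list with numerator `b` and denominator `a`, each length
#'   `order + 1`.
#' @export
butter_lowpass <- function(order, cutoff, rate) {
  stopifnot(order >= 1, order == round(order))
  if (!(cutoff > 0 && cutoff < rate / 2)) {
    stop("cutoff must lie in (0, rate/2); got ", cutoff, " Hz at rate ",
         rate, " Hz", call. = FALSE)
  }
  # pre-warped analog cutoff for the bilinear transform (fs normalized to 2)
  warped <- 2 * tan(pi * cutoff / rate)
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order) + pi / 2
  p_analog <- warped * exp(1i * theta)      # stable left-half-plane poles
  # bilinear transform z = (2 + s) / (2 - s)
  p_dig <- (2 + p_analog) / (2 - p_analog)
  gain <- Re(prod(warped / (2 - p_analog)))  # analog gain warped^order mapped
  a <- Re(poly_from_roots(p_dig))
  b <- Re(poly_from_roots(rep(-1 + 0i, order))) * gain
  # enforce exact unit DC gain (sum b / sum a == 1)
  b <- b * (sum(a) / sum(b))
  list(b = b, a = a)
}

# expand prod (x - r_i) into monic polynomial coefficients, highest first
poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (ri in r) coef <- c(coef, 0) - c(0, coef) * ri
  coef
}

# direct-form II transposed IIR filter with initial conditions
iir_filter <- function(b, a, x, zi = NULL) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  z <- if (is.null(zi)) rep(0, n - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2) {
      for (j in 1:(n - 2)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    }
    z[n - 1] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# steady-state initial state for a unit step input (lfilter_zi equivalent)
filter_zi <- function(b, a) {
  n <- max(length(b), length(a))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  comp <- rbind(-a[-1], cbind(diag(n - 2), 0))  # companion matrix of a
  iminus <- diag(n - 1) - t(comp)
  rhs <- b[-1] - a[-1] * b[1]
  as.numeric(solve(iminus, rhs))
}

#' Zero-phase low-pass filtering
#'
#' Forward-backward Butterworth filtering with odd-reflection end padding and
#' steady-state initial conditions, so the output has no phase lag, no start
#' or end transients, and exactly unit DC gain.
#'
#' @param x numeric vector, uniformly sampled.
#' @param cutoff low-pass cutoff in Hz; must be below the Nyquist frequency.
#' @param rate sampling rate in Hz.
#' @param order Butterworth order of each pass (even, default 4).
#' @return filtered vector of the same length as `x`.
#' @export
lowpass_filter <- function(x, cutoff, rate, order = 4) {
  stopifnot(is.numeric(x))
  if (order %% 2 != 0) stop("order must be even", call. = FALSE)
  if (cutoff >= rate / 2) {
    stop("cutoff (", cutoff, " Hz) must be below Nyquist (", rate / 2, " Hz)",
         call. = FALSE)
  }
  if (anyNA(x)) stop("signal contains NA; fill occlusions first", call. = FALSE)
  co <- butter_lowpass(order, cutoff, rate)
  padlen <- 3 * max(length(co$a), length(co$b))
  if (length(x) <= padlen) {
    stop("signal too short (", length(x), " samples) for padlen ", padlen,
         call. = FALSE)
  }
  # odd reflection about the end points suppresses edge transients
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)]
  ext <- c(pre, x, post)
  zi <- filter_zi(co$b, co$a)
  y <- iir_filter(co$b, co$a, ext, zi * ext[1])
  y <- rev(iir_filter(co$b, co$a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + length(x))]
}
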