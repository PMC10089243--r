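#' Circular arithmetic on the 180-degree orientation circle
#'
#' Orientations are 180-degree periodic: a grating at 170 deg is 20 deg away
#' from one at 10 deg. All circular statistics in this package operate on the
#' doubled-angle circle (angles multiplied by 2, period 360 deg), and signed
#' differences are mapped to the half-open interval (-90, 90]. Exact antipodes
#' (difference of 90 deg) map to +90 by convention; the same tie-break is used
#' everywhere in the package.
#'
#' `circular_error(response, reference)` returns the signed circular distance
#' `response - reference`, i.e. the recall error when `response` is a reported
#' orientation and `reference` the cued target. `wrap_ori()` folds any angle
#' into [0, 180).
#'
#' @param response,reference Orientations in degrees. Recycled to a common
#'   length.
#' @return Signed differences in degrees, in (-90, 90].
#' @examples
#' circular_error(45, 45)   # 0
#' circular_error(10, 170)  # 20 (wraps around 180)
#' circular_error(0, 90)    # 90 (antipode tie-break)
#' @export
circular_error <- function(response, reference) {
  if (!is.numeric(response) || !is.numeric(reference)) {
    abort("`response` and `reference` must be numeric degrees.")
  }
  ok <- is.na(response) | is.na(reference) |
    (is.finite(response) & is.finite(reference))
  if (!all(ok)) {
    abort("non-finite orientation passed to `circular_error()`.")
  }
  d <- (response - reference) %% 180
  out <- ifelse(d > 90, d - 180, d)
  out
}

#' @rdname circular_error
#' @param x Angles in degrees.
#' @export
wrap_ori <- function(x) x %% 180

#' Derivative-of-Gaussian bias kernel
#'
#' The canonical shape of a feature-similarity bias: zero at zero distance,
#' peaking at `width` degrees, decaying for larger distances. Parameterized so
#' the peak value is exactly `amp` degrees at `delta = width`, which makes the
#' amplitude directly interpretable as the maximum bias in degrees.
#'
#' @param delta Signed angular distance in degrees.
#' @param amp Peak bias in degrees (attained at `delta = width`).
#' @param width Distance at which the bias peaks, in degrees; must be > 0.
#' @return Bias in degrees, same sign structure as `delta`.
#' @export
dog_bias <- function(delta, amp, width) {
  stopifnot(is.numeric(delta), length(amp) == 1, length(width) == 1, width > 0)
  amp * (delta / width) * exp(0.5 - delta^2 / (2 * width^2))
}

# von Mises sampling on the doubled-angle circle (Best & Fisher rejection
# sampler). Returns angles in radians in (-pi, pi]; kappa = 0 gives uniform.
rvonmises <- function(n, kappa) {
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa) || kappa < 0) abort("`kappa` must be finite and >= 0.")
  if (kappa < 1e-8) {
    return(runif(n, -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    acc <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    th <- sign(u3 - 0.5) * acos(pmax(pmin(f, 1), -1))
    th <- th[acc]
    k <- length(th)
    if (k > 0) {
      out[(got + 1):(got + k)] <- th
      got <- got + k
    }
  }
  out
}

# Inverse of A(kappa) = I1(kappa)/I0(kappa); mean-resultant-length -> kappa.
a1inv <- function(r) {
  if (r <= 0) return(0)
  if (r >= 1 - 1e-10) r <- 1 - 1e-10
  f <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE) - r
  # A() is increasing in kappa; bracket then root-find
  hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  uniroot(f, c(1e-10, hi), tol = 1e-10)$root
}
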