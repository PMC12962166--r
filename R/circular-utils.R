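#' Wrap angles to [-pi, pi)
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval \code{[-pi, pi)}.
#' @export
#' @examples
#' wrap_pi(c(0, pi, -pi, 3 * pi / 2))
wrap_pi <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Circular distance between two angles
#'
#' Shortest arc length between angles, in \code{[0, pi]}.
#'
#' @param a,b angles in radians.
#' @return non-negative circular distances.
#' @export
circ_dist <- function(a, b) {
  abs(wrap_pi(a - b))
}

#' Circular mean direction
#'
#' @param x angles in radians.
#' @param w optional non-negative weights.
#' @return mean direction in \code{[-pi, pi)}; \code{NA} if the resultant
#'   vector has length (numerically) zero.
#' @export
circ_mean <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  s <- sum(w * sin(x))
  c <- sum(w * cos(x))
  if (sqrt(s^2 + c^2) < 1e-12 * sum(w)) return(NA_real_)
  wrap_pi(atan2(s, c))
}

#' Mean resultant length
#'
#' @param x angles in radians.
#' @param w optional non-negative weights.
#' @return resultant length in \code{[0, 1]}.
#' @export
circ_resultant <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  sqrt(sum(w * sin(x))^2 + sum(w * cos(x))^2) / sum(w)
}

#' von Mises density
#'
#' Numerically stable for large concentrations (exponentially scaled Bessel).
#'
#' @param x angles in radians.
#' @param mu mean direction (radians).
#' @param kappa concentration, \code{>= 0}.
#' @param log return log-density?
#' @return density (per radian) or log-density values.
#' @export
dvonmises <- function(x, mu = 0, kappa = 1, log = FALSE) {
  stopifnot(kappa >= 0)
  ld <- kappa * (cos(x - mu) - 1) - log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE))
  if (log) ld else exp(ld)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; uniform on the circle when
#' \code{kappa} is numerically zero. Uses the current RNG stream.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration, \code{>= 0}.
#' @return \code{n} angles in \code{[-pi, pi)}.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa < 1e-10) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- wrap_pi(sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f))) + mu)
      i <- i + 1L
    }
  }
  out
}

# Ratio I1/I0 (mean resultant length of a von Mises with concentration kappa).
a1_bessel <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Best & Fisher approximate inverse of A1: concentration from resultant length.
a1_inv <- function(r) {
  if (r < 0) r <- 0
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else if (r < 1) {
    1 / (r^3 - 4 * r^2 + 3 * r)
  } else {
    Inf
  }
}
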