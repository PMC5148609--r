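## Circular helpers shared by the synchrony, spike-field and generator code.

#' Wrap angles into (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @keywords internal
wrapAngle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi
  w
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. `kappa = 0` reduces to the uniform
#' distribution on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration, `kappa >= 0`.
#' @return numeric vector of angles in (-pi, pi].
#' @export
rVonMises <- function(n, mu = 0, kappa = 0) {
  stopifnot(n >= 0, kappa >= 0, is.finite(kappa))
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(wrapAngle(stats::runif(n, -pi, pi)))
  ## Best & Fisher envelope constants
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nk <- sum(keep)
    if (nk > 0) {
      u3 <- stats::runif(nk)
      theta <- sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f[keep])))
      out[(got + 1L):(got + nk)] <- theta
      got <- got + nk
    }
  }
  wrapAngle(out + mu)
}

#' Mean resultant length of a sample of angles
#'
#' @param phi angles in radians.
#' @return `|mean(exp(1i * phi))|`, in `[0, 1]`.
#' @export
resultantLength <- function(phi) {
  stopifnot(length(phi) >= 1)
  Mod(mean(exp(1i * phi)))
}

#' Pairwise phase consistency of a sample of phase differences
#'
#' Unbiased pairwise estimator of the squared population resultant: the average
#' cosine of the angular distance over all unordered pairs of observations.
#' Computed through the algebraic identity `PPC = (N R^2 - 1) / (N - 1)` with
#' `R` the mean resultant length, which equals the O(N^2) pairwise sum exactly.
#'
#' @param phi phase differences in radians (length `N >= 2`).
#' @return scalar in `[-1, 1]`.
#' @seealso [ppcPairwiseSum()] for the direct O(N^2) evaluation.
#' @export
ppc <- function(phi) {
  n <- length(phi)
  if (n < 2) stop("PPC requires at least 2 phase observations")
  R <- resultantLength(phi)
  (n * R^2 - 1) / (n - 1)
}

#' Pairwise phase consistency by the direct pairwise sum
#'
#' Reference O(N^2) evaluation `2/(N(N-1)) * sum_{i<j} cos(phi_i - phi_j)`.
#' Kept as an independent cross-check of [ppc()]; the two agree to machine
#' precision.
#'
#' @inheritParams ppc
#' @return scalar in `[-1, 1]`.
#' @export
ppcPairwiseSum <- function(phi) {
  n <- length(phi)
  if (n < 2) stop("PPC requires at least 2 phase observations")
  s <- 0
  for (i in seq_len(n - 1L)) {
    s <- s + sum(cos(phi[i] - phi[(i + 1L):n]))
  }
  2 * s / (n * (n - 1))
}

## PPC from resultant lengths computed on unit-phasor sums (vectorised form
## used on whole time-frequency maps).
.ppcFromResultant <- function(R, n) (n * R^2 - 1) / (n - 1)

## Expected PPC when the two channels of a pair each carry independent
## von Mises phase jitter of concentration kappa: the phase-difference
## resultant is (I1/I0)^2, and PPC estimates its square.
vonMisesPairPPC <- function(kappa) {
  (besselI(kappa, 1) / besselI(kappa, 0))^4
}
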