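#' Circular distance between hours of the day
#'
#' Distance between two hour indices on the 24-hour clock,
#' `min(|i - i'|, 24 - |i - i'|)`, so that hour 24 (midnight) and hour 1
#' are one hour apart. This is the distance entering the cyclic covariance
#' of the hour-of-day effect.
#'
#' @param i,i2 integer hour indices in 1..24 (vectorised, recycled).
#' @return integer vector of circular distances in hours, in 0..12.
#' @examples
#' circ_hour_dist(24, 1)   # 1
#' circ_hour_dist(1, 13)   # 12
#' @export
circ_hour_dist <- function(i, i2) {
  if (any(!is.finite(i)) || any(!is.finite(i2)) ||
      any(i < 1L | i > 24L) || any(i2 < 1L | i2 > 24L) ||
      any(i != round(i)) || any(i2 != round(i2))) {
    stop("hour indices must be integers in 1..24")
  }
  d <- abs(i - i2)
  as.integer(pmin(d, 24 - d))
}

#' Cyclic hour-of-day covariance matrix
#'
#' Builds the 24 x 24 covariance matrix of the hour-of-day effect,
#' \deqn{\Sigma_{ii'} = \exp(-\nu \, d_c(i,i')) / \psi}
#' with \eqn{d_c} the circular hour distance. The matrix is symmetric,
#' circulant and positive definite for any `nu > 0`, `psi > 0`; its diagonal
#' is `1/psi`. The practical range of the correlation (distance at which it
#' drops to ~0.05) is `3/nu` hours.
#'
#' @param nu correlation decay per hour (> 0).
#' @param psi precision-like scale (> 0); marginal variance is `1/psi`.
#' @return object of class `hour_covariance`: list with `nu`, `psi`, and the
#'   matrix `Sigma`.
#' @export
hour_covariance <- function(nu, psi) {
  if (!is.finite(nu) || nu <= 0) stop("nu must be > 0")
  if (!is.finite(psi) || psi <= 0) stop("psi must be > 0")
  d <- outer(1:24, 1:24, circ_hour_dist)
  structure(list(nu = nu, psi = psi, Sigma = exp(-nu * d) / psi),
            class = "hour_covariance")
}

# Inverse of the cyclic covariance through its spectral (DFT) decomposition.
# A circulant matrix is diagonalised by the discrete Fourier basis; its
# eigenvalues are the DFT of the first row, so the inverse is the circulant
# with first row IDFT(1/eigenvalues). Used as the fast path and checked
# against dense inversion in the tests.
hour_covariance_inverse <- function(cov) {
  stopifnot(inherits(cov, "hour_covariance"))
  first <- cov$Sigma[1L, ]
  ev <- Re(stats::fft(first))            # real: the row is even under the cycle
  if (any(ev <= 0)) stop("covariance is not positive definite")
  inv_first <- Re(stats::fft(1 / ev, inverse = TRUE)) / 24
  idx <- outer(1:24, 1:24, function(i, j) ((i - j) %% 24) + 1L)
  matrix(inv_first[idx], 24, 24)
}

# Eigenvalues of the cyclic covariance (DFT of the first row), ascending.
hour_covariance_eigenvalues <- function(cov) {
  sort(Re(stats::fft(cov$Sigma[1L, ])))
}
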