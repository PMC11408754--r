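# Real spherical harmonics used by the synthetic tumor shape models.

# Associated Legendre P_l^m(x) for scalar l, m >= 0, vectorized over x.
# Condon-Shortley phase included; standard upward recurrence in degree.
assoc_legendre <- function(l, m, x) {
  stopifnot(m >= 0, l >= m)
  somx2 <- sqrt(pmax(0, 1 - x^2))
  pmm <- rep(1, length(x))
  if (m > 0) {
    odd <- seq(1, 2 * m - 1, by = 2)
    pmm <- (-1)^m * prod(odd) * somx2^m
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pmmp1)
  for (k in (m + 2):l) {
    pk <- ((2 * k - 1) * x * pmmp1 - (k + m - 1) * pmm) / (k - m)
    pmm <- pmmp1
    pmmp1 <- pk
  }
  pmmp1
}

#' Real spherical harmonic Y_lm
#'
#' Orthonormal real-valued spherical harmonic of degree `l` and order `m`
#' (`m > 0` pairs with `cos(m phi)`, `m < 0` with `sin(|m| phi)`).
#'
#' @param l Integer degree, `l >= 0`.
#' @param m Integer order, `|m| <= l`.
#' @param theta Polar angle(s) from the +z axis, radians.
#' @param phi Azimuthal angle(s), radians.
#' @return Numeric vector of Y_lm values.
#' @export
real_sph_harm <- function(l, m, theta, phi) {
  stopifnot(abs(m) <= l)
  am <- abs(m)
  # log-space normalization: (l - |m|)! / (l + |m|)! stays finite for l <= 20
  nrm <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
  p <- assoc_legendre(l, am, cos(theta))
  if (m > 0) {
    sqrt(2) * nrm * p * cos(am * phi)
  } else if (m < 0) {
    sqrt(2) * nrm * p * sin(am * phi)
  } else {
    nrm * p
  }
}
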