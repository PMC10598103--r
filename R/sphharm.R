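# Real spherical harmonics, used by the synthetic tumour shape model.
#
# Basis ordering: (l, m) for l = 1..lmax, m = -l..l (the constant l = 0
# term is excluded -- any mean radius change is carried by r0 itself, so
# the perturbation fields are exactly zero-mean over the sphere).
# Real convention: Y_l0 = N_l0 P_l0(cos t); for m > 0,
# Y_lm = sqrt(2) N_lm cos(m p) P_lm(cos t) and
# Y_l,-m = sqrt(2) N_lm sin(m p) P_lm(cos t), with
# N_lm = sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!) and Condon-Shortley phase in
# P_lm. Under this normalisation sum_m Y_lm(d)^2 = (2l+1)/(4 pi) for any
# direction d (addition theorem), which makes the pointwise variance of a
# random field with iid N(0, s^2) coefficients exactly
# s^2 * sum_l (2l+1)/(4 pi) -- the simulator relies on this to hit a
# requested pointwise roughness sd.

# Associated Legendre P_lm(x) for all l <= lmax, 0 <= m <= l, vectorised
# over x. Returns a list P[[l+1]][[m+1]] of numeric vectors.
assoc_legendre <- function(lmax, x) {
  P <- rep(list(vector("list", lmax + 1)), lmax + 1)
  sx <- sqrt(pmax(0, 1 - x * x))
  for (m in 0:lmax) {
    # P_mm = (-1)^m (2m-1)!! (1-x^2)^{m/2}
    pmm <- rep(1, length(x))
    if (m > 0) pmm <- (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) * sx^m
    P[[m + 1]][[m + 1]] <- pmm
    if (m < lmax) {
      P[[m + 2]][[m + 1]] <- x * (2 * m + 1) * pmm
      if (m + 2 <= lmax) {
        for (l in (m + 2):lmax) {
          P[[l + 1]][[m + 1]] <-
            ((2 * l - 1) * x * P[[l]][[m + 1]] -
               (l + m - 1) * P[[l - 1]][[m + 1]]) / (l - m)
        }
      }
    }
  }
  P
}

# Evaluate the real spherical-harmonic basis (l = 1..lmax, all m) at unit
# directions given by colatitude theta and azimuth phi. Returns an
# n x (lmax(lmax+2)) matrix; column order l-major, m = -l..l.
sph_basis <- function(lmax, theta, phi) {
  x <- cos(theta)
  P <- assoc_legendre(lmax, x)
  ncol <- lmax * (lmax + 2)
  out <- matrix(0, length(theta), ncol)
  cn <- 0L
  for (l in 1:lmax) {
    for (m in (-l):l) {
      cn <- cn + 1L
      am <- abs(m)
      nrm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      v <- nrm * P[[l + 1]][[am + 1]]
      if (m > 0) v <- sqrt(2) * v * cos(m * phi)
      if (m < 0) v <- sqrt(2) * v * sin(am * phi)
      out[, cn] <- v
    }
  }
  out
}

# Number of basis functions for degrees 1..lmax.
sph_nbasis <- function(lmax) lmax * (lmax + 2)

# sum_{l=1..lmax} (2l+1) / (4 pi): pointwise variance of a field with
# unit-variance iid coefficients.
sph_field_var_unit <- function(lmax) (lmax * (lmax + 2)) / (4 * pi)
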