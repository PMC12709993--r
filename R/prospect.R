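#' PROSPECT-5 style leaf optical model (generalized plate model)
#'
#' Computes hemispherical leaf reflectance and transmittance from the leaf
#' structure parameter N (number of homogeneous plates) and per-constituent
#' absorption, following the generalized plate model: an elementary layer
#' whose transmissivity combines surface (Fresnel, via the average
#' transmissivity `tav`) and volume (Beer-Lambert with diffuse path
#' correction) terms, stacked N times with the Stokes doubling relations.
#'
#' @param params Data frame with columns `N`, `Cab` (ug cm-2), `Car`
#'   (ug cm-2), `Cw` (cm), `Cm` (g cm-2); one row per leaf.
#' @param constants Optical constants tibble from [leaf_optical_constants()].
#' @return List of matrices `reflectance` and `transmittance`
#'   (rows = leaves, cols = bands), each with a `wavelengths_nm` attribute.
#' @export
prospect_leaf <- function(params, constants = leaf_optical_constants()) {
  n_rec <- nrow(params)
  wl <- constants$wavelength_nm
  nb <- length(wl)
  N <- params$N

  # per-layer absorption coefficient (records x bands)
  k <- (outer(params$Cab, constants$k_cab) +
          outer(params$Car, constants$k_car) +
          outer(params$Cw, constants$k_cw) +
          outer(params$Cm, constants$k_cm)) / N
  k[k < 0] <- 0

  # transmissivity of the elementary layer (volume term)
  tau <- layer_transmissivity(k)

  nr <- constants$refractive_index
  talf <- rep(tav_stern(40, nr), each = n_rec)
  dim(talf) <- c(n_rec, nb)
  t12 <- rep(tav_stern(90, nr), each = n_rec)
  dim(t12) <- c(n_rec, nb)
  nr2 <- rep(nr^2, each = n_rec)
  dim(nr2) <- c(n_rec, nb)

  ralf <- 1 - talf
  r12 <- 1 - t12
  t21 <- t12 / nr2
  r21 <- 1 - t21

  denom <- 1 - r21^2 * tau^2
  Ta <- talf * tau * t21 / denom
  Ra <- ralf + r21 * tau * Ta
  tt <- t12 * tau * t21 / denom
  rr <- r12 + r21 * tau * tt

  # Stokes relations for the remaining N - 1 layers
  D2 <- (1 + rr + tt) * (1 + rr - tt) * (1 - rr + tt) * (1 - rr - tt)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  rq <- rr^2
  tq <- tt^2
  a <- (1 + rq - tq + D) / (2 * rr)
  b <- (1 - rq + tq + D) / (2 * pmax(tt, 1e-14))

  bNm1 <- b^(N - 1)
  bN2 <- bNm1^2
  a2 <- a^2
  denom2 <- a2 * bN2 - 1
  Rsub <- a * (bN2 - 1) / denom2
  Tsub <- bNm1 * (a2 - 1) / denom2

  # conservative-scattering limit (r + t ~ 1): plate algebra degenerates
  cons <- (rr + tt) >= 1
  if (any(cons)) {
    Nm <- matrix(N, n_rec, nb)
    Tsub[cons] <- (tt / (tt + (1 - tt) * (Nm - 1)))[cons]
    Rsub[cons] <- 1 - Tsub[cons]
  }

  denom3 <- 1 - Rsub * rr
  tran <- Ta * Tsub / denom3
  refl <- Ra + Ta * Rsub * tt / denom3

  refl <- pmin(pmax(refl, 0), 1)
  tran <- pmin(pmax(tran, 0), 1)
  attr(refl, "wavelengths_nm") <- wl
  attr(tran, "wavelengths_nm") <- wl
  list(reflectance = refl, transmittance = tran)
}

#' Transmissivity of an elementary absorbing layer
#'
#' `(1 - k) exp(-k) + k^2 E1(k)`, the diffuse-path Beer-Lambert integral
#' over an isotropic radiation field.
#'
#' @param k Non-negative absorption (any numeric shape).
#' @return Same shape as `k`, values in \[0, 1\].
#' @keywords internal
layer_transmissivity <- function(k) {
  out <- k
  tiny <- k < 1e-9
  out[tiny] <- 1
  kk <- k[!tiny]
  out[!tiny] <- (1 - kk) * exp(-kk) + kk^2 * expint_e1(kk)
  pmin(pmax(out, 0), 1)
}

# Exponential integral E1(x), x > 0, via the Abramowitz & Stegun rational
# approximations (5.1.53 for x <= 1, 5.1.56 for x > 1; |error| < 2e-7).
# Vectorized; avoids a per-element special-function loop on large grids.
expint_e1 <- function(x) {
  out <- numeric(length(x))
  lo <- x <= 1
  if (any(lo)) {
    xl <- x[lo]
    out[lo] <- -log(xl) +
      ((((0.00107857 * xl - 0.00976004) * xl + 0.05519968) * xl -
          0.24991055) * xl + 0.99999193) * xl - 0.57721566
  }
  if (any(!lo)) {
    xh <- x[!lo]
    num <- (((xh + 8.5733287401) * xh + 18.059016973) * xh +
              8.6347608925) * xh + 0.2677737343
    den <- (((xh + 9.5733223454) * xh + 25.6329561486) * xh +
              21.0996530827) * xh + 3.9584969228
    out[!lo] <- exp(-xh) / xh * num / den
  }
  out
}

#' Average transmissivity of a dielectric surface (Stern closed form)
#'
#' Mean Fresnel transmissivity for unpolarized light over incidence angles
#' from 0 to `theta` degrees, for refractive index `nr` (vectorized over
#' `nr`).
#'
#' @param theta Maximum incidence angle (degrees).
#' @param nr Refractive index vector.
#' @return Vector of transmissivities in \[0, 1\].
#' @keywords internal
tav_stern <- function(theta, nr) {
  if (theta == 0) return(4 * nr / (nr + 1)^2)
  thetarad <- theta * pi / 180
  n2 <- nr^2
  np <- n2 + 1
  nm <- n2 - 1
  a <- (nr + 1)^2 / 2
  k <- -((n2 - 1)^2) / 4
  sin2 <- sin(thetarad)^2

  if (theta == 90) {
    b1 <- 0
  } else {
    b1 <- sqrt((sin2 - np / 2)^2 + k)
  }
  b2 <- sin2 - np / 2
  b <- b1 - b2

  ts <- (k^2 / (6 * b^3) + k / b - b / 2) -
    (k^2 / (6 * a^3) + k / a - a / 2)

  tp1 <- -2 * n2 * (b - a) / np^2
  tp2 <- -2 * n2 * np * log(b / a) / nm^2
  tp3 <- n2 * (1 / b - 1 / a) / 2
  tp4 <- 16 * n2^2 * (n2^2 + 1) *
    log((2 * np * b - nm^2) / (2 * np * a - nm^2)) / (np^3 * nm^2)
  tp5 <- 16 * n2^3 *
    (1 / (2 * np * b - nm^2) - 1 / (2 * np * a - nm^2)) / np^3
  tp <- tp1 + tp2 + tp3 + tp4 + tp5

  (ts + tp) / (2 * sin2)
}
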