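#' Campbell ellipsoidal leaf-angle distribution
#'
#' Discretized leaf-inclination frequencies for the one-parameter Campbell
#' ellipsoidal distribution, on the 13 standard SAIL inclination classes
#' (eight 10-degree classes from 0-80 and five 2-degree classes from
#' 80-90). `alpha` is the mean leaf inclination angle in degrees; the
#' ellipsoid eccentricity is obtained from the standard cubic fit, so
#' `alpha` near 57.3 degrees reproduces the spherical distribution.
#'
#' @param alpha Mean leaf inclination angle (degrees), in (5, 89).
#' @return Tibble with columns `angle_lower`, `angle_upper`, `angle_mid`
#'   (degrees) and `density` (class probability, sums to 1).
#' @export
campbell_lad_density <- function(alpha) {
  if (!is.finite(alpha) || alpha <= 5 || alpha >= 89) {
    stop("alpha must lie in (5, 89) degrees", call. = FALSE)
  }
  freq <- campbell_lidf_matrix(alpha)[1L, ]
  b <- lidf_class_bounds()
  tibble::tibble(
    angle_lower = b$lower, angle_upper = b$upper,
    angle_mid = (b$lower + b$upper) / 2, density = freq
  )
}

lidf_class_bounds <- function() {
  lower <- c(seq(0, 70, by = 10), seq(80, 88, by = 2))
  upper <- c(seq(10, 80, by = 10), seq(82, 90, by = 2))
  list(lower = lower, upper = upper)
}

# Batched Campbell LAD: one row of class frequencies per alpha.
campbell_lidf_matrix <- function(alphas) {
  if (any(!is.finite(alphas)) || any(alphas <= 5) || any(alphas >= 89)) {
    stop("Cam_alpha values must lie in (5, 89) degrees", call. = FALSE)
  }
  b <- lidf_class_bounds()
  n <- length(alphas)
  excent <- exp(-1.6184e-5 * alphas^3 + 2.1145e-3 * alphas^2 -
                  1.2390e-1 * alphas + 3.2491)
  freq <- matrix(0, n, 13L)
  for (i in seq_len(13L)) {
    tl1 <- b$lower[i] * pi / 180
    tl2 <- b$upper[i] * pi / 180
    x1 <- excent / sqrt(1 + excent^2 * tan(tl1)^2)
    x2 <- excent / sqrt(1 + excent^2 * tan(tl2)^2)
    alph <- excent / sqrt(abs(1 - excent^2))
    alph2 <- alph^2
    x12 <- x1^2
    x22 <- x2^2
    pro <- excent > 1
    alpx1 <- sqrt(alph2 + x12)
    alpx2 <- sqrt(alph2 + x22)
    dumP <- abs(x1 * alpx1 + alph2 * log(x1 + alpx1) -
                  (x2 * alpx2 + alph2 * log(x2 + alpx2)))
    almx1 <- sqrt(pmax(alph2 - x12, 0))
    almx2 <- sqrt(pmax(alph2 - x22, 0))
    dumE <- abs(x1 * almx1 + alph2 * asin(pmin(pmax(x1 / alph, -1), 1)) -
                  (x2 * almx2 + alph2 * asin(pmin(pmax(x2 / alph, -1), 1))))
    sph <- abs(excent - 1) < 1e-9
    fr <- ifelse(pro, dumP, dumE)
    fr[sph] <- abs(cos(tl1) - cos(tl2))
    freq[, i] <- fr
  }
  freq / rowSums(freq)
}

# Geometric scattering factors for one leaf inclination class
# (Verhoef's volscatt); all angles in degrees. Returns chi_s, chi_o,
# frho, ftau.
volscatt <- function(tts, tto, psi, ttl) {
  rd <- pi / 180
  cts <- cos(rd * tts); cto <- cos(rd * tto)
  sts <- sin(rd * tts); sto <- sin(rd * tto)
  cospsi <- cos(rd * psi)
  psir <- rd * psi
  costl <- cos(rd * ttl); sintl <- sin(rd * ttl)
  cs <- costl * cts; co <- costl * cto
  ss <- sintl * sts; so <- sintl * sto

  cosbts <- if (abs(ss) > 1e-6) -cs / ss else 5
  cosbto <- if (abs(so) > 1e-6) -co / so else 5

  if (abs(cosbts) < 1) {
    bts <- acos(cosbts); ds <- ss
  } else {
    bts <- pi; ds <- cs
  }
  chi_s <- 2 / pi * ((bts - pi / 2) * cs + sin(bts) * ss)

  if (abs(cosbto) < 1) {
    bto <- acos(cosbto); do_ <- so
  } else if (tto < 90) {
    bto <- pi; do_ <- co
  } else {
    bto <- 0; do_ <- -co
  }
  chi_o <- 2 / pi * ((bto - pi / 2) * co + sin(bto) * so)

  btran1 <- abs(bts - bto)
  btran2 <- pi - abs(bts + bto - pi)
  if (psir <= btran1) {
    bt1 <- psir; bt2 <- btran1; bt3 <- btran2
  } else {
    bt1 <- btran1
    if (psir <= btran2) {
      bt2 <- psir; bt3 <- btran2
    } else {
      bt2 <- btran2; bt3 <- psir
    }
  }
  t1 <- 2 * cs * co + ss * so * cospsi
  t2 <- if (bt2 > 0) sin(bt2) * (2 * ds * do_ + ss * so * cos(bt1) * cos(bt3)) else 0
  denom <- 2 * pi^2
  frho <- max(((pi - bt2) * t1 + t2) / denom, 0)
  ftau <- max((-bt2 * t1 + t2) / denom, 0)
  c(chi_s = chi_s, chi_o = chi_o, frho = frho, ftau = ftau)
}

# J functions of the SAIL solution; vectorized with records-down-rows
# recycling (k, t length n; l may be an n x b matrix).
sail_j1 <- function(k, l, t) {
  del <- (k - l) * t
  small <- abs(del) < 1e-3
  out <- (exp(-l * t) - exp(-k * t)) / (k - l)
  alt <- 0.5 * t * (exp(-k * t) + exp(-l * t)) * (1 - del^2 / 12)
  out[small] <- alt[small]
  out
}
sail_j2 <- function(k, l, t) (1 - exp(-(k + l) * t)) / (k + l)

#' Top-of-canopy bidirectional reflectance (4SAIL, batched)
#'
#' The SAIL turbid-medium canopy model with hot-spot correction, driven by
#' [prospect_leaf()] leaf optics, the Campbell leaf-angle distribution and
#' a wet/dry mixed soil background. Vectorized over parameter records:
#' `params` rows share the viewing geometry but vary in all nine model
#' parameters.
#'
#' @param params Data frame with columns `N`, `Cab`, `Car`, `Cw`, `Cm`,
#'   `LAI`, `Cam_alpha`, `Hspot`, `Psoil` (units as in
#'   [default_param_spec()]).
#' @param soil Soil endmember list from [default_soil_spectra()] (or a
#'   user-supplied list of `wet`/`dry` spectrum tibbles on the simulation
#'   grid).
#' @param geometry List with solar zenith `sza`, view zenith `vza` and
#'   relative azimuth `raa`, all degrees. Default is the nadir-viewing
#'   top-view camera with the sun at 30 degrees.
#' @param constants Leaf optical constants on the simulation grid.
#' @return Matrix (records x bands) of bidirectional reflectance in
#'   \[0, 1\] with a `wavelengths_nm` attribute. With `LAI = 0` a record's
#'   spectrum equals its mixed soil background.
#' @export
simulate_reflectance <- function(params,
                                 soil = default_soil_spectra(),
                                 geometry = default_geometry(),
                                 constants = leaf_optical_constants()) {
  params <- validate_prosail_params(params)
  wl <- constants$wavelength_nm
  if (!isTRUE(all.equal(as.numeric(soil$dry$wavelength_nm), as.numeric(wl)))) {
    stop("soil spectra must be on the simulation wavelength grid", call. = FALSE)
  }
  n <- nrow(params)
  nb <- length(wl)

  leaf <- prospect_leaf(params, constants)
  rho <- leaf$reflectance
  tau <- leaf$transmittance
  rsoil <- mix_soil(soil, params$Psoil)

  tts <- geometry$sza; tto <- geometry$vza; psi <- geometry$raa
  rd <- pi / 180
  cts <- cos(rd * tts); cto <- cos(rd * tto)
  ctscto <- cts * cto
  tants <- tan(rd * tts); tanto <- tan(rd * tto)
  cospsi <- cos(rd * psi)
  dso <- sqrt(tants^2 + tanto^2 - 2 * tants * tanto * cospsi)

  # class-level geometry factors (shared), weighted by per-record LAD
  b <- lidf_class_bounds()
  litab <- (b$lower + b$upper) / 2
  vs <- vapply(litab, function(ttl) volscatt(tts, tto, psi, ttl), numeric(4))
  ksli <- vs["chi_s", ] / cts
  koli <- vs["chi_o", ] / cto
  sobli <- vs["frho", ] * pi / ctscto
  sofli <- vs["ftau", ] * pi / ctscto
  bfli <- cos(rd * litab)^2

  lidf <- campbell_lidf_matrix(params$Cam_alpha)  # n x 13
  ks <- drop(lidf %*% ksli)
  ko <- drop(lidf %*% koli)
  bf <- drop(lidf %*% bfli)
  sob <- drop(lidf %*% sobli)
  sof <- drop(lidf %*% sofli)

  sdb <- 0.5 * (ks + bf); sdf <- 0.5 * (ks - bf)
  dob <- 0.5 * (ko + bf); dof <- 0.5 * (ko - bf)
  ddb <- 0.5 * (1 + bf); ddf <- 0.5 * (1 - bf)

  # n-vector * (n x b) matrix products recycle records down rows
  sigb <- ddb * rho + ddf * tau
  sigf <- ddf * rho + ddb * tau
  att <- 1 - sigf
  m2 <- (att + sigb) * (att - sigb)
  m2[m2 < 0] <- 0
  m <- sqrt(m2)
  sb <- sdb * rho + sdf * tau
  sf <- sdf * rho + sdb * tau
  vb <- dob * rho + dof * tau
  vf <- dof * rho + dob * tau
  w <- sob * rho + sof * tau

  lai <- params$LAI
  hspot <- params$Hspot

  e1 <- exp(-m * lai)
  e2 <- e1^2
  rinf <- ifelse(abs(sigb) < 1e-30, 0, (att - m) / pmax(sigb, 1e-30))
  rinf2 <- rinf^2
  re <- rinf * e1
  denom <- 1 - rinf2 * e2
  denom[abs(denom) < 1e-12] <- 1e-12

  J1ks <- sail_j1(ks, m, lai)
  J2ks <- sail_j2(ks, m, lai)
  J1ko <- sail_j1(ko, m, lai)
  J2ko <- sail_j2(ko, m, lai)

  Ps <- (sf + sb * rinf) * J1ks
  Qs <- (sf * rinf + sb) * J2ks
  Pv <- (vf + vb * rinf) * J1ko
  Qv <- (vf * rinf + vb) * J2ko

  rdd <- rinf * (1 - e2) / denom
  tdd <- (1 - rinf2) * e1 / denom
  tsd <- (Ps - re * Qs) / denom
  rsd <- (Qs - re * Ps) / denom
  tdo <- (Pv - re * Qv) / denom
  rdo <- (Qv - re * Pv) / denom

  tss <- exp(-ks * lai)
  too <- exp(-ko * lai)

  z <- sail_j2(ks, ko, lai)
  g1 <- (z - J1ks * too) / (ko + m)
  g2 <- (z - J1ko * tss) / (ks + m)
  Tv1 <- (vf * rinf + vb) * g1
  Tv2 <- (vf + vb * rinf) * g2
  T1 <- Tv1 * (sf + sb * rinf)
  T2 <- Tv2 * (sf * rinf + sb)
  T3 <- (rdo * Qs + tdo * Ps) * rinf
  rsod <- (T1 + T2 - T3) / (1 - rinf2)

  # hot-spot single scattering (per-record scalars)
  hs <- hotspot_integral(ks, ko, lai, hspot, dso)
  rsos <- w * lai * hs$sumint
  rso <- rsos + rsod

  dn <- 1 - rsoil * rdd
  rsost <- rsos + hs$tsstoo * rsoil
  rsodt <- rsod + ((tss + tsd) * tdo + (tsd + tss * rsoil * rdd) * too) *
    rsoil / dn
  rsot <- rsost + rsodt

  zero <- lai <= 0
  if (any(zero)) rsot[zero, ] <- rsoil[zero, , drop = FALSE]

  rsot <- pmin(pmax(rsot, 0), 1)
  attr(rsot, "wavelengths_nm") <- wl
  rownames(rsot) <- NULL
  rsot
}

# Kuusk hot-spot integral: bidirectional gap fraction tsstoo and the
# single-scattering integral sumint, vectorized over records.
hotspot_integral <- function(ks, ko, lai, hspot, dso) {
  n <- length(ks)
  tss <- exp(-ks * lai)
  sumint <- numeric(n)
  tsstoo <- numeric(n)
  alf <- rep(1e6, n)
  pos <- hspot > 0
  alf[pos] <- (dso / hspot[pos]) * 2 / (ks[pos] + ko[pos])
  alf <- pmin(alf, 200)

  pure <- alf < 1e-12  # exact hot-spot geometry
  if (any(pure)) {
    tsstoo[pure] <- tss[pure]
    sumint[pure] <- (1 - tss[pure]) / (ks[pure] * pmax(lai[pure], 1e-12))
  }
  gen <- !pure
  if (any(gen)) {
    ksg <- ks[gen]; kog <- ko[gen]; laig <- lai[gen]; alfg <- alf[gen]
    fhot <- laig * sqrt(kog * ksg)
    x1 <- numeric(sum(gen)); y1 <- x1; f1 <- x1 + 1
    fint <- (1 - exp(-alfg)) * 0.05
    si <- numeric(sum(gen))
    for (istep in 1:20) {
      x2 <- if (istep < 20) -log(pmax(1 - istep * fint, 1e-12)) / alfg else rep(1, length(alfg))
      y2 <- -(kog + ksg) * laig * x2 + fhot * (1 - exp(-alfg * x2)) / alfg
      f2 <- exp(y2)
      dy <- y2 - y1
      inc <- ifelse(abs(dy) > 1e-12, (f2 - f1) * (x2 - x1) / dy, f1 * (x2 - x1))
      si <- si + inc
      x1 <- x2; y1 <- y2; f1 <- f2
    }
    sumint[gen] <- si
    tsstoo[gen] <- f1
  }
  list(tsstoo = tsstoo, sumint = sumint)
}

#' Default fixed viewing geometry
#'
#' Nadir-viewing camera (view zenith 0), solar zenith 30 degrees, relative
#' azimuth 0; all angles configurable per run.
#' @return List with `sza`, `vza`, `raa` (degrees).
#' @export
default_geometry <- function() list(sza = 30, vza = 0, raa = 0)

#' Validate a table of canopy model parameters
#'
#' Checks presence, finiteness and physical range of the nine model
#' parameters, naming the offending field on failure.
#'
#' @param params Data frame of parameter records.
#' @return The validated tibble (invisibly usable in pipes).
#' @export
validate_prosail_params <- function(params) {
  params <- tibble::as_tibble(params)
  needed <- c("N", "Cab", "Car", "Cw", "Cm", "LAI", "Cam_alpha", "Hspot", "Psoil")
  miss <- setdiff(needed, names(params))
  if (length(miss)) {
    stop("missing parameter column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  chk <- function(field, ok) {
    bad <- !is.finite(params[[field]]) | !ok(params[[field]])
    if (any(bad)) {
      stop(sprintf("parameter %s out of range in %d record(s)", field, sum(bad)),
           call. = FALSE)
    }
  }
  chk("N", function(x) x >= 1)
  chk("Cab", function(x) x >= 0)
  chk("Car", function(x) x >= 0)
  chk("Cw", function(x) x >= 0)
  chk("Cm", function(x) x >= 0)
  chk("LAI", function(x) x >= 0)
  chk("Cam_alpha", function(x) x > 5 & x < 89)
  chk("Hspot", function(x) x > 0)
  chk("Psoil", function(x) x >= 0 & x <= 1)
  params
}

#' Hot-spot parameter from plant morphology
#'
#' The hot-spot parameter is the ratio of effective leaf size to canopy
#' height. Effective leaf diameter is derived from total leaf area spread
#' over three leaves per tiller: `d = root(leaf_area / (3 * tillers))`,
#' with the root being the square root by default (dimensional consistency:
#' area to length) or optionally the cube root.
#'
#' @param leaf_area Total plant leaf area (cm2).
#' @param tiller_number Number of tillering stems.
#' @param canopy_height Canopy height (cm).
#' @param root Either "sqrt" (default) or "cbrt".
#' @return Hspot, unitless.
#' @export
derive_hspot <- function(leaf_area, tiller_number, canopy_height,
                         root = c("sqrt", "cbrt")) {
  root <- match.arg(root)
  if (any(leaf_area <= 0) || any(tiller_number <= 0) || any(canopy_height <= 0)) {
    stop("leaf_area, tiller_number and canopy_height must be positive", call. = FALSE)
  }
  per_leaf <- leaf_area / (3 * tiller_number)
  diameter <- if (root == "sqrt") sqrt(per_leaf) else per_leaf^(1 / 3)
  diameter / canopy_height
}
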