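# Forward radiative-transfer model: leaf optics, canopy reflectance,
# leaf-angle distribution and hot-spot derivation.

test_that("average surface transmissivity matches numerical Fresnel integration", {
  fresnel_t <- function(th, n) {
    st <- sin(th); ct <- cos(th)
    stt <- st / n; ctt <- sqrt(1 - stt^2)
    rs <- ((ct - n * ctt) / (ct + n * ctt))^2
    rp <- ((n * ct - ctt) / (n * ct + ctt))^2
    1 - (rs + rp) / 2
  }
  tav_num <- function(thmax, n) {
    num <- stats::integrate(function(th) fresnel_t(th, n) * sin(th) * cos(th),
                            0, thmax * pi / 180)$value
    den <- stats::integrate(function(th) sin(th) * cos(th),
                            0, thmax * pi / 180)$value
    num / den
  }
  for (n in c(1.3, 1.4, 1.45, 1.52)) {
    expect_equal(canoret:::tav_stern(90, n), tav_num(90, n), tolerance = 1e-4)
    expect_equal(canoret:::tav_stern(40, n), tav_num(40, n), tolerance = 1e-4)
  }
})

test_that("the E1 approximation matches pracma's exponential integral", {
  x <- c(1e-4, 0.01, 0.3, 0.999, 1.001, 2, 5, 20)
  expect_equal(canoret:::expint_e1(x), pracma::expint_E1(x), tolerance = 1e-6)
})

test_that("leaf reflectance and transmittance are physical", {
  lf <- prospect_leaf(typical_params())
  expect_true(all(lf$reflectance >= 0 & lf$reflectance <= 1))
  expect_true(all(lf$transmittance >= 0 & lf$transmittance <= 1))
  expect_true(all(lf$reflectance + lf$transmittance <= 1 + 1e-9))
  wl <- sim_wavelengths()
  # chlorophyll absorption: red trough far below NIR plateau
  expect_lt(lf$reflectance[1, which(wl == 675)], 0.1)
  expect_gt(lf$reflectance[1, which(wl == 800)], 0.3)
})

test_that("zero-LAI canopy equals the mixed soil background (transparent canopy)", {
  p <- typical_params()
  p$LAI <- 0
  for (psoil in c(0, 0.5, 1)) {
    p$Psoil <- psoil
    r <- simulate_reflectance(p)
    soil <- mix_soil(default_soil_spectra(), psoil)
    expect_equal(unname(r[1, ]), unname(soil[1, ]))
  }
})

test_that("soil mixing is linear in Psoil at zero LAI", {
  p <- typical_params()
  p$LAI <- 0
  r0 <- simulate_reflectance(dplyr::mutate(p, Psoil = 0))
  r1 <- simulate_reflectance(dplyr::mutate(p, Psoil = 1))
  rh <- simulate_reflectance(dplyr::mutate(p, Psoil = 0.5))
  expect_equal(unname(rh[1, ]), unname((r0[1, ] + r1[1, ]) / 2))
})

test_that("simulation is deterministic given parameters and soil", {
  p <- typical_params()
  expect_identical(simulate_reflectance(p), simulate_reflectance(p))
})

test_that("stronger absorbers darken their absorption bands", {
  wl <- sim_wavelengths()
  p <- typical_params()
  r <- simulate_reflectance(p)
  # chlorophyll at 670 nm
  r_cab <- simulate_reflectance(dplyr::mutate(p, Cab = 70))
  expect_lt(r_cab[1, which(wl == 670)], r[1, which(wl == 670)])
  # water at the 970 nm overtone
  r_cw <- simulate_reflectance(dplyr::mutate(p, Cw = 0.03))
  expect_lt(r_cw[1, which(wl == 970)], r[1, which(wl == 970)])
  # denser canopy brightens the NIR plateau
  r_lai <- simulate_reflectance(dplyr::mutate(p, LAI = 6))
  expect_gt(r_lai[1, which(wl == 830)], r[1, which(wl == 830)])
})

test_that("reflectance stays in [0,1] over the full sampled parameter space", {
  set.seed(7)
  n <- 1000
  fz <- tibble::tibble(
    N = runif(n, 1.2, 2.2), Cab = runif(n, 5, 90), Car = runif(n, 1, 25),
    Cw = runif(n, 1e-4, 0.08), Cm = runif(n, 1e-4, 0.03),
    LAI = runif(n, 0, 7.5), Cam_alpha = runif(n, 20, 85),
    Hspot = runif(n, 0.005, 0.2), Psoil = runif(n, 0, 1)
  )
  r <- simulate_reflectance(fz)
  expect_true(all(is.finite(r)))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("parameter validation names the offending field", {
  p <- typical_params()
  expect_error(simulate_reflectance(dplyr::mutate(p, Psoil = 1.4)), "Psoil")
  expect_error(simulate_reflectance(dplyr::mutate(p, N = 0.5)), "parameter N")
  expect_error(simulate_reflectance(dplyr::mutate(p, Cab = -3)), "Cab")
  expect_error(simulate_reflectance(dplyr::select(p, -"LAI")), "missing")
})

test_that("Campbell class probabilities are a normalized density", {
  for (a in c(20, 35, 57.3, 70, 85)) {
    d <- campbell_lad_density(a)
    expect_equal(sum(d$density), 1, tolerance = 1e-9)
    expect_true(all(d$density >= 0))
  }
  expect_error(campbell_lad_density(3), "alpha")
  expect_error(campbell_lad_density(92), "alpha")
})

test_that("spherical-equivalent alpha reproduces the spherical LAD tabulation", {
  # the eccentricity polynomial crosses 1 at the spherical-equivalent
  # mean angle; at that alpha the class probabilities must equal the
  # spherical tabulation cos(lower) - cos(upper)
  excent <- function(a) exp(-1.6184e-5 * a^3 + 2.1145e-3 * a^2 -
                              1.2390e-1 * a + 3.2491)
  a_sph <- uniroot(function(a) excent(a) - 1, c(50, 65))$root
  d <- campbell_lad_density(a_sph)
  sph <- cos(d$angle_lower * pi / 180) - cos(d$angle_upper * pi / 180)
  expect_lt(max(abs(d$density - sph)), 5e-3)
})

test_that("discrete class probabilities match the continuous Campbell density", {
  g <- seq(0, 90, length.out = 9001)
  for (a in c(30, 55, 75)) {
    dens <- campbell_density(g, a)
    d <- campbell_lad_density(a)
    cls <- vapply(seq_len(13), function(i) {
      sel <- g >= d$angle_lower[i] & g < d$angle_upper[i]
      sum(dens[sel]) * (g[2] - g[1]) * pi / 180
    }, numeric(1))
    expect_lt(max(abs(d$density - cls)), 5e-4)
  }
})

test_that("larger alpha shifts leaf-angle mass to steeper classes", {
  mean_angle <- vapply(c(25, 40, 55, 70, 85), function(a) {
    d <- campbell_lad_density(a)
    sum(d$angle_mid * d$density)
  }, numeric(1))
  expect_true(all(diff(mean_angle) > 0))
})

test_that("hot-spot derivation follows the leaf-size to canopy-height ratio", {
  expect_equal(derive_hspot(300, 25, 100), 0.02)   # sqrt(300/75) = 2 over 100
  expect_equal(derive_hspot(12, 4, 10), 0.1)       # sqrt(12/12) = 1 over 10
  expect_equal(derive_hspot(300, 25, 200), 0.01)   # doubling height halves it
  expect_equal(derive_hspot(8, 2, 10, root = "cbrt"), (8 / 6)^(1 / 3) / 10)
  expect_error(derive_hspot(-1, 2, 10), "positive")
  expect_error(derive_hspot(10, 0, 10), "positive")
})

test_that("the hot spot brightens the retro-reflection geometry", {
  p <- typical_params()
  geom_hot <- list(sza = 30, vza = 30, raa = 0)    # sun-sensor aligned
  geom_off <- list(sza = 30, vza = 30, raa = 90)
  wl <- sim_wavelengths()
  i <- which(wl == 850)
  r_hot <- simulate_reflectance(p, geometry = geom_hot)[1, i]
  r_off <- simulate_reflectance(p, geometry = geom_off)[1, i]
  expect_gt(r_hot, r_off)
  # at the exact retro-reflection point the reflectance is independent of
  # the hot-spot parameter (the lobe is fully correlated); the parameter
  # widens the lobe, so a larger Hspot brightens geometries NEAR the peak
  geom_near <- list(sza = 30, vza = 24, raa = 0)
  r_near <- simulate_reflectance(p, geometry = geom_near)[1, i]
  r_big <- simulate_reflectance(dplyr::mutate(p, Hspot = 0.15),
                                geometry = geom_near)[1, i]
  expect_gt(r_big, r_near)
})
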