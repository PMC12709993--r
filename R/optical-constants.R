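#' Synthetic leaf optical constants
#'
#' Smooth analytic stand-ins for the tabulated PROSPECT-5 inputs: leaf
#' refractive index and specific absorption coefficients of chlorophyll a+b
#' (cm2 ug-1), carotenoids (cm2 ug-1), water (cm-1) and dry matter
#' (cm2 g-1). The curves are sums of Gaussians placed at the literature
#' absorption features (chlorophyll 420/675 nm, carotenoids 450-500 nm,
#' water 970/1200/1450/1930 nm overtones, dry-matter SWIR bands) with
#' magnitudes chosen so that typical rice leaf parameter values reproduce
#' realistic leaf reflectance/transmittance levels. They are synthetic
#' constructions, not the calibrated PROSPECT coefficient tables.
#'
#' @param wavelengths_nm Wavelengths (nm) at which to evaluate.
#' @return Tibble with columns `wavelength_nm`, `refractive_index`, `k_cab`,
#'   `k_car`, `k_cw`, `k_cm`.
#' @export
leaf_optical_constants <- function(wavelengths_nm = sim_wavelengths()) {
  wl <- as.numeric(wavelengths_nm)
  g <- function(center, width) exp(-((wl - center) / width)^2)
  tibble::tibble(
    wavelength_nm = wl,
    refractive_index = 1.30 + 0.22 * exp(-(wl - 400) / 1200),
    k_cab = 0.10 * g(420, 45) + 0.035 * g(480, 90) + 0.072 * g(672, 32),
    k_car = 0.12 * g(455, 45) + 0.06 * g(500, 30),
    k_cw  = 0.9 * g(975, 55) + 2.2 * g(1200, 70) + 45 * g(1450, 90) +
      110 * g(1930, 115) + 60 * g(2500, 180),
    k_cm  = 0.5 + 18 * g(1720, 120) + 60 * g(2100, 150) + 40 * g(2300, 120)
  )
}

#' Preset wet/dry soil endmember spectra
#'
#' Synthetic smooth endmembers for paddy soil: the dry surface is brighter
#' at every band, the wet (flooded) surface is darker with water-absorption
#' dips near 970, 1450 and 1930 nm. Soil background reflectance for a run is
#' the linear mix `Psoil * dry + (1 - Psoil) * wet`. Users can replace the
#' presets with measured endmembers via a two-column CSV
#' (`wavelength_nm, reflectance`) and [read_spectrum_csv()].
#'
#' @param wavelengths_nm Wavelengths (nm) at which to evaluate.
#' @return List with spectrum tibbles `wet` and `dry`.
#' @export
default_soil_spectra <- function(wavelengths_nm = sim_wavelengths()) {
  wl <- as.numeric(wavelengths_nm)
  g <- function(center, width) exp(-((wl - center) / width)^2)
  dry <- 0.10 + 0.30 * (1 - exp(-(wl - 400) / 800))
  wet <- dry * (0.55 - 0.12 * g(975, 80) - 0.25 * g(1450, 120) - 0.30 * g(1930, 140))
  list(wet = spectrum(wl, pmax(wet, 0)), dry = spectrum(wl, dry))
}

#' Mix soil endmembers by the soil humidity factor
#'
#' @param soil List with `wet` and `dry` spectrum tibbles on one grid.
#' @param psoil Mixing factor(s) in \[0, 1\]; 0 = wet, 1 = dry.
#' @return Matrix (length(psoil) x bands) with `wavelengths_nm` attribute.
#' @export
mix_soil <- function(soil, psoil) {
  if (any(psoil < 0 | psoil > 1)) stop("Psoil must lie in [0, 1]", call. = FALSE)
  wl <- soil$dry$wavelength_nm
  if (!isTRUE(all.equal(wl, soil$wet$wavelength_nm))) {
    stop("wet and dry soil spectra must share one grid", call. = FALSE)
  }
  if (any(soil$dry$reflectance < soil$wet$reflectance - 1e-9)) {
    stop("dry soil reflectance must be >= wet reflectance band-wise", call. = FALSE)
  }
  out <- outer(psoil, soil$dry$reflectance) + outer(1 - psoil, soil$wet$reflectance)
  attr(out, "wavelengths_nm") <- wl
  out
}

#' Read a two-column spectrum CSV (wavelength_nm, reflectance)
#' @param path CSV file path.
#' @return A spectrum tibble.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  spectrum(df[[1]], df[[2]])
}

#' Write a spectrum tibble to CSV
#' @param s Spectrum tibble.
#' @param path Output path.
#' @export
write_spectrum_csv <- function(s, path) {
  utils::write.csv(
    data.frame(wavelength_nm = s$wavelength_nm, reflectance = s$reflectance),
    path, row.names = FALSE
  )
}
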