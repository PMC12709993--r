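#' Spectral grids and spectrum objects
#'
#' A spectrum is represented as a tibble with columns `wavelength_nm`
#' (strictly increasing band centers) and `reflectance` (unitless, in
#' \[0, 1\]). Collections of spectra (look-up tables, image pixels) are
#' stored as numeric matrices (records x bands) with a `wavelengths_nm`
#' attribute; `spectrum()` and `spectra_matrix()` convert between the two.
#'
#' @name spectrum
NULL

#' Native simulation wavelength grid (395-2500 nm, 1 nm)
#'
#' The radiative-transfer forward model simulates top-of-canopy reflectance
#' on this grid; camera-domain work resamples onto [camera_grid()]. The
#' grid starts 5 nm below the classic 400 nm lower edge so that the
#' camera's 397 nm first band lies inside the simulated range.
#'
#' @return Integer vector of wavelengths in nm.
#' @export
sim_wavelengths <- function() 395:2500

#' Hyperspectral camera wavelength grid
#'
#' 203 band centers spanning 397-1006 nm at ~3 nm sampling, matching a
#' portable VNIR imaging spectrometer.
#'
#' @return Numeric vector of 203 wavelengths in nm.
#' @export
camera_grid <- function() seq(397, 1006, length.out = 203L)

#' Construct a spectrum tibble
#'
#' @param wavelengths_nm Strictly increasing numeric vector of band centers.
#' @param reflectance Numeric vector of the same length, values in \[0, 1\].
#' @return A tibble with columns `wavelength_nm`, `reflectance`.
#' @export
spectrum <- function(wavelengths_nm, reflectance) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  reflectance <- as.numeric(reflectance)
  if (length(wavelengths_nm) != length(reflectance)) {
    stop("wavelengths_nm and reflectance must have equal length", call. = FALSE)
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths_nm must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(reflectance)) ||
      any(reflectance < -1e-9) || any(reflectance > 1 + 1e-9)) {
    stop("reflectance values must be finite and in [0, 1]", call. = FALSE)
  }
  tibble::tibble(
    wavelength_nm = wavelengths_nm,
    reflectance = pmin(pmax(reflectance, 0), 1)
  )
}

#' Stack spectra into a records-by-bands matrix
#'
#' @param x A numeric matrix, a single spectrum tibble, or a list of spectrum
#'   tibbles sharing one grid.
#' @param wavelengths_nm Grid to attach when `x` is a bare matrix.
#' @return Numeric matrix with attribute `wavelengths_nm`.
#' @export
spectra_matrix <- function(x, wavelengths_nm = NULL) {
  if (is.matrix(x)) {
    if (is.null(wavelengths_nm)) wavelengths_nm <- attr(x, "wavelengths_nm")
    if (is.null(wavelengths_nm) || length(wavelengths_nm) != ncol(x)) {
      stop("a wavelengths_nm vector matching ncol(x) is required", call. = FALSE)
    }
    attr(x, "wavelengths_nm") <- as.numeric(wavelengths_nm)
    return(x)
  }
  if (is.data.frame(x)) x <- list(x)
  wl <- x[[1]]$wavelength_nm
  mat <- do.call(rbind, lapply(x, function(s) {
    if (!isTRUE(all.equal(s$wavelength_nm, wl))) {
      stop("all spectra must share one wavelength grid", call. = FALSE)
    }
    s$reflectance
  }))
  attr(mat, "wavelengths_nm") <- as.numeric(wl)
  mat
}

#' Resample a spectrum onto a target wavelength grid
#'
#' Linear interpolation; the canonical use is bridging the 1 nm simulation
#' grid to the 203-band camera grid. Resampling onto a spectrum's own grid is
#' the identity, and resampling twice onto the same grid is idempotent.
#'
#' @param s A spectrum tibble or a records-by-bands matrix from
#'   [spectra_matrix()].
#' @param grid Target wavelengths (nm); must lie within the source range.
#' @return Object of the same kind as `s`, on `grid`.
#' @export
resample_to_camera_grid <- function(s, grid = camera_grid()) {
  grid <- as.numeric(grid)
  if (is.matrix(s)) {
    wl <- attr(s, "wavelengths_nm")
    if (is.null(wl)) stop("matrix input needs a wavelengths_nm attribute", call. = FALSE)
    check_grid_range(grid, wl)
    # vectorized linear interpolation: gather the bracketing columns
    i0 <- findInterval(grid, wl, rightmost.closed = TRUE)
    i0 <- pmin(pmax(i0, 1L), length(wl) - 1L)
    w <- (grid - wl[i0]) / (wl[i0 + 1L] - wl[i0])
    out <- s[, i0, drop = FALSE] *
      matrix(1 - w, nrow(s), length(grid), byrow = TRUE) +
      s[, i0 + 1L, drop = FALSE] *
      matrix(w, nrow(s), length(grid), byrow = TRUE)
    attr(out, "wavelengths_nm") <- grid
    return(out)
  }
  check_grid_range(grid, s$wavelength_nm)
  y <- stats::approx(s$wavelength_nm, s$reflectance, xout = grid)$y
  spectrum(grid, y)
}

check_grid_range <- function(grid, wl) {
  if (min(grid) < min(wl) - 1e-9 || max(grid) > max(wl) + 1e-9) {
    stop(sprintf(
      "target grid [%.1f, %.1f] nm outside source range [%.1f, %.1f] nm",
      min(grid), max(grid), min(wl), max(wl)
    ), call. = FALSE)
  }
}

#' Indices of bands inside a wavelength window
#'
#' @param wavelengths_nm Band centers.
#' @param window Length-2 numeric `c(low, high)` in nm.
#' @return Integer indices.
#' @export
band_window <- function(wavelengths_nm, window) {
  idx <- which(wavelengths_nm >= window[1] & wavelengths_nm <= window[2])
  if (length(idx) == 0L) stop("band window selects no bands", call. = FALSE)
  idx
}

#' Index of the band nearest to a target wavelength
#' @param wavelengths_nm Band centers.
#' @param target_nm Target wavelength (nm).
#' @return Integer index.
#' @export
nearest_band <- function(wavelengths_nm, target_nm) {
  which.min(abs(wavelengths_nm - target_nm))
}
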