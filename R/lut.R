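#' Build a Monte-Carlo look-up table
#'
#' Samples `n` parameter records from the prior spec, optionally perturbs
#' them with distribution-consistent noise, simulates top-of-canopy
#' reflectance for each record with [simulate_reflectance()], resamples onto
#' the camera grid and derives the canopy traits CCC and CEW. The table is
#' both the inversion database and the pre-training dataset.
#'
#' @param spec Parameter distribution spec ([default_param_spec()]).
#' @param n Number of records (default 7000).
#' @param seed Integer seed; the table is bit-reproducible given the seed.
#' @param soil Soil endmembers ([default_soil_spectra()]).
#' @param grid Camera wavelength grid ([camera_grid()]).
#' @param geometry Viewing geometry ([default_geometry()]).
#' @param noise_scale Parameter-noise scale passed to
#'   [inject_parameter_noise()] (default 0.05); the stored records are the
#'   perturbed parameters, so every record's spectrum and traits remain
#'   exactly consistent with its parameters.
#' @param correlation Optional parameter correlation matrix (Gaussian
#'   copula).
#' @param chunk_size Records simulated per chunk (memory control).
#' @return A `canoret_lut`: list with `params` (tibble incl. `CCC`, `CEW`),
#'   `spectra` (n x bands matrix), `wavelengths_nm`, and provenance fields
#'   `spec`, `seed`, `noise_scale`, `geometry`.
#' @export
build_lut <- function(spec = default_param_spec(), n = 7000L, seed = 1L,
                      soil = default_soil_spectra(), grid = camera_grid(),
                      geometry = default_geometry(), noise_scale = 0.05,
                      correlation = NULL, chunk_size = 500L) {
  params <- sample_parameters(spec, n, seed = seed, correlation = correlation)
  params <- inject_parameter_noise(params, spec, noise_scale = noise_scale,
                                   seed = seed + 1L)
  constants <- leaf_optical_constants()
  spectra <- matrix(NA_real_, n, length(grid))
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk_size))
  for (ii in idx) {
    sim <- simulate_reflectance(params[ii, , drop = FALSE], soil = soil,
                                geometry = geometry, constants = constants)
    spectra[ii, ] <- resample_to_camera_grid(sim, grid)
  }
  attr(spectra, "wavelengths_nm") <- as.numeric(grid)
  structure(
    list(
      params = add_canopy_traits(params),
      spectra = spectra,
      wavelengths_nm = as.numeric(grid),
      spec = spec, seed = seed, noise_scale = noise_scale,
      geometry = geometry
    ),
    class = "canoret_lut"
  )
}

#' @export
print.canoret_lut <- function(x, ...) {
  cat(sprintf(
    "<canoret_lut> %d records x %d bands (%.0f-%.0f nm), seed %d\n",
    nrow(x$spectra), ncol(x$spectra),
    min(x$wavelengths_nm), max(x$wavelengths_nm), x$seed
  ))
  invisible(x)
}

#' @method tidy canoret_lut
#' @export
tidy.canoret_lut <- function(x, ...) x$params

#' Spectral cost between a measured and a simulated spectrum
#'
#' Root-sum-of-squares distance over a selected band window (the retrieval
#' cost function). The square root is monotone, so inversion ranks are
#' identical with `take_sqrt = FALSE` (plain sum of squares).
#'
#' @param measured,simulated Spectrum tibbles or numeric vectors on one grid.
#' @param window Optional `c(low, high)` nm window; default uses all bands.
#' @param wavelengths_nm Grid for bare numeric vectors.
#' @param take_sqrt Apply the square root (default TRUE).
#' @return Non-negative scalar; zero iff the spectra agree on the window.
#' @export
hellinger_cost <- function(measured, simulated, window = NULL,
                           wavelengths_nm = NULL, take_sqrt = TRUE) {
  get_vec <- function(s) {
    if (is.data.frame(s)) list(wl = s$wavelength_nm, y = s$reflectance)
    else list(wl = wavelengths_nm, y = as.numeric(s))
  }
  m <- get_vec(measured)
  s <- get_vec(simulated)
  if (length(m$y) != length(s$y)) stop("spectra must be on identical grids", call. = FALSE)
  if (!is.null(m$wl) && !is.null(s$wl) && !isTRUE(all.equal(m$wl, s$wl))) {
    stop("spectra must be on identical grids", call. = FALSE)
  }
  idx <- seq_along(m$y)
  if (!is.null(window)) {
    if (is.null(m$wl)) stop("window selection needs wavelengths", call. = FALSE)
    idx <- band_window(m$wl, window)
  }
  ss <- sum((m$y[idx] - s$y[idx])^2)
  if (take_sqrt) sqrt(ss) else ss
}

#' Look-up-table inversion of measured spectra
#'
#' Exhaustive nearest-cost search: every LUT record's simulated spectrum is
#' compared to the measured spectrum with the root-sum-of-squares cost over
#' the trait-sensitive band window, and the lowest-cost record's parameters
#' (and derived CCC/CEW) are returned. Ties break to the lowest record
#' index.
#'
#' @param measured A spectrum tibble, a records-x-bands matrix on the LUT
#'   grid, or a numeric vector (LUT grid assumed).
#' @param lut A `canoret_lut`.
#' @param window Band window in nm; the default 742-841 nm is the
#'   drought-indicative window identified by the band-screening module.
#' @param k Number of ranked candidates to keep per spectrum.
#' @return Tibble with one row per measured spectrum: `sample`, `cost`,
#'   `record`, the retrieved parameters and `CCC`/`CEW`; when `k > 1` a
#'   list-column `top_k` holds the ranked candidate tibble
#'   (`record`, `cost`, parameters) in non-decreasing cost order.
#' @export
lut_invert <- function(measured, lut, window = c(742, 841), k = 1L) {
  stopifnot(inherits(lut, "canoret_lut"))
  if (nrow(lut$spectra) == 0L) stop("empty look-up table", call. = FALSE)
  X <- as_measured_matrix(measured, lut$wavelengths_nm)
  idx <- if (is.null(window)) seq_along(lut$wavelengths_nm) else
    band_window(lut$wavelengths_nm, window)

  Xs <- X[, idx, drop = FALSE]
  Ls <- lut$spectra[, idx, drop = FALSE]
  # ||x - l||^2 = ||x||^2 + ||l||^2 - 2 x.l, one GEMM for all pairs
  d2 <- outer(rowSums(Xs^2), rowSums(Ls^2), "+") - 2 * Xs %*% t(Ls)
  d2[d2 < 0] <- 0
  cost <- sqrt(d2)

  best <- apply(cost, 1L, which.min)
  out <- dplyr::bind_cols(
    tibble::tibble(sample = seq_len(nrow(X)),
                   record = as.integer(best),
                   cost = cost[cbind(seq_len(nrow(X)), best)]),
    lut$params[best, , drop = FALSE]
  )
  if (k > 1L) {
    out$top_k <- purrr::map(seq_len(nrow(X)), function(i) {
      ord <- order(cost[i, ], seq_len(ncol(cost)))[seq_len(min(k, ncol(cost)))]
      dplyr::bind_cols(
        tibble::tibble(record = ord, cost = cost[i, ord]),
        lut$params[ord, , drop = FALSE]
      )
    })
  }
  out
}

as_measured_matrix <- function(measured, wavelengths_nm) {
  if (is.data.frame(measured)) {
    if (!isTRUE(all.equal(as.numeric(measured$wavelength_nm),
                          as.numeric(wavelengths_nm)))) {
      stop("measured spectrum is not on the LUT wavelength grid", call. = FALSE)
    }
    matrix(measured$reflectance, nrow = 1L)
  } else if (is.matrix(measured)) {
    wl <- attr(measured, "wavelengths_nm")
    if (!is.null(wl) && !isTRUE(all.equal(as.numeric(wl), as.numeric(wavelengths_nm)))) {
      stop("measured spectra are not on the LUT wavelength grid", call. = FALSE)
    }
    if (ncol(measured) != length(wavelengths_nm)) {
      stop("measured spectra are not on the LUT wavelength grid", call. = FALSE)
    }
    measured
  } else {
    if (length(measured) != length(wavelengths_nm)) {
      stop("measured spectrum is not on the LUT wavelength grid", call. = FALSE)
    }
    matrix(as.numeric(measured), nrow = 1L)
  }
}

#' Serialize a look-up table to a directory
#'
#' Writes `params.csv` (parameters + traits), `spectra.csv` (dense
#' records-x-bands reflectance, band wavelengths as header) and
#' `meta.json` (spec, seed, noise scale, geometry).
#'
#' @param lut A `canoret_lut`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_lut <- function(lut, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(lut$params, file.path(dir, "params.csv"), row.names = FALSE)
  sp <- as.data.frame(lut$spectra)
  names(sp) <- sprintf("wl_%.4f", lut$wavelengths_nm)
  utils::write.csv(sp, file.path(dir, "spectra.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(spec = lut$spec, seed = lut$seed, noise_scale = lut$noise_scale,
         geometry = lut$geometry),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a look-up table written by [write_lut()]
#' @param dir Directory path.
#' @return A `canoret_lut`.
#' @export
read_lut <- function(dir) {
  params <- tibble::as_tibble(utils::read.csv(file.path(dir, "params.csv")))
  sp <- utils::read.csv(file.path(dir, "spectra.csv"), check.names = FALSE)
  wl <- as.numeric(sub("^wl_", "", names(sp)))
  spectra <- unname(as.matrix(sp))
  attr(spectra, "wavelengths_nm") <- wl
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  structure(
    list(params = params, spectra = spectra, wavelengths_nm = wl,
         spec = tibble::as_tibble(meta$spec), seed = meta$seed,
         noise_scale = meta$noise_scale, geometry = as.list(meta$geometry)),
    class = "canoret_lut"
  )
}
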