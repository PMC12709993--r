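#' Top-view hyperspectral cube
#'
#' @param data 3-D numeric array (rows x cols x bands), non-negative.
#' @param wavelengths_nm Band centers (default the camera grid).
#' @param white_reference Per-band calibration spectrum of the standard
#'   whiteboard (strictly positive); `NULL` marks an already-calibrated
#'   cube.
#' @return A `canoret_cube`.
#' @export
hyperspectral_cube <- function(data, wavelengths_nm = camera_grid(),
                               white_reference = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L || dim(data)[3] != length(wavelengths_nm)) {
    stop("data must be rows x cols x bands matching wavelengths_nm", call. = FALSE)
  }
  if (any(data < 0)) stop("cube values must be non-negative", call. = FALSE)
  structure(
    list(data = data, wavelengths_nm = as.numeric(wavelengths_nm),
         white_reference = white_reference, calibrated = is.null(white_reference)),
    class = "canoret_cube"
  )
}

#' @export
print.canoret_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<canoret_cube> %d x %d pixels, %d bands (%.0f-%.0f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm),
              if (x$calibrated) "calibrated" else "raw"))
  invisible(x)
}

#' Whiteboard reflectance calibration
#'
#' Divides every pixel spectrum band-wise by the white-reference spectrum,
#' clips to \[0, 1.5\] and then to \[0, 1\]; the number of clipped values is
#' recorded in the `clipped` attribute.
#'
#' @param cube A raw `canoret_cube` with a `white_reference`.
#' @return A calibrated `canoret_cube` (values in \[0, 1\]).
#' @export
calibrate_reflectance <- function(cube) {
  stopifnot(inherits(cube, "canoret_cube"))
  wr <- cube$white_reference
  if (is.null(wr)) return(cube)
  if (any(wr <= 0)) stop("white reference must be strictly positive in every band",
                         call. = FALSE)
  d <- dim(cube$data)
  refl <- cube$data / rep(wr, each = d[1] * d[2])
  refl <- pmin(refl, 1.5)
  n_clip <- sum(refl > 1)
  refl <- pmin(refl, 1)
  out <- hyperspectral_cube(refl, cube$wavelengths_nm, white_reference = NULL)
  attr(out, "clipped") <- n_clip
  out
}

#' Plant/soil segmentation by vegetation-index thresholds
#'
#' Computes per-pixel EVI `2.5 (NIR - R) / (NIR + 6 R - 7.5 B + 1)` and
#' NDVI `(NIR - R) / (NIR + R)` from the bands nearest 895 (NIR),
#' 667 (red) and 517 nm (blue). Plant pixels have EVI above `t_evi`; of
#' the remaining pixels, soil pixels have NDVI below `t_ndvi`; anything
#' else is background. The masks are disjoint by construction.
#'
#' @param cube A calibrated `canoret_cube`.
#' @param t_evi EVI plant threshold (default 0.2).
#' @param t_ndvi NDVI soil threshold (default 0.2).
#' @return List with logical matrices `plant_mask`, `soil_mask` and the
#'   index images `evi`, `ndvi`.
#' @export
segment_cube <- function(cube, t_evi = 0.2, t_ndvi = 0.2) {
  stopifnot(inherits(cube, "canoret_cube"))
  if (!cube$calibrated) stop("calibrate the cube before segmentation", call. = FALSE)
  wl <- cube$wavelengths_nm
  need <- c(NIR = 895, R = 667, B = 517)
  if (min(wl) > min(need) || max(wl) < max(need)) {
    stop("cube grid does not cover the 517/667/895 nm index bands", call. = FALSE)
  }
  nir <- cube$data[, , nearest_band(wl, need["NIR"])]
  red <- cube$data[, , nearest_band(wl, need["R"])]
  blue <- cube$data[, , nearest_band(wl, need["B"])]
  evi <- 2.5 * (nir - red) / (nir + 6 * red - 7.5 * blue + 1)
  ndvi <- (nir - red) / pmax(nir + red, 1e-12)
  plant <- evi > t_evi
  soil <- !plant & ndvi < t_ndvi
  list(plant_mask = plant, soil_mask = soil, evi = evi, ndvi = ndvi)
}

#' Mixed plant-soil reflectance of a segmented cube
#'
#' Band-wise mean over all segmented (plant or soil) pixels - the
#' measured spectrum the retrieval methods consume.
#'
#' @param cube A calibrated `canoret_cube`.
#' @param masks Segmentation list from [segment_cube()].
#' @return A spectrum tibble on the cube's grid.
#' @export
mixed_reflectance <- function(cube, masks) {
  sel <- masks$plant_mask | masks$soil_mask
  if (!any(sel)) stop("no segmented pixels to average", call. = FALSE)
  d <- dim(cube$data)
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  spectrum(cube$wavelengths_nm, colMeans(flat[as.vector(sel), , drop = FALSE]))
}

#' Write a cube to an ENVI header + binary pair
#'
#' BSQ interleave, 4-byte little-endian floats; wavelengths stored in the
#' header. The white reference, when present, is written as a sidecar CSV.
#'
#' @param cube A `canoret_cube`.
#' @param path_base Path without extension; writes `<path_base>.hdr`,
#'   `<path_base>.dat` (and `<path_base>_whiteref.csv`).
#' @return `path_base`, invisibly.
#' @export
write_envi <- function(cube, path_base) {
  stopifnot(inherits(cube, "canoret_cube"))
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = {canoret hyperspectral cube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    paste0("wavelength = {",
           paste(sprintf("%.4f", cube$wavelengths_nm), collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path_base, ".hdr"))
  con <- file(paste0(path_base, ".dat"), "wb")
  on.exit(close(con))
  # BSQ: band by band, pixels in row-major (line by line) order
  for (b in seq_len(d[3])) {
    writeBin(as.numeric(t(cube$data[, , b])), con, size = 4L, endian = "little")
  }
  if (!is.null(cube$white_reference)) {
    utils::write.csv(
      data.frame(wavelength_nm = cube$wavelengths_nm,
                 reference = cube$white_reference),
      paste0(path_base, "_whiteref.csv"), row.names = FALSE
    )
  }
  invisible(path_base)
}

#' Read an ENVI cube written by [write_envi()] (BSQ or BIL, float32)
#'
#' @param hdr_path Path to the `.hdr` file.
#' @return A `canoret_cube`; a `<base>_whiteref.csv` sidecar, when
#'   present, populates the white reference.
#' @export
read_envi <- function(hdr_path) {
  lines_ <- readLines(hdr_path, warn = FALSE)
  get_num <- function(key) {
    ln <- grep(sprintf("^%s\\s*=", key), lines_, value = TRUE)[1]
    as.integer(sub(".*=\\s*", "", ln))
  }
  n_samples <- get_num("samples")
  n_lines <- get_num("lines")
  n_bands <- get_num("bands")
  dtype <- get_num("data type")
  if (dtype != 4L) stop("only ENVI data type 4 (float32) is supported", call. = FALSE)
  interleave <- tolower(sub(".*=\\s*", "",
                            grep("^interleave", lines_, value = TRUE)[1]))
  wl_txt <- paste(lines_[seq(grep("^wavelength\\s*=", lines_), length(lines_))],
                  collapse = " ")
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}.*", "", wl_txt), ",")[[1]])

  base <- sub("\\.hdr$", "", hdr_path)
  dat_path <- if (file.exists(paste0(base, ".dat"))) paste0(base, ".dat") else base
  raw <- readBin(dat_path, what = "numeric", size = 4L,
                 n = n_samples * n_lines * n_bands, endian = "little")
  cube <- array(0, c(n_lines, n_samples, n_bands))
  if (interleave == "bsq") {
    for (b in seq_len(n_bands)) {
      off <- (b - 1L) * n_samples * n_lines
      cube[, , b] <- matrix(raw[off + seq_len(n_samples * n_lines)],
                            n_lines, n_samples, byrow = TRUE)
    }
  } else if (interleave == "bil") {
    raw <- array(raw, c(n_samples, n_bands, n_lines))
    cube <- aperm(raw, c(3L, 1L, 2L))
  } else {
    stop("unsupported interleave: ", interleave, call. = FALSE)
  }
  wr <- NULL
  wr_path <- paste0(base, "_whiteref.csv")
  if (file.exists(wr_path)) wr <- utils::read.csv(wr_path)$reference
  hyperspectral_cube(cube, wl, white_reference = wr)
}
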