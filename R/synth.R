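#' Render a synthetic front-view plant image
#'
#' Draws several near-vertical tillers and straight leaf segments whose
#' inclination angles are drawn from the Campbell distribution, as green
#' foreground on a sky/soil background - sufficient structure for
#' excess-green segmentation, Hough angle extraction, convex hull and
#' centroid work, without being a botanical model. Tillers are rendered
#' in stem-brown so only leaf pixels enter the green mask.
#'
#' @param cam_alpha True Campbell mean leaf angle (degrees).
#' @param n_leaves Number of leaf segments (default 100, a dense pot-grown
#'   rice silhouette).
#' @param width,height Image size in pixels (default 384, a moderate
#'   downsample of the camera's native resolution that keeps leaf edges
#'   well sampled).
#' @param leaf_length Segment length in pixels (mean; jittered 20%).
#' @param thickness Segment half-thickness in pixels.
#' @param seed Integer seed.
#' @return List with `image` (rows x cols x 3 array in \[0,1\]), `angles`
#'   (true segment inclinations, degrees), `pot_rim_row`.
#' @export
render_front_view <- function(cam_alpha, n_leaves = 100L, width = 384L,
                              height = 384L, leaf_length = 90, thickness = 1.6,
                              seed = 1L) {
  set.seed(seed)
  img <- array(0, c(height, width, 3L))
  rim <- round(0.92 * height)
  # sky and soil background
  img[1:rim, , 1] <- 0.55; img[1:rim, , 2] <- 0.65; img[1:rim, , 3] <- 0.85
  img[(rim + 1L):height, , 1] <- 0.35
  img[(rim + 1L):height, , 2] <- 0.25
  img[(rim + 1L):height, , 3] <- 0.15

  paint <- function(img, xs, ys, rgb) {
    keep <- xs >= 1 & xs <= width & ys >= 1 & ys <= height
    xs <- xs[keep]; ys <- ys[keep]
    for (k in seq_along(xs)) {
      img[ys[k], xs[k], 1] <- rgb[1]
      img[ys[k], xs[k], 2] <- rgb[2]
      img[ys[k], xs[k], 3] <- rgb[3]
    }
    img
  }
  leaf_rgb <- c(0.10, 0.55, 0.08)
  stem_rgb <- c(0.45, 0.40, 0.20)  # stems read brown, not leaf-green
  draw_segment <- function(img, x0, y0, ang_deg, len, dir, rgb = leaf_rgb) {
    # ang measured from horizontal; y decreases upward in image rows
    t <- seq(0, len, by = 0.5)
    xs <- x0 + dir * cos(ang_deg * pi / 180) * t
    ys <- y0 - sin(ang_deg * pi / 180) * t
    for (off in seq(-thickness, thickness, by = 0.5)) {
      img <- paint(img, round(xs + off * sin(ang_deg * pi / 180)),
                   round(ys + off * cos(ang_deg * pi / 180)), rgb)
    }
    img
  }

  stem_top <- round(0.25 * height)
  n_tillers <- 7L
  tiller_x <- round(seq(0.32, 0.68, length.out = n_tillers) * width) +
    sample(-4:4, n_tillers, replace = TRUE)
  for (tx in tiller_x) {
    img <- draw_segment(img, tx, rim, 90, rim - stem_top, 1, rgb = stem_rgb)
  }

  angles <- sample_campbell_angles(n_leaves, cam_alpha)
  for (i in seq_len(n_leaves)) {
    x0 <- tiller_x[1L + (i - 1L) %% n_tillers]
    y0 <- round(stats::runif(1, stem_top, rim - 4))
    dir <- sample(c(-1, 1), 1)
    len <- leaf_length * stats::runif(1, 0.8, 1.2)
    img <- draw_segment(img, x0, y0, angles[i], len, dir)
  }
  list(image = img, angles = angles, pot_rim_row = rim)
}

#' Generate a ground-truthed synthetic scene
#'
#' Builds a top-view hyperspectral cube (plant pixels carry the simulated
#' canopy spectrum, soil pixels the Psoil-mixed soil background, both
#' under per-pixel multiplicative noise and a known lamp spectrum) plus a
#' rendered front view, with complete truth records.
#'
#' @param params One-row parameter tibble (see
#'   [validate_prosail_params()]).
#' @param plant_fraction Fraction of pixels that are plant, in \[0, 1\].
#' @param size Cube side length in pixels.
#' @param noise_sd Multiplicative spectral noise sd (default 0.01).
#' @param seed Integer seed.
#' @param grid Camera wavelength grid.
#' @return A `canoret_scene`: list with `cube` (raw `canoret_cube` with
#'   white reference), `front_view`, `masks` (truth), `truth` (params,
#'   traits, canopy/soil spectra, leaf angles, phenotype expectations).
#' @export
generate_scene <- function(params, plant_fraction = 0.4, size = 64L,
                           noise_sd = 0.01, seed = 1L, grid = camera_grid()) {
  params <- validate_prosail_params(params)
  stopifnot(nrow(params) == 1L)
  if (plant_fraction < 0 || plant_fraction > 1) {
    stop("plant_fraction must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  soil <- default_soil_spectra()
  canopy <- resample_to_camera_grid(simulate_reflectance(params, soil = soil), grid)
  soil_bg <- resample_to_camera_grid(mix_soil(soil, params$Psoil), grid)
  nb <- length(grid)

  n_px <- size * size
  n_plant <- round(plant_fraction * n_px)
  # plant blob grows from the center outward so masks are spatially coherent
  ctr <- (size + 1) / 2
  d2 <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+")
  ord <- order(as.vector(d2), seq_len(n_px))
  plant_mask <- matrix(FALSE, size, size)
  plant_mask[ord[seq_len(n_plant)]] <- TRUE
  soil_mask <- !plant_mask

  spectra_px <- matrix(0, n_px, nb)
  pm <- as.vector(plant_mask)
  if (any(pm)) {
    noise <- matrix(1 + stats::rnorm(sum(pm) * nb, 0, noise_sd), sum(pm), nb)
    spectra_px[pm, ] <- rep(canopy[1, ], each = sum(pm)) * noise
  }
  if (any(!pm)) {
    noise <- matrix(1 + stats::rnorm(sum(!pm) * nb, 0, noise_sd), sum(!pm), nb)
    spectra_px[!pm, ] <- rep(soil_bg[1, ], each = sum(!pm)) * noise
  }
  spectra_px <- pmin(pmax(spectra_px, 0), 1)
  white_ref <- 0.8 + 0.2 * exp(-((grid - 650) / 400)^2)
  raw <- array(as.vector(spectra_px) * rep(white_ref, each = n_px),
               c(size, size, nb))

  fv <- render_front_view(params$Cam_alpha, seed = seed + 1L)

  structure(
    list(
      cube = hyperspectral_cube(raw, grid, white_reference = white_ref),
      front_view = fv$image,
      masks = list(plant_mask = plant_mask, soil_mask = soil_mask),
      truth = list(
        params = params,
        traits = derive_canopy_traits(params$Cab, params$Cw, params$LAI),
        canopy_spectrum = spectrum(grid, canopy[1, ]),
        soil_spectrum = spectrum(grid, soil_bg[1, ]),
        plant_fraction = plant_fraction,
        leaf_angles = fv$angles,
        pot_rim_row = fv$pot_rim_row
      ),
      seed = seed, noise_sd = noise_sd
    ),
    class = "canoret_scene"
  )
}

#' Generate a measured-like fine-tuning dataset with a sim-to-real gap
#'
#' Stands in for field measurements: parameters are sampled from the
#' prior, spectra are simulated and then degraded by three effects that
#' emulate the simulation-to-reality gap of a real campaign:
#'
#' 1. a multiplicative tilt whose magnitude depends on the phenotype
#'    vector - `tilt = b1 (RHC - 0.5) + b2 (Cam_alpha - 55) / 10`
#'    applied as a linear-in-wavelength ramp - so the phenotype carries
#'    information about the spectral distortion that the spectrum alone
#'    cannot reveal (the structure the hybrid fine-tuned model
#'    exploits);
#' 2. a canopy-structure discrepancy: a smooth NIR-weighted
#'    multiplicative term `c_struct * sin(2 pi LAI / 7.5)` that is a
#'    nonmonotone deterministic function of the true LAI. Real canopies
#'    (row structure, leaf curvature, clumping) deviate from the
#'    turbid-medium model most strongly in the NIR; because the
#'    distortion is deterministic in LAI, regression learners trained on
#'    the measured-like data can learn straight through it, while
#'    nearest-cost search over the undistorted simulated manifold cannot
#'    - reproducing the qualitative failure of pure physical inversion
#'    on measured canopies;
#' 3. multiplicative spectral noise (sd `noise_sd`).
#'
#' The phenotype vector is generated from the true parameters with
#' realistic observation noise (fitted Campbell angle within a couple of
#' degrees; RHC increasing with LAI; hull fill increasing with LAI).
#'
#' @param spec Parameter distribution spec.
#' @param n Number of samples (default 198, a two-season pot campaign).
#' @param gap List with tilt coefficients `b1`, `b2`, the structural
#'   discrepancy amplitude `c_struct`, and `gap_scale` multiplying all
#'   three (0 disables the structured gap entirely).
#' @param noise_sd Multiplicative spectral noise sd (default 0.01).
#' @param seed Integer seed; regeneration is bit-identical.
#' @param grid Camera wavelength grid.
#' @return A `canoret_dataset`: `spectra` (n x bands), `phenotype`
#'   (n x 5 matrix), `traits` (parameters + CCC/CEW), `meta`.
#' @export
generate_measured_like <- function(spec = default_param_spec(), n = 198L,
                                   gap = list(b1 = 0.3, b2 = 0.15,
                                              c_struct = 0.12,
                                              gap_scale = 1),
                                   noise_sd = 0.01, seed = 1L,
                                   grid = camera_grid()) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  gap$gap_scale <- gap$gap_scale %||% 1
  params <- sample_parameters(spec, n, seed = seed)
  spectra <- matrix(0, n, length(grid))
  soil <- default_soil_spectra()
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 500))
  for (ii in chunks) {
    sim <- simulate_reflectance(params[ii, , drop = FALSE], soil = soil)
    spectra[ii, ] <- resample_to_camera_grid(sim, grid)
  }

  set.seed(seed + 1L)
  # phenotype with observation noise
  rhc <- pmin(pmax(0.35 + 0.04 * params$LAI +
                     stats::rnorm(n, 0, 0.03), 0.05), 0.95)
  cam_fit <- pmin(pmax(params$Cam_alpha + stats::rnorm(n, 0, 2), 6), 88)
  ang_stats <- t(vapply(cam_fit, function(a) {
    g <- seq(0, 90, length.out = 901L)
    d <- campbell_density(g, a)
    d <- d / sum(d)
    mu <- sum(g * d)
    c(mu, sqrt(sum((g - mu)^2 * d)))
  }, numeric(2)))
  mean_ang <- ang_stats[, 1] + stats::rnorm(n, 0, 1)
  sd_ang <- pmax(ang_stats[, 2] + stats::rnorm(n, 0, 1), 2)
  hull_fill <- pmin(pmax(0.25 + 0.05 * params$LAI +
                           stats::rnorm(n, 0, 0.04), 0.02), 1)
  phen <- cbind(rhc = rhc, cam_alpha_fit = cam_fit,
                mean_leaf_angle = mean_ang, leaf_angle_sd = sd_ang,
                hull_fill_ratio = hull_fill)

  # structured sim-to-real gap + multiplicative noise
  gap$c_struct <- gap$c_struct %||% 0
  tilt <- gap$gap_scale * (gap$b1 * (rhc - 0.5) + gap$b2 * (cam_fit - 55) / 10)
  ramp <- seq(-0.5, 0.5, length.out = length(grid))
  bias <- 1 + outer(tilt, ramp)
  struct_amp <- gap$gap_scale * gap$c_struct * sin(2 * pi * params$LAI / 7.5)
  nir_weight <- pmin(pmax((grid - 720) / 60, 0), 1)
  bias <- bias * (1 + outer(struct_amp, nir_weight))
  noise <- matrix(1 + stats::rnorm(n * length(grid), 0, noise_sd),
                  n, length(grid))
  spectra <- pmin(pmax(spectra * bias * noise, 0), 1)
  attr(spectra, "wavelengths_nm") <- as.numeric(grid)

  structure(
    list(
      spectra = spectra, phenotype = phen,
      traits = add_canopy_traits(params),
      meta = list(seed = seed, n = n, gap = gap, noise_sd = noise_sd,
                  spec = spec, tilt = tilt, struct_amp = struct_amp)
    ),
    class = "canoret_dataset"
  )
}

#' @export
print.canoret_dataset <- function(x, ...) {
  cat(sprintf(
    "<canoret_dataset> %d measured-like samples x %d bands (seed %d, gap %s)\n",
    nrow(x$spectra), ncol(x$spectra), x$meta$seed,
    paste0(x$meta$gap$gap_scale)))
  invisible(x)
}

#' @method tidy canoret_dataset
#' @export
tidy.canoret_dataset <- function(x, ...) {
  dplyr::bind_cols(x$traits, tibble::as_tibble(x$phenotype))
}
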