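# Hyperspectral cube handling, segmentation, front-view phenotyping.

small_cube <- function(value = 0.4, size = 8L, ref = NULL) {
  nb <- 203L
  data <- array(value, c(size, size, nb))
  hyperspectral_cube(data, camera_grid(), white_reference = ref)
}

test_that("whiteboard calibration is a band-wise division with clipping", {
  nb <- 203L
  ref <- 0.8 + 0.2 * exp(-((camera_grid() - 650) / 400)^2)
  # all-ones reference: identity
  c1 <- hyperspectral_cube(array(0.4, c(4, 4, nb)), white_reference = rep(1, nb))
  expect_equal(calibrate_reflectance(c1)$data, array(0.4, c(4, 4, nb)))
  # pixel equal to reference: all-ones reflectance, nothing clipped
  c2 <- hyperspectral_cube(array(rep(ref, each = 16), c(4, 4, nb)),
                           white_reference = ref)
  cal2 <- calibrate_reflectance(c2)
  expect_equal(cal2$data, array(1, c(4, 4, nb)))
  expect_equal(attr(cal2, "clipped"), 0L)
  # pixel at 0.4 x reference: constant 0.4
  c3 <- hyperspectral_cube(array(rep(0.4 * ref, each = 16), c(4, 4, nb)),
                           white_reference = ref)
  expect_equal(calibrate_reflectance(c3)$data, array(0.4, c(4, 4, nb)),
               tolerance = 1e-12)
  # zero reference band errors
  bad_ref <- ref; bad_ref[10] <- 0
  c4 <- hyperspectral_cube(array(0.4, c(4, 4, nb)), white_reference = bad_ref)
  expect_error(calibrate_reflectance(c4), "strictly positive")
})

test_that("segmentation masks are disjoint and respect the index definitions", {
  # NIR = R everywhere: EVI numerator zero, no plant pixels
  cube <- small_cube(0.3)
  masks <- segment_cube(cube)
  expect_false(any(masks$plant_mask))
  expect_equal(max(abs(masks$ndvi)), 0)
  expect_false(any(masks$plant_mask & masks$soil_mask))
})

test_that("a painted scene is segmented pixel-exactly", {
  scene <- generate_scene(typical_params(), plant_fraction = 0.35,
                          size = 24, noise_sd = 0, seed = 5)
  cal <- calibrate_reflectance(scene$cube)
  masks <- segment_cube(cal)
  expect_equal(masks$plant_mask, scene$masks$plant_mask)
  expect_equal(masks$soil_mask, scene$masks$soil_mask)
  expect_false(any(masks$plant_mask & masks$soil_mask))
})

test_that("mixed reflectance is the segmented-pixel mean", {
  nb <- 203L
  data <- array(0, c(2, 2, nb))
  data[1, , ] <- 0.2
  data[2, , ] <- 0.6
  cube <- hyperspectral_cube(data, camera_grid())
  masks <- list(plant_mask = matrix(TRUE, 2, 2),
                soil_mask = matrix(FALSE, 2, 2))
  mr <- mixed_reflectance(cube, masks)
  expect_equal(mr$reflectance, rep(0.4, nb))
  # identical pixels: exactly that spectrum
  masks1 <- list(plant_mask = rbind(c(TRUE, TRUE), c(FALSE, FALSE)),
                 soil_mask = matrix(FALSE, 2, 2))
  expect_equal(mixed_reflectance(cube, masks1)$reflectance, rep(0.2, nb))
  # no segmented pixels errors
  none <- list(plant_mask = matrix(FALSE, 2, 2), soil_mask = matrix(FALSE, 2, 2))
  expect_error(mixed_reflectance(cube, none), "no segmented")
})

test_that("ENVI write/read round-trips a cube at float32 precision", {
  set.seed(20)
  nb <- 203L
  data <- array(runif(6 * 5 * nb), c(6, 5, nb))
  ref <- runif(nb, 0.7, 1)
  cube <- hyperspectral_cube(data, camera_grid(), white_reference = ref)
  base <- file.path(withr::local_tempdir(), "scene")
  write_envi(cube, base)
  back <- read_envi(paste0(base, ".hdr"))
  expect_equal(dim(back$data), dim(cube$data))
  expect_equal(back$data, cube$data, tolerance = 1e-6)
  expect_equal(back$wavelengths_nm, cube$wavelengths_nm, tolerance = 1e-4)
  expect_equal(back$white_reference, ref, tolerance = 1e-12)
})

test_that("Hough segments recover isolated line inclinations exactly", {
  img <- matrix(FALSE, 256, 256)
  angs <- c(10, 25, 40, 55, 70, 85)
  for (i in seq_along(angs)) {
    x0 <- 40 * i - 20; y0 <- 220
    t <- seq(0, 50, by = 0.5)
    xs <- round(x0 + cos(angs[i] * pi / 180) * t)
    ys <- round(y0 - sin(angs[i] * pi / 180) * t)
    img[cbind(ys, xs)] <- TRUE
  }
  h <- hough_segments(img, min_votes = 15)
  found <- sort(h$angle_deg)
  expect_equal(length(found), 6L)
  expect_equal(found, angs, tolerance = 0.5 / min(angs) * 10)
})

test_that("a plant with all leaves at 45 degrees yields a 45-degree mean angle", {
  img <- array(0, c(256, 256, 3))
  img[, , 1] <- 0.5; img[, , 3] <- 0.8  # non-green background
  set.seed(21)
  for (i in 1:25) {
    x0 <- sample(20:120, 1); y0 <- sample(120:240, 1)
    t <- seq(0, 45, by = 0.5)
    xs <- round(x0 + cos(pi / 4) * t)
    ys <- round(y0 - sin(pi / 4) * t)
    for (k in seq_along(xs)) {
      img[ys[k], xs[k] + 0:1, 1] <- 0.1
      img[ys[k], xs[k] + 0:1, 2] <- 0.6
      img[ys[k], xs[k] + 0:1, 3] <- 0.1
    }
  }
  ph <- extract_front_view_phenotype(img, min_votes = 15)
  expect_equal(ph$mean_leaf_angle, 45, tolerance = 2 / 45)
  expect_false(ph$low_confidence)
})

test_that("RHC maps to its complement under vertical mirroring", {
  fv <- render_front_view(55, seed = 31)
  ph <- extract_front_view_phenotype(fv$image)
  flipped <- fv$image[dim(fv$image)[1]:1, , ]
  ph_f <- extract_front_view_phenotype(flipped)
  expect_equal(ph_f$rhc, 1 - ph$rhc, tolerance = 0.05)
})

test_that("phenotype invariants hold on rendered plants", {
  for (s in 1:3) {
    fv <- render_front_view(50 + 5 * s, seed = s)
    ph <- extract_front_view_phenotype(fv$image, pot_rim_row = fv$pot_rim_row)
    expect_gte(ph$rhc, 0); expect_lte(ph$rhc, 1)
    expect_gt(ph$hull_fill_ratio, 0); expect_lte(ph$hull_fill_ratio, 1)
    expect_gte(ph$mean_leaf_angle, 0); expect_lte(ph$mean_leaf_angle, 90)
  }
  expect_error(extract_front_view_phenotype(array(0, c(10, 10, 3))),
               "no green")
})

test_that("Campbell fitting recovers the generating parameter", {
  a <- sample_campbell_angles(1e4, 57, seed = 9)
  fit <- fit_campbell(a)
  expect_equal(fit$alpha, 57, tolerance = 3 / 57)
  # self-consistency: refitting a sample from the fitted density is a
  # fixed point within tolerance
  a2 <- sample_campbell_angles(1e4, fit$alpha, seed = 10)
  fit2 <- fit_campbell(a2)
  expect_equal(fit2$alpha, fit$alpha, tolerance = 3 / 57)
  # least-squares route agrees with the likelihood route
  fit_ls <- fit_campbell(a, method = "ls")
  expect_equal(fit_ls$alpha, fit$alpha, tolerance = 4 / 57)
})

test_that("goodness of fit degrades monotonically under contamination", {
  set.seed(11)
  base <- sample_campbell_angles(4000, 50)
  gofs <- vapply(c(0, 0.25, 0.5), function(frac) {
    n_con <- round(frac * length(base))
    mixed <- c(base[seq_len(length(base) - n_con)], runif(n_con, 0, 90))
    fit_campbell(mixed)$gof
  }, numeric(1))
  expect_true(all(diff(gofs) > 0))
})

test_that("degenerate angle sets are flagged", {
  expect_warning(f <- fit_campbell(rep(45, 20)), "degenerate")
  expect_true(f$boundary)
  expect_error(fit_campbell(c(10, 20, 30)), "at least 10")
})

test_that("image-fitted alpha tracks the true leaf-angle parameter", {
  set.seed(12)
  alphas <- seq(30, 75, length.out = 15)
  fits <- vapply(seq_along(alphas), function(i) {
    fv <- render_front_view(alphas[i], seed = 100 + i)
    extract_front_view_phenotype(fv$image,
                                 pot_rim_row = fv$pot_rim_row)$cam_alpha_fit
  }, numeric(1))
  expect_gt(cor(fits, alphas), 0.9)
})
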