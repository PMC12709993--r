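# Monte-Carlo look-up table: sampling, noise injection, construction,
# cost function and inversion.

test_that("parameter sampling is reproducible and respects the stated families", {
  a <- sample_parameters(n = 500, seed = 11)
  b <- sample_parameters(n = 500, seed = 11)
  expect_identical(a, b)

  big <- sample_parameters(n = 10000, seed = 3)
  # uniform Psoil: CLT bound on the sample mean
  expect_lt(abs(mean(big$Psoil) - 0.5), 0.02)
  # skewed Weibull water content
  skew <- function(x) mean(((x - mean(x)) / sd(x))^3)
  expect_gt(skew(big$Cw), 0)
  expect_gt(skew(big$Cm), 0)
  # truncation bounds hold everywhere
  spec <- default_param_spec()
  for (j in seq_len(nrow(spec))) {
    x <- big[[spec$parameter[j]]]
    expect_gte(min(x), spec$lower[j])
    expect_lte(max(x), spec$upper[j])
  }
})

test_that("infeasible truncation raises an error", {
  spec <- default_param_spec()
  spec$lower[spec$parameter == "Cab"] <- 200
  spec$upper[spec$parameter == "Cab"] <- 300
  expect_error(sample_parameters(spec, 10, seed = 1), "zero probability")
})

test_that("a Gaussian copula induces the requested rank correlation", {
  spec <- default_param_spec()
  R <- diag(9)
  dimnames(R) <- list(spec$parameter, spec$parameter)
  R["Cab", "LAI"] <- R["LAI", "Cab"] <- 0.6
  s <- sample_parameters(spec, 5000, seed = 5, correlation = R)
  expect_lt(abs(cor(s$Cab, s$LAI, method = "spearman") - 0.58), 0.08)
  # independence elsewhere
  expect_lt(abs(cor(s$Cw, s$Psoil)), 0.06)
})

test_that("parameter noise has the configured scale and respects bounds", {
  spec <- default_param_spec()
  p <- sample_parameters(spec, 1e5, seed = 9)
  expect_identical(inject_parameter_noise(p, spec, noise_scale = 0), p)

  q <- inject_parameter_noise(p, spec, noise_scale = 0.05, seed = 10)
  for (j in seq_len(nrow(spec))) {
    x <- q[[spec$parameter[j]]]
    expect_gte(min(x), spec$lower[j])
    expect_lte(max(x), spec$upper[j])
  }
  # Cab noise is barely clipped, so the empirical sd is close to nominal
  sds <- marginal_sd(spec)
  expect_equal(sd(q$Cab - p$Cab), 0.05 * sds[["Cab"]], tolerance = 0.05)
})

test_that("the look-up table is internally consistent and reproducible", {
  lut <- test_lut(n = 300, seed = 42)
  expect_equal(nrow(lut$spectra), 300L)
  expect_true(all(lut$spectra >= 0 & lut$spectra <= 1))
  expect_equal(lut$params$CCC, lut$params$Cab * lut$params$LAI)
  expect_equal(lut$params$CEW, lut$params$Cw * lut$params$LAI)

  again <- build_lut(n = 300, seed = 42)
  expect_identical(lut$spectra, again$spectra)
  expect_identical(lut$params, again$params)
})

test_that("LUT serialization round-trips through CSV + JSON", {
  lut <- test_lut(n = 300, seed = 42)
  dir <- withr::local_tempdir()
  write_lut(lut, dir)
  back <- read_lut(dir)
  expect_equal(back$params, lut$params, tolerance = 1e-12)
  expect_equal(as.numeric(back$spectra), as.numeric(lut$spectra),
               tolerance = 1e-12)
  # header wavelengths carry 4 decimals
  expect_equal(back$wavelengths_nm, lut$wavelengths_nm, tolerance = 1e-3)
  expect_equal(back$seed, lut$seed)
})

test_that("the spectral cost is a root-sum-of-squares distance", {
  expect_equal(hellinger_cost(c(0.3, 0.4), c(0.3, 0.4)), 0)
  expect_equal(hellinger_cost(c(0.3, 0.4), c(0, 0)), 0.5)  # sqrt(0.25)
  expect_equal(hellinger_cost(c(0.3, 0.4), c(0, 0), take_sqrt = FALSE), 0.25)
  # symmetry
  a <- runif(10); b <- runif(10)
  expect_equal(hellinger_cost(a, b), hellinger_cost(b, a))
  expect_error(hellinger_cost(a, b[1:5]), "identical grids")
  # window selection on spectrum tibbles
  g <- camera_grid()
  s1 <- spectrum(g, rep(0.5, 203))
  s2 <- spectrum(g, rep(0.5, 203) + 0.1 * (g > 900))
  expect_equal(hellinger_cost(s1, s2, window = c(400, 900)), 0)
  expect_gt(hellinger_cost(s1, s2, window = c(900, 1006)), 0)
})

test_that("self-inversion returns each record exactly", {
  lut <- test_lut(n = 300, seed = 42)
  idx <- c(1L, 57L, 300L)
  inv <- lut_invert(lut$spectra[idx, , drop = FALSE], lut)
  expect_equal(inv$record, idx)
  expect_true(all(inv$cost < 1e-6))
  expect_equal(inv$LAI, lut$params$LAI[idx])
})

test_that("top-k candidates cover the table in non-decreasing cost order", {
  lut <- test_lut(n = 300, seed = 42)
  inv <- lut_invert(lut$spectra[5, , drop = FALSE], lut, k = 300L)
  tk <- inv$top_k[[1]]
  expect_equal(nrow(tk), 300L)
  expect_true(all(diff(tk$cost) >= -1e-12))
  expect_equal(tk$cost[1], inv$cost[1])
  expect_equal(tk$record[1], inv$record[1])
})

test_that("the returned best matches an independent exhaustive re-scan", {
  lut <- test_lut(n = 300, seed = 42)
  set.seed(1)
  meas <- lut$spectra[101, ] * (1 + rnorm(203, 0, 0.02))
  meas <- pmin(pmax(meas, 0), 1)
  inv <- lut_invert(meas, lut, window = c(742, 841))
  # brute-force oracle: per-record loop over the same window
  sel <- which(lut$wavelengths_nm >= 742 & lut$wavelengths_nm <= 841)
  costs <- vapply(seq_len(300), function(i) {
    sqrt(sum((meas[sel] - lut$spectra[i, sel])^2))
  }, numeric(1))
  expect_equal(inv$record, which.min(costs))
  expect_equal(inv$cost, min(costs), tolerance = 1e-10)
  expect_true(all(inv$cost <= costs + 1e-12))
})

test_that("noiseless spectra from LUT members recover their traits exactly", {
  lut <- test_lut(n = 300, seed = 42)
  set.seed(3)
  idx <- sample(300, 50)
  inv <- lut_invert(lut$spectra[idx, , drop = FALSE], lut, window = c(742, 841))
  expect_equal(inv$LAI, lut$params$LAI[idx])
  expect_equal(inv$CCC, lut$params$CCC[idx])
})

test_that("LUT retrieval recovers LAI better than the leaf trait Cm under noise", {
  lut7 <- test_lut(n = 7000, seed = 1)   # shared with the acceptance blocks
  truth <- sample_parameters(n = 200, seed = 99)
  sim <- resample_to_camera_grid(simulate_reflectance(truth), camera_grid())
  set.seed(8)
  noisy <- pmin(pmax(sim * (1 + matrix(rnorm(200 * 203, 0, 0.01), 200)), 0), 1)
  attr(noisy, "wavelengths_nm") <- camera_grid()
  inv <- lut_invert(noisy, lut7, window = NULL)  # all camera bands
  r_lai <- cor(inv$LAI, truth$LAI)
  r_cm <- cor(inv$Cm, truth$Cm)
  expect_gt(r_lai, 0.8)
  expect_gt(r_lai, r_cm)
})

test_that("an empty LUT cannot be inverted", {
  lut <- test_lut(n = 300, seed = 42)
  empty <- lut
  empty$spectra <- lut$spectra[0, , drop = FALSE]
  expect_error(lut_invert(lut$spectra[1, ], empty), "empty")
})
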