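#' Extended FAST global sensitivity analysis
#'
#' Variance-based first-order (S1) and total-order (ST) sensitivity
#' indices by the extended Fourier amplitude sensitivity test: each
#' parameter in turn is assigned the high driving frequency while the
#' complementary set oscillates at low frequencies; the model output's
#' Fourier spectrum is then partitioned into the variance at the driving
#' frequency's harmonics (first order) and at the complementary
#' frequencies (everything except the parameter, yielding the total
#' index).
#'
#' @param spec Parameter distribution spec ([default_param_spec()]); the
#'   search curve is pushed through each parameter's truncated quantile
#'   function, so indices refer to the same priors as the look-up table.
#' @param model Function mapping a parameter tibble (columns
#'   `spec$parameter`) to a numeric output vector. The default simulates
#'   canopy reflectance and averages it over `bands`.
#' @param bands Wavelength window (nm) for the default reflectance model.
#' @param n Model evaluations per parameter (>= 65 for the default
#'   interference factor).
#' @param M Interference factor (harmonics summed), default 4.
#' @param seed Seed for the random phase shift of the search curves.
#' @return A `canoret_sensitivity` tibble: `parameter`, `S1`, `ST`.
#' @export
efast_sensitivity <- function(spec = default_param_spec(), model = NULL,
                              bands = c(760, 900), n = 1000L, M = 4L,
                              seed = 1L) {
  spec <- validate_param_spec(spec)
  p <- nrow(spec)
  n <- as.integer(n)
  omega_max <- floor((n - 1) / (2 * M))
  if (omega_max < 8) stop("n_samples too small for the frequency design", call. = FALSE)
  m <- floor(omega_max / (2 * M))
  if (m < 1) stop("n_samples too small for the frequency design", call. = FALSE)
  omega_comp <- if (m >= p - 1) floor(seq(1, m, length.out = max(p - 1, 1))) else
    1 + (seq_len(p - 1) - 1) %% m

  if (is.null(model)) {
    constants <- leaf_optical_constants()
    soil <- default_soil_spectra()
    idx <- band_window(constants$wavelength_nm, bands)
    model <- function(params) {
      out <- numeric(nrow(params))
      chunks <- split(seq_len(nrow(params)), ceiling(seq_len(nrow(params)) / 500))
      for (ii in chunks) {
        r <- simulate_reflectance(params[ii, , drop = FALSE], soil = soil,
                                  constants = constants)
        out[ii] <- rowMeans(r[, idx, drop = FALSE])
      }
      out
    }
  }

  set.seed(seed)
  s <- 2 * pi / n * (seq_len(n) - 1)
  res <- vector("list", p)
  for (i in seq_len(p)) {
    omega <- numeric(p)
    omega[i] <- omega_max
    omega[-i] <- omega_comp
    phase <- stats::runif(p, 0, 2 * pi)
    u <- vapply(seq_len(p), function(j) {
      0.5 + asin(sin(omega[j] * s + phase[j])) / pi
    }, numeric(n))
    u <- pmin(pmax(u, 1e-9), 1 - 1e-9)
    params <- purrr::map(seq_len(p), function(j) {
      row <- spec[j, ]
      flo <- marginal_cdf(row, row$lower)
      fhi <- marginal_cdf(row, row$upper)
      marginal_quantile(row, flo + u[, j] * (fhi - flo))
    })
    names(params) <- spec$parameter
    y <- model(tibble::as_tibble(params))
    res[[i]] <- efast_analyze(y, omega_max, M)
  }
  out <- dplyr::bind_cols(tibble::tibble(parameter = spec$parameter),
                          dplyr::bind_rows(res))
  class(out) <- c("canoret_sensitivity", class(out))
  out
}

# Fourier partition of one search-curve output into S1 and ST.
efast_analyze <- function(y, omega_max, M) {
  n <- length(y)
  f <- stats::fft(y - mean(y))
  A <- (Mod(f) / n)^2
  half <- floor((n - 1) / 2)
  V <- 2 * sum(A[1 + seq_len(half)])
  harmonics <- omega_max * seq_len(M)
  harmonics <- harmonics[harmonics <= half]
  D1 <- 2 * sum(A[1 + harmonics])
  Dc <- 2 * sum(A[1 + seq_len(floor(omega_max / 2))])
  tibble::tibble(S1 = D1 / V, ST = 1 - Dc / V)
}

#' Ishigami test function (sensitivity-estimator benchmark)
#'
#' `f(x) = sin(x1) + a sin^2(x2) + b x3^4 sin(x1)` with inputs uniform on
#' \[-pi, pi\]; its first- and total-order sensitivity indices are known in
#' closed form, making it the standard check of variance-based estimators.
#'
#' @param params Tibble with columns `x1`, `x2`, `x3`.
#' @param a,b Shape constants (defaults 7 and 0.1).
#' @return Numeric output vector.
#' @export
ishigami_fn <- function(params, a = 7, b = 0.1) {
  sin(params$x1) + a * sin(params$x2)^2 + b * params$x3^4 * sin(params$x1)
}

#' Parameter spec for the Ishigami function
#' @return A three-parameter uniform spec on \[-pi, pi\].
#' @export
ishigami_spec <- function() {
  tibble::tibble(
    parameter = c("x1", "x2", "x3"), family = "uniform",
    p1 = -pi, p2 = pi, lower = -pi, upper = pi
  )
}

#' Analytic Ishigami sensitivity indices
#' @param a,b Shape constants.
#' @return Tibble with `parameter`, `S1`, `ST`.
#' @export
ishigami_indices <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- b^2 * pi^8 * 8 / 225
  V <- V1 + V2 + V13
  tibble::tibble(
    parameter = c("x1", "x2", "x3"),
    S1 = c(V1 / V, V2 / V, 0),
    ST = c((V1 + V13) / V, V2 / V, V13 / V)
  )
}
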