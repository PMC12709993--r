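#' Prior distribution specification for the canopy model parameters
#'
#' One row per model parameter with its sampling family and truncation
#' bounds. Families: `normal` (`p1` = mean, `p2` = sd), `weibull`
#' (`p1` = shape, `p2` = scale) and `uniform` (`p1` = low, `p2` = high).
#' LAI, the Campbell leaf-angle parameter, Cab, Car and Hspot are normal;
#' Cw and Cm follow right-skewed Weibull distributions; Psoil and N are
#' uniform. The shipped hyperparameters are package defaults chosen to
#' span realistic pot-grown rice ranges; every value is overridable.
#'
#' @return Tibble with columns `parameter`, `family`, `p1`, `p2`,
#'   `lower`, `upper`.
#' @export
default_param_spec <- function() {
  tibble::tribble(
    ~parameter,  ~family,   ~p1,   ~p2,    ~lower, ~upper,
    "N",         "uniform", 1.2,   2.2,    1.2,    2.2,
    "Cab",       "normal",  45,    20,     5,      90,
    "Car",       "normal",  10,    4,      1,      25,
    "Cw",        "weibull", 2.0,   0.015,  1e-4,   0.08,
    "Cm",        "weibull", 2.0,   0.006,  1e-4,   0.03,
    "LAI",       "normal",  3.5,   1.5,    0.2,    7.5,
    "Cam_alpha", "normal",  55,    12,     20,     85,
    "Hspot",     "normal",  0.05,  0.02,   0.005,  0.2,
    "Psoil",     "uniform", 0,     1,      0,      1
  )
}

validate_param_spec <- function(spec) {
  spec <- tibble::as_tibble(spec)
  stopifnot(all(c("parameter", "family", "p1", "p2", "lower", "upper") %in% names(spec)))
  if (!all(spec$family %in% c("normal", "weibull", "uniform"))) {
    stop("family must be one of normal, weibull, uniform", call. = FALSE)
  }
  if (any(spec$lower >= spec$upper)) stop("lower must be < upper", call. = FALSE)
  spec
}

marginal_cdf <- function(row, x) {
  switch(row$family,
    normal  = stats::pnorm(x, row$p1, row$p2),
    weibull = stats::pweibull(x, shape = row$p1, scale = row$p2),
    uniform = stats::punif(x, row$p1, row$p2)
  )
}

marginal_quantile <- function(row, u) {
  switch(row$family,
    normal  = stats::qnorm(u, row$p1, row$p2),
    weibull = stats::qweibull(u, shape = row$p1, scale = row$p2),
    uniform = stats::qunif(u, row$p1, row$p2)
  )
}

#' Marginal standard deviation of each parameter's (untruncated) family
#' @param spec Parameter distribution spec.
#' @return Named numeric vector of standard deviations.
#' @export
marginal_sd <- function(spec) {
  spec <- validate_param_spec(spec)
  sds <- purrr::map2_dbl(seq_len(nrow(spec)), spec$family, function(i, fam) {
    row <- spec[i, ]
    switch(fam,
      normal  = row$p2,
      uniform = (row$p2 - row$p1) / sqrt(12),
      weibull = row$p2 * sqrt(gamma(1 + 2 / row$p1) - gamma(1 + 1 / row$p1)^2)
    )
  })
  stats::setNames(sds, spec$parameter)
}

#' Monte-Carlo sampling of model parameter sets
#'
#' Draws `n` parameter records from the prior spec by truncated
#' inverse-CDF sampling. An optional correlation matrix induces rank
#' dependence through a Gaussian copula; the default (NULL) samples
#' parameters independently.
#'
#' @param spec Parameter distribution spec ([default_param_spec()]).
#' @param n Number of records.
#' @param seed Integer seed; identical seeds give identical tables.
#' @param correlation Optional symmetric positive-definite correlation
#'   matrix (parameters x parameters, dimnames matching `spec$parameter`).
#' @return Tibble with one column per parameter.
#' @export
sample_parameters <- function(spec = default_param_spec(), n, seed = 1L,
                              correlation = NULL) {
  spec <- validate_param_spec(spec)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  p <- nrow(spec)
  set.seed(seed)
  if (is.null(correlation)) {
    u <- matrix(stats::runif(n * p), n, p)
  } else {
    if (!isSymmetric(unname(correlation))) {
      stop("correlation matrix must be symmetric", call. = FALSE)
    }
    ch <- tryCatch(chol(correlation),
                   error = function(e) stop("correlation matrix must be positive definite",
                                            call. = FALSE))
    z <- matrix(stats::rnorm(n * p), n, p) %*% ch
    u <- stats::pnorm(z)
  }
  out <- purrr::map(seq_len(p), function(j) {
    row <- spec[j, ]
    flo <- marginal_cdf(row, row$lower)
    fhi <- marginal_cdf(row, row$upper)
    if (fhi - flo <= 1e-12) {
      stop(sprintf("truncation interval for %s has zero probability mass",
                   row$parameter), call. = FALSE)
    }
    marginal_quantile(row, flo + u[, j] * (fhi - flo))
  })
  names(out) <- spec$parameter
  tibble::as_tibble(out)
}

#' Perturb parameter records with distribution-consistent noise
#'
#' Adds zero-mean Gaussian noise with per-parameter standard deviation
#' `noise_scale` times the marginal sd of that parameter's family, then
#' clamps back to the truncation bounds.
#'
#' @param params Parameter tibble from [sample_parameters()].
#' @param spec The spec the parameters were drawn from.
#' @param noise_scale Non-negative scale factor (default 0.05).
#' @param seed Integer seed.
#' @return Perturbed tibble, same shape as `params`.
#' @export
inject_parameter_noise <- function(params, spec = default_param_spec(),
                                   noise_scale = 0.05, seed = 1L) {
  spec <- validate_param_spec(spec)
  if (noise_scale < 0) stop("noise_scale must be >= 0", call. = FALSE)
  if (noise_scale == 0) return(tibble::as_tibble(params))
  sds <- marginal_sd(spec)
  set.seed(seed)
  out <- params
  for (j in seq_len(nrow(spec))) {
    nm <- spec$parameter[j]
    x <- params[[nm]] + stats::rnorm(nrow(params), 0, noise_scale * sds[[nm]])
    out[[nm]] <- pmin(pmax(x, spec$lower[j]), spec$upper[j])
  }
  tibble::as_tibble(out)
}
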