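#' Plot a look-up table's spectral envelope
#'
#' Mean simulated reflectance with a band-wise 5-95% quantile ribbon.
#'
#' @param object A `canoret_lut`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot canoret_lut
#' @export
autoplot.canoret_lut <- function(object, ...) {
  qs <- apply(object$spectra, 2L, stats::quantile, probs = c(0.05, 0.5, 0.95))
  df <- tibble::tibble(
    wavelength_nm = object$wavelengths_nm,
    lo = qs[1, ], mid = qs[2, ], hi = qs[3, ]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength_nm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "darkgreen", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mid), color = "darkgreen") +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance",
                  title = "Simulated canopy reflectance (median, 5-95%)") +
    ggplot2::theme_minimal()
}

#' Plot per-band significance counts from waveband screening
#'
#' @param object A `canoret_screening`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot canoret_screening
#' @export
autoplot.canoret_screening <- function(object, ...) {
  ggplot2::ggplot(object$per_band,
                  ggplot2::aes(x = .data$wavelength_nm, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue", width = 2) +
    ggplot2::labs(x = "wavelength (nm)",
                  y = "batches with significant treatment difference",
                  title = "Drought-sensitive waveband screening") +
    ggplot2::theme_minimal()
}

#' Plot first- and total-order sensitivity indices
#'
#' @param object A `canoret_sensitivity` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot canoret_sensitivity
#' @export
autoplot.canoret_sensitivity <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("S1", "ST"),
                            names_to = "order", values_to = "index")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$index,
                                   fill = .data$order)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "sensitivity index",
                  title = "EFAST global sensitivity") +
    ggplot2::theme_minimal()
}

#' Predicted-versus-true scatter for a fitted regressor
#'
#' @param object A `canoret_cnn` with stored held-out predictions.
#' @param ... Unused.
#' @return A ggplot object, one facet per target.
#' @method autoplot canoret_cnn
#' @export
autoplot.canoret_cnn <- function(object, ...) {
  if (is.null(object$predictions)) stop("model has no stored predictions", call. = FALSE)
  long <- purrr::map_dfr(object$targets, function(tg) {
    tibble::tibble(
      target = tg,
      truth = object$predictions[[paste0(tg, "_true")]],
      predicted = object$predictions[[paste0(tg, "_pred")]]
    )
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$truth, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8, color = "darkgreen") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~target, scales = "free") +
    ggplot2::labs(title = sprintf("Held-out retrieval accuracy (%s)", object$origin)) +
    ggplot2::theme_minimal()
}

#' Plot treatment-group distances to the well-watered baseline
#'
#' @param object Tibble from [group_distance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_group_distance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$group, y = .data$mean_distance)) +
    ggplot2::geom_col(fill = "indianred") +
    ggplot2::labs(x = "treatment group",
                  y = "mean Euclidean distance to baseline",
                  title = "Stress separation in the discriminant space") +
    ggplot2::theme_minimal()
}
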