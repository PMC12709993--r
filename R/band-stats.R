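#' Assemble grouped spectra for waveband screening
#'
#' @param spectra Records-by-bands matrix (with `wavelengths_nm` attribute)
#'   or data frame of band columns.
#' @param group Treatment label per sample (e.g. WF/WM/WS/HS).
#' @param batch Sampling-date label per sample.
#' @return Tibble with `group`, `batch` factors and one numeric column per
#'   band (named `wl_<nm>` when wavelengths are known, `band_<j>` otherwise).
#' @export
grouped_spectra <- function(spectra, group, batch = rep(1L, length(group))) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) != length(group) || nrow(spectra) != length(batch)) {
    stop("group and batch labels must match the number of spectra", call. = FALSE)
  }
  wl <- attr(spectra, "wavelengths_nm")
  nm <- if (!is.null(wl)) sprintf("wl_%g", wl) else
    sprintf("band_%d", seq_len(ncol(spectra)))
  out <- tibble::as_tibble(as.data.frame(spectra, col.names = nm))
  names(out) <- nm
  dplyr::bind_cols(tibble::tibble(group = factor(group), batch = factor(batch)),
                   out)
}

#' Screen drought-sensitive wavebands
#'
#' For every band and sampling batch, a one-way ANOVA tests for treatment
#' differences; when the ANOVA p-value is below `alpha`, Tukey's HSD
#' post-hoc test (family-wise error controlled at `alpha`) checks all
#' treatment pairs, and the band is flagged significant for that batch if
#' any pair differs. Flags are accumulated across batches into a
#' per-band significance count.
#'
#' @param data Tibble from [grouped_spectra()] (columns `group`, `batch`,
#'   band columns).
#' @param alpha Significance level (default 0.05) for both the ANOVA and
#'   the Tukey family-wise error rate.
#' @return A `canoret_screening`: list with `per_band` (band, wavelength,
#'   significance count, number of batches) and `per_batch` (band x batch
#'   ANOVA p-values and flags). Constant (zero-variance) bands get p = 1.
#' @export
screen_bands <- function(data, alpha = 0.05) {
  band_cols <- setdiff(names(data), c("group", "batch"))
  if (nlevels(factor(data$group)) < 2) stop("need >= 2 treatment groups", call. = FALSE)
  batches <- levels(factor(data$batch))
  rows <- list()
  for (b in batches) {
    d <- data[data$batch == b, , drop = FALSE]
    g <- droplevels(factor(d$group))
    if (nlevels(g) < 2 || any(table(g) < 2)) {
      stop(sprintf("batch %s needs >= 2 groups with >= 2 samples", b), call. = FALSE)
    }
    for (j in band_cols) {
      y <- d[[j]]
      if (stats::sd(y) < 1e-300) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          band = j, batch = b, p_anova = 1, significant = FALSE)
        next
      }
      fit <- stats::aov(y ~ g)
      p <- stats::anova(fit)$`Pr(>F)`[1]
      sig <- FALSE
      if (is.finite(p) && p < alpha) {
        tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
        sig <- any(tk[, "p adj"] < alpha)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        band = j, batch = b, p_anova = p, significant = sig)
    }
  }
  per_batch <- dplyr::bind_rows(rows)
  per_band <- per_batch |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(count = sum(.data$significant),
                     n_batches = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(wavelength_nm = band_name_to_nm(.data$band)) |>
    dplyr::arrange(.data$wavelength_nm)
  structure(list(per_band = per_band, per_batch = per_batch, alpha = alpha),
            class = "canoret_screening")
}

band_name_to_nm <- function(x) {
  suppressWarnings(as.numeric(sub("^(wl|band)_", "", x)))
}

#' @export
print.canoret_screening <- function(x, ...) {
  cat(sprintf("<canoret_screening> %d bands x %d batches, alpha = %g\n",
              nrow(x$per_band), length(unique(x$per_batch$batch)), x$alpha))
  print(utils::head(dplyr::arrange(x$per_band, dplyr::desc(.data$count)), 5))
  invisible(x)
}

#' @method tidy canoret_screening
#' @export
tidy.canoret_screening <- function(x, ...) x$per_band

#' Fisher linear discriminant projection of screened band features
#'
#' Standardizes the features (z-scores from the training data), builds the
#' within-class scatter `S_w` as the sum over classes of the class
#' covariance `E[x x'] - m_k m_k'` and the between-class scatter `S_b` as
#' the sum of outer products of all pairwise class-mean differences, and
#' projects onto the leading eigenvectors of `S_w^{-1} S_b` (the
#' directions maximizing the between/within variance ratio).
#'
#' @param features Numeric matrix or data frame (samples x screened bands).
#' @param labels Class labels (coerced to factor).
#' @param dims Projection dimensionality, 1 or 2 (<= classes - 1).
#' @return A `canoret_lda`: projection matrix `W`, eigenvalues, scatter
#'   matrices `S_w`/`S_b`, class means and standardization parameters.
#' @export
fit_lda <- function(features, labels, dims = 2L) {
  X <- as.matrix(features)
  y <- factor(labels)
  if (nrow(X) != length(y)) stop("labels must match rows of features", call. = FALSE)
  if (nrow(X) < nlevels(y)) stop("need at least as many samples as classes", call. = FALSE)
  dims <- as.integer(dims)
  if (dims < 1L || dims > 2L || dims > nlevels(y) - 1L) {
    stop("dims must be 1 or 2 and at most classes - 1", call. = FALSE)
  }
  center <- colMeans(X)
  scale_ <- apply(X, 2L, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  Z <- sweep(sweep(X, 2L, center), 2L, scale_, "/")

  p <- ncol(Z)
  classes <- levels(y)
  means <- matrix(0, length(classes), p, dimnames = list(classes, colnames(Z)))
  Sw <- matrix(0, p, p)
  for (k in seq_along(classes)) {
    Zk <- Z[y == classes[k], , drop = FALSE]
    mk <- colMeans(Zk)
    means[k, ] <- mk
    Sw <- Sw + crossprod(Zk) / nrow(Zk) - tcrossprod(mk)
  }
  Sb <- matrix(0, p, p)
  for (i in seq_along(classes)) {
    for (j in seq_along(classes)) {
      if (i != j) {
        d <- means[i, ] - means[j, ]
        Sb <- Sb + tcrossprod(d)
      }
    }
  }
  Swi <- tryCatch(solve(Sw), error = function(e) {
    warning("singular within-class scatter; using ridge-regularized inverse",
            call. = FALSE)
    solve(Sw + diag(1e-6 * mean(diag(Sw)) + 1e-12, p))
  })
  eig <- eigen(Swi %*% Sb)
  ord <- order(Re(eig$values), decreasing = TRUE)
  W <- Re(eig$vectors[, ord[seq_len(dims)], drop = FALSE])
  W <- apply(W, 2L, function(v) v / sqrt(sum(v^2)))
  colnames(W) <- paste0("LD", seq_len(dims))
  structure(
    list(W = W, eigenvalues = Re(eig$values[ord[seq_len(dims)]]),
         S_w = Sw, S_b = Sb, class_means = means,
         center = center, scale = scale_, classes = classes, dims = dims),
    class = "canoret_lda"
  )
}

#' Project samples with a fitted discriminant
#'
#' @param object A `canoret_lda`.
#' @param features New samples (same band columns as the training data);
#'   standardized with the training z-score parameters.
#' @param ... Unused.
#' @return Tibble with columns `LD1` (and `LD2`).
#' @export
predict.canoret_lda <- function(object, features, ...) {
  X <- as.matrix(features)
  Z <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  tibble::as_tibble(as.data.frame(Z %*% object$W))
}

#' @export
print.canoret_lda <- function(x, ...) {
  cat(sprintf("<canoret_lda> %d classes -> %d dim(s); leading eigenvalues: %s\n",
              length(x$classes), x$dims,
              paste(signif(x$eigenvalues, 4), collapse = ", ")))
  invisible(x)
}

#' @method tidy canoret_lda
#' @export
tidy.canoret_lda <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$W)) |>
    dplyr::mutate(feature = rownames(x$W) %||% paste0("f", dplyr::row_number()),
                  .before = 1L)
}

#' Euclidean distance of each treatment group to a baseline group
#'
#' Distances are computed per sample from the projected coordinates to the
#' mean coordinate of the baseline (well-watered) group, then averaged
#' within each group. The baseline group's own value is its within-group
#' dispersion.
#'
#' @param projected Data frame of projected coordinates (e.g. from
#'   [predict.canoret_lda()]).
#' @param labels Group label per row.
#' @param baseline Baseline group label (default `"WF"`).
#' @return Tibble with `group`, `mean_distance`, `n`.
#' @export
group_distance <- function(projected, labels, baseline = "WF") {
  X <- as.matrix(projected)
  y <- factor(labels)
  if (!baseline %in% levels(y)) {
    stop(sprintf("baseline group '%s' not present", baseline), call. = FALSE)
  }
  base_mean <- colMeans(X[y == baseline, , drop = FALSE])
  d <- sqrt(rowSums(sweep(X, 2L, base_mean)^2))
  tibble::tibble(group = y, distance = d) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_distance = mean(.data$distance), n = dplyr::n(),
                     .groups = "drop")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
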