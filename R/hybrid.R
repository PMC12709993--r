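#' Pre-train the convolutional regressor on a simulated look-up table
#'
#' Trains the spectrum-only CNN on the LUT's simulated reflectance with the
#' derived canopy traits (and optionally raw model parameters) as targets.
#' The table is split 70/30 into training and test partitions; targets are
#' standardized with training-split statistics and predictions are
#' de-standardized before evaluation.
#'
#' @param lut A `canoret_lut` from [build_lut()].
#' @param targets Character vector of target columns in `lut$params`
#'   (default the canopy traits `CCC` and `CEW`).
#' @param cfg Training configuration ([training_config()]); `cfg$seed`
#'   governs the split, initialization and shuffling.
#' @param split Training fraction (default 0.7).
#' @return A `canoret_cnn` model with elements `metrics` (per-target
#'   evaluation on the held-out split), `test_idx`, `predictions`.
#' @export
pretrain <- function(lut, targets = c("CCC", "CEW"), cfg = training_config(),
                     split = 0.7) {
  stopifnot(inherits(lut, "canoret_lut"))
  miss <- setdiff(targets, names(lut$params))
  if (length(miss)) stop("targets not in LUT: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  n <- nrow(lut$spectra)
  set.seed(cfg$seed)
  tr <- sort(sample.int(n, round(split * n)))
  te <- setdiff(seq_len(n), tr)
  Y <- as.matrix(lut$params[, targets, drop = FALSE])

  core <- cnn_train_core(lut$spectra[tr, , drop = FALSE],
                         Y[tr, , drop = FALSE],
                         cnn_arch(length(targets)), cfg)
  model <- new_canoret_cnn(core, targets, input = "spectrum",
                           origin = "pretrained")
  pred <- cnn_predict_core(model, lut$spectra[te, , drop = FALSE])
  model$metrics <- eval_targets(Y[te, , drop = FALSE], pred, targets)
  model$test_idx <- te
  model$predictions <- pred_tibble(te, Y[te, , drop = FALSE], pred, targets)
  model
}

#' Fine-tune a pre-trained model on measured-style samples
#'
#' Freezes the convolutional feature extractor of a pre-trained model,
#' concatenates the 5-dimensional image-derived phenotype vector onto the
#' flattened convolution features, and trains two fresh dense layers plus
#' the output head on a 50/50 train/test split of the measured-style
#' dataset. Frozen convolution weights are bit-identical before and after.
#'
#' @param model A pre-trained `canoret_cnn` (spectrum-only input schema).
#' @param data A `canoret_dataset` ([generate_measured_like()]) or list
#'   with `spectra` (n x 203), `phenotype` (n x 5) and `traits` (tibble
#'   containing the model's targets).
#' @param cfg Training configuration; `cfg$seed` governs the split and the
#'   new-head initialization. The default uses batch size 32: with ~100
#'   fine-tuning samples, larger batches degenerate to one optimizer step
#'   per epoch.
#' @param split Training fraction of the measured samples (default 0.5).
#' @return A fine-tuned `canoret_cnn` (input schema spectrum+phenotype)
#'   with held-out `metrics`, `test_idx` and `predictions`.
#' @export
finetune <- function(model, data, cfg = training_config(batch_size = 32L),
                     split = 0.5) {
  stopifnot(inherits(model, "canoret_cnn"))
  if (model$input != "spectrum") {
    stop("finetune() expects a spectrum-only pre-trained model", call. = FALSE)
  }
  targets <- model$targets
  miss <- setdiff(targets, names(data$traits))
  if (length(miss)) stop("dataset lacks target(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  n <- nrow(data$spectra)
  set.seed(cfg$seed)
  tr <- sort(sample.int(n, round(split * n)))
  te <- setdiff(seq_len(n), tr)
  Y <- as.matrix(data$traits[, targets, drop = FALSE])
  phen <- as.matrix(data$phenotype)

  arch <- cnn_arch(length(targets), n_phenotype = ncol(phen))
  init <- cnn_init(arch, seed = cfg$seed)
  init$W1 <- model$weights$W1; init$b1 <- model$weights$b1
  init$W2 <- model$weights$W2; init$b2 <- model$weights$b2

  core <- cnn_train_core(data$spectra[tr, , drop = FALSE],
                         Y[tr, , drop = FALSE], arch, cfg,
                         phen = phen[tr, , drop = FALSE],
                         init_weights = init, frozen_conv = TRUE)
  stopifnot(identical(core$weights$W1, model$weights$W1),
            identical(core$weights$W2, model$weights$W2))
  out <- new_canoret_cnn(core, targets, input = "spectrum+phenotype",
                         origin = "finetuned")
  pred <- cnn_predict_core(out, data$spectra[te, , drop = FALSE],
                           phen = phen[te, , drop = FALSE])
  out$metrics <- eval_targets(Y[te, , drop = FALSE], pred, targets)
  out$test_idx <- te
  out$predictions <- pred_tibble(te, Y[te, , drop = FALSE], pred, targets)
  out
}

#' Train the purely data-driven regressor
#'
#' Trains the same CNN family from random initialization on measured-style
#' spectra only (no simulated prior, no phenotype input) - the data-driven
#' baseline of the three-method comparison.
#'
#' @param data A `canoret_dataset` or list with `spectra` and `traits`.
#' @param targets Target trait columns.
#' @param cfg Training configuration; defaults to batch size 32 for the
#'   small measured-sample regime.
#' @param split Training fraction (default 0.5, matching the fine-tuning
#'   protocol so baselines share test sets under one seed).
#' @return A `canoret_cnn` with held-out `metrics`.
#' @export
train_data_driven <- function(data, targets = c("CCC", "CEW"),
                              cfg = training_config(batch_size = 32L),
                              split = 0.5) {
  if (nrow(data$spectra) < 20L) {
    stop("need at least 20 samples for data-driven training", call. = FALSE)
  }
  n <- nrow(data$spectra)
  set.seed(cfg$seed)
  tr <- sort(sample.int(n, round(split * n)))
  te <- setdiff(seq_len(n), tr)
  Y <- as.matrix(data$traits[, targets, drop = FALSE])
  core <- cnn_train_core(data$spectra[tr, , drop = FALSE],
                         Y[tr, , drop = FALSE],
                         cnn_arch(length(targets)), cfg)
  model <- new_canoret_cnn(core, targets, input = "spectrum",
                           origin = "data_driven")
  pred <- cnn_predict_core(model, data$spectra[te, , drop = FALSE])
  model$metrics <- eval_targets(Y[te, , drop = FALSE], pred, targets)
  model$test_idx <- te
  model$predictions <- pred_tibble(te, Y[te, , drop = FALSE], pred, targets)
  model
}

new_canoret_cnn <- function(core, targets, input, origin) {
  structure(
    list(weights = core$weights, arch = core$arch, norm = core$norm,
         log = core$log, config = core$config, targets = targets,
         input = input, origin = origin),
    class = "canoret_cnn"
  )
}

eval_targets <- function(Y, pred, targets) {
  dplyr::bind_rows(lapply(seq_along(targets), function(j) {
    dplyr::bind_cols(tibble::tibble(target = targets[j]),
                     evaluate_retrieval(Y[, j], pred[, j]))
  }))
}

pred_tibble <- function(idx, Y, pred, targets) {
  out <- tibble::tibble(sample = idx)
  for (j in seq_along(targets)) {
    out[[paste0(targets[j], "_true")]] <- Y[, j]
    out[[paste0(targets[j], "_pred")]] <- pred[, j]
  }
  out
}

#' Predict traits for new samples
#'
#' @param object A `canoret_cnn`.
#' @param spectra Spectrum matrix (n x 203 on the camera grid), a spectrum
#'   tibble, or a `canoret_dataset`.
#' @param phenotype Phenotype matrix (n x 5) for hybrid models; taken from
#'   `spectra$phenotype` when a dataset is given.
#' @param ... Unused.
#' @return Tibble with one column per target, rows in input order.
#' @export
predict.canoret_cnn <- function(object, spectra, phenotype = NULL, ...) {
  if (is.list(spectra) && !is.data.frame(spectra) && !is.matrix(spectra)) {
    phenotype <- spectra$phenotype
    spectra <- spectra$spectra
  }
  if (is.data.frame(spectra)) spectra <- matrix(spectra$reflectance, nrow = 1L)
  pred <- cnn_predict_core(object, spectra, phen = phenotype)
  colnames(pred) <- object$targets
  tibble::as_tibble(pred)
}

#' @export
print.canoret_cnn <- function(x, ...) {
  cat(sprintf("<canoret_cnn> %s (%s input) targets: %s | %d epochs trained\n",
              x$origin, x$input, paste(x$targets, collapse = ", "),
              max(x$log$epoch)))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Held-out evaluation metrics of a fitted model
#' @param x A `canoret_cnn`.
#' @param ... Unused.
#' @return Tibble with one row per target: `R`, `RMSE`, `RRMSE`, `GAI`, `n`.
#' @method tidy canoret_cnn
#' @export
tidy.canoret_cnn <- function(x, ...) x$metrics

#' One-row training summary of a fitted model
#' @param x A `canoret_cnn`.
#' @param ... Unused.
#' @return One-row tibble: origin, input schema, epochs, final losses.
#' @method glance canoret_cnn
#' @export
glance.canoret_cnn <- function(x, ...) {
  tibble::tibble(
    origin = x$origin, input = x$input,
    n_targets = length(x$targets),
    epochs = max(x$log$epoch),
    train_loss = x$log$train_loss[which.min(x$log$val_loss)],
    val_loss = min(x$log$val_loss)
  )
}
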