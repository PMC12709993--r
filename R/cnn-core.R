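#' Spectrum-to-image encoding for the convolutional regressor
#'
#' Arranges a 203-value reflectance vector as a 15 x 14 grid (row-major,
#' seven zero-padded trailing cells) so 2-D convolutions can be applied.
#' The mapping is a bijection on the real cells: element 1 of the vector
#' lands at grid position (1, 1) and [decode_spectrum()] recovers the
#' vector exactly.
#'
#' @param x Numeric vector of length 203 (or `nrow x 14` multiple).
#' @param shape Grid shape, default `c(15, 14)`.
#' @return List with `grid` (matrix `shape`), `pad_mask` (logical matrix,
#'   TRUE where zero-padded) and `n_values`.
#' @export
encode_spectrum <- function(x, shape = c(15L, 14L)) {
  n_cells <- prod(shape)
  if (length(x) > n_cells) stop("input longer than the encoding grid", call. = FALSE)
  if (length(x) != 203L) stop("expected a 203-value reflectance vector", call. = FALSE)
  padded <- c(as.numeric(x), rep(0, n_cells - length(x)))
  grid <- matrix(padded, nrow = shape[1], ncol = shape[2], byrow = TRUE)
  pad <- matrix(seq_len(n_cells) > length(x), nrow = shape[1], ncol = shape[2],
                byrow = TRUE)
  list(grid = grid, pad_mask = pad, n_values = length(x))
}

#' Invert [encode_spectrum()]
#' @param enc Encoding list from [encode_spectrum()].
#' @return The original numeric vector.
#' @export
decode_spectrum <- function(enc) {
  as.numeric(t(enc$grid))[seq_len(enc$n_values)]
}

#' Architecture description of the convolutional regressor
#'
#' Two 3x3 convolution blocks (16 then 32 filters, ReLU, 2x2 max-pool)
#' followed by a 64-unit dense layer and a linear output head; the
#' fine-tuning variant freezes the convolutions and replaces the head by
#' `concat(conv features, phenotype)` -> dense 32 -> dense 16 -> linear.
#'
#' @param n_targets Number of regression targets.
#' @param n_phenotype Phenotype input width (0 = spectrum-only).
#' @param shape Input grid shape.
#' @param filters Convolution filter counts.
#' @param dense Dense width of the spectrum-only head.
#' @param head Dense widths of the hybrid head.
#' @return List describing the architecture with precomputed gather
#'   indices for the im2col convolutions and poolings.
#' @export
cnn_arch <- function(n_targets, n_phenotype = 0L, shape = c(15L, 14L),
                     filters = c(16L, 32L), dense = 64L, head = c(32L, 16L)) {
  c1 <- conv_indices(shape[1], shape[2], 1L, filters[1])
  p1 <- pool_indices(c1$h_out, c1$w_out, filters[1])
  c2 <- conv_indices(p1$h_out, p1$w_out, filters[1], filters[2])
  p2 <- pool_indices(c2$h_out, c2$w_out, filters[2])
  list(
    shape = shape, filters = filters, dense = dense, head = head,
    n_targets = as.integer(n_targets), n_phenotype = as.integer(n_phenotype),
    conv1 = c1, pool1 = p1, conv2 = c2, pool2 = p2,
    n_flat = p2$h_out * p2$w_out * filters[2],
    cidx = list(idx1 = c1$idx, g1 = p1$gathers, idx2 = c2$idx,
                g2 = p2$gathers,
                ncol1 = as.integer(shape[1] * shape[2]),
                ncol2 = as.integer(p1$h_out * p1$w_out * filters[1]))
  )
}

# im2col gather indices for a valid 3x3 convolution on an H x W x C input
# stored as N x (H*W*C) with channel-major, row-major-position layout.
conv_indices <- function(h, w, c_in, c_out, k = 3L) {
  h_out <- h - k + 1L
  w_out <- w - k + 1L
  p_out <- h_out * w_out
  idx <- matrix(0L, p_out, k * k * c_in)
  for (ch in seq_len(c_in)) {
    for (di in seq_len(k)) {
      for (dj in seq_len(k)) {
        o <- (di - 1L) * k + dj
        col_k <- (ch - 1L) * k * k + o
        for (i in seq_len(h_out)) {
          for (j in seq_len(w_out)) {
            p <- (i - 1L) * w_out + j
            idx[p, col_k] <- (ch - 1L) * h * w + (i + di - 2L) * w + (j + dj - 1L)
          }
        }
      }
    }
  }
  list(idx = idx, h_in = h, w_in = w, c_in = c_in, c_out = c_out,
       h_out = h_out, w_out = w_out, p_out = p_out, k = k)
}

# 2x2 stride-2 max-pool gather indices (4 gathers, each aligned with the
# pooled output layout).
pool_indices <- function(h, w, c) {
  h_out <- h %/% 2L
  w_out <- w %/% 2L
  p_out <- h_out * w_out
  gathers <- vector("list", 4L)
  g <- 0L
  for (gi in 1:2) {
    for (gj in 1:2) {
      g <- g + 1L
      v <- integer(p_out * c)
      t <- 0L
      for (ch in seq_len(c)) {
        for (i in seq_len(h_out)) {
          for (j in seq_len(w_out)) {
            t <- t + 1L
            v[t] <- (ch - 1L) * h * w + (2L * i - 3L + gi) * w + (2L * j - 2L + gj)
          }
        }
      }
      gathers[[g]] <- v
    }
  }
  list(gathers = do.call(cbind, gathers), h_in = h, w_in = w, c = c,
       h_out = h_out, w_out = w_out, p_out = p_out)
}

# He-initialized weights for the given architecture.
cnn_init <- function(arch, seed = 1L) {
  set.seed(seed)
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  w <- list(
    W1 = he(9L * arch$conv1$c_in, arch$filters[1]), b1 = numeric(arch$filters[1]),
    W2 = he(9L * arch$conv2$c_in, arch$filters[2]), b2 = numeric(arch$filters[2])
  )
  if (arch$n_phenotype > 0L) {
    nin <- arch$n_flat + arch$n_phenotype
    w$Wh1 <- he(nin, arch$head[1]); w$bh1 <- numeric(arch$head[1])
    w$Wh2 <- he(arch$head[1], arch$head[2]); w$bh2 <- numeric(arch$head[2])
    w$Wo <- he(arch$head[2], arch$n_targets); w$bo <- numeric(arch$n_targets)
  } else {
    w$Wd <- he(arch$n_flat, arch$dense); w$bd <- numeric(arch$dense)
    w$Wo <- he(arch$dense, arch$n_targets); w$bo <- numeric(arch$n_targets)
  }
  w
}

conv_forward <- function(x, ci, W, b) {
  fw <- cpp_conv_fwd(x, ci$idx, W, b)
  names(fw) <- c("p", "z", "a")
  fw
}

conv_backward <- function(da_mat, fw, ci, W, n, need_dx = TRUE) {
  bw <- cpp_conv_bwd(da_mat, fw$z, fw$p, ci$idx, W, n, need_dx,
                     ci$h_in * ci$w_in * ci$c_in)
  list(dx = bw$dx, dW = bw$dW, db = as.numeric(bw$db))
}

pool_forward <- function(x, pi) {
  fw <- cpp_pool_fwd(x, pi$gathers)
  list(a = fw$A, which_g = fw$which)
}

pool_backward <- function(dm, fw, pi, n) {
  cpp_pool_bwd(dm, fw$which_g, pi$gathers, pi$h_in * pi$w_in * pi$c)
}

# Full forward pass. x: N x (H*W) zero-padded standardized spectra;
# phen: N x n_phenotype (hybrid only). Returns prediction and cached
# intermediates for backprop.
cnn_forward <- function(w, x, arch, phen = NULL) {
  n <- nrow(x)
  c1 <- conv_forward(x, arch$conv1, w$W1, w$b1)
  p1 <- pool_forward(c1$a, arch$pool1)
  c2 <- conv_forward(p1$a, arch$conv2, w$W2, w$b2)
  p2 <- pool_forward(c2$a, arch$pool2)
  flat <- p2$a
  if (arch$n_phenotype > 0L) {
    hin <- cbind(flat, phen)
    z1 <- sweep(hin %*% w$Wh1, 2L, w$bh1, "+"); a1 <- pmax(z1, 0)
    z2 <- sweep(a1 %*% w$Wh2, 2L, w$bh2, "+"); a2 <- pmax(z2, 0)
    pred <- sweep(a2 %*% w$Wo, 2L, w$bo, "+")
    list(pred = pred, c1 = c1, p1 = p1, c2 = c2, p2 = p2, hin = hin,
         z1 = z1, a1 = a1, z2 = z2, a2 = a2)
  } else {
    zd <- sweep(flat %*% w$Wd, 2L, w$bd, "+"); ad <- pmax(zd, 0)
    pred <- sweep(ad %*% w$Wo, 2L, w$bo, "+")
    list(pred = pred, c1 = c1, p1 = p1, c2 = c2, p2 = p2, flat = flat,
         zd = zd, ad = ad)
  }
}

# Gradients of mean-squared-error loss w.r.t. all weights.
cnn_backward <- function(w, fw, x, y, arch, frozen_conv = FALSE) {
  n <- nrow(x)
  dpred <- 2 * (fw$pred - y) / length(y)
  g <- list()
  if (arch$n_phenotype > 0L) {
    g$dWo <- crossprod(fw$a2, dpred); g$dbo <- colSums(dpred)
    da2 <- tcrossprod(dpred, w$Wo); da2[fw$z2 <= 0] <- 0
    g$dWh2 <- crossprod(fw$a1, da2); g$dbh2 <- colSums(da2)
    da1 <- tcrossprod(da2, w$Wh2); da1[fw$z1 <= 0] <- 0
    g$dWh1 <- crossprod(fw$hin, da1); g$dbh1 <- colSums(da1)
    dflat <- tcrossprod(da1, w$Wh1)[, seq_len(arch$n_flat), drop = FALSE]
  } else {
    g$dWo <- crossprod(fw$ad, dpred); g$dbo <- colSums(dpred)
    dad <- tcrossprod(dpred, w$Wo); dad[fw$zd <= 0] <- 0
    g$dWd <- crossprod(fw$flat, dad); g$dbd <- colSums(dad)
    dflat <- tcrossprod(dad, w$Wd)
  }
  if (!frozen_conv) {
    dp2 <- pool_backward(dflat, fw$p2, arch$pool2, n)
    bc2 <- conv_backward(dp2, fw$c2, arch$conv2, w$W2, n)
    g$dW2 <- bc2$dW; g$db2 <- bc2$db
    dp1 <- pool_backward(bc2$dx, fw$p1, arch$pool1, n)
    bc1 <- conv_backward(dp1, fw$c1, arch$conv1, w$W1, n, need_dx = FALSE)
    g$dW1 <- bc1$dW; g$db1 <- bc1$db
  }
  g
}

#' Training configuration for the convolutional regressor
#'
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); the best weights are restored.
#' @param val_fraction Fraction of the training split held out for early
#'   stopping.
#' @param seed Integer seed governing splits, initialization and
#'   shuffling.
#' @param lr_decay Factor applied to the learning rate when the validation
#'   loss has not improved for `lr_patience` epochs (reduce-on-plateau).
#' @param lr_patience Plateau length (epochs) triggering a decay step.
#' @param min_lr Floor for the decayed learning rate.
#' @return List of settings.
#' @export
training_config <- function(epochs = 300L, batch_size = 256L, lr = 1e-3,
                            patience = 30L, val_fraction = 0.1, seed = 1L,
                            lr_decay = 0.5, lr_patience = 10L, min_lr = 1e-5) {
  list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr = lr, patience = as.integer(patience),
       val_fraction = val_fraction, seed = as.integer(seed),
       lr_decay = lr_decay, lr_patience = as.integer(lr_patience),
       min_lr = min_lr)
}

# Adam update; state holds first/second moments per weight tensor.
adam_step <- function(w, g, state, lr, t, trainable,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in trainable) {
    gn <- paste0("d", nm)
    if (is.null(g[[gn]])) next
    if (!is.matrix(w[[nm]])) g[[gn]] <- as.numeric(g[[gn]])
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[gn]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[gn]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, state = state)
}

# Core trainer: standardizes inputs/targets, runs minibatch Adam with
# early stopping, returns weights + normalization + training log.
cnn_train_core <- function(spectra, targets, arch, cfg, phen = NULL,
                           init_weights = NULL, frozen_conv = FALSE) {
  n <- nrow(spectra)
  stopifnot(ncol(spectra) == 203L)
  x_center <- colMeans(spectra)
  x_scale <- apply(spectra, 2L, stats::sd)
  x_scale[x_scale < 1e-12] <- 1
  xs <- sweep(sweep(spectra, 2L, x_center), 2L, x_scale, "/")
  xs <- cbind(xs, matrix(0, n, prod(arch$shape) - 203L))

  y <- as.matrix(targets)
  y_center <- colMeans(y)
  y_scale <- apply(y, 2L, stats::sd)
  # zero-variance targets are degenerate: the exact predictor is the
  # constant itself, recorded via y_scale = 0 and honored at prediction
  y_const <- y_scale < 1e-12
  y_scale[y_const] <- 0
  ys <- sweep(sweep(y, 2L, y_center), 2L,
              ifelse(y_const, 1, y_scale), "/")

  p_center <- NULL; p_scale <- NULL; ps <- NULL
  if (!is.null(phen)) {
    phen <- as.matrix(phen)
    p_center <- colMeans(phen)
    p_scale <- apply(phen, 2L, stats::sd)
    p_scale[p_scale < 1e-12] <- 1
    ps <- sweep(sweep(phen, 2L, p_center), 2L, p_scale, "/")
  }

  set.seed(cfg$seed)
  w <- if (is.null(init_weights)) cnn_init(arch, seed = cfg$seed) else init_weights
  trainable <- names(w)
  if (frozen_conv) trainable <- setdiff(trainable, c("W1", "b1", "W2", "b2"))

  n_val <- max(2L, round(cfg$val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) < 2L) { tr_idx <- seq_len(n); val_idx <- seq_len(n) }

  state <- list(m = lapply(w, function(z) z * 0), v = lapply(w, function(z) z * 0))
  best <- list(loss = Inf, w = w, epoch = 0L)
  t_step <- 0L
  lr_now <- cfg$lr
  last_decay <- 0L
  log <- vector("list", cfg$epochs)
  hybrid <- arch$n_phenotype > 0L
  mse <- function(idx) {
    pred <- cpp_cnn_predict(w, xs[idx, , drop = FALSE], arch$cidx, hybrid,
                            if (is.null(ps)) NULL else ps[idx, , drop = FALSE])
    mean((pred - ys[idx, , drop = FALSE])^2)
  }
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample(tr_idx)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    tr_loss <- 0
    for (b in batches) {
      res <- cpp_cnn_step(
        w, xs[b, , drop = FALSE], ys[b, , drop = FALSE], arch$cidx,
        hybrid, frozen_conv,
        if (is.null(ps)) NULL else ps[b, , drop = FALSE]
      )
      t_step <- t_step + 1L
      up <- adam_step(w, res$grads, state, lr_now, t_step, trainable)
      w <- up$w; state <- up$state
      tr_loss <- tr_loss + res$loss * length(b)
    }
    tr_loss <- tr_loss / length(ord)
    val_loss <- mse(val_idx)
    log[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = tr_loss,
                                   val_loss = val_loss)
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, w = w, epoch = epoch)
    } else {
      if (epoch - max(best$epoch, last_decay) >= cfg$lr_patience &&
          lr_now > cfg$min_lr) {
        lr_now <- max(lr_now * cfg$lr_decay, cfg$min_lr)
        last_decay <- epoch
      }
      if (epoch - best$epoch >= cfg$patience) break
    }
  }
  list(
    weights = best$w, arch = arch,
    norm = list(x_center = x_center, x_scale = x_scale,
                y_center = y_center, y_scale = y_scale,
                p_center = p_center, p_scale = p_scale),
    log = dplyr::bind_rows(log[!vapply(log, is.null, logical(1))]),
    config = cfg
  )
}

# Predict on raw spectra (and phenotype for hybrid nets) using stored
# normalization; returns de-standardized target matrix.
cnn_predict_core <- function(model, spectra, phen = NULL) {
  arch <- model$arch
  nm <- model$norm
  xs <- sweep(sweep(spectra, 2L, nm$x_center), 2L, nm$x_scale, "/")
  xs <- cbind(xs, matrix(0, nrow(spectra), prod(arch$shape) - 203L))
  ps <- NULL
  if (arch$n_phenotype > 0L) {
    if (is.null(phen)) stop("this model requires a phenotype matrix", call. = FALSE)
    ps <- sweep(sweep(as.matrix(phen), 2L, nm$p_center), 2L, nm$p_scale, "/")
  }
  pred <- cpp_cnn_predict(model$weights, xs, arch$cidx,
                          arch$n_phenotype > 0L, ps)
  sweep(sweep(pred, 2L, nm$y_scale, "*"), 2L, nm$y_center, "+")
}
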