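# Convolutional regressor core: encoding, gradients, training mechanics.

test_that("spectrum-image encoding is a bijection with the stated convention", {
  set.seed(1)
  for (i in 1:5) {
    v <- runif(203)
    enc <- encode_spectrum(v)
    expect_equal(dim(enc$grid), c(15L, 14L))
    expect_equal(decode_spectrum(enc), v)
  }
  v <- seq_len(203) / 203
  enc <- encode_spectrum(v)
  expect_equal(enc$grid[1, 1], v[1])          # element 1 at grid (1,1)
  expect_equal(enc$grid[1, 14], v[14])        # row-major fill
  expect_equal(enc$grid[2, 1], v[15])
  expect_equal(sum(enc$pad_mask), 7L)         # 15*14 - 203 pad cells
  expect_true(all(enc$grid[enc$pad_mask] == 0))

  const <- encode_spectrum(rep(0.3, 203))
  expect_true(all(const$grid[!const$pad_mask] == 0.3))
  expect_error(encode_spectrum(runif(200)), "203")
})

test_that("analytic gradients match finite differences for both architectures", {
  set.seed(42)
  for (nph in c(0L, 5L)) {
    arch <- canoret:::cnn_arch(2L, n_phenotype = nph)
    w <- canoret:::cnn_init(arch, seed = 3)
    n <- 4L
    x <- matrix(rnorm(n * 210), n, 210)
    y <- matrix(rnorm(n * 2), n, 2)
    ph <- if (nph > 0) matrix(rnorm(n * 5), n, 5) else NULL
    fw <- canoret:::cnn_forward(w, x, arch, ph)
    g <- canoret:::cnn_backward(w, fw, x, y, arch)
    loss <- function(w) {
      f <- canoret:::cnn_forward(w, x, arch, ph)
      mean((f$pred - y)^2)
    }
    for (nm in names(w)) {
      gn <- g[[paste0("d", nm)]]
      if (is.null(gn)) next
      for (k in 1:3) {
        i <- sample(length(w[[nm]]), 1)
        eps <- 1e-6
        wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
        wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
        num <- (loss(wp) - loss(wm)) / (2 * eps)
        expect_equal(gn[i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("the fused training step reproduces the modular forward/backward path", {
  set.seed(5)
  x <- matrix(rnorm(8 * 210), 8, 210)
  y <- matrix(rnorm(8 * 2), 8, 2)
  for (nph in c(0L, 5L)) {
    arch <- canoret:::cnn_arch(2L, n_phenotype = nph)
    w <- canoret:::cnn_init(arch, seed = 5)
    ph <- if (nph > 0) matrix(rnorm(8 * 5), 8, 5) else NULL
    fw <- canoret:::cnn_forward(w, x, arch, ph)
    gR <- canoret:::cnn_backward(w, fw, x, y, arch)
    res <- canoret:::cpp_cnn_step(w, x, y, arch$cidx, nph > 0, FALSE, ph)
    expect_equal(res$loss, mean((fw$pred - y)^2), tolerance = 1e-12)
    for (nm in names(gR)) {
      expect_equal(as.numeric(gR[[nm]]), as.numeric(res$grads[[nm]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("the network can overfit a tiny dataset (optimization sanity)", {
  set.seed(2)
  X <- matrix(runif(10 * 203), 10, 203)
  Y <- matrix(rnorm(10), 10, 1)
  m <- canoret:::cnn_train_core(X, Y, canoret:::cnn_arch(1L),
                      training_config(epochs = 300, batch_size = 10,
                                      lr = 3e-3, patience = 300,
                                      val_fraction = 0.2, seed = 1))
  expect_lt(dplyr::last(m$log$train_loss), 1e-3 * m$log$train_loss[1])
})

test_that("a constant target is learned with near-zero error", {
  set.seed(3)
  X <- matrix(runif(60 * 203), 60, 203)
  Y <- matrix(5, 60, 1)
  m <- canoret:::cnn_train_core(X, Y, canoret:::cnn_arch(1L),
                                fast_cfg(epochs = 20))
  pred <- canoret:::cnn_predict_core(m, X)
  expect_lt(sqrt(mean((pred - 5)^2)), 1e-9)
  # unseen inputs also get the constant
  pred2 <- canoret:::cnn_predict_core(m, matrix(runif(5 * 203), 5, 203))
  expect_lt(max(abs(pred2 - 5)), 1e-9)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(99)
  X <- matrix(runif(80 * 203), 80, 203)
  Y <- matrix(rowMeans(X) + rnorm(80, 0, 0.01), 80, 1)
  m1 <- canoret:::cnn_train_core(X, Y, canoret:::cnn_arch(1L), fast_cfg(seed = 7, epochs = 20))
  m2 <- canoret:::cnn_train_core(X, Y, canoret:::cnn_arch(1L), fast_cfg(seed = 7, epochs = 20))
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$log, m2$log)
})

test_that("batch prediction preserves order and equals single predictions", {
  set.seed(4)
  X <- matrix(runif(30 * 203), 30, 203)
  Y <- matrix(rnorm(30 * 2), 30, 2)
  m <- canoret:::cnn_train_core(X, Y, canoret:::cnn_arch(2L), fast_cfg(epochs = 5))
  batch <- canoret:::cnn_predict_core(m, X)
  singles <- do.call(rbind, lapply(seq_len(30), function(i) {
    canoret:::cnn_predict_core(m, X[i, , drop = FALSE])
  }))
  expect_equal(batch, singles, tolerance = 1e-12)
  perm <- sample(30)
  expect_equal(canoret:::cnn_predict_core(m, X[perm, ]), batch[perm, ], tolerance = 1e-12)
})
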