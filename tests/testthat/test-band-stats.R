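# Waveband screening, discriminant projection and treatment distances.

make_null_spectra <- function(n_per_group = 5, groups = 3, bands = 4) {
  m <- matrix(rnorm(n_per_group * groups * bands, 0.3, 0.05),
              n_per_group * groups, bands)
  grouped_spectra(m, rep(letters[seq_len(groups)], each = n_per_group))
}

test_that("screening controls the per-band type-I error near alpha", {
  set.seed(31)
  alpha <- 0.05
  n_sims <- 500
  bands <- 4
  flags <- matrix(FALSE, n_sims, bands)
  for (s in seq_len(n_sims)) {
    res <- screen_bands(make_null_spectra(bands = bands), alpha = alpha)
    flags[s, ] <- res$per_band$count > 0
  }
  rate <- colMeans(flags)
  half_width <- 2 * sqrt(alpha * (1 - alpha) / n_sims)
  for (j in seq_len(bands)) {
    expect_lt(rate[j], alpha + half_width)
    expect_gt(rate[j], alpha - half_width)
  }
})

test_that("a strong single-band effect is counted in every batch", {
  set.seed(7)
  n <- 6
  batches <- 3
  rows <- list(); grp <- c(); bat <- c()
  for (b in seq_len(batches)) {
    g1 <- matrix(rnorm(n * 5, 0.3, 0.01), n, 5)
    g2 <- matrix(rnorm(n * 5, 0.3, 0.01), n, 5)
    g2[, 3] <- g2[, 3] + 0.1   # 10 sd shift at band 3 only
    rows[[b]] <- rbind(g1, g2)
    grp <- c(grp, rep(c("WF", "WS"), each = n))
    bat <- c(bat, rep(b, 2 * n))
  }
  data <- grouped_spectra(do.call(rbind, rows), grp, bat)
  res <- screen_bands(data)
  counts <- res$per_band$count[order(canoret:::band_name_to_nm(res$per_band$band))]
  expect_equal(counts[3], batches)
  expect_true(all(counts[-3] <= 1))
})

test_that("single-batch counts are binary and constant bands get p = 1", {
  set.seed(8)
  m <- matrix(rnorm(12 * 3, 0.4, 0.02), 12, 3)
  m[, 2] <- 0.25   # zero-variance band
  res <- screen_bands(grouped_spectra(m, rep(c("a", "b"), each = 6)))
  expect_true(all(res$per_band$count %in% c(0L, 1L)))
  pb <- res$per_batch
  expect_equal(pb$p_anova[pb$band == "band_2"], 1)
  expect_false(pb$significant[pb$band == "band_2"])
})

test_that("screening rejects degenerate group structures", {
  m <- matrix(rnorm(8), 4, 2)
  expect_error(screen_bands(grouped_spectra(m, rep("a", 4))), "2 treatment groups")
  expect_error(screen_bands(grouped_spectra(m, c("a", "a", "a", "b"))),
               ">= 2 samples")
})

test_that("scatter matrices match an element-wise brute-force computation", {
  set.seed(9)
  X <- matrix(rnorm(6 * 3), 6, 3)
  y <- c("a", "a", "b", "b", "c", "c")
  fit <- fit_lda(X, y, dims = 2)
  # brute force on the standardized features
  Z <- sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, sd), "/")
  Sw <- matrix(0, 3, 3); ms <- list()
  for (cl in unique(y)) {
    Zk <- Z[y == cl, , drop = FALSE]
    mk <- colMeans(Zk)
    ms[[cl]] <- mk
    acc <- matrix(0, 3, 3)
    for (i in seq_len(nrow(Zk))) acc <- acc + Zk[i, ] %*% t(Zk[i, ])
    Sw <- Sw + acc / nrow(Zk) - mk %*% t(mk)
  }
  Sb <- matrix(0, 3, 3)
  for (i in names(ms)) for (j in names(ms)) if (i != j) {
    d <- ms[[i]] - ms[[j]]
    Sb <- Sb + d %*% t(d)
  }
  expect_equal(fit$S_w, Sw, tolerance = 1e-12)
  expect_equal(fit$S_b, Sb, tolerance = 1e-12)
})

test_that("the leading discriminant matches the closed-form Fisher direction", {
  set.seed(10)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rep(c("a", "b"), each = n / 2)
  X[y == "b", 1] <- X[y == "b", 1] + 4   # separation along axis 1
  fit <- fit_lda(X, y, dims = 1)
  # oracle: w = Sw^-1 (m1 - m2) on the same standardized features
  Z <- sweep(sweep(X, 2, fit$center), 2, fit$scale, "/")
  m1 <- colMeans(Z[y == "a", ]); m2 <- colMeans(Z[y == "b", ])
  Sw <- fit$S_w
  w_oracle <- solve(Sw, m1 - m2)
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  cosine <- abs(sum(fit$W[, 1] * w_oracle))
  expect_gt(cosine, 0.99)
  # and the direction is essentially axis 1
  expect_gt(abs(fit$W[1, 1]), 0.95)
})

test_that("the projection maximizes the Fisher ratio over random directions", {
  set.seed(11)
  n <- 45
  X <- matrix(rnorm(n * 4), n, 4)
  y <- rep(c("a", "b", "c"), each = n / 3)
  X[y == "b", 2] <- X[y == "b", 2] + 2
  X[y == "c", 3] <- X[y == "c", 3] + 3
  fit <- fit_lda(X, y, dims = 1)
  ratio <- function(w) {
    as.numeric(t(w) %*% fit$S_b %*% w) / as.numeric(t(w) %*% fit$S_w %*% w)
  }
  r_lda <- ratio(fit$W[, 1])
  rand <- replicate(1000, {
    w <- rnorm(4)
    ratio(w / sqrt(sum(w^2)))
  })
  expect_true(all(rand <= r_lda + 1e-9))
})

test_that("projection workflow is invariant to feature permutation", {
  set.seed(12)
  X <- matrix(rnorm(40 * 4), 40, 4)
  y <- rep(c("a", "b"), each = 20)
  X[y == "b", ] <- X[y == "b", ] + matrix(rep(c(1, 2, 0, -1), each = 20), 20)
  perm <- c(3, 1, 4, 2)
  f1 <- fit_lda(X, y, dims = 1)
  f2 <- fit_lda(X[, perm], y, dims = 1)
  p1 <- predict(f1, X)
  p2 <- predict(f2, X[, perm])
  # projected coordinates agree up to sign
  expect_equal(abs(cor(p1$LD1, p2$LD1)), 1, tolerance = 1e-9)
  # class-mean distances identical
  d1 <- abs(mean(p1$LD1[y == "a"]) - mean(p1$LD1[y == "b"]))
  d2 <- abs(mean(p2$LD1[y == "a"]) - mean(p2$LD1[y == "b"]))
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("group distances behave like Euclidean geometry", {
  proj <- rbind(c(0, 0), c(0, 0), c(3, 4), c(3, 4))
  labs <- c("WF", "WF", "WS", "WS")
  d <- group_distance(proj, labs, baseline = "WF")
  expect_equal(d$mean_distance[d$group == "WF"], 0)
  expect_equal(d$mean_distance[d$group == "WS"], 5)
  # identical samples: all distances zero
  same <- group_distance(matrix(1, 6, 2), rep(c("WF", "WS"), 3), "WF")
  expect_true(all(same$mean_distance == 0))
  # invariance under rotation of the projected plane
  set.seed(13)
  P <- matrix(rnorm(20 * 2), 20, 2)
  labs2 <- rep(c("WF", "WS"), 10)
  th <- 0.7
  Rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  d0 <- group_distance(P, labs2, "WF")
  d1 <- group_distance(P %*% Rot, labs2, "WF")
  expect_equal(d0$mean_distance, d1$mean_distance, tolerance = 1e-12)
  expect_error(group_distance(P, labs2, baseline = "XX"), "not present")
})

test_that("stressed groups separate further than the baseline dispersion", {
  # mirrors the treatment-gap pattern: mean shift >= 3 within-group sd
  set.seed(14)
  n <- 30
  X <- rbind(matrix(rnorm(n * 6, 0, 1), n, 6),
             matrix(rnorm(n * 6, 0, 1), n, 6) + 3.5)
  y <- rep(c("WF", "WS"), each = n)
  fit <- fit_lda(X, y, dims = 1)
  proj <- predict(fit, X)
  d <- group_distance(proj, y, "WF")
  expect_gt(d$mean_distance[d$group == "WS"],
            d$mean_distance[d$group == "WF"])
})
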