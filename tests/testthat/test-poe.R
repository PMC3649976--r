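test_that("log unnormalized density follows the product-of-Student-t form", {
  W <- matrix(c(1, 0, 0, 1), 2)
  # x orthogonal to every filter row
  expect_equal(poe_log_unnorm(c(0, 0), W, c(1, 2)), 0)
  expect_equal(poe_log_unnorm(c(0, 0, 1),
                              matrix(c(1, 0, 0, 0, 1, 0), 2, byrow = TRUE),
                              c(1, 1)), 0)
  # single expert, alpha 1, w.x = sqrt(2): -log(1 + 1) = -log 2
  expect_equal(poe_log_unnorm(sqrt(2), matrix(1), 1), -log(2))
  # even in x
  for (i in 1:5) {
    x <- stats::rnorm(2)
    W2 <- matrix(stats::rnorm(6), 3, 2)
    a <- stats::rexp(3) + 0.1
    expect_equal(poe_log_unnorm(x, W2, a), poe_log_unnorm(-x, W2, a))
  }
  expect_error(poe_log_unnorm(c(0, 0), W, c(1, -1)), "positive")
})

test_that("training is bit-reproducible under a fixed seed", {
  set.seed(10)
  Z <- matrix(stats::rt(600 * 4, 5), ncol = 4)
  cfg <- train_config(M = 6, n_epochs = 3, batch_size = 50, seed = 3)
  m1 <- poe_train_cd(Z, cfg)
  m2 <- poe_train_cd(Z, cfg)
  expect_identical(m1$W, m2$W)
  expect_identical(m1$alpha, m2$alpha)
})

test_that("training failure with non-finite parameters is reported with the iteration", {
  set.seed(11)
  Z <- matrix(stats::rt(500 * 3, 4), ncol = 3)
  cfg <- train_config(M = 4, n_epochs = 5, learning_rate = 1e8,
                      lr_decay = 0, seed = 1)
  expect_error(poe_train_cd(Z, cfg), "update")
})

test_that("the complete model performs ICA: 2-D toy sources are recovered", {
  set.seed(12)
  n <- 8000
  S <- cbind(stats::rt(n, 4), stats::rt(n, 4))
  A <- matrix(c(2, 1, 1, 1.5), 2)
  X <- S %*% t(A)
  wm <- fit_whitening(X, k = 2)
  m <- poe_train_cd(whiten(wm, X), train_config(M = 2, n_epochs = 40,
                                                seed = 7))
  # input-space unmixing map of a whitened-space filter row w is
  # w diag(1/sqrt(lambda)) V; recovered unmixing composed with the true
  # mixing must be a scaled permutation
  unmix <- function(W) W %*% (wm$components * (1 / sqrt(wm$eigenvalues)))
  expect_lt(amari_index(unmix(m$W) %*% A), 0.1)
  # cross-check against an independent FastICA estimate of the same data
  ica_ref <- fit_ica(whiten(wm, X), seed = 1)
  expect_lt(amari_index(unmix(ica_ref$W) %*% A), 0.1)
})

test_that("HMC on a single Student-t expert reproduces the analytic distribution", {
  # one expert with alpha = 1.5 on a unit filter is exactly t(df = 2)
  withr::with_seed(13, {
    W <- matrix(1, 1, 1)
    X <- matrix(stats::rnorm(10000), ncol = 1)
    for (i in 1:60) {
      X <- poe_sample(X, W, alpha = 1.5, steps = 1, sampler = "hmc",
                      eps = 1.0, n_leapfrog = 5)$X
    }
    ks <- suppressWarnings(
      stats::ks.test(as.vector(X), function(q) stats::pt(q, df = 2)))
    expect_lt(unname(ks$statistic), 0.05)
  })
})

test_that("Langevin sampling approximately tracks the expert distribution", {
  withr::with_seed(14, {
    W <- matrix(1, 1, 1)
    X <- matrix(stats::rnorm(8000), ncol = 1)
    X <- poe_sample(X, W, alpha = 1.5, steps = 80, sampler = "langevin",
                    eps = 0.35)$X
    ks <- suppressWarnings(
      stats::ks.test(as.vector(X), function(q) stats::pt(q, df = 2)))
    expect_lt(unname(ks$statistic), 0.08)
  })
})

test_that("the long-chain CD gradient matches the exact likelihood gradient", {
  withr::with_seed(15, {
    W <- matrix(stats::rnorm(4), 2, 2)
    alpha <- c(1.5, 1.8)
    Xd <- cbind(stats::rt(4000, 3), stats::rt(4000, 3)) %*%
      matrix(c(1, 0.4, 0.2, 1), 2)
    gpos <- v1rear:::poe_grad_params(Xd, W, alpha)
    # exact model expectation of the energy gradient by 2-D quadrature
    g <- seq(-60, 60, by = 0.05)
    quad_gW <- matrix(0, 2, 2)
    Zc <- 0
    for (chunk in split(g, ceiling(seq_along(g) / 200))) {
      Xg <- as.matrix(expand.grid(chunk, g))
      S <- Xg %*% t(W)
      p <- exp(-rowSums(sweep(log1p(0.5 * S^2), 2, alpha, `*`)))
      Phi <- sweep(S / (1 + 0.5 * S^2), 2, alpha, `*`)
      quad_gW <- quad_gW + crossprod(Phi * p, Xg)
      Zc <- Zc + sum(p)
    }
    exact <- quad_gW / Zc - gpos$W
    Xs <- Xd
    for (i in 1:80) {
      Xs <- poe_sample(Xs, W, alpha, steps = 1, sampler = "hmc", eps = 0.8,
                       n_leapfrog = 5)$X
    }
    cd <- v1rear:::poe_grad_params(Xs, W, alpha)$W - gpos$W
    cosine <- sum(exact * cd) / sqrt(sum(exact^2) * sum(cd^2))
    expect_gt(cosine, 0.95)
  })
})

test_that("PoE learns mostly oriented fields from monocular naturalistic patches", {
  res <- cached("poe_monocular_gabors", {
    imgs <- fixture_images()
    ps <- extract_patches(imgs, 8000, patch_side = 16, region = 192,
                          seed = 51)
    eye <- split_eyes(ps$data)$left # monocular training set
    wm <- fit_whitening(eye, k = 48)
    m <- poe_train_cd(whiten(wm, eye),
                      train_config(M = 72, n_epochs = 60, seed = 51))
    filters_to_pixel_space(m$W, wm)
  })
  bank <- grating_bank(16)
  cvs <- apply(res, 1, function(rf) {
    surf <- grating_response(rf, bank = bank)
    best_sf <- which.max(apply(surf$response, 2, max))
    circular_variance(surf$response[, best_sf], bank$orientations)
  })
  expect_gte(mean(cvs < 0.6), 0.5)
})
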