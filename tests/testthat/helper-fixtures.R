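# Shared fixtures and oracles. Expensive condition runs are memoized so that
# the qualitative-reproduction, invariant and statistics tests reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small shared stereo image set (deterministic).
fixture_images <- function(n = 8, size = 256, seed = 101) {
  cached(sprintf("img_%d_%d_%d", n, size, seed),
         gen_naturalistic_stereo(n, size = size, seed = seed))
}

# Desk-scale condition run: 16x16 binocular patches, k = 48, M = 72
# (1.5x overcomplete), 8000 patches, 60 training epochs.
desk_run <- function(config, seed = 1, learner = "poe", key = NULL) {
  key <- key %||% paste("desk", config$condition, learner, seed,
                        config$binocular_fraction, config$noise_fraction,
                        sep = "_")
  cached(key, {
    tc <- train_config(M = 72, n_epochs = 60, seed = seed)
    run_condition(config, images = fixture_images(), learner = learner,
                  seed = seed, n_patches = 8000, patch_side = 16, k = 48,
                  train_cfg = tc)
  })
}

# Mini-scale run for repeat-based checks: 12x12 patches, k = 36, M = 54,
# 5000 patches, 40 epochs.
mini_run <- function(config, seed = 1) {
  key <- paste("mini", config$condition, seed, sep = "_")
  cached(key, {
    tc <- train_config(M = 54, n_epochs = 40, seed = seed)
    run_condition(config, images = fixture_images(6, 256, 202), seed = seed,
                  n_patches = 5000, patch_side = 12, k = 36,
                  region = 160, train_cfg = tc)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Amari permutation-invariance index of P = W_est %*% A_true: 0 iff P is a
# scaled permutation.
amari_index <- function(P) {
  P <- abs(P)
  n <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1)
  c <- sum(colSums(P / apply(P, 2, max)) - 1)
  (r + c) / (2 * n * (n - 1))
}

# Radially averaged log-log power-spectrum slope by an independent FFT +
# least-squares fit.
spectrum_slope <- function(img) {
  n <- nrow(img)
  ps <- Mod(stats::fft(img))^2
  fx <- c(0:(n / 2), -((n / 2 - 1):1)) / n
  fgrid <- sqrt(outer(fx^2, fx^2, "+"))
  f <- as.vector(fgrid)
  p <- as.vector(ps)
  bins <- cut(f, breaks = exp(seq(log(2 / n), log(0.5), length.out = 30)))
  mp <- tapply(p, bins, mean)
  mf <- tapply(f, bins, mean)
  ok <- is.finite(mp) & is.finite(mf) & mp > 0
  unname(stats::coef(stats::lm(log(mp[ok]) ~ log(mf[ok])))[2])
}

# Spectral energy of an image in an orientation sector (structure
# orientation within +/- half_width degrees of `ori`), by direct FFT
# sector integration.
sector_energy <- function(img, ori, half_width = 20) {
  h <- nrow(img)
  w <- ncol(img)
  sp <- Mod(stats::fft(img))^2
  fy <- (seq_len(h) - 1) / h
  fy[fy > 0.5] <- fy[fy > 0.5] - 1
  fx <- (seq_len(w) - 1) / w
  fx[fx > 0.5] <- fx[fx > 0.5] - 1
  u <- matrix(fx, h, w, byrow = TRUE)
  v <- matrix(fy, h, w)
  theta <- atan2(u, v) * 180 / pi # structure orientation of each component
  d <- abs((theta - ori) %% 180)
  d <- pmin(d, 180 - d)
  sel <- d <= half_width
  sel[1, 1] <- FALSE
  sum(sp[sel])
}

# Circular orientation difference in degrees, period 180.
ori_diff_deg <- function(a, b) {
  d <- abs((a - b) %% 180)
  min(d, 180 - d)
}

# A P x P Gabor patch with bar orientation `ori` (deg) and SF cycles/pixel.
gabor_patch <- function(p, ori, sf, phase = 0, sigma = p / 5) {
  xy <- expand.grid(y = seq_len(p) - (p + 1) / 2,
                    x = seq_len(p) - (p + 1) / 2)
  th <- ori * pi / 180
  across <- xy$x * sin(th) + xy$y * cos(th)
  along <- xy$x * cos(th) - xy$y * sin(th)
  g <- exp(-(across^2 + along^2) / (2 * sigma^2)) *
    cos(2 * pi * sf * across + phase)
  matrix(g, p, p)
}
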