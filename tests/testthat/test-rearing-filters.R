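test_that("oriented Gaussian filter: identity, DC preservation, sector attenuation", {
  img <- matrix(stats::rnorm(128 * 128), 128)
  expect_equal(oriented_gaussian_filter(img, 45, 0), img, tolerance = 1e-10)
  cst <- matrix(3.7, 64, 64)
  expect_equal(oriented_gaussian_filter(cst, 30, 5), cst, tolerance = 1e-8)

  # strong horizontal filter on isotropic noise: vertical-structure energy
  # crushed relative to horizontal-structure energy (FFT sector oracle)
  filt <- oriented_gaussian_filter(img, 0, 8)
  expect_lt(sector_energy(filt, 90) / sector_energy(filt, 0), 0.1)
  # and mean (DC) is preserved
  expect_equal(mean(filt), mean(img), tolerance = 1e-10)
})

test_that("boxcar occlusion removes contrast as a direct convolution would", {
  cst <- matrix(2.5, 40, 40)
  expect_equal(boxcar_occlude(cst, 15), cst, tolerance = 1e-10)
  img <- matrix(stats::rnorm(600 * 600), 600)
  expect_identical(boxcar_occlude(img, 1), img)

  sm <- boxcar_occlude(img, 150)
  # variance of a box average of iid noise drops by the kernel area
  expect_equal(stats::var(as.vector(sm)), 1 / 150^2, tolerance = 0.25)
  # interior pixels agree with a direct sliding-window mean (the even
  # 150-px kernel window sits at offsets -74 .. +75)
  for (pt in list(c(300, 300), c(200, 411))) {
    r <- pt[1]; cc <- pt[2]
    direct <- mean(img[(r - 74):(r + 75), (cc - 74):(cc + 75)])
    expect_equal(sm[r, cc], direct, tolerance = 1e-8)
  }
})

test_that("monocular deprivation removes nearly all deprived-eye variance", {
  imgs <- fixture_images(4)
  cfg <- rearing_config("monocular", deprived_eye = "right")
  ps <- build_training_set(cfg, imgs, 1000, patch_side = 16, region = 192,
                           seed = 6)
  e <- split_eyes(ps$data)
  ev <- function(m) mean(apply(m, 1, stats::var))
  expect_lt(ev(e$right), 0.01 * ev(e$left))
})

test_that("partial-monocular at zero binocular fraction is bit-identical to monocular", {
  imgs <- fixture_images(4)
  mono <- build_training_set(rearing_config("monocular"), imgs, 500,
                             patch_side = 16, region = 192, seed = 8)
  part <- build_training_set(
    rearing_config("partial_monocular", binocular_fraction = 0), imgs, 500,
    patch_side = 16, region = 192, seed = 8)
  expect_identical(mono$data, part$data)
})

test_that("alternation deprives each eye by a fair per-patch coin", {
  imgs <- fixture_images(4)
  ps <- build_training_set(rearing_config("alternating"), imgs, 10000,
                           patch_side = 16, region = 192, seed = 9)
  e <- split_eyes(ps$data)
  vr <- apply(e$right, 1, stats::var)
  vl <- apply(e$left, 1, stats::var)
  n_right_dep <- sum(vr < vl)
  # within 3 sigma of 5000 under Binomial(10000, 0.5)
  expect_lt(abs(n_right_dep - 5000), 3 * sqrt(10000 * 0.25))
  # each patch has exactly one deprived eye
  expect_true(all(pmin(vr, vl) < 0.05 * pmax(vr, vl)))
})

test_that("the normal condition is an exact pass-through of patch extraction", {
  imgs <- fixture_images(4)
  a <- build_training_set(rearing_config("normal"), imgs, 200,
                          patch_side = 16, region = 192, seed = 10)
  b <- extract_patches(imgs, 200, patch_side = 16, region = 192, seed = 10)
  expect_identical(a$data, b$data)
})

test_that("stripe-reared patch ensembles concentrate orientation energy at the reared orientation", {
  imgs <- fixture_images(4)
  for (ori in c(0, 90)) {
    cfg <- rearing_config("stripe", stripe_orientation = ori,
                          filter_strength = 6, normal_fraction = 0)
    ps <- build_training_set(cfg, imgs, 300, patch_side = 16, region = 192,
                             seed = 11)
    e <- split_eyes(ps$data)
    energy <- vapply(c(0, 45, 90, 135), function(o) {
      sum(vapply(seq_len(100), function(i) {
        sector_energy(matrix(e$left[i, ], 16, 16), o, half_width = 22)
      }, 0))
    }, 0)
    expect_equal(c(0, 45, 90, 135)[which.max(energy)], ori)
  }
})

test_that("noise mixtures interleave standardized noise with natural patches", {
  imgs <- fixture_images(4)
  cfg <- rearing_config("noise_mixture", noise_fraction = 0.5,
                        noise_spec = noise_spec("gaussian", seed = 1))
  ps <- build_training_set(cfg, imgs, 2000, patch_side = 16, region = 192,
                           seed = 12)
  expect_equal(nrow(ps$data), 2000)
  expect_equal(mean(ps$data), 0, tolerance = 0.05)
  expect_equal(stats::var(as.vector(ps$data)), 1, tolerance = 0.1)
  # noise rows have uncorrelated eyes; natural rows correlated: mixture of
  # interocular correlations should be bimodal with about half near zero
  e <- split_eyes(ps$data)
  rc <- vapply(seq_len(2000), function(i) {
    suppressWarnings(stats::cor(e$left[i, ], e$right[i, ]))
  }, 0)
  expect_equal(mean(abs(rc) < 0.3, na.rm = TRUE), 0.5, tolerance = 0.1)

  expect_error(
    rearing_config("noise_mixture", noise_fraction = 0.5),
    "noise_spec")
})

test_that("rearing configurations survive a YAML round trip", {
  td <- withr::local_tempdir()
  cfg <- rearing_config("noise_mixture", noise_fraction = 0.6,
                        noise_spec = noise_spec("student_t_df2", seed = 3),
                        stripe_orientation = 45)
  f <- file.path(td, "cfg.yaml")
  write_rearing_yaml(cfg, f)
  back <- read_rearing_yaml(f)
  expect_equal(back, cfg)
})

test_that("shipped condition configuration fixtures parse", {
  dir <- system.file("extdata", "conditions", package = "v1rear")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  expect_gte(length(files), 7)
  for (f in files) {
    cfg <- read_rearing_yaml(f)
    expect_s3_class(cfg, "rearing_config")
  }
})
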