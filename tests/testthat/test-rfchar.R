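test_that("binocularity index follows the eye-norm contrast", {
  p2 <- 9
  left_only <- c(stats::rnorm(p2), rep(0, p2))
  expect_equal(binocularity_index(left_only), 1)
  sym <- c(rep(1, p2), rep(-1, p2))
  expect_equal(binocularity_index(sym), 0)
  # ||w_L|| = 3, ||w_R|| = 1 -> (3 - 1)/(3 + 1)
  w <- c(3, rep(0, p2 - 1), 1, rep(0, p2 - 1))
  expect_equal(binocularity_index(w), 0.5)
  expect_error(binocularity_index(rep(0, 2 * p2)), "zero")
})

test_that("eye swap negates the binocularity index", {
  set.seed(30)
  for (i in 1:20) {
    rf <- stats::rnorm(2 * 16)
    swapped <- c(rf[17:32], rf[1:16])
    expect_equal(binocularity_index(swapped), -binocularity_index(rf))
  }
})

test_that("ocular dominance bins split [-1, 1] into the 7-point scale", {
  expect_equal(od_bin(0), 4L)
  expect_equal(od_bin(1), 1L)   # fully left-monocular
  expect_equal(od_bin(-1), 7L)  # fully right-monocular
  expect_equal(od_bin(0.6), 2L)
  expect_equal(od_bin(-0.6), 6L)
  expect_equal(od_bin(c(0.9, 0.14, -0.2)), c(1L, 4L, 5L))
  # monotone non-increasing in b; bin 4 symmetric about 0
  b <- seq(-1, 1, by = 0.01)
  expect_true(all(diff(od_bin(b)) <= 0))
  expect_equal(od_bin(0.1), od_bin(-0.1))
  # extreme bins capture |b| near 1 only
  expect_true(all(od_bin(b[abs(b) < 0.85]) %in% 2:6))
  expect_error(od_bin(1.2), "\\[-1, 1\\]")
})

test_that("quadrature grating responses are phase invariant and self-matching", {
  p <- 25
  bank <- grating_bank(p)
  zero <- grating_response(matrix(0, p, p), bank = bank)
  expect_true(all(zero$response == 0))

  rf <- {
    xy <- expand.grid(y = seq_len(p) - 13, x = seq_len(p) - 13)
    th <- 45 * pi / 180
    matrix(cos(2 * pi * 0.1 * (xy$x * sin(th) + xy$y * cos(th))), p, p)
  }
  surf <- grating_response(rf, bank = bank)
  peak <- arrayInd(which.max(surf$response), dim(surf$response))
  expect_equal(surf$orientations[peak[1]], 45)
  expect_equal(surf$sfs[peak[2]], 0.10)

  # quadrature identity: the response is invariant to the spatial phase of
  # the probe grating
  bank_shifted <- local({
    xy <- expand.grid(y = seq_len(p) - (p + 1) / 2,
                      x = seq_len(p) - (p + 1) / 2)
    grid <- expand.grid(theta = bank$orientations * pi / 180, f = bank$sfs)
    ph <- 2 * pi * grid$f *
      (outer(grid$theta, xy$x, function(t, x) sin(t) * x) +
         outer(grid$theta, xy$y, function(t, y) cos(t) * y)) + 1.1
    list(cos = cos(ph), sin = sin(ph), orientations = bank$orientations,
         sfs = bank$sfs)
  })
  surf2 <- grating_response(rf, bank = bank_shifted)
  expect_equal(surf2$response, surf$response, tolerance = 1e-8)
})

test_that("rotating a Gabor by 90 degrees shifts its preferred orientation by 90", {
  p <- 25
  bank <- grating_bank(p)
  g0 <- gabor_patch(p, 30, 0.12)
  g90 <- gabor_patch(p, 120, 0.12)
  pref <- function(g) {
    s <- grating_response(g, bank = bank)
    best_sf <- which.max(apply(s$response, 2, max))
    s$orientations[which.max(s$response[, best_sf])]
  }
  d <- (pref(g90) - pref(g0)) %% 180
  expect_lt(abs(min(d, 180 - d) - 90), 5)
})

test_that("circular variance has the analytic values and invariances", {
  th <- 0:179
  expect_equal(circular_variance(rep(2, 180), th), 1)
  delta <- c(5, rep(0, 179))
  expect_equal(circular_variance(delta, th), 0)
  r <- cos((th - 20) * pi / 180)^2
  expect_equal(circular_variance(r, th), 0.5, tolerance = 1e-10)
  # scale invariance and rotation invariance
  expect_equal(circular_variance(3.7 * r, th), 0.5, tolerance = 1e-10)
  r2 <- cos((th - 140) * pi / 180)^2
  expect_equal(circular_variance(r2, th), circular_variance(r, th),
               tolerance = 1e-10)
  expect_error(circular_variance(rep(0, 180), th), "all-zero")
  expect_error(circular_variance(c(-1, rep(1, 179)), th), "non-negative")
})

test_that("selectivity threshold is strict at 0.6", {
  expect_true(orientation_selectivity(0))
  expect_false(orientation_selectivity(1))
  expect_true(orientation_selectivity(0.59))
  expect_false(orientation_selectivity(0.61))
  expect_false(orientation_selectivity(0.6))
})

test_that("tuning FWHM matches hand-computed widths", {
  th <- 0:179
  # cos^2 tuning: half maximum at +/- 45 degrees
  expect_equal(tuning_fwhm(cos((th - 70) * pi / 180)^2, th), 90,
               tolerance = 0.5)
  # triangular peak of half-width 20: r = max(0, 1 - |d|/20) crosses half
  # max at |d| = 10, so FWHM = 20
  d <- pmin(abs(th - 90), 180 - abs(th - 90))
  expect_equal(tuning_fwhm(pmax(0, 1 - d / 20), th), 20, tolerance = 0.5)
  # curve above half-max everywhere except one sample
  r <- rep(1, 180); r[5] <- 0.2
  expect_gt(tuning_fwhm(r, th), 170)
  # flat curve never crosses half maximum
  expect_equal(tuning_fwhm(rep(1, 180), th), 180)
  expect_true(is.na(tuning_fwhm(rep(0, 180), th)))
  # peak wrapping across 0/180 is handled circularly
  rw <- cos(th * pi / 180)^4
  w <- tuning_fwhm(rw, th)
  expect_equal(w, 2 * 180 / pi * acos(2^(-1 / 4)), tolerance = 1)
})

test_that("preferred spatial frequency picks the argmax with low-SF ties", {
  p <- 25
  bank <- grating_bank(p)
  rf <- gabor_patch(p, 45, 0.1, sigma = 8)
  sft <- sf_tuning(grating_response(rf, bank = bank))
  expect_equal(sft$pref_sf, 0.10)
  # broadband field responds at every probed SF
  set.seed(31)
  wn <- matrix(stats::rnorm(p * p), p)
  expect_true(all(sf_tuning(grating_response(wn, bank = bank))$profile > 0))
  # tie broken toward the lower SF
  fake <- structure(list(response = matrix(1, 5, 4), orientations = 0:4,
                         sfs = c(0.1, 0.2, 0.3, 0.4)),
                    class = "tuning_surface")
  expect_equal(sf_tuning(fake)$pref_sf, 0.1)
})

test_that("localization fraction separates diffuse from spiky fields", {
  set.seed(32)
  g <- stats::rnorm(1e5)
  expect_equal(localization_fraction(g), 2 * stats::pnorm(-1),
               tolerance = 0.01)
  expect_equal(localization_fraction(rep(4, 100)), 0)
  # one spike among near-zero weights: only the spike exceeds 1 sd
  toy <- c(10, rep(0, 9))
  expect_equal(localization_fraction(toy), 1 / 10)
})

test_that("the metrics table characterises constructed binocular units correctly", {
  p <- 16
  # unit 1: left-eye Gabor at 30 deg, right eye empty-ish
  rf1 <- c(gabor_patch(p, 30, 0.12), 1e-6 * stats::rnorm(p * p))
  # unit 2: balanced binocular Gabor at 90 deg
  g <- gabor_patch(p, 90, 0.12)
  rf2 <- c(g, g)
  m <- rf_metrics(rbind(rf1, rf2), patch_side = p)
  expect_equal(nrow(m), 2)
  expect_gt(m$b[1], 0.9)
  expect_equal(m$od_bin[1], 1L)
  expect_true(m$oriented_left[1])
  expect_false(m$oriented_right[1]) # unresponsive eye cannot be oriented
  expect_lt(ori_diff_deg(m$pref_ori[1], 30), 4)
  expect_equal(m$b[2], 0)
  expect_equal(m$od_bin[2], 4L)
  expect_true(m$oriented_left[2] && m$oriented_right[2])
  expect_lt(ori_diff_deg(m$pref_ori[2], 90), 4)
  expect_true(all(m$localization_fraction >= 0 &
                    m$localization_fraction <= 1))
})
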