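#' Synthetic stereo natural images
#'
#' Generates surrogate stereo photographs with the second- and higher-order
#' statistics the downstream sparse-coding analysis relies on: an
#' approximately 1/f-spectrum background, sparse oriented Gabor/edge
#' elements with heavy-tailed amplitudes, and binocular disparity applied as
#' an independent horizontal shift per element. Because the shifts are
#' horizontal, structure oriented horizontally (which is invariant to
#' horizontal translation) remains more strongly correlated between the two
#' eyes than vertically oriented structure -- the interocular-correlation
#' asymmetry that drives orientation-dependent binocularity in the learned
#' receptive fields.
#'
#' @param n_images number of stereo pairs to generate.
#' @param size side length of each (square) image, pixels; must be >= 64.
#' @param disparity_scale standard deviation, in pixels, of the per-element
#'   horizontal shift between the left and right views. `0` makes the two
#'   views identical.
#' @param n_elements number of oriented Gabor elements superimposed on the
#'   1/f background.
#' @param seed integer seed; the same seed reproduces the images exactly.
#' @param element_gain ratio of total element RMS contrast to background RMS
#'   contrast.
#' @param mono_fraction fraction of elements rendered in one randomly chosen
#'   eye only, emulating half-occlusion at depth boundaries (structure seen
#'   by a single eye); the source of partially monocular input under normal
#'   viewing.
#'
#' @return A list of `stereo_image` objects (fields `left`, `right`:
#'   numeric matrices of identical dimensions).
#' @export
gen_naturalistic_stereo <- function(n_images, size = 256, disparity_scale = 2,
                                    n_elements = 150, seed = 1,
                                    element_gain = 1.2,
                                    mono_fraction = 0.15) {
  if (!is.numeric(n_images) || n_images < 1) {
    stop_invalid("n_images must be a positive count")
  }
  if (!is.numeric(size) || size < 64) stop_invalid("size must be >= 64")
  if (disparity_scale < 0) stop_invalid("disparity_scale must be >= 0")
  if (mono_fraction < 0 || mono_fraction > 1) {
    stop_invalid("mono_fraction must lie in [0, 1]")
  }
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_images), function(i) {
      gen_one_stereo(size, disparity_scale, n_elements, element_gain,
                     mono_fraction)
    })
  })
}

gen_one_stereo <- function(size, disparity_scale, n_elements, element_gain,
                           mono_fraction) {
  bg <- one_over_f_noise(size)
  bg <- bg / stats::sd(bg)

  # Element parameters drawn once, shared by the two eyes; only the
  # horizontal position differs between eyes.
  ori <- runif(n_elements, 0, 180)
  wavelength <- exp(runif(n_elements, log(6), log(size / 8)))
  amp <- sign(runif(n_elements, -1, 1)) * stats::rexp(n_elements) # Laplace
  phase <- runif(n_elements, 0, 2 * pi)
  row0 <- runif(n_elements, 1, size)
  col0 <- runif(n_elements, 1, size)
  dx <- if (disparity_scale > 0) rnorm(n_elements, 0, disparity_scale) else
    numeric(n_elements)
  # eye assignment: 0 = both, 1 = left only, 2 = right only (half-occluded).
  # A zero-disparity scene is flat, so it has no occlusion either: the two
  # views are then exactly identical.
  eye <- if (disparity_scale > 0) {
    ifelse(runif(n_elements) < mono_fraction,
           sample(1:2, n_elements, replace = TRUE), 0L)
  } else rep(0L, n_elements)

  left <- bg
  right <- bg
  for (e in seq_len(n_elements)) {
    if (eye[e] != 2L) {
      left <- add_gabor(left, row0[e], col0[e], ori[e], wavelength[e],
                        amp[e], phase[e])
    }
    if (eye[e] != 1L) {
      right <- add_gabor(right, row0[e], col0[e] + dx[e], ori[e],
                         wavelength[e], amp[e], phase[e])
    }
  }
  # Rescale the element layer so its RMS relative to the background is fixed.
  el_sd <- stats::sd(left - bg)
  if (el_sd > 0) {
    g <- element_gain / el_sd
    right <- bg + (right - bg) * g
    left <- bg + (left - bg) * g
  }
  stereo_image(left, right)
}

# Gaussian noise field with amplitude ~ f^-0.85 (power ~ f^-1.7); together
# with the oriented elements the generated images end up with a radial
# power-spectrum log-log slope near -2, as in natural scenes.
one_over_f_noise <- function(size) {
  f <- fft_freq_grid(size, size)
  amp <- (f$u^2 + f$v^2)^(-0.7 / 2)
  amp[1, 1] <- 0
  spec <- matrix(complex(real = rnorm(size * size),
                         imaginary = rnorm(size * size)), size, size) * amp
  Re(stats::fft(spec, inverse = TRUE)) / (size * size)
}

# Frequency coordinate grids for an H x W spectrum, cycles/pixel.
# u varies along columns (x), v along rows (y).
fft_freq_grid <- function(h, w) {
  fy <- (seq_len(h) - 1) / h
  fy[fy > 0.5] <- fy[fy > 0.5] - 1
  fx <- (seq_len(w) - 1) / w
  fx[fx > 0.5] <- fx[fx > 0.5] - 1
  list(u = matrix(fx, h, w, byrow = TRUE), v = matrix(fy, h, w))
}

# Add one Gabor element in place. Orientation convention: `ori` (degrees) is
# the orientation of the bars; ori = 0 gives horizontal bars (intensity
# varies along rows only), ori = 90 vertical bars.
add_gabor <- function(img, row0, col0, ori, wavelength, amp, phase) {
  size <- nrow(img)
  sigma_across <- wavelength * 0.35
  sigma_along <- wavelength * 0.7
  half <- ceiling(3 * sigma_along)
  r <- max(1, floor(row0 - half)):min(size, ceiling(row0 + half))
  c <- max(1, floor(col0 - half)):min(size, ceiling(col0 + half))
  if (!length(r) || !length(c)) return(img)
  y <- matrix(r - row0, length(r), length(c))
  x <- matrix(c - col0, length(r), length(c), byrow = TRUE)
  th <- ori * pi / 180
  along <- x * cos(th) - y * sin(th)   # along the bars
  across <- x * sin(th) + y * cos(th)  # across the bars
  env <- exp(-(along^2 / (2 * sigma_along^2) +
                 across^2 / (2 * sigma_across^2)))
  img[r, c] <- img[r, c] +
    amp * env * cos(2 * pi * across / wavelength + phase)
  img
}

#' Noise patch generators for sparse-rearing stimuli
#'
#' Draws patch sets whose pixels are i.i.d. from one of three distributions:
#' Student-t with 2 degrees of freedom (sparse noise, close to the
#' coefficient statistics of natural scenes), Gaussian, or uniform. By
#' default the ensemble is standardized to zero mean and unit variance, the
#' normalization applied before noise is mixed with natural input.
#'
#' @param spec a [noise_spec()] (distribution, scale, seed).
#' @param n number of patches.
#' @param patch_shape integer vector of patch dimensions, e.g. `c(2, 25, 25)`
#'   for a binocular patch; the patch vector length is `prod(patch_shape)`.
#' @param standardize standardize the ensemble to mean 0, variance 1
#'   (default `TRUE`); set `FALSE` to obtain the raw draws.
#' @return an `n x prod(patch_shape)` matrix.
#' @export
gen_noise_patches <- function(spec, n, patch_shape, standardize = TRUE) {
  if (!inherits(spec, "noise_spec")) stop_invalid("spec must be a noise_spec")
  if (!is.numeric(n) || n < 1) stop_invalid("n must be >= 1")
  d <- prod(patch_shape)
  x <- withr::with_seed(as.integer(spec$seed), switch(
    spec$distribution,
    student_t_df2 = rt(n * d, df = 2),
    gaussian = rnorm(n * d),
    uniform = runif(n * d, -1, 1),
    stop_invalid("unknown noise distribution: ", spec$distribution)
  )) * spec$scale
  m <- matrix(x, nrow = n, ncol = d)
  if (standardize) m <- normalize_mean_var(m, 0, 1)
  m
}

#' Noise stimulus specification
#'
#' @param distribution one of `"student_t_df2"`, `"gaussian"`, `"uniform"`.
#' @param scale multiplicative scale applied to the raw draws (irrelevant
#'   after standardization).
#' @param seed integer seed.
#' @export
noise_spec <- function(distribution = c("student_t_df2", "gaussian",
                                        "uniform"),
                       scale = 1, seed = 1) {
  distribution <- match.arg(distribution)
  structure(list(distribution = distribution, scale = as.numeric(scale),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Affine ensemble normalization to a target mean and variance
#'
#' Rescales a patch matrix so that the mean and variance over all entries
#' equal the targets exactly; used to put natural and noise patch sets on a
#' common scale before mixing.
#'
#' @param patches numeric matrix.
#' @param target_mean,target_var targets for the ensemble mean and variance.
#' @return matrix of the same shape.
#' @export
normalize_mean_var <- function(patches, target_mean = 0, target_var = 1) {
  m <- mean(patches)
  v <- stats::var(as.vector(patches))
  if (!is.finite(v) || v <= 0) {
    stop_invalid("degenerate input: patch set has zero variance")
  }
  (patches - m) / sqrt(v) * sqrt(target_var) + target_mean
}
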