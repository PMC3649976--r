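#' Rearing-condition configuration
#'
#' Bundles a rearing-condition identifier with every filter and mixture
#' parameter the condition needs. Irrelevant fields are ignored by
#' [build_training_set()].
#'
#' Conditions:
#' \describe{
#'   \item{normal}{unfiltered binocular input.}
#'   \item{stripe}{both eyes filtered to a single orientation
#'     (`stripe_orientation`); a `normal_fraction` share of patches (default
#'     10\%) is left unfiltered to avoid collapse of the retained principal
#'     components.}
#'   \item{orthogonal}{left eye filtered at `stripe_orientation`, right eye
#'     at `stripe_orientation + 90`; same unfiltered share.}
#'   \item{monocular}{the deprived eye's images are occluded with a
#'     `boxcar_length`-pixel square-kernel blur in every patch (lid-suture
#'     surrogate: spatial pattern removed, mean luminance kept).}
#'   \item{alternating}{per patch a fair coin decides which eye is
#'     boxcar-occluded.}
#'   \item{partial_monocular}{a `binocular_fraction` share of patches is
#'     normal, the remainder monocularly deprived.}
#'   \item{strabismic}{per-eye independent patch offsets (shared focal
#'     squares), removing interocular correlation.}
#'   \item{noise_mixture}{a `noise_fraction` share of patches is replaced by
#'     i.i.d. noise patches from `noise_spec`; both sources are normalized
#'     to a common mean and variance before combination.}
#' }
#'
#' @param condition condition name, see Details.
#' @param stripe_orientation reared orientation, degrees in `[0, 180)`;
#'   0 = horizontal.
#' @param filter_strength reciprocal angular bandwidth of the oriented
#'   Gaussian filter (dimensionless; 0 disables filtering). Default 4.
#' @param normal_fraction unfiltered share for stripe/orthogonal (default
#'   0.10).
#' @param binocular_fraction share of normal binocular experience in
#'   partial-monocular rearing.
#' @param boxcar_length side of the square occlusion kernel, pixels
#'   (default 150).
#' @param noise_spec a [noise_spec()]; required when `noise_fraction > 0`.
#' @param noise_fraction share of noise patches in the noise-mixture
#'   condition.
#' @param deprived_eye which eye is occluded (default `"right"`).
#' @return object of class `rearing_config`.
#' @export
rearing_config <- function(condition = c("normal", "stripe", "orthogonal",
                                         "monocular", "alternating",
                                         "partial_monocular", "strabismic",
                                         "noise_mixture"),
                           stripe_orientation = 0,
                           filter_strength = 4,
                           normal_fraction = 0.10,
                           binocular_fraction = 0,
                           boxcar_length = 150,
                           noise_spec = NULL,
                           noise_fraction = 0,
                           deprived_eye = c("right", "left")) {
  condition <- match.arg(condition)
  deprived_eye <- match.arg(deprived_eye)
  for (f in c(normal_fraction, binocular_fraction, noise_fraction)) {
    if (f < 0 || f > 1) stop_invalid("fractions must lie in [0, 1]")
  }
  if (boxcar_length < 1) stop_invalid("boxcar_length must be >= 1")
  if (condition == "noise_mixture" && noise_fraction > 0 &&
      is.null(noise_spec)) {
    stop_invalid("noise_mixture with noise_fraction > 0 requires noise_spec")
  }
  structure(list(condition = condition,
                 stripe_orientation = as.numeric(stripe_orientation) %% 180,
                 filter_strength = as.numeric(filter_strength),
                 normal_fraction = as.numeric(normal_fraction),
                 binocular_fraction = as.numeric(binocular_fraction),
                 boxcar_length = as.integer(boxcar_length),
                 noise_spec = noise_spec,
                 noise_fraction = as.numeric(noise_fraction),
                 deprived_eye = deprived_eye),
            class = "rearing_config")
}

#' @export
print.rearing_config <- function(x, ...) {
  cat(sprintf("<rearing_config: %s>\n", x$condition))
  invisible(x)
}

#' Read/write a rearing configuration as YAML
#' @param config a [rearing_config()].
#' @param path file path.
#' @export
write_rearing_yaml <- function(config, path) {
  lst <- unclass(config)
  if (!is.null(lst$noise_spec)) lst$noise_spec <- unclass(lst$noise_spec)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_rearing_yaml
#' @export
read_rearing_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  ns <- if (!is.null(lst$noise_spec)) {
    do.call(noise_spec, lst$noise_spec)
  }
  rearing_config(condition = lst$condition,
                 stripe_orientation = lst$stripe_orientation %||% 0,
                 filter_strength = lst$filter_strength %||% 4,
                 normal_fraction = lst$normal_fraction %||% 0.10,
                 binocular_fraction = lst$binocular_fraction %||% 0,
                 boxcar_length = lst$boxcar_length %||% 150,
                 noise_spec = ns,
                 noise_fraction = lst$noise_fraction %||% 0,
                 deprived_eye = lst$deprived_eye %||% "right")
}

#' Oriented Gaussian orientation filter
#'
#' Frequency-domain anisotropic Gaussian that passes spectral components
#' whose structure orientation matches `orientation` and attenuates
#' orthogonal components: a component at angular distance `d` is scaled by
#' `exp(-(strength * sin(d))^2 / 2)`, so `strength` is the reciprocal
#' angular bandwidth. The DC component is always preserved, and
#' `strength = 0` is the identity.
#'
#' @param image 2-D numeric matrix.
#' @param orientation pass orientation, degrees (0 = horizontal structure).
#' @param strength reciprocal angular bandwidth, `>= 0`.
#' @return filtered matrix of the same dimensions.
#' @export
oriented_gaussian_filter <- function(image, orientation, strength) {
  if (strength < 0) stop_invalid("strength must be >= 0")
  if (strength == 0) return(image)
  h <- nrow(image)
  w <- ncol(image)
  f <- fft_freq_grid(h, w)
  # Structure orientation of a component with wavevector (u, v): bars are
  # perpendicular to the wavevector; with our convention (0 deg = horizontal
  # bars = variation along rows) theta = atan2(u, v).
  theta <- atan2(f$u, f$v)
  d <- theta - orientation * pi / 180
  mask <- exp(-(strength * sin(d))^2 / 2)
  mask[1, 1] <- 1
  Re(stats::fft(stats::fft(image) * mask, inverse = TRUE)) / (h * w)
}

#' Boxcar occlusion filter
#'
#' Circular convolution with a normalized `kernel_length` x `kernel_length`
#' uniform square kernel; with the default 150-pixel kernel this removes all
#' but extremely low spatial frequencies, emulating lid suture while
#' preserving mean luminance.
#'
#' @param image 2-D numeric matrix.
#' @param kernel_length box side, pixels; 1 is the identity.
#' @return filtered matrix.
#' @export
boxcar_occlude <- function(image, kernel_length = 150) {
  if (kernel_length < 1) stop_invalid("kernel_length must be >= 1")
  kernel_length <- as.integer(kernel_length)
  if (kernel_length == 1L) return(image)
  h <- nrow(image)
  w <- ncol(image)
  if (kernel_length > min(h, w)) {
    stop_invalid("kernel_length exceeds image dimensions")
  }
  ker <- matrix(0, h, w)
  idx_r <- ((seq_len(kernel_length) - 1L - (kernel_length %/% 2L)) %% h) + 1L
  idx_c <- ((seq_len(kernel_length) - 1L - (kernel_length %/% 2L)) %% w) + 1L
  ker[idx_r, idx_c] <- 1 / kernel_length^2
  Re(stats::fft(stats::fft(image) * stats::fft(ker), inverse = TRUE)) /
    (h * w)
}

apply_to_eyes <- function(images, fun_left, fun_right) {
  lapply(images, function(im) {
    stereo_image(fun_left(im$left), fun_right(im$right))
  })
}

#' Build a rearing-condition training set
#'
#' Applies the condition's input manipulation at image level (filters) or at
#' sampling level (strabismus, alternation, noise mixing) and extracts
#' `n_patches` binocular patches. The `normal` condition is an exact
#' pass-through of [extract_patches()]. Mixture shares (`normal_fraction`,
#' `binocular_fraction`, `noise_fraction`) are enforced as exact counts;
#' alternation uses a fair per-patch coin. Patch order is randomly shuffled
#' so mixtures are interleaved.
#'
#' @param config a [rearing_config()].
#' @param images list of [stereo_image()] (may be empty for a pure-noise
#'   mixture, `noise_fraction = 1`).
#' @param n_patches patches to return.
#' @param patch_side patch side, pixels.
#' @param region focal square side, pixels.
#' @param n_focal focal points per image.
#' @param seed integer seed governing sampling, alternation, mixing.
#' @return a `stereo_patchset` with `condition` recorded.
#' @export
build_training_set <- function(config, images, n_patches, patch_side = 25,
                               region = 300, n_focal = 5, seed = 1) {
  stopifnot(inherits(config, "rearing_config"))
  if (config$condition != "noise_mixture" || config$noise_fraction < 1) {
    if (length(images) == 0) stop_invalid("images must be nonempty")
  }
  seed <- as.integer(seed)
  ex <- function(imgs, n, independent = FALSE, subseed = seed) {
    extract_patches(imgs, n, patch_side = patch_side, region = region,
                    independent_eyes = independent, n_focal = n_focal,
                    seed = subseed)$data
  }
  ori_filt <- function(o) {
    function(im) oriented_gaussian_filter(im, o, config$filter_strength)
  }
  box <- function(im) boxcar_occlude(im, config$boxcar_length)
  idf <- identity
  dep_right <- config$deprived_eye == "right"

  data <- switch(
    config$condition,
    normal = ex(images, n_patches),
    stripe = {
      filt <- apply_to_eyes(images, ori_filt(config$stripe_orientation),
                            ori_filt(config$stripe_orientation))
      mix_two(ex(filt, n_patches), ex(images, n_patches, subseed = seed + 1L),
              1 - config$normal_fraction, n_patches, seed)
    },
    orthogonal = {
      filt <- apply_to_eyes(images, ori_filt(config$stripe_orientation),
                            ori_filt(config$stripe_orientation + 90))
      mix_two(ex(filt, n_patches), ex(images, n_patches, subseed = seed + 1L),
              1 - config$normal_fraction, n_patches, seed)
    },
    monocular = {
      filt <- apply_to_eyes(images, if (dep_right) idf else box,
                            if (dep_right) box else idf)
      ex(filt, n_patches)
    },
    alternating = {
      rdep <- apply_to_eyes(images, idf, box)
      ldep <- apply_to_eyes(images, box, idf)
      # Same sampling seed in both sets: patch p differs only in which eye
      # is occluded; a fair coin picks the eye per patch.
      a <- ex(rdep, n_patches)
      b <- ex(ldep, n_patches)
      coin <- withr::with_seed(seed + 7L,
                               runif(n_patches) < 0.5)
      out <- a
      out[!coin, ] <- b[!coin, ]
      out
    },
    partial_monocular = {
      filt <- apply_to_eyes(images, if (dep_right) idf else box,
                            if (dep_right) box else idf)
      mix_two(ex(filt, n_patches), ex(images, n_patches, subseed = seed + 1L),
              1 - config$binocular_fraction, n_patches, seed)
    },
    strabismic = ex(images, n_patches, independent = TRUE),
    noise_mixture = {
      d <- 2 * patch_side^2
      n_noise <- round(config$noise_fraction * n_patches)
      parts <- list()
      if (n_noise < n_patches) {
        nat <- ex(images, n_patches - n_noise)
        parts$nat <- normalize_mean_var(nat, 0, 1)
      }
      if (n_noise > 0) {
        ns <- config$noise_spec
        ns$seed <- ns$seed + seed # repeats see different noise
        parts$noise <- gen_noise_patches(ns, n_noise,
                                         c(2, patch_side, patch_side))
      }
      out <- do.call(rbind, unname(parts))
      out[withr::with_seed(seed + 11L, sample.int(n_patches)), ,
          drop = FALSE]
    }
  )
  ps <- stereo_patchset(data, patch_side, seed = seed,
                        condition = config$condition)
  ps
}

# Exact-count mixture of two aligned patch matrices: a share `frac_a` of rows
# comes from `a`, the rest from `b`, interleaved by a seeded shuffle.
mix_two <- function(a, b, frac_a, n, seed) {
  n_a <- round(frac_a * n)
  take_a <- withr::with_seed(seed + 3L, sample.int(n) <= n_a)
  out <- b
  out[take_a, ] <- a[take_a, ]
  out
}
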