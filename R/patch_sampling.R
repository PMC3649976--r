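#' Binocular patch set
#'
#' Internal constructor for the canonical training-set container: an
#' `n_patches x 2*P^2` matrix whose first `P^2` columns are the left eye and
#' remaining `P^2` the right eye, each eye's `P x P` window stored
#' column-major.
#'
#' @keywords internal
stereo_patchset <- function(data, patch_side, seed = NA_integer_,
                            condition = "normal") {
  stopifnot(ncol(data) == 2 * patch_side^2)
  if (!all(is.finite(data))) stop_invalid("patch data must be finite")
  structure(
    list(data = data, patch_side = as.integer(patch_side),
         eye_layout = EYE_LAYOUT, seed = seed, condition = condition),
    class = "stereo_patchset"
  )
}

#' @export
print.stereo_patchset <- function(x, ...) {
  cat(sprintf("<stereo_patchset: %d patches, 2 x %d x %d, condition=%s>\n",
              nrow(x$data), x$patch_side, x$patch_side, x$condition))
  invisible(x)
}

#' Split a patch matrix (or vector) into per-eye halves
#'
#' @param x patch matrix (rows = patches) or a single patch vector.
#' @return list with elements `left` and `right`.
#' @export
split_eyes <- function(x) {
  if (is.matrix(x)) {
    d <- ncol(x) / 2
    list(left = x[, seq_len(d), drop = FALSE],
         right = x[, d + seq_len(d), drop = FALSE])
  } else {
    d <- length(x) / 2
    list(left = x[seq_len(d)], right = x[d + seq_len(d)])
  }
}

#' Random focal points with a margin constraint
#'
#' Chooses `n` focal points uniformly at random such that the
#' `region x region` sampling square centred on each point lies inside the
#' image. Coordinates are 1-based `(row, col)`.
#'
#' @param image a [stereo_image()].
#' @param n number of focal points.
#' @param region side of the sampling square, pixels (300 for full-size
#'   photographs).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return data frame with columns `row`, `col`.
#' @export
sample_focal_points <- function(image, n = 5, region = 300, seed = NULL) {
  h <- nrow(image$left)
  w <- ncol(image$left)
  if (h < region || w < region) {
    stop_invalid("image (", h, "x", w, ") smaller than sampling region ",
                 region)
  }
  draw <- function() {
    half <- floor(region / 2)
    # top-left corner of the square ranges over 1 .. dim - region + 1
    r0 <- sample.int(h - region + 1L, n, replace = TRUE)
    c0 <- sample.int(w - region + 1L, n, replace = TRUE)
    data.frame(row = r0 + half, col = c0 + half)
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

# Top-left corners of the focal square for given focal points.
focal_corners <- function(points, region) {
  half <- floor(region / 2)
  data.frame(row = points$row - half, col = points$col - half)
}

#' Extract binocular training patches
#'
#' Draws `n_patches` binocular patches: for each patch an image and one of
#' its focal points are chosen uniformly, then a `patch_side`-square window
#' is placed uniformly at random inside the `region`-square around the focal
#' point. In aligned mode (the default) the same window is read from both
#' eyes, so residual interocular disparity comes from the images themselves;
#' with `independent_eyes = TRUE` (strabismic sampling) the window offset is
#' drawn independently per eye within the same focal square, destroying
#' interocular correlation.
#'
#' @param images list of [stereo_image()].
#' @param n_patches number of patches (the full-scale analyses use 1e5).
#' @param patch_side patch side, pixels (default 25).
#' @param region focal square side, pixels.
#' @param independent_eyes draw per-eye independent window offsets.
#' @param n_focal focal points per image (default 5).
#' @param seed integer seed.
#' @return a `stereo_patchset`.
#' @export
extract_patches <- function(images, n_patches, patch_side = 25,
                            region = 300, independent_eyes = FALSE,
                            n_focal = 5, seed = 1) {
  if (n_patches < 1) stop_invalid("n_patches must be >= 1")
  if (patch_side > region) stop_invalid("patch_side must be <= region")
  withr::with_seed(as.integer(seed), {
    corners <- lapply(images, function(im) {
      focal_corners(sample_focal_points(im, n_focal, region, seed = NULL),
                    region)
    })
    img_idx <- sample.int(length(images), n_patches, replace = TRUE)
    fp_idx <- sample.int(n_focal, n_patches, replace = TRUE)
    span <- region - patch_side + 1L
    off_r <- sample.int(span, n_patches, replace = TRUE) - 1L
    off_c <- sample.int(span, n_patches, replace = TRUE) - 1L
    if (independent_eyes) {
      off_r2 <- sample.int(span, n_patches, replace = TRUE) - 1L
      off_c2 <- sample.int(span, n_patches, replace = TRUE) - 1L
    } else {
      off_r2 <- off_r
      off_c2 <- off_c
    }
    d <- patch_side^2
    data <- matrix(0, n_patches, 2L * d)
    for (p in seq_len(n_patches)) {
      im <- images[[img_idx[p]]]
      corner <- corners[[img_idx[p]]][fp_idx[p], ]
      rl <- corner$row + off_r[p]
      cl <- corner$col + off_c[p]
      rr <- corner$row + off_r2[p]
      cr <- corner$col + off_c2[p]
      data[p, seq_len(d)] <-
        im$left[rl:(rl + patch_side - 1L), cl:(cl + patch_side - 1L)]
      data[p, d + seq_len(d)] <-
        im$right[rr:(rr + patch_side - 1L), cr:(cr + patch_side - 1L)]
    }
    stereo_patchset(data, patch_side, seed = as.integer(seed))
  })
}
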