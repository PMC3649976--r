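#' Stereo image container
#'
#' @param left,right grayscale intensity matrices of identical dimensions.
#' @return object of class `stereo_image`.
#' @export
stereo_image <- function(left, right) {
  left <- as.matrix(left)
  right <- as.matrix(right)
  if (!identical(dim(left), dim(right))) {
    stop_invalid("left and right views must have identical dimensions")
  }
  if (!all(is.finite(left)) || !all(is.finite(right))) {
    stop_invalid("stereo image intensities must be finite")
  }
  structure(list(left = left, right = right), class = "stereo_image")
}

#' @export
print.stereo_image <- function(x, ...) {
  cat(sprintf("<stereo_image %d x %d>\n", nrow(x$left), ncol(x$left)))
  invisible(x)
}

# Rec. 601 luminance weights; the conversion rule when colour input arrives.
LUMA_WEIGHTS <- c(0.299, 0.587, 0.114)

read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_invalid("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3) {
    nc <- dim(img)[3]
    if (nc >= 3) {
      img <- img[, , 1] * LUMA_WEIGHTS[1] + img[, , 2] * LUMA_WEIGHTS[2] +
        img[, , 3] * LUMA_WEIGHTS[3]
    } else {
      img <- img[, , 1]
    }
  }
  img
}

#' Load a stereo image pair from raster files
#'
#' Reads the two views (PNG or TIFF), converting colour to grayscale with
#' standard luminance weights (0.299, 0.587, 0.114).
#'
#' @param left_path,right_path file paths to the left- and right-eye views.
#' @return a [stereo_image()].
#' @export
load_stereo_image <- function(left_path, right_path) {
  for (p in c(left_path, right_path)) {
    if (!file.exists(p)) stop_invalid("file not found: ", p)
  }
  l <- read_gray(left_path)
  r <- read_gray(right_path)
  if (!identical(dim(l), dim(r))) {
    stop_invalid("left and right images have mismatched dimensions (",
                 paste(dim(l), collapse = "x"), " vs ",
                 paste(dim(r), collapse = "x"), ")")
  }
  stereo_image(l, r)
}

#' Write a stereo pair as grayscale PNGs
#'
#' Intensities are affinely mapped to `[0, 1]` over the pair (a shared
#' mapping, so interocular contrast relationships are preserved) and written
#' as grayscale PNG.
#'
#' @param img a [stereo_image()].
#' @param left_path,right_path output paths.
#' @export
write_stereo_png <- function(img, left_path, right_path) {
  lo <- min(img$left, img$right)
  hi <- max(img$left, img$right)
  rng <- if (hi > lo) hi - lo else 1
  png::writePNG((img$left - lo) / rng, left_path, dpi = NULL)
  png::writePNG((img$right - lo) / rng, right_path, dpi = NULL)
  invisible(c(left_path, right_path))
}
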