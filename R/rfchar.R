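#' Binocularity index of a pixel-space receptive field
#'
#' `b = (||w_L|| - ||w_R||) / (||w_L|| + ||w_R||)` with the Euclidean norm
#' over each eye's sub-vector: `+1` for a purely left-eye field, `-1` for
#' purely right-eye, `0` for equal drive. Antisymmetric under eye swap.
#'
#' @param rf binocular receptive field vector (length `2 P^2`, canonical
#'   eye layout).
#' @return scalar in `[-1, 1]`.
#' @export
binocularity_index <- function(rf) {
  e <- split_eyes(rf)
  nl <- sqrt(sum(e$left^2))
  nr <- sqrt(sum(e$right^2))
  if (nl + nr == 0) stop_invalid("undefined: both eye sub-vectors are zero")
  (nl - nr) / (nl + nr)
}

# Default symmetric boundaries of the 7-bin ocular-dominance scale.
OD_BOUNDARIES <- c(0.15, 0.5, 0.85)

#' Ocular-dominance bin on a 7-point scale
#'
#' Bins the binocularity index so that bin 1 holds strongly LEFT-dominated
#' fields (`b` near `+1`), bin 4 is centred on balanced fields, and bin 7
#' strongly RIGHT-dominated fields (`b` near `-1`); under the default
#' monocular deprivation of the right eye, open-eye units therefore land in
#' the low bins. Bins 1 and 7 are "monocular".
#'
#' @param b binocularity index in `[-1, 1]` (vectorized).
#' @param boundaries positive boundary magnitudes (default
#'   `c(0.15, 0.5, 0.85)` giving edges at `+/-` those values).
#' @return integer bin(s) in `1..7`.
#' @export
od_bin <- function(b, boundaries = OD_BOUNDARIES) {
  if (any(abs(b) > 1)) stop_invalid("b must lie in [-1, 1]")
  edges <- c(-1 - 1e-12, -rev(boundaries), boundaries, 1)
  # edges ascending in b; bin 1 must hold b near +1 -> reverse
  idx <- findInterval(b, edges, left.open = TRUE)
  as.integer(8L - idx)
}

#' Quadrature grating bank
#'
#' Pre-computes cosine and sine full-field gratings on a `P x P` patch for
#' every (orientation, spatial frequency) pair of the probe grids, as the
#' rows of two matrices. Cached per `(P, grids)` in the session.
#'
#' @param patch_side patch side `P`, pixels.
#' @param orientations orientation grid, degrees (default `0:179`, 1 deg
#'   spacing).
#' @param sfs spatial-frequency grid, cycles/pixel (default 0.02 to 0.5 in
#'   steps of 0.02).
#' @return list with `cos`, `sin` (`n_ori*n_sf x P^2` matrices, gratings in
#'   rows, orientation varying fastest), `orientations`, `sfs`.
#' @export
grating_bank <- function(patch_side, orientations = 0:179,
                         sfs = seq(0.02, 0.5, by = 0.02)) {
  key <- paste(patch_side, length(orientations), length(sfs),
               orientations[1], sfs[1], sep = "|")
  cached <- .grating_cache[[key]]
  if (!is.null(cached)) return(cached)
  p <- patch_side
  xy <- expand.grid(y = seq_len(p) - (p + 1) / 2,
                    x = seq_len(p) - (p + 1) / 2)
  grid <- expand.grid(theta = orientations * pi / 180, f = sfs)
  # phase(x, y) for bar orientation theta: wavevector (sin t, cos t)
  ph <- 2 * pi * grid$f *
    (outer(grid$theta, xy$x, function(t, x) sin(t) * x) +
       outer(grid$theta, xy$y, function(t, y) cos(t) * y))
  bank <- list(cos = cos(ph), sin = sin(ph),
               orientations = orientations, sfs = sfs)
  .grating_cache[[key]] <- bank
  bank
}
.grating_cache <- new.env(parent = emptyenv())

#' Grating tuning surface of a single-eye receptive field
#'
#' Phase-invariant response to a quadrature pair of sinusoidal gratings at
#' every probe (orientation, SF):
#' `r(theta, f) = sqrt((rf . g_cos)^2 + (rf . g_sin)^2)`.
#'
#' @param rf_eye single-eye field: `P x P` matrix or length-`P^2` vector
#'   (column-major).
#' @param bank a [grating_bank()]; built on the fly if `NULL`.
#' @param orientations,sfs probe grids when `bank` is `NULL`.
#' @return object of class `tuning_surface`: `response` matrix
#'   (`n_ori x n_sf`, non-negative), `orientations`, `sfs`.
#' @export
grating_response <- function(rf_eye, bank = NULL, orientations = 0:179,
                             sfs = seq(0.02, 0.5, by = 0.02)) {
  v <- as.vector(rf_eye)
  p <- sqrt(length(v))
  if (p != round(p)) stop_invalid("rf_eye must be square")
  if (is.null(bank)) bank <- grating_bank(p, orientations, sfs)
  r <- sqrt((bank$cos %*% v)^2 + (bank$sin %*% v)^2)
  structure(list(response = matrix(r, length(bank$orientations),
                                   length(bank$sfs)),
                 orientations = bank$orientations, sfs = bank$sfs),
            class = "tuning_surface")
}

#' Circular variance of an orientation tuning curve
#'
#' `CV = 1 - |sum_theta r(theta) exp(2 i theta)| / sum_theta r(theta)` on
#' the orientation-doubled circle: 0 for a perfectly selective curve, 1 for
#' a flat one. Invariant to positive rescaling and to rotation of the curve.
#'
#' @param r non-negative responses on an orientation grid covering
#'   `[0, 180)` degrees.
#' @param orientations grid in degrees (default evenly spaced over 180).
#' @return CV in `[0, 1]`.
#' @export
circular_variance <- function(r, orientations = NULL) {
  if (any(r < 0)) stop_invalid("responses must be non-negative")
  tot <- sum(r)
  if (tot == 0) stop_invalid("undefined: all-zero tuning curve")
  if (is.null(orientations)) {
    orientations <- seq(0, 180, length.out = length(r) + 1)[seq_along(r)]
  }
  th <- orientations * pi / 180
  1 - Mod(sum(r * exp(2i * th))) / tot
}

#' Orientation-selectivity flag
#'
#' A unit (eye) counts as orientation selective when its circular variance
#' is strictly below the threshold (default 0.6).
#'
#' @param cv circular variance value(s).
#' @param threshold selectivity cutoff.
#' @return logical.
#' @export
orientation_selectivity <- function(cv, threshold = 0.6) cv < threshold

#' Full width at half maximum of an orientation tuning curve
#'
#' Width, in degrees, of the contiguous region around the global peak where
#' the curve stays at or above half its maximum, with linear interpolation
#' at the crossings and circular topology on `[0, 180)`.
#'
#' @param r non-negative responses.
#' @param orientations evenly spaced grid in degrees over `[0, 180)`.
#' @return width in degrees, or `NA` if the curve never crosses half
#'   maximum (flat curve).
#' @export
tuning_fwhm <- function(r, orientations = NULL) {
  n <- length(r)
  if (is.null(orientations)) {
    orientations <- seq(0, 180, length.out = n + 1)[seq_len(n)]
  }
  step <- 180 / n
  if (max(r) == 0) return(NA_real_)
  half <- max(r) / 2
  if (all(r >= half)) return(180)
  i0 <- which.max(r)
  above <- r >= half
  # walk left/right circularly from the peak
  walk <- function(dir) {
    i <- i0
    dist <- 0
    repeat {
      j <- ((i - 1 + dir) %% n) + 1
      if (!above[j]) {
        # linear interpolation between i (>= half) and j (< half)
        frac <- (r[i] - half) / (r[i] - r[j])
        return(dist + frac * step)
      }
      dist <- dist + step
      i <- j
      if (dist >= 180) return(180)
    }
  }
  min(180, walk(-1L) + walk(1L))
}

#' Preferred spatial frequency and SF response profile
#'
#' The preferred SF is the probe frequency whose best-orientation response
#' is maximal; ties are broken towards the lower frequency. The per-SF
#' profile (max over orientation) feeds the population acuity curves.
#'
#' @param surface a [grating_response()] tuning surface.
#' @return list with `pref_sf` (cycles/pixel) and `profile` (named vector of
#'   max-over-orientation responses per SF).
#' @export
sf_tuning <- function(surface) {
  prof <- apply(surface$response, 2, max)
  names(prof) <- surface$sfs
  list(pref_sf = surface$sfs[which.max(prof)], profile = prof)
}

#' Pixel localization fraction of a receptive field
#'
#' Fraction of weights lying more than one standard deviation from the mean
#' of the filter: near `2 * pnorm(-1) = 0.317` for diffuse Gaussian-like
#' fields, and very small (of order `1/D`, since the few active pixels
#' dominate the standard deviation) for fields localized to a small number
#' of pixels -- so SMALL values indicate extreme pixel localization, the
#' signature of rearing on sparse noise. A constant field returns 0 by
#' convention.
#'
#' @param rf receptive-field weight vector (any length).
#' @return proportion in `[0, 1]`.
#' @export
localization_fraction <- function(rf) {
  s <- stats::sd(rf)
  if (!is.finite(s) || s == 0) return(0)
  mean(abs(rf - mean(rf)) > s)
}

#' Per-unit receptive-field metrics table
#'
#' Characterises every learned unit on its pixel-space binocular receptive
#' field: binocularity index and OD bin; per eye, the quadrature grating
#' tuning surface, preferred SF, orientation tuning curve at the preferred
#' SF, circular variance, preferred orientation and FWHM; and the pixel
#' localization fraction of the full binocular field. An eye is counted as
#' responsive when its peak grating response reaches `resp_threshold` of the
#' binocular peak; an eye is "oriented" when it is responsive and its CV is
#' below `cv_threshold`.
#'
#' @param model a `learned_model` with `pixel_rfs` populated (or an
#'   `M x D` pixel receptive-field matrix).
#' @param patch_side patch side `P`; inferred from the model's whitening
#'   model when possible.
#' @param cv_threshold circular-variance selectivity cutoff (default 0.6).
#' @param resp_threshold relative response floor for counting an eye as
#'   responsive (default 0.1).
#' @param orientations,sfs probe grids.
#' @return data frame with one row per unit (class `rf_metrics`): columns
#'   `unit, b, od_bin, cv_left, cv_right, pref_ori_left, pref_ori_right,
#'   pref_sf_left, pref_sf_right, fwhm_left, fwhm_right, resp_left,
#'   resp_right, responsive_left, responsive_right, oriented_left,
#'   oriented_right, pref_ori, localization_fraction`. `pref_ori` is the
#'   preference of the better-tuned responsive eye (NA when neither eye is
#'   oriented).
#' @export
rf_metrics <- function(model, patch_side = NULL, cv_threshold = 0.6,
                       resp_threshold = 0.1, orientations = 0:179,
                       sfs = seq(0.02, 0.5, by = 0.02)) {
  R <- if (inherits(model, "learned_model")) model$pixel_rfs else model
  if (is.null(R)) stop_invalid("model has no pixel-space receptive fields")
  if (is.null(patch_side)) {
    patch_side <- if (inherits(model, "learned_model") &&
                      !is.null(model$whitening$patch_side)) {
      model$whitening$patch_side
    } else {
      p <- sqrt(ncol(R) / 2)
      if (p != round(p)) stop_invalid("cannot infer patch_side")
      as.integer(p)
    }
  }
  bank <- grating_bank(patch_side, orientations, sfs)
  rows <- lapply(seq_len(nrow(R)), function(i) {
    rf <- R[i, ]
    e <- split_eyes(rf)
    b <- binocularity_index(rf)
    eye_stats <- lapply(e, function(w) {
      surf <- grating_response(w, bank = bank)
      sft <- sf_tuning(surf)
      curve <- surf$response[, which.max(sft$profile)]
      peak <- max(surf$response)
      cv <- if (peak > 0) circular_variance(curve, bank$orientations) else 1
      list(cv = cv,
           pref_ori = bank$orientations[which.max(curve)],
           pref_sf = sft$pref_sf,
           fwhm = if (peak > 0) tuning_fwhm(curve, bank$orientations)
                  else NA_real_,
           resp = peak)
    })
    peak_all <- max(eye_stats$left$resp, eye_stats$right$resp)
    resp_l <- peak_all > 0 && eye_stats$left$resp >= resp_threshold * peak_all
    resp_r <- peak_all > 0 &&
      eye_stats$right$resp >= resp_threshold * peak_all
    or_l <- resp_l && orientation_selectivity(eye_stats$left$cv,
                                              cv_threshold)
    or_r <- resp_r && orientation_selectivity(eye_stats$right$cv,
                                              cv_threshold)
    pref <- if (or_l && or_r) {
      if (eye_stats$left$cv <= eye_stats$right$cv) eye_stats$left$pref_ori
      else eye_stats$right$pref_ori
    } else if (or_l) eye_stats$left$pref_ori
    else if (or_r) eye_stats$right$pref_ori
    else NA_real_
    data.frame(unit = i, b = b, od_bin = od_bin(b),
               cv_left = eye_stats$left$cv, cv_right = eye_stats$right$cv,
               pref_ori_left = eye_stats$left$pref_ori,
               pref_ori_right = eye_stats$right$pref_ori,
               pref_sf_left = eye_stats$left$pref_sf,
               pref_sf_right = eye_stats$right$pref_sf,
               fwhm_left = eye_stats$left$fwhm,
               fwhm_right = eye_stats$right$fwhm,
               resp_left = eye_stats$left$resp,
               resp_right = eye_stats$right$resp,
               responsive_left = resp_l, responsive_right = resp_r,
               oriented_left = or_l, oriented_right = or_r,
               pref_ori = pref,
               localization_fraction = localization_fraction(rf))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rf_metrics", "data.frame")
  out
}

#' Mean SF response profiles per eye over a model's units
#'
#' Averages, across responsive eyes, each unit's max-over-orientation
#' grating response per probe SF; used for the spatial-acuity recovery
#' curves.
#'
#' @inheritParams rf_metrics
#' @param normalize scale each unit's profile to peak 1 before averaging.
#' @return matrix with rows `left`, `right` and one column per probe SF.
#' @export
sf_profiles <- function(model, patch_side = NULL, orientations = 0:179,
                        sfs = seq(0.02, 0.5, by = 0.02), normalize = TRUE) {
  R <- if (inherits(model, "learned_model")) model$pixel_rfs else model
  if (is.null(patch_side)) {
    patch_side <- if (inherits(model, "learned_model")) {
      model$whitening$patch_side %||% as.integer(sqrt(ncol(R) / 2))
    } else as.integer(sqrt(ncol(R) / 2))
  }
  bank <- grating_bank(patch_side, orientations, sfs)
  acc <- matrix(0, 2, length(sfs), dimnames = list(c("left", "right"), sfs))
  cnt <- c(0, 0)
  for (i in seq_len(nrow(R))) {
    e <- split_eyes(R[i, ])
    for (j in 1:2) {
      prof <- sf_tuning(grating_response(e[[j]], bank = bank))$profile
      if (max(prof) > 0) {
        if (normalize) prof <- prof / max(prof)
        acc[j, ] <- acc[j, ] + prof
        cnt[j] <- cnt[j] + 1
      }
    }
  }
  sweep(acc, 1, pmax(cnt, 1), `/`)
}
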