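#' PCA whitening model
#'
#' Fits the whitening transform used by every learner: remove the ensemble
#' mean, project on the leading `k` principal components, and rescale each
#' component to unit variance, so the whitened training data has identity
#' covariance. The full-scale analyses retain `k = 150` components of the
#' 1250-dimensional binocular patch vectors.
#'
#' @param patches a `stereo_patchset` or a numeric matrix (rows = patches).
#' @param k retained dimension (default 150); must not exceed the data rank.
#' @return object of class `whitening_model` with fields `mean` (length-D
#'   ensemble average), `components` (`k x D`, orthonormal rows, leading
#'   eigenvectors), `eigenvalues` (length-k variances, non-increasing), `k`,
#'   and `patch_side` when known.
#' @export
fit_whitening <- function(patches, k = 150) {
  ps <- NULL
  if (inherits(patches, "stereo_patchset")) {
    ps <- patches$patch_side
    patches <- patches$data
  }
  n <- nrow(patches)
  d <- ncol(patches)
  if (k > d) stop_invalid("k must not exceed the patch dimension")
  if (n <= k) stop_invalid("need more patches than retained components")
  mu <- colMeans(patches)
  xc <- sweep(patches, 2, mu)
  sv <- svd(xc, nu = 0, nv = min(n, d))
  ev <- sv$d^2 / (n - 1)
  if (ev[k] < max(ev) * 1e-12) {
    stop_invalid("rank deficiency: k exceeds the numerical rank of the data")
  }
  structure(list(mean = mu,
                 components = t(sv$v[, seq_len(k), drop = FALSE]),
                 eigenvalues = ev[seq_len(k)],
                 k = as.integer(k),
                 patch_side = ps),
            class = "whitening_model")
}

#' @export
print.whitening_model <- function(x, ...) {
  cat(sprintf("<whitening_model: k=%d of D=%d>\n", x$k, length(x$mean)))
  invisible(x)
}

#' Apply / invert the whitening transform
#'
#' `whiten()` maps pixel-space patches into the k-dimensional whitened
#' space; `unwhiten()` maps whitened vectors back (exactly within the
#' retained subspace; energy in discarded components is lost).
#'
#' @param wm a [fit_whitening()] model.
#' @param x matrix with patches (rows) in pixel space (`whiten`) or whitened
#'   space (`unwhiten`).
#' @return matrix of transformed rows.
#' @export
whiten <- function(wm, x) {
  if (inherits(x, "stereo_patchset")) x <- x$data
  sweep(x, 2, wm$mean) %*% t(wm$components * (1 / sqrt(wm$eigenvalues)))
}

#' @rdname whiten
#' @export
unwhiten <- function(wm, x) {
  sweep(x %*% (wm$components * sqrt(wm$eigenvalues)), 2, wm$mean, `+`)
}

#' Back-project whitened-space filters to pixel space
#'
#' Maps each learned filter row through the right inverse of the whitening
#' transform (`r = t(V) diag(sqrt(lambda)) w`, the de-whitened feature
#' direction): the stimulus pattern, in pixel coordinates, that the unit
#' represents. These are the receptive fields that get rendered and on
#' which the binocularity, tuning and localization metrics are computed;
#' using the de-whitened direction keeps the contribution of each principal
#' component proportional to its actual variance in the input instead of
#' amplifying near-discarded components.
#'
#' @param W `M x k` filter matrix in whitened space.
#' @param wm the [fit_whitening()] model used to whiten the training data.
#' @return `M x D` matrix of pixel-space receptive fields.
#' @export
filters_to_pixel_space <- function(W, wm) {
  if (ncol(W) != wm$k) stop_invalid("filter dimension does not match k")
  W %*% (wm$components * sqrt(wm$eigenvalues))
}

#' Map a pixel-space receptive field back into whitened-filter coordinates
#'
#' Inverse of [filters_to_pixel_space()] for fields inside the retained
#' subspace.
#'
#' @param R `M x D` matrix of pixel-space fields (rows).
#' @param wm whitening model.
#' @return `M x k` matrix.
#' @export
pixel_to_whitened_filters <- function(R, wm) {
  R %*% t(wm$components * (1 / sqrt(wm$eigenvalues)))
}
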