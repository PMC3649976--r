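#' Learned sparse-code model
#'
#' Common container returned by [poe_train_cd()], [fit_ica()] and
#' [fit_kmeans()]: `M` whitened-space filters (rows of `W`), optional
#' sparseness exponents `alpha` (PoE only), the whitening model used, and
#' the pixel-space receptive fields obtained by back-projection.
#'
#' @param learner `"poe"`, `"ica"` or `"kmeans"`.
#' @param W `M x k` filter matrix in whitened space.
#' @param alpha sparseness exponents (PoE) or `NULL`.
#' @param wm whitening model or `NULL`; when given, `pixel_rfs` is populated
#'   via [filters_to_pixel_space()].
#' @param training_log per-iteration diagnostics data frame or `NULL`.
#' @param seed seed used in fitting.
#' @param converged convergence flag (ICA).
#' @return object of class `learned_model`.
#' @export
learned_model <- function(learner, W, alpha = NULL, wm = NULL,
                          training_log = NULL, seed = NA_integer_,
                          converged = TRUE) {
  if (!is.null(alpha) && any(alpha <= 0)) {
    stop_invalid("alpha must be strictly positive")
  }
  structure(list(learner = learner, W = W, alpha = alpha,
                 M = nrow(W), k = ncol(W),
                 pixel_rfs = if (!is.null(wm)) filters_to_pixel_space(W, wm),
                 whitening = wm, training_log = training_log,
                 seed = seed, converged = converged),
            class = "learned_model")
}

#' @export
print.learned_model <- function(x, ...) {
  cat(sprintf("<learned_model: %s, M=%d units, k=%d>\n", x$learner, x$M,
              x$k))
  invisible(x)
}

#' Fit a complete sparse code by FastICA
#'
#' Runs the FastICA fixed-point algorithm (symmetric decorrelation, logcosh
#' contrast; delegated to `ica::icafast`) on whitened input. ICA is
#' complete: the number of units equals the whitened dimension `k`.
#'
#' @param patches whitened matrix (`n x k`) or a `stereo_patchset` (then
#'   `wm` is used to whiten).
#' @param seed integer seed for the random initial rotation.
#' @param wm optional whitening model for pixel-space back-projection.
#' @param maxit,tol FastICA iteration cap and convergence tolerance.
#' @return a `learned_model` with `learner = "ica"`; `converged` is `FALSE`
#'   (with a warning) if the fixed point was not reached.
#' @export
fit_ica <- function(patches, seed = 1, wm = NULL, maxit = 200, tol = 1e-6) {
  Z <- if (inherits(patches, "stereo_patchset")) {
    if (is.null(wm)) stop_invalid("a whitening model is required")
    whiten(wm, patches)
  } else patches
  fit <- withr::with_seed(as.integer(seed),
                          ica::icafast(Z, nc = ncol(Z), center = FALSE,
                                       maxit = maxit, tol = tol,
                                       alg = "par", fun = "logcosh"))
  if (!isTRUE(fit$converged)) {
    warning("FastICA did not converge within ", maxit,
            " iterations; returning the partial result")
  }
  # icafast estimates sources S = Z W'; rows of W are the unmixing filters
  # in whitened space.
  W <- fit$W
  dimnames(W) <- NULL
  learned_model("ica", W, wm = wm, seed = as.integer(seed),
                converged = isTRUE(fit$converged))
}

#' Fit a sparse code by k-means clustering
#'
#' Clusters the whitened patches with `stats::kmeans` and uses the
#' unit-normalized cluster centroids as filters. An empty-cluster failure is
#' retried with a reseeded initialization (logged via a message).
#'
#' @param patches whitened matrix or `stereo_patchset`.
#' @param M number of centroids (>= 2).
#' @param seed integer seed.
#' @param wm optional whitening model.
#' @param iter.max Lloyd iteration cap.
#' @return a `learned_model` with `learner = "kmeans"`.
#' @export
fit_kmeans <- function(patches, M, seed = 1, wm = NULL, iter.max = 100) {
  if (M < 1) stop_invalid("M must be >= 1")
  Z <- if (inherits(patches, "stereo_patchset")) {
    if (is.null(wm)) stop_invalid("a whitening model is required")
    whiten(wm, patches)
  } else patches
  km <- NULL
  for (try in 0:4) {
    km <- withr::with_seed(as.integer(seed) + try, tryCatch(
      kmeans(Z, centers = M, iter.max = iter.max),
      error = function(e) e, warning = function(w) w
    ))
    if (inherits(km, "kmeans")) break
    message("kmeans restart ", try + 1, ": ", conditionMessage(km))
  }
  if (!inherits(km, "kmeans")) {
    stop_invalid("kmeans failed after reseeded restarts")
  }
  W <- km$centers
  nrm <- sqrt(rowSums(W^2))
  nrm[nrm == 0] <- 1
  W <- W / nrm
  dimnames(W) <- NULL
  m <- learned_model("kmeans", W, wm = wm, seed = as.integer(seed))
  m$objective <- km$tot.withinss
  m$centers <- unname(km$centers) # raw (unnormalized) centroids
  m
}
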