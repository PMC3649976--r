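#' Save / load a binocular patch set as HDF5
#'
#' The patch matrix is stored as dataset `"patches"` with attributes
#' `patch_side`, `eye_layout`, `seed` and `condition`. Requires the
#' suggested rhdf5 package.
#'
#' @param ps a `stereo_patchset`.
#' @param path output `.h5` path (overwritten).
#' @export
write_patchset_h5 <- function(ps, path) {
  require_rhdf5()
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(ps$data, path, "patches")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "patches")
  rhdf5::h5writeAttribute(ps$patch_side, did, "patch_side")
  rhdf5::h5writeAttribute(ps$eye_layout, did, "eye_layout")
  rhdf5::h5writeAttribute(as.integer(ps$seed %||% NA), did, "seed")
  rhdf5::h5writeAttribute(ps$condition, did, "condition")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_patchset_h5
#' @export
read_patchset_h5 <- function(path) {
  require_rhdf5()
  data <- rhdf5::h5read(path, "patches")
  at <- rhdf5::h5readAttributes(path, "patches")
  stereo_patchset(data, patch_side = as.integer(at$patch_side),
                  seed = as.vector(at$seed),
                  condition = as.character(at$condition))
}

#' Save / load a learned model (with its whitening transform) as HDF5
#'
#' Stores datasets `W`, `alpha` (when present), `mean`, `components`,
#' `eigenvalues`, with `learner` and `seed` as attributes of `W`.
#'
#' @param model a `learned_model` with a whitening model attached.
#' @param path output `.h5` path (overwritten).
#' @export
write_model_h5 <- function(model, path) {
  require_rhdf5()
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(model$W, path, "W")
  if (!is.null(model$alpha)) rhdf5::h5write(model$alpha, path, "alpha")
  if (!is.null(model$whitening)) {
    rhdf5::h5write(model$whitening$mean, path, "mean")
    rhdf5::h5write(model$whitening$components, path, "components")
    rhdf5::h5write(model$whitening$eigenvalues, path, "eigenvalues")
    if (!is.null(model$whitening$patch_side)) {
      rhdf5::h5write(as.integer(model$whitening$patch_side), path,
                     "patch_side")
    }
  }
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "W")
  rhdf5::h5writeAttribute(model$learner, did, "learner")
  rhdf5::h5writeAttribute(as.integer(model$seed %||% NA), did, "seed")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_model_h5
#' @export
read_model_h5 <- function(path) {
  require_rhdf5()
  cont <- rhdf5::h5ls(path)$name
  at <- rhdf5::h5readAttributes(path, "W")
  wm <- if ("components" %in% cont) {
    structure(list(mean = as.vector(rhdf5::h5read(path, "mean")),
                   components = rhdf5::h5read(path, "components"),
                   eigenvalues = as.vector(rhdf5::h5read(path,
                                                         "eigenvalues")),
                   k = nrow(rhdf5::h5read(path, "components")),
                   patch_side = if ("patch_side" %in% cont) {
                     as.integer(rhdf5::h5read(path, "patch_side"))
                   }),
              class = "whitening_model")
  }
  learned_model(as.character(at$learner), rhdf5::h5read(path, "W"),
                alpha = if ("alpha" %in% cont) {
                  as.vector(rhdf5::h5read(path, "alpha"))
                },
                wm = wm, seed = as.vector(at$seed))
}

require_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop_invalid("HDF5 i/o requires the rhdf5 package")
  }
}

#' Write a receptive-field metrics table as CSV
#'
#' @param metrics an [rf_metrics()] table.
#' @param path output path.
#' @export
write_metrics_csv <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' Render a mosaic of receptive fields to PNG
#'
#' Lays out each unit's left/right-eye pair side by side on a grid, each
#' field scaled to its own symmetric range, and writes a grayscale PNG.
#'
#' @param model a `learned_model` with `pixel_rfs`, or an `M x D` matrix.
#' @param path output PNG path.
#' @param patch_side patch side `P` (inferred when possible).
#' @param n_show number of units to render (default up to 36).
#' @param ncol mosaic columns (unit pairs per row).
#' @export
write_rf_mosaic_png <- function(model, path, patch_side = NULL,
                                n_show = 36, ncol = 6) {
  R <- if (inherits(model, "learned_model")) model$pixel_rfs else model
  if (is.null(patch_side)) {
    patch_side <- if (inherits(model, "learned_model")) {
      model$whitening$patch_side %||% as.integer(sqrt(ncol(R) / 2))
    } else as.integer(sqrt(ncol(R) / 2))
  }
  p <- patch_side
  n_show <- min(n_show, nrow(R))
  nrow_m <- ceiling(n_show / ncol)
  pad <- 2
  tile_w <- 2 * p + 3 * pad
  tile_h <- p + 2 * pad
  canvas <- matrix(1, nrow_m * tile_h, ncol * tile_w)
  for (i in seq_len(n_show)) {
    e <- split_eyes(R[i, ])
    rng <- max(abs(R[i, ]))
    if (rng == 0) rng <- 1
    l <- matrix(e$left, p, p) / (2 * rng) + 0.5
    r <- matrix(e$right, p, p) / (2 * rng) + 0.5
    gr <- (ceiling(i / ncol) - 1) * tile_h
    gc <- ((i - 1) %% ncol) * tile_w
    canvas[gr + pad + seq_len(p), gc + pad + seq_len(p)] <- l
    canvas[gr + pad + seq_len(p), gc + 2 * pad + p + seq_len(p)] <- r
  }
  png::writePNG(pmin(pmax(canvas, 0), 1), path)
  invisible(path)
}
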