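#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic two-sided p-value; the
#' default test for comparing receptive-field property distributions across
#' rearing conditions.
#'
#' @param a,b numeric samples (nonempty).
#' @return list with `statistic` (D), `p_value`, `test = "ks"`.
#' @export
ks_test_2sample <- function(a, b) {
  if (!length(a) || !length(b)) stop_invalid("samples must be nonempty")
  ht <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, test = "ks")
}

#' Two-sided paired t-test
#'
#' Standard paired t statistic. Identical samples return `t = 0, p = 1`;
#' constant nonzero differences (zero variance) raise a degenerate-input
#' error.
#'
#' @param a,b paired numeric samples of equal length.
#' @return list with `statistic`, `p_value`, `test = "paired_t"`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop_invalid("paired samples differ in length")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(statistic = 0, p_value = 1, test = "paired_t"))
    }
    stop_invalid("degenerate input: differences have zero variance")
  }
  ht <- t.test(a, b, paired = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       test = "paired_t")
}

#' Kruskal-Wallis rank test across groups
#'
#' @param groups list of numeric samples (>= 2 groups).
#' @return list with `statistic`, `p_value`, `test = "kruskal_wallis"`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop_invalid("need at least two groups")
  ht <- kruskal.test(groups)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       test = "kruskal_wallis")
}

#' Population summary of a receptive-field metrics table
#'
#' @param metrics an [rf_metrics()] table.
#' @param ori_bin_width width of orientation-histogram bins, degrees.
#' @return list with the ocular-dominance histogram (7 bins), monocular
#'   fraction (bins 1 or 7), central-bin fraction (bin 4), per-eye oriented
#'   fractions, the orientation-preference histogram of selective units
#'   (joint with a monocular/binocular split), median FWHM, and the median
#'   localization fraction.
#' @export
summarize_metrics <- function(metrics, ori_bin_width = 15) {
  n <- nrow(metrics)
  odh <- tabulate(metrics$od_bin, nbins = 7)
  sel <- !is.na(metrics$pref_ori)
  breaks <- seq(0, 180, by = ori_bin_width)
  ori_hist <- if (any(sel)) {
    graphics::hist(metrics$pref_ori[sel] %% 180, breaks = breaks,
                   plot = FALSE, right = FALSE)$counts
  } else rep(0L, length(breaks) - 1)
  mono <- metrics$od_bin %in% c(1L, 7L)
  list(n_units = n,
       od_hist = odh,
       monocular_fraction = mean(mono),
       central_bin_fraction = mean(metrics$od_bin == 4L),
       oriented_fraction_left = mean(metrics$oriented_left),
       oriented_fraction_right = mean(metrics$oriented_right),
       oriented_fraction_any = mean(metrics$oriented_left |
                                      metrics$oriented_right),
       ori_hist = setNames(ori_hist, head(breaks, -1)),
       ori_hist_monocular = if (any(sel & mono)) {
         graphics::hist(metrics$pref_ori[sel & mono] %% 180, breaks = breaks,
                        plot = FALSE, right = FALSE)$counts
       } else rep(0L, length(breaks) - 1),
       median_fwhm = median(c(metrics$fwhm_left[metrics$oriented_left],
                              metrics$fwhm_right[metrics$oriented_right]),
                            na.rm = TRUE),
       median_localization = median(metrics$localization_fraction))
}

#' Run one rearing condition end to end
#'
#' Composes the full pipeline deterministically from one seed: (optionally)
#' generate synthetic stereo images, build the condition's training set,
#' whiten, fit the chosen learner, characterise the receptive fields and
#' summarise the population.
#'
#' @param config a [rearing_config()].
#' @param images list of [stereo_image()]; if `NULL`, synthetic stereo
#'   images are generated from `image_params`.
#' @param learner `"poe"`, `"ica"` or `"kmeans"`.
#' @param seed integer seed governing image synthesis, sampling and fitting.
#' @param n_patches training patches.
#' @param patch_side patch side, pixels.
#' @param k retained principal components.
#' @param overcomplete overcompleteness factor for PoE / k-means unit count
#'   (`M = round(overcomplete * k)`); ICA is complete by construction.
#' @param train_cfg optional [train_config()] overriding the PoE defaults
#'   (its `M` and `seed` are taken from this call).
#' @param region focal-square side passed to the sampler.
#' @param image_params list of arguments for [gen_naturalistic_stereo()]
#'   when `images` is `NULL`.
#' @param metrics_args list of extra arguments for [rf_metrics()].
#' @return list of class `condition_result`: `config`, `learner`, `seed`,
#'   `model`, `metrics`, `summary`, `provenance`.
#' @export
run_condition <- function(config, images = NULL, learner = c("poe", "ica",
                                                             "kmeans"),
                          seed = 1, n_patches = 20000, patch_side = 16,
                          k = 48, overcomplete = 1.5, train_cfg = NULL,
                          region = 192,
                          image_params = list(n_images = 8, size = 256),
                          metrics_args = list()) {
  learner <- match.arg(learner)
  seed <- as.integer(seed)
  if (is.null(images)) {
    images <- do.call(gen_naturalistic_stereo,
                      c(image_params, list(seed = seed)))
  }
  ps <- build_training_set(config, images, n_patches,
                           patch_side = patch_side, region = region,
                           seed = seed)
  wm <- fit_whitening(ps, k = k)
  Z <- whiten(wm, ps)
  M <- round(overcomplete * k)
  model <- switch(learner,
    poe = {
      cfg <- train_cfg %||% train_config(M = M, seed = seed)
      cfg$M <- as.integer(M)
      cfg$seed <- seed
      poe_train_cd(Z, cfg, wm = wm)
    },
    ica = fit_ica(Z, seed = seed, wm = wm),
    kmeans = fit_kmeans(Z, M = M, seed = seed, wm = wm))
  metrics <- do.call(rf_metrics,
                     c(list(model, patch_side = patch_side), metrics_args))
  structure(list(config = config, learner = learner, seed = seed,
                 model = model, metrics = metrics,
                 summary = summarize_metrics(metrics),
                 provenance = list(n_patches = n_patches, k = k,
                                   patch_side = patch_side,
                                   M = model$M, region = region,
                                   package_version =
                                     as.character(utils::packageVersion("v1rear")))),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("<condition_result: %s / %s, seed %d, %d units>\n",
              x$config$condition, x$learner, x$seed, x$summary$n_units))
  cat("  OD histogram:", x$summary$od_hist, "\n")
  cat(sprintf("  monocular fraction %.2f | oriented L %.2f R %.2f\n",
              x$summary$monocular_fraction,
              x$summary$oriented_fraction_left,
              x$summary$oriented_fraction_right))
  invisible(x)
}

#' Repeat conditions over a seed ladder and summarise
#'
#' Runs every configuration `n_repeats` times with seeds
#' `base_seed + 0 .. n_repeats - 1` (each seed drives both the input
#' sampling and the model fit), collects per-repeat scalar summaries, and
#' reports their means and standard errors. The full-scale analyses use 25
#' repeats.
#'
#' @param configs named list of [rearing_config()] objects; a condition
#'   named `"normal"` enables [compare_to_normal()].
#' @param n_repeats repeats per condition (>= 2; default 25).
#' @param base_seed first seed of the ladder.
#' @param ... further arguments passed to [run_condition()].
#' @return list of class `repeat_summary`: `results` (condition -> list of
#'   `condition_result`), `stats` (data frame of mean and SEM per scalar
#'   summary statistic), `tests` (KS comparisons vs normal when available),
#'   `n_repeats`, `failed` (count of excluded repeats).
#' @export
repeat_conditions <- function(configs, n_repeats = 25, base_seed = 1, ...) {
  if (n_repeats < 2) stop_invalid("n_repeats must be >= 2")
  stopifnot(length(names(configs)) == length(configs))
  failed <- 0L
  results <- lapply(configs, function(cfg) {
    out <- list()
    for (i in seq_len(n_repeats)) {
      r <- tryCatch(run_condition(cfg, seed = base_seed + i - 1L, ...),
                    error = function(e) e)
      if (inherits(r, "error")) {
        warning("repeat ", i, " failed and was excluded: ",
                conditionMessage(r))
        failed <<- failed + 1L
      } else {
        out[[length(out) + 1L]] <- r
      }
    }
    out
  })
  scalar_stats <- c("monocular_fraction", "central_bin_fraction",
                    "oriented_fraction_left", "oriented_fraction_right",
                    "oriented_fraction_any", "median_fwhm",
                    "median_localization")
  stats_df <- do.call(rbind, lapply(names(results), function(cond) {
    do.call(rbind, lapply(scalar_stats, function(s) {
      vals <- vapply(results[[cond]], function(r) r$summary[[s]], 0)
      data.frame(condition = cond, statistic = s, mean = mean(vals),
                 sem = stats::sd(vals) / sqrt(length(vals)),
                 n = length(vals))
    }))
  }))
  tests <- if ("normal" %in% names(results)) {
    compare_to_normal(results)
  }
  structure(list(results = results, stats = stats_df, tests = tests,
                 n_repeats = n_repeats, failed = failed),
            class = "repeat_summary")
}

pool_metric <- function(res_list, col) {
  unlist(lapply(res_list, function(r) r$metrics[[col]]))
}

pool_pref_ori <- function(res_list) {
  v <- pool_metric(res_list, "pref_ori")
  v[!is.na(v)]
}

#' Compare each condition's pooled distributions to the normal condition
#'
#' Two-sided KS tests, pooling units across repeats, of: the binocularity
#' index distribution, the per-eye circular variances (tuning/oriented
#' fractions), and the orientation-preference distribution of selective
#' units, each condition against `"normal"`. Raw p-values are reported (no
#' multiplicity correction).
#'
#' @param results named list (condition -> list of `condition_result`), as
#'   in `repeat_conditions()$results`; must include `"normal"`.
#' @return data frame with one row per (condition, statistic): columns
#'   `condition, statistic, D, p_value`.
#' @export
compare_to_normal <- function(results) {
  if (!"normal" %in% names(results)) {
    stop_invalid("a 'normal' baseline condition is required")
  }
  base <- results$normal
  comps <- list(
    binocularity = function(r) pool_metric(r, "b"),
    cv_left = function(r) pool_metric(r, "cv_left"),
    cv_right = function(r) pool_metric(r, "cv_right"),
    orientation_pref = pool_pref_ori
  )
  out <- list()
  for (cond in setdiff(names(results), "normal")) {
    for (s in names(comps)) {
      a <- comps[[s]](results[[cond]])
      b <- comps[[s]](base)
      if (!length(a) || !length(b)) next
      kt <- ks_test_2sample(a, b)
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, statistic = s, D = kt$statistic,
        p_value = kt$p_value)
    }
  }
  do.call(rbind, out)
}
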