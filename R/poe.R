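#' Training configuration for the product-of-experts model
#'
#' @param M number of experts/units. The full-scale analyses use an
#'   overcompleteness factor of 1.5 over the whitened dimension
#'   (M = 225 at k = 150).
#' @param learning_rate initial gradient step size (default 0.01, decayed as
#'   `1 / (1 + t * lr_decay)` over updates `t`).
#' @param lr_decay learning-rate decay constant per update.
#' @param momentum heavy-ball momentum on the parameter updates (default
#'   0.9, the usual choice for contrastive-divergence training; 0 disables).
#' @param batch_size minibatch size (default 100).
#' @param n_epochs passes over the training set.
#' @param cd_steps Markov-chain steps per contrastive-divergence update
#'   (CD-k; default 1).
#' @param sampler negative-phase sampler: `"hmc"` (Hamiltonian Monte Carlo
#'   with step size auto-tuned towards 90\% acceptance) or `"langevin"`
#'   (unadjusted Langevin steps).
#' @param n_leapfrog leapfrog steps per HMC proposal.
#' @param hmc_eps0 initial HMC/Langevin step size.
#' @param learn_alpha learn the sparseness exponents (default) or freeze
#'   them at their initial value 1.
#' @param seed integer seed for initialization, shuffling and sampling.
#' @return list of class `train_config`.
#' @export
train_config <- function(M, learning_rate = 0.01, lr_decay = 2e-4,
                         momentum = 0.9, batch_size = 100, n_epochs = 30,
                         cd_steps = 1,
                         sampler = c("hmc", "langevin"), n_leapfrog = 5,
                         hmc_eps0 = 0.2, learn_alpha = TRUE, seed = 1) {
  sampler <- match.arg(sampler)
  vals <- c(M, learning_rate, batch_size, n_epochs, cd_steps, n_leapfrog,
            hmc_eps0)
  if (any(vals <= 0)) stop_invalid("train_config values must be positive")
  if (momentum < 0 || momentum >= 1) {
    stop_invalid("momentum must lie in [0, 1)")
  }
  structure(list(M = as.integer(M), learning_rate = learning_rate,
                 lr_decay = lr_decay, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs),
                 cd_steps = as.integer(cd_steps), sampler = sampler,
                 n_leapfrog = as.integer(n_leapfrog), hmc_eps0 = hmc_eps0,
                 learn_alpha = isTRUE(learn_alpha), seed = as.integer(seed)),
            class = "train_config")
}

#' Log unnormalized density of the product of Student-t experts
#'
#' The model assigns a whitened input vector `x` the unnormalized log
#' density `sum_i -alpha_i * log(1 + (w_i . x)^2 / 2)`: each expert is a
#' heavy-tailed Student-t-shaped function of the projection on its filter,
#' and `alpha_i > 0` sets the expert's sparseness (an expert with
#' `alpha = 1.5` is exactly a t distribution with 2 degrees of freedom on
#' its projection). The normalization constant is intractable for
#' overcomplete models and is never materialized.
#'
#' @param x whitened input vector (length k).
#' @param W `M x k` filter matrix.
#' @param alpha length-M vector of positive sparseness exponents.
#' @return scalar log unnormalized density (0 at `x = 0`).
#' @export
poe_log_unnorm <- function(x, W, alpha) {
  if (any(alpha <= 0)) stop_invalid("alpha must be strictly positive")
  if (length(x) != ncol(W)) stop_invalid("dimension mismatch")
  s <- as.vector(W %*% x)
  -sum(alpha * log1p(0.5 * s^2))
}

# Energy and gradients, vectorized over a batch X (B x k).
# E(x) = sum_i alpha_i log(1 + s_i^2/2), s = W x.
poe_energy <- function(X, W, alpha) {
  S <- X %*% t(W)
  rowSums(sweep(log1p(0.5 * S^2), 2, alpha, `*`))
}

# Gradient of E w.r.t. x for each row of X: (alpha * s/(1+s^2/2)) W.
poe_grad_x <- function(X, W, alpha) {
  S <- X %*% t(W)
  (sweep(S / (1 + 0.5 * S^2), 2, alpha, `*`)) %*% W
}

# Batch-mean gradients of E w.r.t. W (M x k) and log alpha (M).
poe_grad_params <- function(X, W, alpha) {
  S <- X %*% t(W)
  Phi <- S / (1 + 0.5 * S^2)
  gW <- (crossprod(Phi, X) / nrow(X)) * alpha
  gphi <- alpha * colMeans(log1p(0.5 * S^2)) # d/d log(alpha)
  list(W = gW, phi = gphi)
}

# One HMC round over a batch: returns updated samples and acceptance rate.
hmc_step <- function(X, W, alpha, eps, n_leapfrog) {
  B <- nrow(X)
  P0 <- matrix(rnorm(length(X)), B)
  X1 <- X
  P <- P0 - 0.5 * eps * poe_grad_x(X1, W, alpha)
  for (l in seq_len(n_leapfrog)) {
    X1 <- X1 + eps * P
    if (l < n_leapfrog) P <- P - eps * poe_grad_x(X1, W, alpha)
  }
  P <- P - 0.5 * eps * poe_grad_x(X1, W, alpha)
  dH <- (poe_energy(X1, W, alpha) + 0.5 * rowSums(P^2)) -
    (poe_energy(X, W, alpha) + 0.5 * rowSums(P0^2))
  # a numerically exploded proposal is always rejected
  acc <- is.finite(dH) & (log(runif(B)) < -dH)
  X[acc, ] <- X1[acc, , drop = FALSE]
  list(X = X, acc_rate = mean(acc))
}

# Unadjusted Langevin step.
langevin_step <- function(X, W, alpha, eps) {
  X - 0.5 * eps^2 * poe_grad_x(X, W, alpha) +
    eps * matrix(rnorm(length(X)), nrow(X))
}

#' Draw negative-phase samples by MCMC initialized at the data
#'
#' Runs `steps` rounds of the configured sampler (HMC with Metropolis
#' correction, or unadjusted Langevin) on the product-of-experts energy,
#' starting the chains at the rows of `X` (the contrastive-divergence
#' initialization).
#'
#' @param X starting points, one chain per row (whitened space).
#' @param W,alpha model parameters.
#' @param steps number of sampler rounds.
#' @param sampler `"hmc"` or `"langevin"`.
#' @param eps step size.
#' @param n_leapfrog leapfrog steps per HMC proposal.
#' @return list with `X` (samples) and `acc_rate` (HMC acceptance, `NA` for
#'   Langevin).
#' @export
poe_sample <- function(X, W, alpha, steps = 1, sampler = "hmc", eps = 0.2,
                       n_leapfrog = 5) {
  acc <- NA_real_
  for (s in seq_len(steps)) {
    if (sampler == "hmc") {
      r <- hmc_step(X, W, alpha, eps, n_leapfrog)
      X <- r$X
      acc <- r$acc_rate
    } else {
      X <- langevin_step(X, W, alpha, eps)
    }
  }
  list(X = X, acc_rate = acc)
}

#' Train the product-of-experts model by contrastive divergence
#'
#' Stochastic gradient ascent on the CD objective: for each minibatch the
#' positive phase evaluates the energy gradient at the data and the negative
#' phase at samples obtained by `cd_steps` rounds of the configured sampler
#' initialized at the data. Filters `W` are initialized i.i.d. Gaussian
#' (sd 0.1) and sparseness exponents at 1, learned on the log scale to stay
#' positive. The HMC step size is adapted towards 90\% acceptance.
#'
#' @param patches whitened training matrix (`n x k`), or a
#'   `stereo_patchset` together with `wm`.
#' @param cfg a [train_config()].
#' @param wm optional [fit_whitening()] model; required to populate
#'   pixel-space receptive fields (and to whiten `patches` if they are given
#'   as a patch set).
#' @return a `learned_model` (fields `learner = "poe"`, `W`, `alpha`, `M`,
#'   `pixel_rfs` when `wm` is supplied, `training_log` data frame).
#' @export
poe_train_cd <- function(patches, cfg, wm = NULL) {
  stopifnot(inherits(cfg, "train_config"))
  Z <- if (inherits(patches, "stereo_patchset")) {
    if (is.null(wm)) stop_invalid("a whitening model is required")
    whiten(wm, patches)
  } else patches
  k <- ncol(Z)
  n <- nrow(Z)
  withr::with_seed(cfg$seed, {
    W <- matrix(rnorm(cfg$M * k, sd = 0.1), cfg$M, k)
    phi <- rep(0, cfg$M) # log alpha
    mom <- cfg$momentum %||% 0
    vW <- matrix(0, cfg$M, k)
    vphi <- rep(0, cfg$M)
    eps <- cfg$hmc_eps0
    t_up <- 0L
    log_rows <- vector("list", cfg$n_epochs)
    for (epoch in seq_len(cfg$n_epochs)) {
      ord <- sample.int(n)
      acc_sum <- 0
      acc_n <- 0
      gnorm <- 0
      nb <- 0L
      for (start in seq(1L, n - cfg$batch_size + 1L, by = cfg$batch_size)) {
        Xb <- Z[ord[start:(start + cfg$batch_size - 1L)], , drop = FALSE]
        alpha <- exp(phi)
        gpos <- poe_grad_params(Xb, W, alpha)
        smp <- poe_sample(Xb, W, alpha, steps = cfg$cd_steps,
                          sampler = cfg$sampler, eps = eps,
                          n_leapfrog = cfg$n_leapfrog)
        if (cfg$sampler == "hmc") {
          eps <- min(2, max(1e-3, eps * exp(0.05 * (smp$acc_rate - 0.9))))
          acc_sum <- acc_sum + smp$acc_rate
          acc_n <- acc_n + 1
        }
        gneg <- poe_grad_params(smp$X, W, alpha)
        t_up <- t_up + 1L
        lr <- cfg$learning_rate / (1 + t_up * cfg$lr_decay)
        dW <- gneg$W - gpos$W # ascend likelihood ~ descend data energy
        vW <- mom * vW + lr * dW
        W <- W + vW
        if (cfg$learn_alpha) {
          vphi <- mom * vphi + lr * (gneg$phi - gpos$phi)
          phi <- phi + vphi
        }
        gnorm <- gnorm + sqrt(sum(dW^2))
        nb <- nb + 1L
        if (!all(is.finite(W)) || !all(is.finite(phi))) {
          stop_invalid("training failure: non-finite parameters at update ",
                       t_up)
        }
      }
      log_rows[[epoch]] <- data.frame(
        epoch = epoch,
        energy = mean(poe_energy(Z[ord[seq_len(min(n, 2000L))], ,
                                   drop = FALSE], W, exp(phi))),
        grad_norm = gnorm / max(1L, nb),
        acc_rate = if (acc_n > 0) acc_sum / acc_n else NA_real_,
        eps = eps)
    }
    learned_model("poe", W, alpha = exp(phi), wm = wm,
                  training_log = do.call(rbind, log_rows), seed = cfg$seed)
  })
}
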