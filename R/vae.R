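#' Variational-autoencoder architecture
#'
#' One hidden layer of `hidden_dim` rectified-linear units on both the
#' encoder and the decoder. The encoder maps a binary contact vector to the
#' mean and log-variance of a diagonal Gaussian posterior over
#' `latent_dim` latent variables; the decoder maps a latent vector to
#' per-feature Bernoulli probabilities through a logistic output layer. The
#' prior is a standard multivariate Gaussian. Two latent variables are used
#' when the model defines the folding coordinate; 25 when it serves as a
#' probability (free-energy) estimator.
#'
#' @param input_dim number of contact features (378 for 28 bins).
#' @param hidden_dim hidden-layer width.
#' @param latent_dim number of latent variables.
#' @return an object of class `vae_architecture`.
#' @export
vae_architecture <- function(input_dim, hidden_dim = 200L, latent_dim = 2L) {
  stopifnot(input_dim >= 1, hidden_dim >= 1, latent_dim >= 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 latent_dim = as.integer(latent_dim),
                 hidden_activation = "relu", output_activation = "logistic"),
            class = "vae_architecture")
}

#' Training configuration for the variational autoencoder
#'
#' @param epochs number of passes over the training set.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param seed integer RNG seed controlling weight initialization, shuffling
#'   and reparameterization noise.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 1000L, batch_size = 500L,
                         learning_rate = 0.001, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "train_config")
}

relu <- function(x) (x > 0) * x

sigmoid <- function(x) 1 / (1 + exp(-x))

# log Bernoulli likelihood from logits, numerically stable:
# x*log(p) + (1-x)*log(1-p) = x*l - softplus(l)
log_bernoulli <- function(x, logits) {
  sp <- ifelse(logits > 30, logits, log1p(exp(pmin(logits, 30))))
  x * logits - sp
}

init_weights <- function(arch) {
  d <- arch$input_dim; h <- arch$hidden_dim; l <- arch$latent_dim
  fan <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(1 / nin)),
                                    nin, nout)
  list(W1 = fan(d, h), b1 = numeric(h),
       Wmu = fan(h, l), bmu = numeric(l),
       Wlv = fan(h, l), blv = numeric(l),
       W4 = fan(l, h), b4 = numeric(h),
       W5 = fan(h, d), b5 = numeric(d))
}

encode_raw <- function(w, X) {
  He <- relu(sweep(X %*% w$W1, 2, w$b1, "+"))
  list(He = He,
       mu = sweep(He %*% w$Wmu, 2, w$bmu, "+"),
       lv = sweep(He %*% w$Wlv, 2, w$blv, "+"))
}

decode_raw <- function(w, Z) {
  Hd <- relu(sweep(Z %*% w$W4, 2, w$b4, "+"))
  list(Hd = Hd, logits = sweep(Hd %*% w$W5, 2, w$b5, "+"))
}

#' Train a variational autoencoder on contact vectors
#'
#' Maximizes the evidence lower bound -- Bernoulli reconstruction
#' log-likelihood minus the closed-form Gaussian Kullback-Leibler divergence
#' of the posterior from the standard-normal prior -- by stochastic gradient
#' ascent with the Adam optimizer and the reparameterization trick.
#' Training is exactly reproducible for a given `cfg$seed`.
#'
#' @param X matrix of binary contact vectors (cells x features).
#' @param arch a [vae_architecture()]; defaults to a 2-latent model sized to
#'   the data.
#' @param cfg a [train_config()].
#' @param verbose print the mean ELBO every 50 epochs.
#' @return an object of class `vae_model` holding the architecture, trained
#'   weights and per-epoch mean-ELBO history.
#' @export
train_vae <- function(X, arch = vae_architecture(ncol(X)),
                      cfg = train_config(), verbose = FALSE) {
  stopifnot(is.matrix(X), nrow(X) >= 1L)
  if (ncol(X) != arch$input_dim)
    stop("data have ", ncol(X), " features but architecture expects ",
         arch$input_dim)
  set.seed(cfg$seed)
  w <- init_weights(arch)
  m <- lapply(w, function(p) p * 0)   # Adam first moment
  v <- lapply(w, function(p) p * 0)   # Adam second moment
  beta1 <- 0.9; beta2 <- 0.999; eps_adam <- 1e-8
  t_adam <- 0L
  n <- nrow(X)
  elbo_hist <- numeric(cfg$epochs)

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    epoch_elbo <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      B <- nrow(Xb)

      enc <- encode_raw(w, Xb)
      eps <- matrix(stats::rnorm(B * arch$latent_dim), B, arch$latent_dim)
      sd_z <- exp(enc$lv / 2)
      Z <- enc$mu + sd_z * eps
      dec <- decode_raw(w, Z)
      P <- sigmoid(dec$logits)

      recon <- sum(log_bernoulli(Xb, dec$logits))
      kl <- 0.5 * sum(enc$mu^2 + exp(enc$lv) - 1 - enc$lv)
      elbo <- (recon - kl) / B
      if (!is.finite(elbo))
        stop("non-finite training loss at epoch ", epoch)
      epoch_elbo <- epoch_elbo + elbo * B / n

      # gradients of mean negative ELBO
      dlogits <- (P - Xb) / B
      g <- list()
      g$W5 <- crossprod(dec$Hd, dlogits); g$b5 <- colSums(dlogits)
      dHd <- (dlogits %*% t(w$W5)) * (dec$Hd > 0)
      g$W4 <- crossprod(Z, dHd); g$b4 <- colSums(dHd)
      dZ <- dHd %*% t(w$W4)
      dmu <- dZ + enc$mu / B
      dlv <- dZ * eps * sd_z / 2 + (exp(enc$lv) - 1) / (2 * B)
      g$Wmu <- crossprod(enc$He, dmu); g$bmu <- colSums(dmu)
      g$Wlv <- crossprod(enc$He, dlv); g$blv <- colSums(dlv)
      dHe <- (dmu %*% t(w$Wmu) + dlv %*% t(w$Wlv)) * (enc$He > 0)
      g$W1 <- crossprod(Xb, dHe); g$b1 <- colSums(dHe)

      t_adam <- t_adam + 1L
      for (nm in names(w)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- m[[nm]] / (1 - beta1^t_adam)
        vhat <- v[[nm]] / (1 - beta2^t_adam)
        w[[nm]] <- w[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps_adam)
      }
    }
    elbo_hist[epoch] <- epoch_elbo
    if (verbose && epoch %% 50 == 0)
      message(sprintf("epoch %d  mean ELBO %.2f", epoch, epoch_elbo))
  }
  structure(list(arch = arch, weights = w, cfg = cfg, elbo = elbo_hist),
            class = "vae_model")
}

#' @export
print.vae_model <- function(x, ...) {
  cat("<vae_model> ", x$arch$input_dim, " -> ", x$arch$hidden_dim, " -> ",
      x$arch$latent_dim, " latent; final mean ELBO ",
      round(utils::tail(x$elbo, 1), 2), " nats\n", sep = "")
  invisible(x)
}

#' Encode contact vectors into the latent space
#'
#' Deterministic mapping to the posterior mean (the structure's embedding)
#' and log-variance.
#'
#' @param model a trained [train_vae()] model.
#' @param X contact vector or matrix of vectors.
#' @return list with matrices `mean` and `logvar` (rows = inputs).
#' @export
encode <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$arch$input_dim)
    stop("input has ", ncol(X), " features; model expects ",
         model$arch$input_dim)
  enc <- encode_raw(model$weights, X)
  list(mean = enc$mu, logvar = enc$lv)
}

#' Estimate the log-probability of contact vectors
#'
#' Monte-Carlo evidence lower bound: the mean over `n_samples` posterior
#' samples of the Bernoulli reconstruction log-likelihood, minus the
#' closed-form Gaussian Kullback-Leibler divergence of the posterior from
#' the prior. For binary data this lower-bounds `log p(Q)` and is always
#' non-positive. Values are in nats, i.e. units of k_B T at T = 1.
#'
#' @param model a trained [train_vae()] model.
#' @param X contact vector or matrix of vectors.
#' @param n_samples number of latent samples.
#' @param seed integer RNG seed; sharing the seed between two models of
#'   equal latent dimension draws identical latent noise for both (common
#'   random numbers), which reduces the variance of log-probability
#'   differences.
#' @return numeric vector of log-probability estimates (one per row of `X`)
#'   with attribute `n_samples`.
#' @export
estimate_log_prob <- function(model, X, n_samples = 20L, seed = 1L) {
  stopifnot(n_samples >= 1L)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$arch$input_dim)
    stop("input has ", ncol(X), " features; model expects ",
         model$arch$input_dim)
  set.seed(seed)
  w <- model$weights
  enc <- encode_raw(w, X)
  nL <- model$arch$latent_dim
  B <- nrow(X)
  sd_z <- exp(enc$lv / 2)
  kl <- 0.5 * rowSums(enc$mu^2 + exp(enc$lv) - 1 - enc$lv)
  eps_all <- array(stats::rnorm(n_samples * B * nL), c(n_samples, B, nL))
  recon <- numeric(B)
  for (s in seq_len(n_samples)) {
    eps <- matrix(eps_all[s, , ], B, nL)
    Z <- enc$mu + sd_z * eps
    dec <- decode_raw(w, Z)
    recon <- recon + rowSums(log_bernoulli(X, dec$logits))
  }
  structure(recon / n_samples - kl, n_samples = n_samples)
}

#' Sample contact matrices from the generative model
#'
#' Draws latent vectors from the standard-normal prior, decodes them into
#' per-feature Bernoulli probabilities, and samples binary contacts.
#'
#' @param model a trained [train_vae()] model.
#' @param n number of matrices to generate.
#' @param seed integer RNG seed.
#' @return list of symmetric binary `contact_matrix` objects.
#' @export
sample_contacts <- function(model, n, seed = 1L) {
  set.seed(seed)
  nL <- model$arch$latent_dim
  Z <- matrix(stats::rnorm(n * nL), n, nL)
  P <- sigmoid(decode_raw(model$weights, Z)$logits)
  draws <- (matrix(stats::runif(length(P)), nrow(P), ncol(P)) < P) * 1L
  lapply(seq_len(n), function(k) unvectorize(draws[k, ]))
}
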