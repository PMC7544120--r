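# hand-built VAE with zero weights: the posterior equals the prior and the
# decoder emits a constant probability, so log-probabilities have closed forms
const_decoder_model <- function(input_dim, latent_dim = 1L, hidden = 4L,
                                logit_out = 0, mu_bias = 0, lv_bias = 0) {
  arch <- vae_architecture(input_dim, hidden_dim = hidden,
                           latent_dim = latent_dim)
  w <- list(W1 = matrix(0, input_dim, hidden), b1 = numeric(hidden),
            Wmu = matrix(0, hidden, latent_dim),
            bmu = rep(mu_bias, latent_dim),
            Wlv = matrix(0, hidden, latent_dim),
            blv = rep(lv_bias, latent_dim),
            W4 = matrix(0, latent_dim, hidden), b4 = numeric(hidden),
            W5 = matrix(0, hidden, input_dim),
            b5 = rep(logit_out, input_dim))
  structure(list(arch = arch, weights = w, cfg = NULL, elbo = NA_real_),
            class = "vae_model")
}
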