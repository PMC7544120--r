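# Expensive shared fixtures, built lazily once per test run.
#
# The polymer ensembles and trained models below are the desk-scale study
# conditions used throughout the suite: 5e5 production steps thinned to 2000
# frames per ensemble, and 25-latent probability models trained at the
# package defaults for this data size.

.fixtures <- new.env(parent = emptyenv())

fixture_ensembles <- function() {
  if (is.null(.fixtures$Xr)) {
    p <- polymer_params()
    ref <- run_langevin(p, 5e5, save_every = 250, seed = 101)
    chrom <- run_langevin(p, 5e5, save_every = 250, seed = 102,
                          chromatin_like = TRUE)
    to_x <- function(tr) do.call(rbind, lapply(tr, function(f)
      vectorize(contacts_from_conformation(f, p$contact_cutoff))))
    .fixtures$params <- p
    .fixtures$ref <- ref
    .fixtures$chrom <- chrom
    .fixtures$Xr <- to_x(ref)
    .fixtures$Xc <- to_x(chrom)
  }
  .fixtures
}

fixture_prob_models <- function(epochs = 100) {
  fx <- fixture_ensembles()
  if (is.null(fx$vae_ref)) {
    arch <- vae_architecture(ncol(fx$Xr), latent_dim = 25L)
    fx$vae_ref <- train_vae(fx$Xr, arch, train_config(epochs = epochs,
                                                      seed = 201))
    fx$vae_chrom <- train_vae(fx$Xc, arch, train_config(epochs = epochs,
                                                        seed = 202))
  }
  fx
}

fixture_energy_validation <- function() {
  fx <- fixture_prob_models()
  if (is.null(fx$ie)) {
    fx$du <- vapply(fx$chrom, specific_energy_delta, numeric(1),
                    params = fx$params)
    fx$u_chrom <- vapply(fx$chrom, function(f)
      total_energy(f, fx$params, chromatin_like = TRUE)$total, numeric(1))
    fx$u_ref <- vapply(fx$ref, function(f)
      total_energy(f, fx$params, chromatin_like = FALSE)$total, numeric(1))
    fx$ie <- interaction_energy(fx$vae_chrom, fx$vae_ref, fx$Xc, seed = 401)
    fx$nlp_chrom <- -as.numeric(estimate_log_prob(fx$vae_chrom, fx$Xc,
                                                  seed = 402))
    fx$nlp_ref <- -as.numeric(estimate_log_prob(fx$vae_ref, fx$Xr,
                                                seed = 403))
  }
  fx
}

fixture_synth_pipeline <- function() {
  fx <- fixture_ensembles()
  if (is.null(fx$coord_model)) {
    cfg <- synth_config(n_per_type = 700L, seed = 301L)
    cells <- generate_dataset(fx$ref, fx$chrom, cfg)
    qd <- preprocess_traces(cells, cutoff_nm = 450, seed = 302L)
    model <- train_vae(qd$vectors,
                       vae_architecture(ncol(qd$vectors), latent_dim = 2L),
                       train_config(epochs = 120, seed = 303))
    emb <- encode(model, qd$vectors)$mean
    wt <- qd$labels == "WT"
    sep <- fit_separator(emb[wt, , drop = FALSE], emb[!wt, , drop = FALSE])
    fx$cells <- cells
    fx$qdata <- qd
    fx$coord_model <- model
    fx$embeddings <- emb
    fx$separator <- sep
    fx$coords <- coordinate_value(sep, emb)
  }
  fx
}
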