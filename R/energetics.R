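#' Interaction energy by reference-model subtraction
#'
#' Estimates the specific interaction energy of a structure as the negative
#' log of the probability ratio between a target and a reference generative
#' model: `-log[P(Q) / P_ref(Q)] = log P_ref(Q) - log P(Q)`, in units of
#' k_B T. When the two models describe polymers of equal length and similar
#' generic properties, the conformational-entropy contribution to each log
#' probability cancels in the difference, leaving the energetic part.
#' Latent noise is shared between the two estimates (same seed), so
#' identical models give exactly zero.
#'
#' @param model,model_ref trained [train_vae()] models of equal input and
#'   latent dimension.
#' @param X contact vector or matrix of vectors.
#' @param n_samples latent samples per estimate.
#' @param seed integer RNG seed.
#' @return numeric vector of interaction energies (k_B T).
#' @export
interaction_energy <- function(model, model_ref, X, n_samples = 20L,
                               seed = 1L) {
  if (model$arch$input_dim != model_ref$arch$input_dim)
    stop("models have different input dimensions")
  lp <- estimate_log_prob(model, X, n_samples = n_samples, seed = seed)
  lp_ref <- estimate_log_prob(model_ref, X, n_samples = n_samples, seed = seed)
  as.numeric(lp_ref) - as.numeric(lp)
}

#' Bin values along the folding coordinate
#'
#' Per-bin mean, standard deviation and count of `values`, with bins of
#' width `bin_width` centred on integer multiples of `bin_width` (so the
#' bin centres read 0, +-0.4, +-0.8, ... at the default). Empty bins are
#' omitted.
#'
#' @param values numeric values (e.g. energies in k_B T).
#' @param coordinates folding-coordinate value per element of `values`.
#' @param bin_width coordinate bin width.
#' @return data frame of class `energy_profile` with columns `bin_center`,
#'   `mean`, `sd`, `n`.
#' @export
profile_along_coordinate <- function(values, coordinates, bin_width = 0.4) {
  stopifnot(length(values) == length(coordinates), bin_width > 0)
  k <- round(coordinates / bin_width)
  sp <- split(values, k)
  centers <- as.numeric(names(sp)) * bin_width
  out <- data.frame(
    bin_center = centers,
    mean = vapply(sp, mean, numeric(1)),
    sd = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) else 0,
                numeric(1)),
    n = lengths(sp))
  out <- out[order(out$bin_center), ]
  rownames(out) <- NULL
  class(out) <- c("energy_profile", "data.frame")
  out
}

#' Mixing entropy of a contact-probability vector
#'
#' `S = sum_ij [ Q_ij log Q_ij + (1 - Q_ij) log(1 - Q_ij) ]` with the
#' convention `0 log 0 = 0`; counts (in nats) the configurational
#' multiplicity of contact patterns consistent with the given mean contact
#' probabilities, e.g. of all structures at one folding-coordinate value.
#' Always non-positive.
#'
#' @param mean_contact_probs probabilities in `[0, 1]` (vector or matrix).
#' @return entropy in nats.
#' @export
mixing_entropy <- function(mean_contact_probs) {
  p <- as.numeric(mean_contact_probs)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("contact probabilities must lie in [0, 1]")
  xlogx <- function(x) ifelse(x == 0, 0, x * log(x))
  sum(xlogx(p) + xlogx(1 - p))
}

#' Free energy and population along the folding coordinate
#'
#' Combines the per-bin mean structure free energy with the per-bin mixing
#' entropy: `F(q) = <F>_q - T S(q)`, then converts to a normalized
#' Boltzmann population `P(q) = exp(-F(q)) / sum exp(-F(q))` over the bins.
#'
#' @param mean_f an [profile_along_coordinate()] data frame of mean
#'   negative-log-probability values per bin.
#' @param mixing_s numeric vector of mixing entropies (nats), one per bin of
#'   `mean_f`, in the same bin order.
#' @param temperature temperature in reduced units.
#' @return data frame with columns `bin_center`, `free_energy`, `prob`.
#' @export
coordinate_free_energy <- function(mean_f, mixing_s, temperature = 1) {
  stopifnot(inherits(mean_f, "data.frame"),
            all(c("bin_center", "mean") %in% names(mean_f)))
  if (length(mixing_s) != nrow(mean_f))
    stop("mixing entropies (", length(mixing_s),
         ") do not align with the ", nrow(mean_f), " coordinate bins")
  f <- mean_f$mean - temperature * mixing_s
  p <- exp(-(f - min(f)) / temperature)
  data.frame(bin_center = mean_f$bin_center, free_energy = f,
             prob = p / sum(p))
}

#' Relative entropy profile of the reference polymer
#'
#' Bins reference-model log probabilities along the folding coordinate and
#' reports each bin's mean relative to the lowest occupied coordinate bin.
#' Because the reference homopolymer's interaction energy barely varies
#' with the degree of folding, this difference approximates the
#' conformational-entropy change along the coordinate.
#'
#' @param log_probs_ref reference-model log probabilities (nats) per
#'   structure.
#' @param coordinates folding coordinate per structure.
#' @param bin_width coordinate bin width.
#' @return an `energy_profile` data frame whose `mean` column is the entropy
#'   change relative to the first occupied bin.
#' @export
reference_entropy_profile <- function(log_probs_ref, coordinates,
                                      bin_width = 0.4) {
  pr <- profile_along_coordinate(log_probs_ref, coordinates, bin_width)
  pr$mean <- pr$mean - pr$mean[1]
  pr
}

#' Write an energy profile as TSV
#'
#' @param profile an `energy_profile` data frame.
#' @param path output file path.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
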