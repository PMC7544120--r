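#' Parameters of the coarse-grained polymer models
#'
#' Constructs the full parameter set of the bead-spring polymer used to
#' validate the generative-model energetics. Two variants share these
#' parameters: a *reference* homopolymer whose non-bonded beads interact only
#' through a capped soft-core repulsion and a weak collapse attraction, and a
#' *chromatin-like* polymer that adds a stronger attraction between beads
#' lying in the same half of the chain, producing two TAD-like domains.
#' All quantities are in reduced units (length sigma, energy epsilon,
#' time tau).
#'
#' @param n_beads number of beads in the chain.
#' @param bond_k harmonic bond constant (epsilon/sigma^2); the bond energy is
#'   `k * (r - r0)^2`.
#' @param bond_r0 equilibrium bond length (sigma).
#' @param softcore_cap finite energy cost (epsilon) of fully overlapping
#'   non-bonded beads; the purely repulsive truncated-shifted Lennard-Jones
#'   potential (diameter `lj_diameter`, well depth `lj_eps`, cut at its
#'   minimum) is saturated to this cap via `U = cap * tanh(U_LJ / cap)`,
#'   which keeps the potential and forces continuous everywhere, makes
#'   overlap cost finite, and so allows chain crossing.
#' @param lj_diameter,lj_eps diameter (sigma) and well depth (epsilon) of
#'   the underlying Lennard-Jones repulsion. The default diameter of 1 sigma
#'   with bonds resting at 2 sigma lets the collapsed chain pack densely
#'   enough to form clear attraction domains while keeping the
#'   adjacent-bead contact probability at the ~0.8 calibration value.
#' @param collapse_alpha depth (epsilon) of the weak collapse attraction
#'   applied to every non-bonded pair; negative is attractive.
#' @param collapse_eta steepness (1/sigma) of the tanh switching function.
#' @param collapse_rc midpoint (sigma) of the tanh switching function.
#' @param specific_alpha depth (epsilon) of the additional same-half
#'   attraction of the chromatin-like model.
#' @param domain_split 0-based bead index at which the second half starts
#'   (default half the chain, i.e. 14 for 28 beads); beads `0..split-1` form
#'   the first domain, `split..n-1` the second.
#' @param timestep integration timestep (tau).
#' @param damping Langevin damping time (tau); the friction coefficient is
#'   its reciprocal.
#' @param temperature thermostat temperature (energy units, k_B = 1).
#' @param contact_cutoff distance (sigma) below which two beads are counted
#'   as being in contact.
#'
#' @return an object of class `polymer_params`.
#' @export
polymer_params <- function(n_beads = 28L,
                           bond_k = 1.0, bond_r0 = 2.0,
                           softcore_cap = 4.0,
                           lj_diameter = 1.0, lj_eps = 1.0,
                           collapse_alpha = -0.04, collapse_eta = 10.0,
                           collapse_rc = 3.0,
                           specific_alpha = -0.1,
                           domain_split = n_beads %/% 2L,
                           timestep = 0.01, damping = 0.5, temperature = 1.0,
                           contact_cutoff = 3.0) {
  n_beads <- as.integer(n_beads)
  domain_split <- as.integer(domain_split)
  stopifnot(n_beads >= 2L, timestep > 0, collapse_rc > 0,
            domain_split >= 0L, domain_split <= n_beads,
            damping > 0, temperature >= 0, contact_cutoff > 0)
  structure(list(
    n_beads = n_beads, bond_k = bond_k, bond_r0 = bond_r0,
    softcore_cap = softcore_cap, lj_diameter = lj_diameter, lj_eps = lj_eps,
    collapse_alpha = collapse_alpha, collapse_eta = collapse_eta,
    collapse_rc = collapse_rc, specific_alpha = specific_alpha,
    domain_split = domain_split, timestep = timestep, damping = damping,
    temperature = temperature, contact_cutoff = contact_cutoff
  ), class = "polymer_params")
}

check_conformation <- function(conf, params = NULL) {
  if (!is.matrix(conf) || ncol(conf) != 3L)
    stop("a conformation must be an n x 3 coordinate matrix")
  if (nrow(conf) < 2L) stop("a conformation needs at least 2 beads")
  if (!all(is.finite(conf))) stop("conformation contains non-finite coordinates")
  if (!is.null(params) && nrow(conf) != params$n_beads)
    stop("conformation has ", nrow(conf), " beads but params declare ",
         params$n_beads)
  invisible(conf)
}

bond_lengths <- function(conf) {
  d <- diff(conf)
  sqrt(rowSums(d^2))
}

pair_distance_matrix <- function(conf) {
  as.matrix(stats::dist(conf))
}

# distances of non-bonded pairs |i-j| >= 2, plus their index offsets
nonbonded_pairs <- function(conf) {
  n <- nrow(conf)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] >= 2L, , drop = FALSE]
  d <- pair_distance_matrix(conf)
  list(i = idx[, 1], j = idx[, 2], r = d[idx])
}

#' Harmonic bond energy of a conformation
#'
#' Sum over consecutive beads of `k * (r - r0)^2`.
#'
#' @param conf n x 3 coordinate matrix (sigma units).
#' @param params a [polymer_params()] object.
#' @return bond energy in epsilon.
#' @export
bonded_energy <- function(conf, params = polymer_params(n_beads = nrow(conf))) {
  check_conformation(conf)
  r <- bond_lengths(conf)
  sum(params$bond_k * (r - params$bond_r0)^2)
}

softcore_pair_energy <- function(r, params) {
  rcut <- 2^(1 / 6) * params$lj_diameter
  u <- numeric(length(r))
  inside <- r < rcut
  if (any(inside)) {
    s6 <- (params$lj_diameter / r[inside])^6
    ulj <- 4 * params$lj_eps * (s6^2 - s6) + params$lj_eps
    ulj[r[inside] == 0] <- Inf
    cap <- params$softcore_cap
    u[inside] <- cap * tanh(ulj / cap)
  }
  u
}

#' Soft-core repulsion energy
#'
#' Capped, purely repulsive excluded-volume energy summed over all non-bonded
#' pairs (`|i - j| >= 2`). Finite even for exactly superposed beads, where
#' each overlapping pair contributes `softcore_cap`.
#'
#' @inheritParams bonded_energy
#' @return soft-core energy in epsilon (non-negative).
#' @export
softcore_energy <- function(conf, params = polymer_params(n_beads = nrow(conf))) {
  check_conformation(conf)
  nb <- nonbonded_pairs(conf)
  sum(softcore_pair_energy(nb$r, params))
}

collapse_pair_energy <- function(r, alpha, params) {
  alpha / 2 * (1 + tanh(params$collapse_eta * (params$collapse_rc - r)))
}

#' Collapse attraction energy
#'
#' Tanh-switched pair attraction `alpha/2 * (1 + tanh(eta * (rc - r)))`
#' summed over all non-bonded pairs (`|i - j| >= 2`).
#'
#' @inheritParams bonded_energy
#' @param alpha attraction depth in epsilon (defaults to
#'   `params$collapse_alpha`).
#' @return collapse energy in epsilon.
#' @export
collapse_energy <- function(conf, params = polymer_params(n_beads = nrow(conf)),
                            alpha = params$collapse_alpha) {
  check_conformation(conf)
  nb <- nonbonded_pairs(conf)
  sum(collapse_pair_energy(nb$r, alpha, params))
}

#' Specific same-domain interaction energy
#'
#' The extra attraction of the chromatin-like model: the tanh pair attraction
#' with depth `specific_alpha`, restricted to non-bonded pairs whose beads
#' both lie in the first half (`0..split-1`) or both in the second half
#' (`split..n-1`) of the chain. This is also the ground-truth interaction
#' energy difference between the chromatin-like and the reference model for
#' a given conformation, against which the generative-model estimate is
#' validated.
#'
#' @inheritParams bonded_energy
#' @return specific interaction energy in epsilon (non-positive for
#'   attractive `specific_alpha`).
#' @export
specific_energy_delta <- function(conf,
                                  params = polymer_params(n_beads = nrow(conf))) {
  check_conformation(conf)
  nb <- nonbonded_pairs(conf)
  s <- params$domain_split           # 0-based; beads are rows 1..n
  same <- (nb$i <= s & nb$j <= s) | (nb$i > s & nb$j > s)
  sum(collapse_pair_energy(nb$r[same], params$specific_alpha, params))
}

#' Full potential-energy decomposition of a conformation
#'
#' @inheritParams bonded_energy
#' @param chromatin_like if `TRUE`, includes the specific same-half
#'   attraction; otherwise the specific term is zero (reference model).
#' @return a list of class `energy_decomposition` with components `bonded`,
#'   `softcore`, `collapse`, `specific` and `total` (all in epsilon).
#' @export
total_energy <- function(conf, params = polymer_params(n_beads = nrow(conf)),
                         chromatin_like = FALSE) {
  b <- bonded_energy(conf, params)
  sc <- softcore_energy(conf, params)
  cl <- collapse_energy(conf, params)
  sp <- if (chromatin_like) specific_energy_delta(conf, params) else 0.0
  structure(list(bonded = b, softcore = sc, collapse = cl, specific = sp,
                 total = b + sc + cl + sp),
            class = "energy_decomposition")
}

#' Run Langevin dynamics of a polymer model
#'
#' Underdamped Langevin dynamics (BAOAB splitting, unit bead mass, friction
#' `1/damping`) starting from a straight chain at the equilibrium bond length
#' with small Gaussian jitter. Equilibration steps are discarded; production
#' frames are saved every `save_every` steps. Trajectories are exactly
#' reproducible for a given seed.
#'
#' @param params a [polymer_params()] object.
#' @param n_steps number of production steps.
#' @param save_every save one frame per this many steps.
#' @param seed integer RNG seed.
#' @param chromatin_like simulate the chromatin-like model (extra same-half
#'   attraction) rather than the reference homopolymer.
#' @param equil_steps discarded equilibration steps.
#' @param jitter_sd standard deviation (sigma) of the initial coordinate
#'   jitter.
#' @return list of n x 3 conformation matrices with a numeric attribute
#'   `kinetic` holding the total kinetic energy of each saved frame.
#' @export
run_langevin <- function(params, n_steps, save_every = 500L, seed = 1L,
                         chromatin_like = FALSE, equil_steps = 100000L,
                         jitter_sd = 0.1) {
  stopifnot(n_steps >= save_every, save_every >= 1L, equil_steps >= 0L)
  set.seed(seed)
  n <- params$n_beads
  coords0 <- cbind((seq_len(n) - 1) * params$bond_r0, 0, 0) +
    matrix(stats::rnorm(n * 3L, sd = jitter_sd), n, 3L)
  res <- cpp_langevin(coords0, unclass(params), as.integer(n_steps),
                      as.integer(save_every), as.integer(equil_steps),
                      chromatin_like)
  frames <- res$frames
  attr(frames, "kinetic") <- res$kinetic
  frames
}

#' Contact matrix of a conformation
#'
#' @param conf n x 3 coordinate matrix.
#' @param cutoff contact distance cutoff (same units as `conf`); a pair at
#'   exactly the cutoff counts as a contact.
#' @return symmetric binary n x n matrix with unit diagonal, of class
#'   `contact_matrix`.
#' @export
contacts_from_conformation <- function(conf, cutoff = 3.0) {
  check_conformation(conf)
  stopifnot(cutoff > 0)
  d <- pair_distance_matrix(conf)
  q <- (d <= cutoff) * 1L
  diag(q) <- 1L
  new_contact_matrix(q)
}

#' Write a trajectory as plain-text XYZ-style frames
#'
#' Each frame is a block `bead_index x y z` (sigma units) preceded by a
#' `# frame k` comment line.
#'
#' @param frames list of conformations as returned by [run_langevin()].
#' @param path output file path.
#' @export
write_trajectory <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    writeLines(sprintf("# frame %d", k), con)
    f <- frames[[k]]
    writeLines(sprintf("%d %.8g %.8g %.8g", seq_len(nrow(f)) - 1L,
                       f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}
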