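---
title: "Chromatin folding coordinates and free-energy landscapes from single-cell contact matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin folding coordinates and free-energy landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Multiplexed chromatin tracing images the 3D positions of consecutive genomic
segments in thousands of individual cells. Population-averaged distance maps
from such data show topologically associating domains (TADs) in wild-type
cells and their disappearance after cohesin depletion — yet domain-like
structures persist in many *individual* cohesin-depleted cells. Making sense
of that heterogeneity needs two things: a low-dimensional *folding
coordinate* that orders single-cell structures by their degree of TAD
formation, and a way to ask whether folded configurations are
*energetically* favoured even when they are rare.

`tadfold` implements both. Single-cell traces are converted to binary
contact matrices; a variational autoencoder (VAE) learns a generative model
of those matrices; a linear separator in the two-dimensional latent space
defines the folding coordinate; and the VAE's probability estimates are
turned into an energy decomposition by subtracting a reference-polymer
model. Every stage can be validated end to end against coarse-grained
polymer simulations bundled with the package, so no external data are
required.

## Polymer models

The in-silico validation system is a 28-bead bead-spring chain (one bead
per 90 kb of a 2.5 Mb region), simulated in reduced units (length
$\sigma$, energy $\epsilon$, time $\tau$) by underdamped Langevin dynamics.
The reference homopolymer has the potential

$$U_\mathrm{ref} = \sum_{i} k\,(r_{i,i+1} - r_0)^2
 + \sum_{|i-j|\ge 2} U_\mathrm{sc}(r_{ij})
 + \sum_{|i-j|\ge 2} \frac{\alpha}{2}\bigl[1 + \tanh(\eta\,(r_c - r_{ij}))\bigr]$$

with $k = 1\,\epsilon/\sigma^2$, $r_0 = 2\,\sigma$, $\alpha = -0.04\,
\epsilon$, $\eta = 10\,\sigma^{-1}$ and $r_c = 3\,\sigma$. The
*chromatin-like* variant adds the same tanh attraction with
$\alpha_\mathrm{spec} = -0.1\,\epsilon$ restricted to pairs of beads lying
in the same half of the chain, which promotes two TAD-like domains meeting
at bead 14. The per-configuration sum of that specific term,
`specific_energy_delta()`, is the ground-truth interaction energy
difference $\Delta U(Q)$ between the two models.

Two numerical choices deserve comment because only their intent, not their
form, is fixed by the physics:

* **Soft-core repulsion.** Excluded volume must be finite at overlap so
  the phantom chain can cross itself. We use a purely repulsive
  truncated-shifted Lennard-Jones potential (diameter $1\,\sigma$, well
  depth $1\,\epsilon$, cut at its minimum $2^{1/6}\sigma$) saturated as
  $U_\mathrm{sc} = U_\mathrm{cap}\tanh(U_\mathrm{LJ}/U_\mathrm{cap})$ with
  $U_\mathrm{cap} = 4\,\epsilon$. The $\tanh$ saturation keeps the
  potential *and* its force continuous everywhere and equal to zero at the
  cutoff; blends that leave a finite step at the cutoff inject a spurious
  repulsive energy proportional to the number of near-contact pairs, which
  measurably contaminates the energy validation below. The diameter is
  deliberately smaller than the $2\,\sigma$ bond rest length: with an
  excluded-volume diameter as large as a bond, the chain cannot pack
  densely enough for the weak $-0.1\,\epsilon$ same-half attraction to
  produce visible domains. At $1\,\sigma$ the collapsed chain forms a clear
  two-domain structure and the adjacent-bead contact probability of the
  reference ensemble lands at $\approx 0.80$ with the $3\,\sigma$ contact
  cutoff — the calibration value that matches the neighbouring-segment
  contact frequency of 90 kb imaging data binarized at 450 nm.
* **Integrator.** BAOAB splitting of underdamped Langevin dynamics with
  unit bead mass, timestep $0.01\,\tau$, friction $1/\gamma$ with damping
  time $\gamma = 0.5\,\tau$, and thermostat temperature $T = 1$. All
  randomness (initial jitter, initial velocities, thermostat noise) is
  drawn from R's seeded RNG, so trajectories are bitwise reproducible.

Desk-scale production runs are $5\times10^5$ steps thinned to 2000 frames
after $10^5$ discarded equilibration steps; at $10^4$ discarded steps the
chromatin-like chain's radius of gyration still drifts visibly across the
production run. Full-scale settings ($5\times10^7$ steps, $10^5$ frames)
remain configurable but are not the test conditions.

## From traces to contact vectors

The imaging-side pipeline mirrors how real trace tables are processed:
optional coarsening (every third 30 kb probe giving 90 kb bins), Euclidean
distance matrices with entries involving missing probes undefined,
binarization at 450 nm (ties count as contacts), and imputation of the
undefined entries by Bernoulli draws from the *separation profile* — the
dataset-wide mean contact probability at each genomic separation.
Imputation never alters observed entries, is mirrored for symmetry, and
flags what it filled in. The profile pools both cell types by default
(per-label profiles are available); the choice matters little because
missingness is independent of cell type in the generator. Complete
matrices are vectorized as the strict upper triangle in row-major order
(378 features for 28 bins).

The synthetic-data generator maps simulated conformations to imaging-like
traces at 150 nm/$\sigma$, so the $3\,\sigma$ simulation cutoff and the
450 nm imaging cutoff coincide. Defaults: isotropic Gaussian localization
noise of 30 nm per axis (typical super-resolution localization precision),
10% of probes missing completely at random, and a depleted-like population
drawn as an 85/15 mixture of reference and chromatin-like frames —
emulating the observation that a substantial minority of cohesin-depleted
cells retains TAD-like structures. The generator does *not* emulate
optical point-spread functions, chromatic offsets, locus-dependent
detection efficiency, or any missingness mechanism correlated with
structure; passing tests therefore demonstrate the pipeline's internal
consistency, not robustness to those real-data artifacts.

## The variational autoencoder

The VAE has one hidden layer of 200 rectified-linear units on each side,
a diagonal-Gaussian encoder, a standard-normal prior, and an independent
Bernoulli decoder with logistic outputs. Training maximizes the evidence
lower bound (ELBO)

$$\log P_\mathrm{VAE}(Q) \;\ge\;
 \mathbb{E}_{q(z|Q)}[\log p(Q|z)] - D_\mathrm{KL}[q(z|Q)\,\|\,p(z)]$$

by Adam (learning rate 0.001, batch size 500) with the reparameterization
trick; the KL term is evaluated in closed form. The implementation is
plain R matrix code with hand-written gradients — the model is small
enough that a deep-learning framework would add nothing but a dependency.
Log-probability estimates use 20 posterior samples by default. Two model
roles are kept strictly separate, as the analysis requires: a 2-latent
model defines the folding coordinate, and 25-latent models (one per
condition or ensemble) provide all probability and energy estimates.

Training epochs scale with data size. At the full data scale of the
original analyses ($10^5$ configurations) 1000 epochs are appropriate; at
the desk scale used in the tests (2000 frames per ensemble) we train the
25-latent probability models for 100 epochs. The choice balances two
failure modes that we measured explicitly: under-training leaves the
density estimates too blunt for the energy validation, while heavy
over-training makes each model memorize its own ensemble, which inflates
the variance of the log-probability *difference* between models and
degrades both the correlation with the ground-truth energy and the slope
of its linear fit. Hidden-layer width, nonlinearity and fan-in-scaled
Gaussian weight initialization are fixed choices; training is
deterministic given the seed.

## Folding coordinate

The two cell populations are embedded by the pooled 2-latent model's
posterior means, and a soft-margin linear SVM (cost 1) fitted to the
labelled embeddings defines the decision boundary. The folding coordinate
of any structure is its signed distance from that boundary, oriented so
the WT population has positive mean. Separation is quantified by a
histogram KL divergence (50 shared equal-width bins over the pooled range,
one pseudo-count per bin, reported in nats); first-principal-component
projection and k-means cluster overlap (summed per-cluster minority mass)
provide the standard baselines. Downstream profiles bin the coordinate at
width 0.4, centred on multiples of 0.4.

## Energetics

Writing $F(Q) = -\log P(Q)$ (units of $k_BT$, $T = 1$), the free energy of
a contact pattern splits into an interaction energy and a chain entropy,
$F = U - TS$. For two polymers of equal length and similar generic
properties the entropy functional cancels in differences, so

$$-\log\frac{P_\mathrm{VAE}(Q)}{P^\mathrm{ref}_\mathrm{VAE}(Q)}
 \;\approx\; U(Q) - U_\mathrm{ref}(Q) \;=\; \Delta U(Q).$$

`interaction_energy()` implements exactly this difference, sharing the
latent noise between the two estimates (common random numbers), so a model
differenced against itself gives exactly zero and the Monte-Carlo variance
of the ratio is small. The in-silico validation correlates this estimate
with the brute-force $\Delta U$ over chromatin-like frames; without the
reference subtraction the raw $-\log P_\mathrm{VAE}$ correlates only
weakly (and negatively) with the full potential energy, because the
conformational entropy dominates — that contrast is reproduced by the
acceptance tests.

Along the folding coordinate, the mean structure free energy per bin is
corrected by the mixing entropy
$S(q) = \sum_{ij} Q_{ij}\log Q_{ij} + (1-Q_{ij})\log(1-Q_{ij})$
(computed from per-bin mean contact probabilities, $0\log 0 \equiv 0$)
before converting to a Boltzmann population $P(q) \propto e^{-F(q)}$. The
reference model's binned log-probabilities, referenced to the lowest
occupied bin, approximate the entropy change along the coordinate.

## Structure statistics

Boundary scores follow the insulation-ratio definition: for each candidate
boundary, $d_\mathrm{inter}$ is the mean distance between the two flanking
180 kb windows (2 bins at 90 kb) and $d_\mathrm{intra}$ the smaller of the
two within-window means; their ratio peaks at domain boundaries. The
within-window mean uses distinct-locus pairs only. A "window" reading that
straddles the locus would be nearly degenerate at 90 kb resolution, which
is why the cross-window interpretation is used. TAD-contact fractions
exclude pairs closer than 2 bins, since adjacent contacts occur with
probability ~0.8 regardless of folding. Ensemble checks compare first
contact moments $\langle Q_i\rangle$ and pairwise moments
$\langle Q_iQ_j\rangle$ of generated versus training ensembles, with
$\langle Q_i\rangle\langle Q_j\rangle$ as the independence baseline.

## Orchestration and reproducibility

`validate_config()`/`run_pipeline()` run the stages
simulate → synth → preprocess → train → coordinate → energetics → stats
from one YAML file with a single global seed fanned out deterministically
to per-stage seeds (`seed * 131 + 17 * stage_index mod 2^31-1`), writing
TSV/JSON artifacts and a hash manifest; reruns reproduce identical hashes.
The package's functions are the primary interface; the pipeline runner is
a thin layer over them.

## Known limitations

* The desk-scale ensembles (2000 frames from $5\times10^5$ steps) carry
  substantial autocorrelation; correlation-based validation numbers
  fluctuate noticeably with the simulation seed, and approach the
  full-scale values only as sampling grows.
* The ELBO is a lower bound, not the likelihood; its looseness varies
  across structures, which systematically steepens the fitted slope of
  VAE energies against ground truth (observed slope > 1).
* The reference-subtraction argument assumes the two ensembles share
  generic polymer properties; it degrades if the compared systems differ
  in persistence length or excluded volume.
* Effective free energies for real nuclei are interpretive devices: living
  chromatin is driven and non-equilibrium, and the generator does not
  attempt to model active processes.
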