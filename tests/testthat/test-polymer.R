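test_that("bonded energy follows the k*(r-r0)^2 convention", {
  p2 <- polymer_params(n_beads = 2)
  expect_equal(bonded_energy(rbind(c(0, 0, 0), c(2, 0, 0)), p2), 0)
  expect_equal(bonded_energy(rbind(c(0, 0, 0), c(3, 0, 0)), p2), 1.0)
  # straight 28-bead chain at 2.5 sigma spacing: 27 bonds x 0.25
  conf <- straight_chain(28, 2.5)
  expect_equal(bonded_energy(conf, polymer_params()), 6.75)
  expect_error(bonded_energy(matrix(0, 1, 3)), "at least 2 beads")
})

test_that("energy terms match brute-force pair-loop oracles", {
  p <- polymer_params(n_beads = 10)
  for (seed in 1:5) {
    conf <- random_conformation(10, spread = 3, seed = seed)
    expect_equal(bonded_energy(conf, p),
                 oracle_bonded(conf, p$bond_k, p$bond_r0), tolerance = 1e-9)
    expect_equal(softcore_energy(conf, p),
                 oracle_softcore(conf, p$lj_diameter, p$lj_eps, p$softcore_cap),
                 tolerance = 1e-9)
    expect_equal(collapse_energy(conf, p),
                 oracle_collapse(conf, p$collapse_alpha, p$collapse_eta,
                                 p$collapse_rc), tolerance = 1e-9)
    expect_equal(specific_energy_delta(conf, p),
                 oracle_collapse(conf, p$specific_alpha, p$collapse_eta,
                                 p$collapse_rc, same_half_only = TRUE,
                                 split = p$domain_split), tolerance = 1e-9)
  }
  p28 <- polymer_params()
  conf <- random_conformation(28, spread = 5, seed = 42)
  expect_equal(collapse_energy(conf, p28),
               oracle_collapse(conf, -0.04, 10, 3), tolerance = 1e-9)
  expect_equal(specific_energy_delta(conf, p28),
               oracle_collapse(conf, -0.1, 10, 3, TRUE, 14), tolerance = 1e-9)
})

test_that("soft-core repulsion is capped, finite, and zero beyond its cutoff", {
  p <- polymer_params(n_beads = 4)
  far <- straight_chain(4, 5)           # all non-bonded pairs way out of range
  expect_equal(softcore_energy(far, p), 0)
  # two non-bonded beads exactly superposed: one pair at the cap
  conf <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 0, 0), c(20, 0, 0))
  expect_equal(softcore_energy(conf, p), p$softcore_cap)
  expect_true(is.finite(softcore_energy(conf, p)))
  # one pair exactly at the LJ diameter: U_LJ = lj_eps, saturated by tanh
  conf2 <- rbind(c(0, 0, 0), c(10, 0, 0), c(1, 0, 0), c(20, 0, 0))
  expect_equal(softcore_energy(conf2, p), 4 * tanh(1 / 4), tolerance = 1e-12)
})

test_that("collapse attraction has the tanh switch values", {
  p <- polymer_params(n_beads = 3)
  # the only non-bonded pair (1,3) at exactly r_c: alpha/2 since tanh(0) = 0
  conf <- rbind(c(0, 0, 0), c(10, 10, 10), c(3, 0, 0))
  expect_equal(collapse_energy(conf, p, alpha = -0.04), -0.02)
  conf_far <- rbind(c(0, 0, 0), c(50, 50, 50), c(100, 0, 0))
  expect_lt(abs(collapse_energy(conf_far, p)), 1e-8)
})

test_that("specific energy is restricted to same-half pairs", {
  p <- polymer_params(n_beads = 6, domain_split = 3L)
  # all same-half pairs far apart: zero
  far <- straight_chain(6, 50)
  expect_equal(specific_energy_delta(far, p), 0, tolerance = 1e-10)
  # beads 1 and 3 (both in first half, |i-j|=2) at exactly r_c
  conf <- rbind(c(0, 0, 0), c(100, 0, 0), c(3, 0, 0),
                c(200, 0, 0), c(300, 0, 0), c(400, 0, 0))
  expect_equal(specific_energy_delta(conf, p), -0.05)
  # a cross-half pair at r_c contributes nothing
  conf2 <- rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0),
                 c(3, 0, 0), c(300, 0, 0), c(400, 0, 0))
  expect_equal(specific_energy_delta(conf2, p), 0, tolerance = 1e-10)
})

test_that("total energy decomposes consistently", {
  p <- polymer_params()
  conf <- random_conformation(28, spread = 5, seed = 7)
  e_ref <- total_energy(conf, p, chromatin_like = FALSE)
  expect_equal(e_ref$specific, 0)
  expect_equal(e_ref$total, e_ref$bonded + e_ref$softcore + e_ref$collapse,
               tolerance = 1e-12)
  e_chr <- total_energy(conf, p, chromatin_like = TRUE)
  expect_equal(e_chr$total - e_ref$total, specific_energy_delta(conf, p),
               tolerance = 1e-9)
  # toy 4-bead square, hand-checkable: bonds at 2.0 are relaxed; non-bonded
  # pairs are the two diagonals at 2*sqrt(2) plus the (1,4) side at 2.0,
  # all beyond the 2^(1/6) sigma repulsive cutoff
  sq <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0))
  p4 <- polymer_params(n_beads = 4, domain_split = 2L)
  r_diag <- 2 * sqrt(2)
  e <- total_energy(sq, p4)
  expect_equal(e$bonded, 0)
  expect_equal(e$collapse,
               2 * (-0.02) * (1 + tanh(10 * (3 - r_diag))) +
                 (-0.02) * (1 + tanh(10 * (3 - 2))),
               tolerance = 1e-12)
  expect_equal(e$softcore, 0)
  # with a 2|2 split no same-half pair has |i-j| >= 2
  expect_equal(total_energy(sq, p4, TRUE)$specific, 0)
})

test_that("zero-temperature bonded-only dynamics relaxes bonds to r0", {
  p <- polymer_params(n_beads = 8, temperature = 0, collapse_alpha = 0,
                      specific_alpha = 0)
  frames <- run_langevin(p, n_steps = 30000, save_every = 30000, seed = 4,
                         equil_steps = 0, jitter_sd = 0.3)
  bl <- sqrt(rowSums(diff(frames[[1]])^2))
  expect_true(all(abs(bl - 2.0) < 1e-3))
})

test_that("langevin trajectories are reproducible and thermostated", {
  p <- polymer_params()
  a <- run_langevin(p, 5000, save_every = 500, seed = 99)
  b <- run_langevin(p, 5000, save_every = 500, seed = 99)
  expect_identical(a, b)
  cc <- run_langevin(p, 5000, save_every = 500, seed = 100)
  expect_false(identical(a, cc))
})

test_that("contact conversion uses an inclusive distance cutoff", {
  near <- rbind(c(0, 0, 0), c(2.9, 0, 0))
  expect_equal(contacts_from_conformation(near, 3.0)[1, 2], 1L)
  far <- rbind(c(0, 0, 0), c(3.1, 0, 0))
  expect_equal(contacts_from_conformation(far, 3.0)[1, 2], 0L)
  tie <- rbind(c(0, 0, 0), c(3.0, 0, 0))
  expect_equal(contacts_from_conformation(tie, 3.0)[1, 2], 1L)
  # straight chain at 2 sigma spacing: contacts exactly at |i-j| <= 1
  q <- contacts_from_conformation(straight_chain(10, 2.0), 3.0)
  sep <- abs(row(q) - col(q))
  expect_true(all(q[sep <= 1] == 1))
  expect_true(all(q[sep > 1] == 0))
  expect_true(isSymmetric(unclass(unname(q))))
})

test_that("the chromatin-like ensemble forms more within-half contacts than
           the reference ensemble", {
  fx <- fixture_ensembles()
  within_half <- function(frames, split) {
    vapply(frames, function(f) {
      q <- contacts_from_conformation(f)
      same <- (row(q) <= split & col(q) <= split) |
        (row(q) > split & col(q) > split)
      keep <- upper.tri(q) & abs(row(q) - col(q)) >= 2
      sum(q[keep & same])
    }, numeric(1))
  }
  s <- fx$params$domain_split
  wt <- t.test(within_half(fx$chrom, s), within_half(fx$ref, s),
               alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})
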