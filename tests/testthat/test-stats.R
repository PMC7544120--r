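two_block_map <- function(n = 10, split = 5, within = 100, across = 300) {
  m <- matrix(across, n, n)
  m[1:split, 1:split] <- within
  m[(split + 1):n, (split + 1):n] <- within
  diag(m) <- 0
  m
}

test_that("mean distance maps average only defined entries", {
  tr <- toy_trace(5, seed = 1)
  expect_equal(mean_distance_map(list(tr)), distance_matrix(tr))
  t1 <- tadfold:::new_cell_trace("a", rbind(c(0, 0, 0), c(100, 0, 0)))
  t2 <- tadfold:::new_cell_trace("b", rbind(c(0, 0, 0), c(300, 0, 0)))
  expect_equal(mean_distance_map(list(t1, t2))[1, 2], 200)
  # a cell with a missing probe contributes nothing to that entry
  t3 <- tadfold:::new_cell_trace("c", rbind(c(NA, NA, NA), c(0, 0, 0)))
  expect_equal(mean_distance_map(list(t1, t2, t3))[1, 2], 200)
  expect_error(mean_distance_map(list()), "no cells")
})

test_that("boundary score is 1 on uniform maps and d_inter/d_intra on blocks", {
  u <- matrix(250, 12, 12); diag(u) <- 0
  # treat the map as spatial distances between distinct loci (off-diagonal
  # uniform); windows never include the diagonal
  prof <- boundary_score_profile(u, window_bins = 2)
  expect_true(all(abs(prof[!is.na(prof)] - 1) < 1e-12))
  expect_true(all(is.na(prof[c(1, 2, 12)])))
  bm <- two_block_map(10, split = 5)
  profb <- boundary_score_profile(bm, window_bins = 2)
  expect_equal(profb[6], 3.0)            # boundary just before bin 6
  expect_equal(which.max(profb), 6)
})

test_that("boundary detection finds peaks and respects separation", {
  flat <- structure(c(NA, NA, rep(1, 8), NA), class = "boundary_profile")
  expect_length(detect_boundaries(flat), 0)
  spike <- structure(c(NA, 1, 1, 2.5, 1, 1, NA), class = "boundary_profile")
  expect_equal(as.integer(detect_boundaries(spike)), 4L)
  profb <- boundary_score_profile(two_block_map(10, 5), window_bins = 2)
  expect_equal(as.integer(detect_boundaries(profb, min_score = 1.2)), 6L)
  # two nearby peaks: only the higher survives a wide separation constraint
  twin <- structure(c(NA, 2.0, 1.0, 2.6, 1.0, 1.0, NA),
                    class = "boundary_profile")
  expect_equal(as.integer(detect_boundaries(twin, min_separation_bins = 4)), 4L)
  expect_equal(as.integer(detect_boundaries(twin, min_separation_bins = 2)),
               c(2L, 4L))
})

test_that("TAD contact fraction counts same-domain contacts", {
  n <- 8
  q <- matrix(0L, n, n); diag(q) <- 1L
  put <- function(q, i, j) { q[i, j] <- q[j, i] <- 1L; q }
  # contacts only inside the two domains [1..4], [5..8]
  q1 <- put(put(put(q, 1, 3), 2, 4), 5, 7)
  expect_equal(tad_contact_fraction(q1, 5L), 1.0)
  # 3 within + 1 across
  q2 <- put(q1, 3, 6)
  expect_equal(tad_contact_fraction(q2, 5L), 0.75)
  q3 <- put(put(q, 3, 6), 4, 7)
  expect_equal(tad_contact_fraction(q3, 5L), 0.0)
  # an adjacent cross-domain pair is ignored by the separation filter
  expect_equal(tad_contact_fraction(put(q1, 4, 5), 5L), 1.0)
  # counting adjacent pairs too brings it back into the ratio
  expect_equal(tad_contact_fraction(put(q1, 4, 5), 5L, min_separation = 1L),
               0.75)
  expect_true(is.na(tad_contact_fraction(q, 5L)))
})

test_that("contact moments match brute force and detect independence", {
  qs <- lapply(1:3, function(k) {
    set.seed(k)
    m <- matrix(0L, 6, 6); m[lower.tri(m)] <- rbinom(15, 1, 0.5)
    m[upper.tri(m)] <- t(m)[upper.tri(m)]; diag(m) <- 1L
    tadfold:::new_contact_matrix(m)
  })
  mo <- contact_moments(qs, n_pairs = 1000, seed = 1)
  V <- do.call(rbind, lapply(qs, vectorize))
  expect_equal(mo$first, colMeans(V))
  for (k in seq_len(nrow(mo$pairs)))
    expect_equal(mo$second[k], mean(V[, mo$pairs[k, 1]] * V[, mo$pairs[k, 2]]))
  # identical matrices: <QiQj> = Qi * Qj exactly
  same <- contact_moments(list(qs[[1]], qs[[1]]), n_pairs = 1000, seed = 2)
  expect_equal(same$second, same$independent)
  # independent Bernoulli features: second moments track the products
  set.seed(3)
  Vind <- matrix(rbinom(3000 * 36, 1, 0.5), 3000, 36)
  moi <- contact_moments(Vind, n_pairs = 200, seed = 4)
  se <- sqrt(0.25 * 0.75 / 3000)
  expect_gte(mean(abs(moi$second - moi$independent) < 3 * se), 0.95)
})

test_that("ensemble agreement returns exact correlations", {
  x <- c(0.1, 0.4, 0.8, 0.3, 0.6)
  expect_equal(ensemble_agreement(x, x)$r, 1)
  expect_equal(ensemble_agreement(x, 1 - x)$r, -1)
  set.seed(5)
  y <- x + rnorm(5, sd = 0.01)
  expect_gt(ensemble_agreement(rep(x, 20), rep(x, 20) +
                                 rnorm(100, sd = 0.01))$r, 0.95)
  expect_error(ensemble_agreement(x[1:2], x[1:2]), "at least 3")
})

test_that("the domain boundary of simulated WT-like cells is detected at the
           split bead", {
  fs <- fixture_synth_pipeline()
  labs <- vapply(fs$cells, function(tr) tr$label, character(1))
  md <- mean_distance_map(fs$cells[labs == "WT"])
  prof <- boundary_score_profile(md, window_bins = 2)
  # split at 0-based bead 14 = boundary just before 1-based bin 15
  expect_equal(which.max(prof), 15L)
})

test_that("TAD intervals export as half-open BED records", {
  path <- tempfile(fileext = ".bed")
  write_tads_bed(structure(15L, class = "tad_annotation"), 28L,
                 "chr21", 34600000, 90000, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, c(34600000, 34600000 + 14 * 90000))
  expect_equal(bed$V3, c(34600000 + 14 * 90000, 34600000 + 28 * 90000))
})
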