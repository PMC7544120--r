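test_that("coarsening keeps every factor-th probe", {
  tr <- toy_trace(84)
  expect_equal(nrow(coarsen_trace(tr, 3)$positions), 28)
  tr10 <- toy_trace(10)
  kept <- coarsen_trace(tr10, 3)
  expect_equal(kept$positions, tr10$positions[c(1, 4, 7, 10), ])
  expect_identical(coarsen_trace(tr10, 1), tr10)
  expect_error(coarsen_trace(tr10, 11), "exceeds probe count")
})

test_that("distance matrices are Euclidean with NA at missing probes", {
  pos <- rbind(c(0, 0, 0), c(3, 4, 0))
  tr <- tadfold:::new_cell_trace("a", pos)
  expect_equal(distance_matrix(tr)[1, 2], 5)
  trm <- toy_trace(5, missing = c(2, 4))
  d <- distance_matrix(trm)
  expect_true(all(is.na(d[2, ])) && all(is.na(d[, 4])))
  # brute-force pairwise loop oracle on defined entries
  tr5 <- toy_trace(5, seed = 3)
  d5 <- distance_matrix(tr5)
  for (i in 1:5) for (j in 1:5)
    expect_equal(d5[i, j], sqrt(sum((tr5$positions[i, ] - tr5$positions[j, ])^2)))
  all_na <- tadfold:::new_cell_trace("b", matrix(NA_real_, 4, 3))
  expect_true(all(is.na(distance_matrix(all_na))))
})

test_that("binarization uses an inclusive 450 nm cutoff and is idempotent", {
  d <- matrix(c(0, 400, 500, 400, 0, 450, 500, 450, 0), 3, 3)
  q <- binarize(d, 450)
  expect_equal(q[1, 2], 1L)
  expect_equal(q[1, 3], 0L)
  expect_equal(q[2, 3], 1L)   # tie counts as contact
  # deterministic: repeated binarization of the same distances agrees
  expect_identical(binarize(d, 450), q)
  dn <- d; dn[1, 3] <- dn[3, 1] <- NA
  expect_true(is.na(binarize(dn, 450)[1, 3]))
})

test_that("separation profile averages defined entries per separation", {
  ones <- tadfold:::new_contact_matrix(matrix(1L, 4, 4))
  expect_equal(as.numeric(separation_profile(list(ones))), c(1, 1, 1))
  # half ones / half zeros at s = 2
  a <- matrix(1L, 4, 4); a[1, 3] <- a[3, 1] <- 0L
  qa <- tadfold:::new_contact_matrix(a)
  expect_equal(as.numeric(separation_profile(list(qa)))[2], 0.5)
  # brute-force check on a random matrix
  set.seed(8)
  m <- matrix(0L, 6, 6); m[upper.tri(m)] <- rbinom(15, 1, 0.5)
  m <- m + t(m); diag(m) <- 1L
  prof <- as.numeric(separation_profile(list(tadfold:::new_contact_matrix(m))))
  for (s in 1:5) {
    vals <- m[col(m) - row(m) == s]
    expect_equal(prof[s], mean(vals))
  }
})

test_that("separation profile errors when a separation is never observed", {
  m <- matrix(1L, 3, 3)
  m[1, 3] <- m[3, 1] <- NA
  expect_error(separation_profile(list(tadfold:::new_contact_matrix(m))), "2")
})

test_that("imputation fills only undefined entries at the profile rate", {
  m <- matrix(1L, 4, 4)
  q <- tadfold:::new_contact_matrix(m)
  prof <- structure(c(1, 1, 1), class = "separation_profile")
  expect_equal(unclass(unname(impute_missing(q, prof))), unclass(unname(q)))
  # undefined entry with probability-1 profile is filled with 1
  m2 <- m; m2[1, 3] <- m2[3, 1] <- NA
  q2 <- impute_missing(tadfold:::new_contact_matrix(m2), prof, seed = 2)
  expect_equal(q2[1, 3], 1L)
  expect_true(attr(q2, "imputed")[1, 3] && attr(q2, "imputed")[3, 1])
  # empirical fill rate matches the profile probability
  prof3 <- structure(c(0.9, 0.3, 0.1), class = "separation_profile")
  fills <- vapply(1:4000, function(k) {
    mk <- matrix(1L, 4, 4); mk[1, 3] <- mk[3, 1] <- NA
    impute_missing(tadfold:::new_contact_matrix(mk), prof3, seed = k)[1, 3]
  }, integer(1))
  expect_equal(mean(fills), 0.3, tolerance = 0.07)
  # defined entries never altered
  set.seed(5)
  m3 <- matrix(0L, 5, 5); m3[upper.tri(m3)] <- rbinom(10, 1, 0.5)
  m3 <- m3 + t(m3); diag(m3) <- 1L
  m3na <- m3; m3na[2, 5] <- m3na[5, 2] <- NA
  q3 <- impute_missing(tadfold:::new_contact_matrix(m3na),
                       structure(rep(0.5, 4), class = "separation_profile"))
  defined <- !is.na(m3na)
  expect_equal(unclass(q3)[defined], m3[defined])
})

test_that("vectorization is the row-major strict upper triangle", {
  m <- matrix(c(1, 1, 0, 1, 1, 1, 0, 1, 1), 3, 3)
  q <- tadfold:::new_contact_matrix(m)
  expect_equal(vectorize(q), c(1, 0, 1))
  q28 <- contacts_from_conformation(straight_chain(28, 2.0), 3.0)
  expect_length(vectorize(q28), 378)
  # round-trip
  v <- vectorize(q28)
  expect_equal(unclass(unname(unvectorize(v))), unclass(unname(q28)),
               ignore_attr = TRUE)
  mna <- m; mna[1, 2] <- mna[2, 1] <- NA
  expect_error(vectorize(tadfold:::new_contact_matrix(mna)), "undefined")
})

test_that("noise-free preprocessing reproduces simulation contacts", {
  p <- polymer_params(n_beads = 12)
  frames <- run_langevin(p, 4000, save_every = 400, seed = 17)
  cfg <- synth_config(noise_sd = 0, missing_prob = 0, n_per_type = 10, seed = 1)
  cells <- generate_dataset(frames, frames, cfg)
  wt <- Filter(function(tr) tr$label == "WT", cells)
  for (tr in wt[1:3]) {
    q_img <- binarize(distance_matrix(tr), 450)
    # identify the source frame by matching scaled coordinates
    src <- which(vapply(frames, function(f)
      isTRUE(all.equal(f * 150, tr$positions, tolerance = 1e-8)), logical(1)))
    expect_length(src, 1)
    q_sim <- contacts_from_conformation(frames[[src]], 3.0)
    expect_equal(unclass(unname(q_img)), unclass(unname(q_sim)),
                 ignore_attr = TRUE)
  }
})
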