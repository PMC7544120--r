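#' Mean distance map of a set of cells
#'
#' Entrywise mean of the per-cell distance matrices over defined
#' (non-missing) entries; an entry never observed in any cell is `NA`.
#'
#' @param cells list of `cell_trace` objects.
#' @return symmetric matrix of mean distances (nm).
#' @export
mean_distance_map <- function(cells) {
  if (length(cells) == 0) stop("no cells supplied")
  n <- nrow(cells[[1]]$positions)
  acc <- cnt <- matrix(0, n, n)
  for (tr in cells) {
    d <- distance_matrix(tr)
    ok <- !is.na(d)
    acc[ok] <- acc[ok] + d[ok]
    cnt <- cnt + ok
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Boundary-score profile of a distance map
#'
#' For each bin `i`, compares the chain upstream window `U = [i-w, i)` and
#' downstream window `D = [i, i+w)` (so the candidate boundary lies just
#' before bin `i`): `d_inter` is the mean distance over all U x D pairs and
#' `d_intra = min(mean within-U distance, mean within-D distance)`. The
#' score `d_inter / d_intra` peaks where two spatially segregated domains
#' meet. `NA` where a full window does not fit. At 90 kb bins, the default
#' `window_bins = 2` spans 180 kb windows.
#'
#' @param mean_dist_map symmetric distance matrix (e.g. from
#'   [mean_distance_map()]).
#' @param window_bins window width in bins.
#' @return numeric vector of length `n` of class `boundary_profile`;
#'   element `i` scores a boundary between bins `i - 1` and `i`.
#' @export
boundary_score_profile <- function(mean_dist_map, window_bins = 2L) {
  stopifnot(is.matrix(mean_dist_map), nrow(mean_dist_map) == ncol(mean_dist_map))
  n <- nrow(mean_dist_map)
  w <- as.integer(window_bins)
  score <- rep(NA_real_, n)
  if (2L * w > n) {
    warning("window of ", w, " bins does not fit a ", n, "-bin map")
    return(structure(score, class = "boundary_profile"))
  }
  within_mean <- function(bins) {
    if (length(bins) < 2L) return(NA_real_)
    sub <- mean_dist_map[bins, bins]
    mean(sub[upper.tri(sub)])
  }
  for (i in seq.int(w + 1L, n - w + 1L)) {
    u <- seq.int(i - w, i - 1L)
    d <- seq.int(i, i + w - 1L)
    d_inter <- mean(mean_dist_map[u, d])
    d_intra <- min(within_mean(u), within_mean(d))
    score[i] <- d_inter / d_intra
  }
  structure(score, class = "boundary_profile")
}

#' Detect TAD boundaries from a boundary-score profile
#'
#' Local maxima of the profile above `min_score`, greedily pruned (highest
#' score first) so that kept boundaries are at least `min_separation_bins`
#' apart.
#'
#' @param profile a [boundary_score_profile()] vector.
#' @param min_score minimum peak score.
#' @param min_separation_bins minimum bin distance between boundaries.
#' @return increasing integer vector of boundary bins (1-based index of the
#'   first bin of each new domain), class `tad_annotation`; possibly empty.
#' @export
detect_boundaries <- function(profile, min_score = 1.2,
                              min_separation_bins = 2L) {
  p <- as.numeric(profile)
  n <- length(p)
  cand <- which(!is.na(p) & p >= min_score)
  is_peak <- vapply(cand, function(i) {
    left <- if (i > 1) p[i - 1] else -Inf
    right <- if (i < n) p[i + 1] else -Inf
    p[i] >= max(left, right, na.rm = TRUE)
  }, logical(1))
  cand <- cand[is_peak]
  keep <- integer(0)
  for (i in cand[order(p[cand], decreasing = TRUE)]) {
    if (all(abs(i - keep) >= min_separation_bins)) keep <- c(keep, i)
  }
  structure(sort(keep), class = "tad_annotation")
}

#' Fraction of contacts formed within TADs
#'
#' Ratio of the number of contacts with both ends inside one domain to the
#' total number of contacts. By default only pairs separated by at least
#' `min_separation` bins count, so that trivially adjacent contacts (whose
#' probability is ~0.8 regardless of folding) do not swamp the signal.
#'
#' @param q a complete `contact_matrix`.
#' @param boundaries a `tad_annotation` (1-based first bin of each domain
#'   after the first).
#' @param min_separation minimum `|i - j|` for a pair to count.
#' @return fraction in `[0, 1]`, or `NA` if there are no counted contacts.
#' @export
tad_contact_fraction <- function(q, boundaries, min_separation = 2L) {
  stopifnot(is.matrix(q))
  if (any(is.na(q))) stop("contact matrix has undefined entries")
  n <- nrow(q)
  idx <- which(upper.tri(q), arr.ind = TRUE)
  idx <- idx[idx[, 2] - idx[, 1] >= min_separation, , drop = FALSE]
  contact <- q[idx] == 1
  if (!any(contact)) return(NA_real_)
  dom <- findInterval(seq_len(n), c(1L, as.integer(boundaries)))
  same <- dom[idx[, 1]] == dom[idx[, 2]]
  sum(contact & same) / sum(contact)
}

#' Contact moments of an ensemble
#'
#' First moments `<Q_i>` over the contact feature space, second moments
#' `<Q_i Q_j>` over a random subsample of feature pairs, and the
#' independent-model products `<Q_i><Q_j>` for the same pairs. Deviation of
#' the second moments from the independent products measures cooperativity
#' among contacts.
#'
#' @param qs list of complete `contact_matrix` objects, or a matrix of
#'   contact vectors (rows = cells).
#' @param n_pairs number of feature pairs sampled for the second moments.
#' @param seed integer RNG seed for the pair subsample.
#' @return list with `first`, `second`, `independent` and the sampled
#'   `pairs` (2-column index matrix).
#' @export
contact_moments <- function(qs, n_pairs = 2000L, seed = 1L) {
  V <- if (is.matrix(qs)) qs else do.call(rbind, lapply(qs, vectorize))
  if (nrow(V) < 2) stop("need at least 2 matrices")
  d <- ncol(V)
  first <- colMeans(V)
  set.seed(seed)
  n_all <- d * (d - 1) / 2
  n_pairs <- min(n_pairs, n_all)
  sel <- sample.int(n_all, n_pairs)
  j <- ceiling((1 + sqrt(1 + 8 * sel)) / 2)
  i <- sel - (j - 1) * (j - 2) / 2
  pairs <- cbind(i = as.integer(i), j = as.integer(j))
  second <- colMeans(V[, pairs[, 1], drop = FALSE] *
                     V[, pairs[, 2], drop = FALSE])
  list(first = first, second = second,
       independent = first[pairs[, 1]] * first[pairs[, 2]],
       pairs = pairs)
}

#' Agreement between two sets of contact moments
#'
#' @param moments_data,moments_model numeric vectors of aligned moments
#'   (e.g. `first` from [contact_moments()] of data and of generated
#'   ensembles).
#' @return list with Pearson `r` and mean absolute deviation `mad`.
#' @export
ensemble_agreement <- function(moments_data, moments_model) {
  stopifnot(length(moments_data) == length(moments_model))
  if (length(moments_data) < 3) stop("need at least 3 aligned moments")
  list(r = stats::cor(moments_data, moments_model),
       mad = mean(abs(moments_data - moments_model)))
}

#' Export TAD intervals as BED
#'
#' Converts a boundary annotation into genomic intervals (one per domain)
#' in 3-column BED format.
#'
#' @param boundaries a `tad_annotation` from [detect_boundaries()].
#' @param n_bins total number of bins.
#' @param chrom chromosome name.
#' @param start_bp 0-based genomic start of bin 1.
#' @param binsize_bp bin width in bp.
#' @param path output file.
#' @export
write_tads_bed <- function(boundaries, n_bins, chrom, start_bp, binsize_bp,
                           path) {
  edges <- c(1L, as.integer(boundaries), n_bins + 1L)
  df <- data.frame(chrom = chrom,
                   start = start_bp + (edges[-length(edges)] - 1L) * binsize_bp,
                   end = start_bp + (edges[-1] - 1L) * binsize_bp)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
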