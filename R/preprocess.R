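#' @useDynLib tadfold, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

new_contact_matrix <- function(entries, imputed = NULL) {
  stopifnot(is.matrix(entries), nrow(entries) == ncol(entries))
  if (is.null(imputed))
    imputed <- matrix(FALSE, nrow(entries), ncol(entries))
  structure(entries, imputed = imputed, class = c("contact_matrix", "matrix"))
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", nrow(x), "x", ncol(x),
      ", ", sum(is.na(x)), " undefined, ",
      sum(attr(x, "imputed")), " imputed entries\n", sep = "")
  invisible(x)
}

#' Coarsen a trace to a lower genomic resolution
#'
#' Keeps every `factor`-th probe (indices 0, factor, 2*factor, ... of the
#' original trace), e.g. turning an 84-probe 30 kb trace into a 28-probe
#' 90 kb trace with `factor = 3`.
#'
#' @param trace a `cell_trace` (see [generate_dataset()]).
#' @param factor positive integer coarsening factor.
#' @return the coarsened `cell_trace`.
#' @export
coarsen_trace <- function(trace, factor = 3L) {
  factor <- as.integer(factor)
  stopifnot(inherits(trace, "cell_trace"), factor >= 1L)
  n <- nrow(trace$positions)
  if (factor > n) stop("coarsening factor ", factor, " exceeds probe count ", n)
  keep <- seq.int(1L, n, by = factor)
  new_cell_trace(trace$cell_id, trace$positions[keep, , drop = FALSE],
                 trace$label)
}

#' Pairwise distance matrix of a trace
#'
#' Euclidean distances between probe positions in nm; any entry involving a
#' missing probe is `NA`.
#'
#' @param trace a `cell_trace`.
#' @return symmetric numeric matrix of distances (nm) with `NA` where
#'   undefined.
#' @export
distance_matrix <- function(trace) {
  stopifnot(inherits(trace, "cell_trace"))
  d <- as.matrix(stats::dist(trace$positions))
  d[trace$missing_mask, ] <- NA_real_
  d[, trace$missing_mask] <- NA_real_
  d
}

#' Binarize a distance matrix into contacts
#'
#' `Q_ij = 1` iff `d_ij <= cutoff_nm`; undefined (`NA`) distances stay
#' undefined so they can be imputed later. The diagonal is set to 1 for
#' probes with defined positions.
#'
#' @param dist_matrix symmetric distance matrix in nm (possibly with `NA`).
#' @param cutoff_nm contact cutoff in nm; a tie counts as a contact.
#' @return a `contact_matrix` with entries in \{0, 1, NA\}.
#' @export
binarize <- function(dist_matrix, cutoff_nm = 450) {
  stopifnot(is.matrix(dist_matrix), cutoff_nm > 0)
  q <- (dist_matrix <= cutoff_nm) * 1L
  diag(q)[!is.na(diag(dist_matrix))] <- 1L
  new_contact_matrix(q)
}

#' Mean contact probability by genomic separation
#'
#' For each separation `s = |i - j|` in `1..n-1`, the mean of all defined,
#' non-imputed contact entries at that separation across the dataset.
#'
#' @param qs list of `contact_matrix` objects with equal dimensions.
#' @return numeric vector of length `n - 1`, class `separation_profile`;
#'   element `s` is the contact probability at separation `s`.
#' @export
separation_profile <- function(qs) {
  stopifnot(length(qs) >= 1L)
  n <- nrow(qs[[1]])
  num <- den <- numeric(n - 1L)
  sep <- abs(row(qs[[1]]) - col(qs[[1]]))
  ut <- upper.tri(qs[[1]])
  for (q in qs) {
    ok <- ut & !is.na(q) & !attr(q, "imputed")
    num <- num + vapply(seq_len(n - 1L),
                        function(s) sum(q[ok & sep == s]), numeric(1))
    den <- den + vapply(seq_len(n - 1L),
                        function(s) sum(ok & sep == s), numeric(1))
  }
  if (any(den == 0))
    stop("no defined entries at separation(s): ",
         paste(which(den == 0), collapse = ", "))
  structure(num / den, class = "separation_profile")
}

#' Impute undefined contact entries
#'
#' Each undefined entry at separation `s` is drawn Bernoulli with the
#' separation profile's probability at `s`, mirrored for symmetry and
#' flagged in the `imputed` attribute. Defined entries are never altered.
#'
#' @param q a `contact_matrix`, possibly with `NA` entries.
#' @param profile a [separation_profile()].
#' @param seed integer RNG seed.
#' @return a complete `contact_matrix`.
#' @export
impute_missing <- function(q, profile, seed = 1L) {
  stopifnot(inherits(q, "contact_matrix"))
  n <- nrow(q)
  if (length(profile) < n - 1L)
    stop("separation profile does not cover all separations up to ", n - 1L)
  set.seed(seed)
  ent <- unclass(q)
  attributes(ent) <- list(dim = dim(q))
  imputed <- attr(q, "imputed")
  idx <- which(is.na(ent) & upper.tri(ent), arr.ind = TRUE)
  if (nrow(idx) > 0) {
    s <- idx[, 2] - idx[, 1]
    draws <- as.integer(stats::runif(nrow(idx)) < profile[s])
    ent[idx] <- draws
    ent[idx[, c(2, 1), drop = FALSE]] <- draws
    imputed[idx] <- TRUE
    imputed[idx[, c(2, 1), drop = FALSE]] <- TRUE
  }
  dg <- which(is.na(diag(ent)))
  if (length(dg)) { ent[cbind(dg, dg)] <- 1L; imputed[cbind(dg, dg)] <- TRUE }
  new_contact_matrix(ent, imputed)
}

#' Vectorize a contact matrix
#'
#' Strict upper triangle in row-major order: `(1,2), (1,3), ..., (1,n),
#' (2,3), ...`; length `n(n-1)/2`.
#'
#' @param q a complete `contact_matrix` (no `NA`).
#' @return numeric feature vector.
#' @export
vectorize <- function(q) {
  if (any(is.na(q))) stop("contact matrix has undefined entries; impute first")
  m <- unclass(q)
  attributes(m) <- list(dim = dim(q))
  # row-major upper triangle of a symmetric matrix == column-major lower
  as.numeric(m[lower.tri(m)])
}

#' Reshape a feature vector back into a contact matrix
#'
#' Inverse of [vectorize()].
#'
#' @param v feature vector of length `n(n-1)/2`.
#' @param diag_value value placed on the diagonal.
#' @return a `contact_matrix`.
#' @export
unvectorize <- function(v, diag_value = 1) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(n - round(n)) > 1e-9)
    stop("vector length ", length(v), " is not n(n-1)/2 for integer n")
  n <- as.integer(round(n))
  m <- matrix(diag_value, n, n)
  m[lower.tri(m)] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  new_contact_matrix(m)
}

#' Preprocess a trace dataset into contact feature vectors
#'
#' The full imaging pipeline: optional coarsening, distance matrices,
#' binarization at `cutoff_nm`, separation-profile imputation of missing
#' entries (pooled over the dataset by default), and vectorization.
#'
#' @param traces list of `cell_trace` objects.
#' @param cutoff_nm contact cutoff in nm.
#' @param coarsen integer coarsening factor (1 = keep resolution).
#' @param seed RNG seed for imputation.
#' @param profile_by_label compute a separate separation profile per cell
#'   label rather than pooling all cells.
#' @return list with `vectors` (cells x features matrix), `labels`,
#'   `cell_ids`, `n_bins`, `matrices` (imputed contact matrices) and
#'   `profile`.
#' @export
preprocess_traces <- function(traces, cutoff_nm = 450, coarsen = 1L, seed = 1L,
                              profile_by_label = FALSE) {
  stopifnot(length(traces) >= 1L)
  if (coarsen > 1L) traces <- lapply(traces, coarsen_trace, factor = coarsen)
  qs <- lapply(traces, function(tr) binarize(distance_matrix(tr), cutoff_nm))
  labels <- vapply(traces, function(tr) tr$label, character(1))
  if (profile_by_label) {
    profile <- lapply(split(qs, labels), separation_profile)
    imp <- qs
    for (lb in names(profile)) {
      sel <- which(labels == lb)
      imp[sel] <- lapply(seq_along(sel), function(k)
        impute_missing(qs[[sel[k]]], profile[[lb]], seed = seed + sel[k]))
    }
  } else {
    profile <- separation_profile(qs)
    imp <- lapply(seq_along(qs), function(k)
      impute_missing(qs[[k]], profile, seed = seed + k))
  }
  vecs <- do.call(rbind, lapply(imp, vectorize))
  list(vectors = vecs,
       labels = labels,
       cell_ids = vapply(traces, function(tr) tr$cell_id, character(1)),
       n_bins = nrow(qs[[1]]),
       matrices = imp,
       profile = profile)
}
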