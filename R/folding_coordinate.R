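#' Fit the folding-coordinate separator
#'
#' Fits a soft-margin linear support-vector machine to the latent-space
#' embeddings of two cell populations and keeps its decision boundary. The
#' folding coordinate of any structure is then its signed distance from this
#' boundary, with the sign fixed so that population A (conventionally WT)
#' has a positive mean coordinate.
#'
#' @param embeddings_a,embeddings_b matrices of latent embeddings (rows =
#'   cells) for the two populations; A is the WT-like set.
#' @param cost soft-margin regularization constant.
#' @return an object of class `folding_model` with fields `w` (weights),
#'   `b` (offset) and `wnorm`.
#' @export
fit_separator <- function(embeddings_a, embeddings_b, cost = 1) {
  stopifnot(is.matrix(embeddings_a), is.matrix(embeddings_b),
            nrow(embeddings_a) >= 1, nrow(embeddings_b) >= 1,
            ncol(embeddings_a) == ncol(embeddings_b))
  X <- rbind(embeddings_a, embeddings_b)
  if (all(apply(X, 2, function(c) diff(range(c)) == 0)))
    stop("degenerate embeddings: all points identical")
  y <- factor(c(rep("A", nrow(embeddings_a)), rep("B", nrow(embeddings_b))))
  fit <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  coord_a <- (embeddings_a %*% w + b) / sqrt(sum(w^2))
  if (mean(coord_a) < 0) { w <- -w; b <- -b }
  structure(list(w = w, b = b, wnorm = sqrt(sum(w^2))), class = "folding_model")
}

#' Folding coordinate of latent embeddings
#'
#' Signed distance `(w . z + b) / ||w||` from the separating boundary.
#'
#' @param model a [fit_separator()] model.
#' @param z latent vector or matrix of latent vectors.
#' @return numeric vector of coordinates.
#' @export
coordinate_value <- function(model, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) != length(model$w))
    stop("embedding dimension ", ncol(z), " does not match model (",
         length(model$w), ")")
  drop(z %*% model$w + model$b) / model$wnorm
}

#' Misclassification rate of the separator
#'
#' Fraction of population-A points with a negative coordinate plus
#' population-B points with a positive coordinate, over all points.
#'
#' @inheritParams fit_separator
#' @param model a [fit_separator()] model.
#' @return fraction in `[0, 1]`.
#' @export
misclassification_rate <- function(model, embeddings_a, embeddings_b) {
  ca <- coordinate_value(model, embeddings_a)
  cb <- coordinate_value(model, embeddings_b)
  (sum(ca < 0) + sum(cb > 0)) / (length(ca) + length(cb))
}

#' Histogram-based Kullback-Leibler divergence of two 1-D samples
#'
#' KL(p || q) estimated on `bins` shared equal-width bins spanning the
#' pooled sample range, with one pseudo-count per bin for regularization.
#'
#' @param samples_p,samples_q numeric samples from the two distributions.
#' @param bins number of shared histogram bins.
#' @return divergence in nats (non-negative).
#' @export
kl_divergence_1d <- function(samples_p, samples_q, bins = 50L) {
  stopifnot(length(samples_p) >= 1, length(samples_q) >= 1, bins >= 2)
  rng <- range(c(samples_p, samples_q))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  cp <- tabulate(findInterval(samples_p, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), bins) + 1
  cq <- tabulate(findInterval(samples_q, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), bins) + 1
  p <- cp / sum(cp)
  q <- cq / sum(cq)
  sum(p * log(p / q))
}

#' First-principal-component projection
#'
#' Centers the data and projects onto the top eigenvector of the sample
#' covariance; a linear baseline for the folding coordinate.
#'
#' @param vectors matrix (observations x features).
#' @return numeric vector of PC1 scores with attributes `direction` (the
#'   loading vector) and `explained` (share of variance explained).
#' @export
pca_projection <- function(vectors) {
  stopifnot(is.matrix(vectors), nrow(vectors) >= 2)
  pc <- stats::prcomp(vectors, center = TRUE, scale. = FALSE)
  structure(pc$x[, 1], direction = pc$rotation[, 1],
            explained = pc$sdev[1]^2 / sum(pc$sdev^2))
}

#' Cell-type overlap under k-means clustering
#'
#' Clusters the pooled data and reports the summed per-cluster minority
#' mass: `sum_c min(n_Ac, n_Bc) / N`. 0 means the clustering separates the
#' two labels perfectly; a clustering uninformative about the labels gives
#' about the share of the minority label.
#'
#' @param vectors matrix (observations x features).
#' @param labels vector of two distinct labels, one per row.
#' @param k number of clusters.
#' @param seed integer RNG seed.
#' @param nstart number of random k-means restarts.
#' @return overlap fraction in `[0, 1]`.
#' @export
kmeans_overlap <- function(vectors, labels, k = 10L, seed = 1L, nstart = 10L) {
  stopifnot(is.matrix(vectors), nrow(vectors) == length(labels), k >= 2)
  if (k > nrow(vectors)) stop("k exceeds the number of observations")
  lv <- unique(labels)
  stopifnot(length(lv) == 2L)
  set.seed(seed)
  km <- stats::kmeans(vectors, centers = k, nstart = nstart, iter.max = 100L)
  tab <- table(km$cluster, factor(labels, levels = lv))
  sum(pmin(tab[, 1], tab[, 2])) / length(labels)
}
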