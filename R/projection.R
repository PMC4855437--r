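# PCA of a fingerprint matrix (mean-centering + covariance
# eigendecomposition, no variance scaling by default) and the two projection
# diagnostics: cumulative variance coverage and the correlation between
# pairwise distances in the PC subspace and in the original fingerprint
# space.

#' Fit a PCA model to a fingerprint matrix
#'
#' Mean-centers the columns (optionally scales to unit variance) and
#' eigendecomposes the covariance matrix. Loading columns are ordered by
#' decreasing eigenvalue and sign-fixed so that each column's
#' largest-magnitude entry is positive. Eigenvalues are clipped at zero
#' (degenerate data is allowed).
#'
#' @param X numeric matrix, n molecules x D fingerprint components (n >= 2).
#' @param scale. scale columns to unit variance before PCA (default FALSE:
#'   raw counts, matching standard practice for these fingerprints).
#' @return an object of class `pca_model`: list with `means`, `scales`,
#'   `loadings` (D x D), `eigenvalues` (length D).
#' @export
fit_pca <- function(X, scale. = FALSE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, ncol(X) >= 1)
  means <- colMeans(X)
  scales <- rep(1, ncol(X))
  if (scale.) {
    s <- apply(X, 2, sd)
    scales <- ifelse(s > 0, s, 1)
  }
  Xc <- sweep(sweep(X, 2, means), 2, scales, "/")
  cv <- crossprod(Xc) / (nrow(X) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  # deterministic sign: largest-|.| entry of each column made positive
  for (j in seq_len(ncol(vecs))) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(means = means, scales = scales, loadings = vecs,
                 eigenvalues = vals, dim = ncol(X),
                 colnames = colnames(X)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model: D=%d, top eigenvalues %s>\n", x$dim,
              paste(signif(head(x$eigenvalues, 3), 4), collapse = ", ")))
  invisible(x)
}

#' Project data with a fitted PCA model
#'
#' Centers (and scales, if the model was fitted with scaling) with the
#' model's stored parameters and projects onto the first `k` loadings. Valid
#' for external molecules that were not part of the fitting set.
#'
#' @param model a `pca_model`.
#' @param X numeric matrix with `model$dim` columns.
#' @param k number of components (default 3).
#' @return n x k score matrix.
#' @export
pca_project <- function(model, X, k = 3L) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$dim)
    stop(sprintf("dimension mismatch: data has %d columns, model expects %d",
                 ncol(X), model$dim), call. = FALSE)
  stopifnot(k >= 1, k <= model$dim)
  Xc <- sweep(sweep(X, 2, model$means), 2, model$scales, "/")
  Xc %*% model$loadings[, seq_len(k), drop = FALSE]
}

#' Fraction of data variance covered by the first k components
#'
#' @param model a `pca_model`.
#' @param k number of leading components, `1 <= k <= D`.
#' @return fraction in `[0, 1]`; equals 1 at `k = D`. For all-constant data
#'   (zero total variance) the coverage is defined as 1.
#' @export
variance_coverage <- function(model, k) {
  stopifnot(inherits(model, "pca_model"))
  if (k < 1 || k > model$dim) stop("k out of range", call. = FALSE)
  tot <- sum(model$eigenvalues)
  if (tot == 0) return(1)
  sum(model$eigenvalues[seq_len(k)]) / tot
}

# decode linear indices 1..n(n-1)/2 into unordered pair (i < j)
pair_from_index <- function(L, n) {
  # pairs ordered (1,2),(1,3)..(1,n),(2,3)...; row i starts after
  # cum(i-1) = (i-1)*n - i*(i-1)/2 pairs
  i <- as.integer(ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * L)))
  start <- (i - 1) * n - i * (i - 1) / 2
  j <- as.integer(L - start + i)
  cbind(i, j)
}

#' Correlation between subspace and original-space pair distances
#'
#' Pearson correlation between Euclidean distances of molecule pairs in the
#' k-dimensional PC subspace and in the original fingerprint space, over a
#' seeded uniform sample of unordered pairs (all pairs when there are no
#' more than `n_pairs`).
#'
#' @param coords n x k score matrix.
#' @param fps n x D fingerprint matrix, same molecule order.
#' @param n_pairs maximum number of sampled pairs (default 1e6).
#' @param seed integer seed for the pair sample.
#' @return Pearson correlation coefficient.
#' @export
distance_correlation <- function(coords, fps, n_pairs = 1e6, seed = 1L) {
  coords <- as.matrix(coords); fps <- as.matrix(fps)
  n <- nrow(coords)
  stopifnot(n == nrow(fps), n >= 3)
  P <- n * (n - 1) / 2
  if (P <= n_pairs) {
    idx <- seq_len(P)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
    idx <- sample(P, n_pairs)
  }
  ij <- pair_from_index(idx, n)
  d1 <- sqrt(rowSums((coords[ij[, 1], , drop = FALSE] -
                        coords[ij[, 2], , drop = FALSE])^2))
  d2 <- sqrt(rowSums((fps[ij[, 1], , drop = FALSE] -
                        fps[ij[, 2], , drop = FALSE])^2))
  if (sd(d1) == 0 || sd(d2) == 0)
    stop("undefined correlation: zero variance in pairwise distances",
         call. = FALSE)
  cor(d1, d2)
}

#' Save a PCA model as JSON
#' @param model `pca_model`.
#' @param path output file.
#' @export
write_pca_model <- function(model, path) {
  jsonlite::write_json(
    list(means = model$means, scales = model$scales,
         loadings = model$loadings, eigenvalues = model$eigenvalues,
         dim = model$dim,
         colnames = if (is.null(model$colnames)) character(0) else model$colnames),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Load a PCA model from JSON
#' @param path file written by [write_pca_model()].
#' @return a `pca_model`.
#' @export
read_pca_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(means = as.numeric(x$means), scales = as.numeric(x$scales),
                 loadings = matrix(as.numeric(x$loadings), nrow = x$dim),
                 eigenvalues = as.numeric(x$eigenvalues),
                 dim = as.integer(x$dim),
                 colnames = if (length(x$colnames)) x$colnames else NULL),
            class = "pca_model")
}
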