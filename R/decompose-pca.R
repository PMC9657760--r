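# Principal component analysis of data blocks, scree-based component
# selection, and the explained-variance convention shared by all
# decompositions.

block_matrix <- function(x) {
  if (inherits(x, "data_block")) x$matrix
  else if (is.matrix(x)) x
  else stopf("expected a data_block or a matrix")
}

block_feature_axis <- function(x) {
  if (inherits(x, "data_block")) x$feature_axis else NULL
}

# Make each column's largest-magnitude loading element positive; flips the
# matching score columns so the reconstruction is unchanged.
fix_signs <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

new_decomposition <- function(kind, scores, loadings, ev, total_ev, p, extra = list()) {
  colnames(scores) <- paste0("C", seq_len(ncol(scores)))
  if (!is.null(loadings)) colnames(loadings) <- colnames(scores)
  structure(c(list(kind = kind, scores = scores, loadings = loadings,
                   ev = ev, total_ev = total_ev, p = p), extra),
            class = c(kind, "decomposition"))
}

#' Principal component analysis of a data block
#'
#' Columns are mean-centred and the centred matrix is decomposed by SVD.
#' Scores are the sample projections, loadings the right singular vectors;
#' per-component explained variance is the eigenvalue fraction of the
#' sample covariance. Sign convention: each loading's largest-magnitude
#' element is positive.
#'
#' @param block a `data_block` or numeric matrix (samples x features).
#' @param p number of components to retain,
#'   `p <= min(n_samples - 1, n_features)`.
#' @return object of class `c("pca", "decomposition")` with fields
#'   `scores` (n x p), `loadings` (features x p), `eigenvalues` (all),
#'   `ev` (per retained component), `total_ev`, `center`, `feature_axis`.
#' @export
pca_fit <- function(block, p = 2L) {
  X <- block_matrix(block)
  n <- nrow(X); f <- ncol(X)
  if (p < 1 || p > min(n - 1, f))
    stopf("p must lie in [1, min(n_samples - 1, n_features)] = [1, %d]", min(n - 1, f))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (all(abs(Xc) < 1e-300)) stopf("constant matrix: zero variance")
  if (f > n) {
    # wide matrix: eigendecompose the small Gram matrix X_c X_c'
    G <- tcrossprod(Xc)
    e <- eigen(G, symmetric = TRUE)
    pos <- pmax(e$values, 0)
    r <- sum(pos > max(pos) * 1e-12)
    d <- sqrt(pos[seq_len(max(r, p))])
    U <- e$vectors[, seq_along(d), drop = FALSE]
    V <- crossprod(Xc, sweep(U[, seq_len(p), drop = FALSE], 2,
                             d[seq_len(p)], "/"))
    lambda_all <- pos / (n - 1)
  } else {
    s <- svd(Xc)
    U <- s$u; d <- s$d
    V <- s$v[, seq_len(p), drop = FALSE]
    lambda_all <- d^2 / (n - 1)
  }
  if (any(d[seq_len(p)] <= max(d) * 1e-12))
    stopf("p = %d exceeds the numerical rank of the centred matrix", p)
  scores <- sweep(U[, seq_len(p), drop = FALSE], 2, d[seq_len(p)], "*")
  sg <- fix_signs(V, scores)
  ev_all <- lambda_all / sum(lambda_all)
  new_decomposition("pca", sg$scores, sg$loadings,
                    ev = ev_all[seq_len(p)], total_ev = sum(ev_all[seq_len(p)]),
                    p = p,
                    extra = list(eigenvalues = lambda_all, center = ctr,
                                 centered = TRUE, data = X,
                                 feature_axis = block_feature_axis(block)))
}

#' Project new samples onto fitted principal components
#'
#' @param object a `pca` decomposition.
#' @param newdata matrix with the same feature columns, or a `data_block`.
#' @param ... unused.
#' @return scores matrix (rows of `newdata` x p).
#' @export
predict.pca <- function(object, newdata, ...) {
  X <- block_matrix(newdata)
  if (ncol(X) != length(object$center)) stopf("feature count mismatch")
  sweep(X, 2, object$center) %*% object$loadings
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<%s decomposition> %d samples, %d features, p = %d | total EV %.4f\n",
              toupper(x$kind), nrow(x$scores),
              if (is.null(x$loadings)) NA_integer_ else nrow(x$loadings),
              x$p, x$total_ev))
  invisible(x)
}

#' @export
summary.decomposition <- function(object, ...) {
  tab <- data.frame(component = seq_len(object$p), ev = object$ev,
                    cumulative_ev = cumsum(object$ev))
  cat(sprintf("%s decomposition, p = %d components\n", toupper(object$kind), object$p))
  print(tab, row.names = FALSE, digits = 4)
  invisible(tab)
}

#' Fitted reconstruction of a decomposition
#' @param object a `decomposition`.
#' @param ... unused.
#' @return reconstructed samples x features matrix.
#' @export
fitted.decomposition <- function(object, ...) {
  R <- tcrossprod(object$scores, object$loadings)
  if (isTRUE(object$centered)) R <- sweep(R, 2, object$center, "+")
  R
}

#' Residual matrix of a decomposition
#' @param object a `decomposition`.
#' @param ... unused.
#' @return data minus reconstruction.
#' @export
residuals.decomposition <- function(object, ...) {
  if (is.null(object$data)) stopf("decomposition does not carry its data")
  object$data - fitted(object)
}

#' Suggest a component count from an eigenvalue scree
#'
#' Returns the index before the largest relative eigenvalue drop among the
#' first `min(10, n - 1)` eigenvalues, together with the full scree table
#' for manual override. Ties resolve to the smallest index; a flat scree
#' (no drop) warns and suggests 1.
#'
#' @param eigenvalues numeric vector sorted in descending order.
#' @return list with `p` (suggested count) and `table` (index, eigenvalue,
#'   relative drop to the next).
#' @export
scree_select <- function(eigenvalues) {
  n <- length(eigenvalues)
  if (is.unsorted(rev(eigenvalues))) stopf("eigenvalues must be sorted descending")
  tab <- data.frame(index = seq_len(n), eigenvalue = eigenvalues,
                    rel_drop = c((eigenvalues[-n] - eigenvalues[-1]) /
                                   eigenvalues[-n], NA)[seq_len(n)])
  if (n < 3) return(list(p = n, table = tab))
  m <- min(10L, n - 1L)
  drops <- tab$rel_drop[seq_len(m)]
  if (all(drops <= 0, na.rm = TRUE) || all(!is.finite(drops))) {
    warning("flat scree: no eigenvalue drop; suggesting 1 component")
    return(list(p = 1L, table = tab))
  }
  if (max(drops, na.rm = TRUE) == 0) {
    warning("flat scree: no eigenvalue drop; suggesting 1 component")
    return(list(p = 1L, table = tab))
  }
  list(p = which.max(drops), table = tab)
}

#' Explained variance of a reconstruction
#'
#' `1 - ||X - Xhat||_F^2 / ||Xref||_F^2`, where the reference `Xref` is
#' the column-centred matrix when `centered = TRUE` (the PCA convention)
#' and the raw matrix otherwise (the NMF convention). The convention used
#' is recorded in the `"centered"` attribute of the result.
#'
#' @param block data matrix or `data_block`.
#' @param reconstruction matrix of the same shape.
#' @param centered logical; which reference norm to use.
#' @return explained-variance fraction.
#' @export
explained_variance <- function(block, reconstruction, centered = FALSE) {
  X <- block_matrix(block)
  if (!all(dim(X) == dim(reconstruction))) stopf("shape mismatch")
  ref <- if (centered) sweep(X, 2, colMeans(X)) else X
  denom <- sum(ref^2)
  if (denom == 0) stopf("zero-norm reference matrix")
  structure(1 - sum((X - reconstruction)^2) / denom, centered = centered)
}
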