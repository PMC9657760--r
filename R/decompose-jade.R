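# Independent component analysis by joint approximate diagonalisation of
# fourth-order cumulant matrices (JADE), after PCA whitening. Under the
# blind-source-separation model x = A s with statistically independent,
# non-Gaussian sources s, the rotation that jointly diagonalises the
# cumulant matrices of the whitened data recovers the sources up to sign
# and permutation.

# Sample fourth-order cumulant matrices of whitened data Z (n x p), one per
# pair (i <= j): C_ij = E[z_i z_j z z'] - delta_ij I - e_i e_j' - e_j e_i'.
cumulant_matrices <- function(Z) {
  n <- nrow(Z); p <- ncol(Z)
  I <- diag(p)
  out <- vector("list", p * (p + 1) / 2)
  k <- 0L
  for (i in seq_len(p)) for (j in seq_len(i)) {
    k <- k + 1L
    w <- Z[, i] * Z[, j]
    M <- crossprod(Z * w, Z) / n
    M <- M - I * (i == j)
    Eij <- matrix(0, p, p)
    Eij[i, j] <- Eij[i, j] + 1
    Eij[j, i] <- Eij[j, i] + 1
    out[[k]] <- M - Eij
  }
  out
}

# Joint approximate diagonalisation of a set of symmetric matrices by
# Jacobi rotations (Cardoso-Souloumiac). Returns the orthogonal rotation.
joint_diagonalize <- function(mats, tol = 1e-10, max_sweeps = 100L) {
  p <- nrow(mats[[1]])
  V <- diag(p)
  if (p < 2) return(V)
  repeat {
    rotated <- FALSE
    for (a in seq_len(p - 1)) for (b in (a + 1):p) {
      g1 <- vapply(mats, function(M) M[a, a] - M[b, b], 0)
      g2 <- vapply(mats, function(M) M[a, b] + M[b, a], 0)
      ton <- sum(g1 * g1) - sum(g2 * g2)
      toff <- 2 * sum(g1 * g2)
      theta <- 0.5 * atan2(toff, ton + sqrt(ton^2 + toff^2))
      s <- sin(theta)
      if (abs(s) > tol) {
        rotated <- TRUE
        c_ <- cos(theta)
        R <- diag(p); R[a, a] <- c_; R[b, b] <- c_; R[a, b] <- -s; R[b, a] <- s
        V <- V %*% R
        mats <- lapply(mats, function(M) crossprod(R, M) %*% R)
      }
    }
    max_sweeps <- max_sweeps - 1L
    if (!rotated || max_sweeps <= 0L) break
  }
  V
}

excess_kurtosis <- function(x) {
  xc <- x - mean(x)
  mean(xc^4) / mean(xc^2)^2 - 3
}

#' JADE independent component analysis of a data block
#'
#' Whitens the column-centred data to `p` dimensions by PCA, then jointly
#' diagonalises the fourth-order cumulant matrices of the whitened scores
#' by Jacobi rotations. Components are ordered by descending kurtosis
#' magnitude and sign-fixed so each loading's largest-magnitude element is
#' positive. If every component's excess kurtosis is statistically
#' indistinguishable from zero the data look Gaussian, ICA is
#' unidentifiable, and the result carries `gaussian_warning = TRUE`
#' (components are still returned).
#'
#' @param block `data_block` or matrix (samples x features).
#' @param p number of components, at most the numerical rank.
#' @return object of class `c("ica", "decomposition")`: `scores` (whitened
#'   unmixed sources, n x p, unit variance), `loadings` (features x p
#'   mixing vectors), `kurtosis`, `gaussian_warning`, `total_ev` (variance
#'   captured by the whitening subspace).
#' @export
jade_ica <- function(block, p = 2L) {
  X <- block_matrix(block)
  n <- nrow(X)
  if (p < 1 || p > min(n - 1, ncol(X)))
    stopf("p must lie in [1, min(n_samples - 1, n_features)]")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  s <- svd(Xc, nu = min(n, ncol(X)), nv = 0)
  d <- s$d
  if (d[p] <= max(d) * 1e-10) stopf("p = %d exceeds the numerical rank", p)
  U <- s$u[, seq_len(p), drop = FALSE]
  Z <- U * sqrt(n - 1)                     # whitened: crossprod(Z)/(n-1) = I
  V <- joint_diagonalize(cumulant_matrices(Z))
  S <- Z %*% V
  kur <- apply(S, 2, excess_kurtosis)
  ord <- order(abs(kur), decreasing = TRUE)
  S <- S[, ord, drop = FALSE]
  V <- V[, ord, drop = FALSE]
  kur <- kur[ord]
  # feature-space mixing: X_c ~ S %*% t(loadings)
  Vsvd <- crossprod(Xc, U) %*% diag(1 / d[seq_len(p)], p)  # right sing. vectors
  loadings <- Vsvd %*% diag(d[seq_len(p)] / sqrt(n - 1), p) %*% V
  sg <- fix_signs(loadings, S)
  ev_all <- d^2 / sum(d^2)
  gw <- all(abs(kur) < 2 * sqrt(24 / n))
  new_decomposition("ica", sg$scores, sg$loadings,
                    ev = ev_all[seq_len(p)], total_ev = sum(ev_all[seq_len(p)]),
                    p = p,
                    extra = list(kurtosis = kur, gaussian_warning = gw,
                                 center = ctr, centered = TRUE, data = X,
                                 rotation = V,
                                 feature_axis = block_feature_axis(block)))
}
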