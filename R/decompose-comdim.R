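# ComDim / CCSWA: common components and specific weights analysis.
#
# Each block X_k (samples x features_k, shared samples) defines a
# cross-product matrix W_k = X_k X_k', modelled as
# W_k = Q Lambda_k Q' + E_k with one orthonormal set of common components
# Q shared by all blocks and a non-negative diagonal salience matrix
# Lambda_k per block. The salience quantifies how much block k contributes
# to each common dimension; components are extracted one by one with
# deflation.

#' ComDim / CCSWA multi-block analysis
#'
#' Blocks are column-centred and scaled to unit Frobenius norm; for each
#' of the `p` dimensions the algorithm initialises all saliences at 1 and
#' alternates `q <-` dominant eigenvector of `sum_k lambda_k W_k`,
#' `lambda_k <- q' W_k q`, until `||q_new - q_old|| < 1e-10` (or 100
#' iterations), then deflates every block by `X_k <- (I - q q') X_k`.
#' With `inner_method = "ica"` the dominant-eigenvector step is replaced
#' by the leading JADE component of the salience-weighted concatenation of
#' the blocks.
#'
#' @param blocks list of `data_block` objects (or matrices) sharing row
#'   ids and order.
#' @param p number of common components, `p <= N - 1`.
#' @param inner_method `"pca"` (dominant eigenvector) or `"ica"` (leading
#'   JADE component).
#' @param tol convergence tolerance on the common-component update.
#' @param max_iter inner iteration cap per dimension.
#' @return object of class `comdim`: `Q` (N x p orthonormal common
#'   components), `saliences` (p x K matrix, `saliences[d, k]` =
#'   lambda_k on dimension d), `block_ev` (per-block explained variance),
#'   `residual_norms`, `scores` (= Q, for score plots), `block_names`,
#'   `inner_method`.
#' @export
comdim <- function(blocks, p = 2L, inner_method = c("pca", "ica"),
                   tol = 1e-10, max_iter = 100L) {
  inner_method <- match.arg(inner_method)
  if (!length(blocks)) stopf("no blocks")
  K <- length(blocks)
  mats <- lapply(blocks, block_matrix)
  ids <- rownames(mats[[1]]) %||% as.character(seq_len(nrow(mats[[1]])))
  N <- nrow(mats[[1]])
  for (m in mats) {
    if (nrow(m) != N) stopf("blocks disagree in sample count")
    mid <- rownames(m) %||% as.character(seq_len(nrow(m)))
    if (!identical(mid, ids)) stopf("blocks disagree in sample ids or order")
  }
  if (p < 1 || p >= N) stopf("p must lie in [1, N - 1]")
  # centre and scale each block to unit Frobenius norm
  Xs <- lapply(mats, function(m) {
    mc <- sweep(m, 2, colMeans(m))
    nrm <- sqrt(sum(mc^2))
    if (nrm == 0) stopf("a block is constant (zero centred norm)")
    mc / nrm
  })
  Wk <- lapply(Xs, tcrossprod)
  block_names <- vapply(seq_len(K), function(k) {
    b <- blocks[[k]]
    if (inherits(b, "data_block")) b$block_name else paste0("block", k)
  }, "")

  Q <- matrix(0, N, p)
  saliences <- matrix(0, p, K, dimnames = list(NULL, block_names))
  for (d in seq_len(p)) {
    lambda <- rep(1, K)
    q <- NULL
    for (it in seq_len(max_iter)) {
      if (inner_method == "pca" || is.null(q)) {
        Wsum <- Reduce(`+`, Map(`*`, Wk, lambda))
        q_new <- eigen(Wsum, symmetric = TRUE)$vectors[, 1]
      }
      if (inner_method == "ica") {
        conc <- do.call(cbind, Map(function(X, l) sqrt(l) * X, Xs, as.list(lambda)))
        q_new <- tryCatch(leading_jade_direction(conc),
                          error = function(e) q_new)
      }
      q_new <- q_new / sqrt(sum(q_new^2))
      if (!is.null(q)) {
        if (sum(q * q_new) < 0) q_new <- -q_new
        if (sqrt(sum((q_new - q)^2)) < tol) { q <- q_new; break }
      }
      q <- q_new
      lambda <- vapply(Wk, function(W) drop(crossprod(q, W %*% q)), 0)
    }
    lambda <- vapply(Wk, function(W) drop(crossprod(q, W %*% q)), 0)
    # numerical re-orthogonalisation against earlier components
    if (d > 1) {
      q <- q - Q[, seq_len(d - 1), drop = FALSE] %*%
        crossprod(Q[, seq_len(d - 1), drop = FALSE], q)
      q <- q / sqrt(sum(q^2))
    }
    if (q[which.max(abs(q))] < 0) q <- -q
    Q[, d] <- q
    saliences[d, ] <- pmax(lambda, 0)
    Xs <- lapply(Xs, function(X) X - q %*% crossprod(q, X))
    Wk <- lapply(Xs, tcrossprod)
  }
  residual_norms <- vapply(Xs, function(X) sqrt(sum(X^2)), 0)
  block_ev <- 1 - residual_norms^2      # blocks were unit-norm
  names(block_ev) <- names(residual_norms) <- block_names
  rownames(Q) <- ids
  structure(list(Q = Q, saliences = saliences, block_ev = block_ev,
                 residual_norms = residual_norms, scores = Q,
                 block_names = block_names, inner_method = inner_method,
                 p = p, N = N,
                 total_ev = sum(saliences) / K),
            class = "comdim")
}

# Leading JADE source direction (unit vector in sample space) of a
# samples x features matrix: whiten to a few dimensions, rotate by joint
# diagonalisation, return the source with the largest kurtosis magnitude.
leading_jade_direction <- function(X, p_inner = 3L) {
  n <- nrow(X)
  s <- svd(X, nu = min(n, 8L), nv = 0)
  r <- sum(s$d > max(s$d) * 1e-10)
  p_inner <- min(p_inner, r, n - 1)
  if (p_inner < 1) stopf("degenerate matrix")
  if (p_inner == 1) return(s$u[, 1])
  Z <- s$u[, seq_len(p_inner), drop = FALSE] * sqrt(n - 1)
  V <- joint_diagonalize(cumulant_matrices(Z))
  S <- Z %*% V
  kur <- apply(S, 2, excess_kurtosis)
  # weight candidate sources by captured variance x kurtosis prominence:
  # the leading component should stay close to the dominant direction
  energy <- vapply(seq_len(p_inner), function(j)
    sum((s$d[seq_len(p_inner)] * V[, j])^2), 0)
  best <- which.max(energy * (1 + abs(kur)))
  S[, best] / sqrt(sum(S[, best]^2))
}

#' @export
print.comdim <- function(x, ...) {
  cat(sprintf("<comdim> %d samples, %d blocks (%s), p = %d, inner = %s\n",
              x$N, length(x$block_names),
              paste(x$block_names, collapse = ", "), x$p, x$inner_method))
  cat("saliences:\n")
  print(round(x$saliences, 4))
  cat("block explained variance:\n")
  print(round(x$block_ev, 4))
  invisible(x)
}

#' @export
summary.comdim <- function(object, ...) {
  tab <- data.frame(dimension = seq_len(object$p), object$saliences,
                    check.names = FALSE)
  print(tab, row.names = FALSE, digits = 4)
  invisible(tab)
}
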