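# Multi-restart non-negative matrix factorisation. The factorisation is
# non-unique (rotational ambiguity), so the standard remedy is applied:
# several runs from random non-negative initialisations, keeping the run
# with the highest explained variance.

nmf_single <- function(X, p, seed, tol, max_iter) {
  n <- nrow(X); f <- ncol(X)
  eps <- .Machine$double.eps
  init <- with_seed(seed, list(W = matrix(runif(n * p), n, p),
                               H = matrix(runif(p * f), p, f)))
  W <- init$W * sqrt(mean(X) / p); H <- init$H * sqrt(mean(X) / p)
  xnorm2 <- sum(X^2)
  ev_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # Lee-Seung multiplicative updates for the Frobenius objective
    H <- H * (crossprod(W, X) / (crossprod(W) %*% H + eps))
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (iter %% 10L == 0L || iter >= max_iter) {
      ev <- 1 - sum((X - W %*% H)^2) / xnorm2
      if (iter >= max_iter || abs(ev - ev_old) < tol) {
        return(list(W = W, H = H, ev = ev, iterations = iter))
      }
      ev_old <- ev
    }
  }
}

#' Non-negative matrix factorisation with restarts
#'
#' Factorises a non-negative samples x features matrix `X` as
#' `X ~ W H` with `W` (n x p) the score factor and `H` (p x features) the
#' loading factor, both elementwise non-negative, by Lee--Seung
#' multiplicative updates. `n_restarts` random non-negative
#' initialisations are derived from `seed` and the run with the highest
#' explained variance `1 - ||X - WH||_F^2 / ||X||_F^2` is returned;
#' results are bit-reproducible for a fixed seed.
#'
#' @param block `data_block` or matrix with all entries >= 0 (clip or
#'   shift negatives first; see [clip_negatives()]).
#' @param p number of components, `p <= min(n, features)`.
#' @param n_restarts number of random restarts (default 20).
#' @param seed root seed for the restart stream.
#' @param tol convergence tolerance on the explained-variance change.
#' @param max_iter maximum update iterations per restart.
#' @return object of class `c("nmf", "decomposition")`: `scores` = W,
#'   `loadings` = t(H) (features x p), `total_ev`, `restarts`,
#'   `restart_ev` (EV of every restart), `best_restart`, `seed`.
#' @export
nmf_fit <- function(block, p, n_restarts = 20L, seed = 1L, tol = 1e-6,
                    max_iter = 500L) {
  X <- block_matrix(block)
  if (any(X < 0))
    stopf("NMF requires non-negative entries; clip or shift negatives first (see clip_negatives)")
  if (p < 1) stopf("p must be >= 1")
  if (p > min(dim(X))) stopf("p must be <= min(n_samples, n_features)")
  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts))
    runs[[r]] <- nmf_single(X, p, derive_seed(seed, 1000L + r), tol, max_iter)
  evs <- vapply(runs, function(z) z$ev, 0)
  best <- which.max(evs)
  z <- runs[[best]]
  # per-component EV: variance share of each rank-1 term's reconstruction
  comp_norm <- vapply(seq_len(p), function(j)
    sum((z$W[, j, drop = FALSE] %*% z$H[j, , drop = FALSE])^2), 0)
  ev_comp <- z$ev * comp_norm / sum(comp_norm)
  new_decomposition("nmf", z$W, t(z$H), ev = ev_comp, total_ev = z$ev, p = p,
                    extra = list(restarts = n_restarts, restart_ev = evs,
                                 best_restart = best, seed = seed,
                                 iterations = z$iterations, centered = FALSE,
                                 data = X,
                                 feature_axis = block_feature_axis(block)))
}

#' Clip negative matrix entries to zero
#'
#' Small negatives can appear after background correction; NMF only admits
#' physically valid (non-negative) solutions, so they are clipped, with
#' the clipped-cell count recorded in the `"n_clipped"` attribute.
#'
#' @param block `data_block` or matrix.
#' @return the clipped object, with attribute `n_clipped`.
#' @export
clip_negatives <- function(block) {
  X <- block_matrix(block)
  n_neg <- sum(X < 0)
  if (n_neg > 0) X[X < 0] <- 0
  if (inherits(block, "data_block")) {
    block$matrix <- X
    attr(block, "n_clipped") <- n_neg
    block
  } else structure(X, n_clipped = n_neg)
}
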