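# Matrix decompositions: PCA against an eigendecomposition oracle, scree
# selection, multi-restart NMF, JADE-ICA blind source recovery, ComDim
# saliences, oblique coordinates and loading signatures.

test_that("PCA matches the covariance eigendecomposition oracle", {
  set.seed(1)
  X <- matrix(rnorm(20 * 12), 20, 12)
  fit <- pca_fit(X, 5)

  ev_oracle <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(fit$eigenvalues[1:12], ev_oracle, tolerance = 1e-10)

  # loadings orthonormal, scores uncorrelated
  expect_equal(crossprod(fit$loadings), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  cc <- cov(fit$scores)
  expect_equal(cc - diag(diag(cc)), matrix(0, 5, 5), tolerance = 1e-10,
               ignore_attr = TRUE)

  # sign convention: largest-magnitude loading entry positive
  for (j in 1:5) expect_gt(fit$loadings[which.max(abs(fit$loadings[, j])), j], 0)

  # full-rank reconstruction is exact
  full <- pca_fit(X, 12)
  Xc <- sweep(X, 2, colMeans(X))
  expect_lt(norm(Xc - tcrossprod(full$scores, full$loadings), "F") / norm(Xc, "F"),
            1e-8)

  # wide-matrix (Gram) path agrees with the svd path
  set.seed(2)
  W <- matrix(rnorm(10 * 300), 10, 300)
  fw <- pca_fit(W, 4)
  sv <- svd(sweep(W, 2, colMeans(W)))
  expect_equal(abs(fw$scores), abs(sweep(sv$u[, 1:4], 2, sv$d[1:4], "*")),
               tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(pca_fit(X, 20), "p must")
  expect_error(pca_fit(matrix(1, 5, 4), 2), "zero variance")
})

test_that("rank-1 data put all variance on PC1 and predict projects", {
  t <- seq(-1, 1, length.out = 15)
  X <- outer(t, c(1, 2, 3))
  fit <- pca_fit(X, 1)
  expect_equal(fit$ev[1], 1, tolerance = 1e-12)
  expect_equal(unname(predict(fit, X)), unname(fit$scores), tolerance = 1e-10)
})

test_that("scree selection finds the elbow", {
  expect_equal(scree_select(c(10, 9.5, 1, 0.9, 0.8))$p, 2L)
  expect_equal(scree_select(c(10, 9))$p, 2L)         # fewer than 3 -> count
  expect_warning(res <- scree_select(rep(2, 6)), "flat")
  expect_equal(res$p, 1L)
  expect_equal(scree_select(10 * 2^-(0:6))$p, 1L)    # equal drops -> first
  expect_error(scree_select(c(1, 2, 3)), "descending")
})

test_that("multi-restart NMF recovers an exact non-negative factorisation", {
  set.seed(2)
  W <- matrix(runif(30 * 2), 30, 2)
  H <- matrix(runif(2 * 40), 2, 40)
  X <- W %*% H
  fit <- nmf_fit(X, 2, n_restarts = 10, seed = 3)
  expect_gte(fit$total_ev, 0.999)
  expect_true(all(fit$scores >= 0))
  expect_true(all(fit$loadings >= 0))

  # determinism and best-of-restarts dominance
  fit2 <- nmf_fit(X, 2, n_restarts = 10, seed = 3)
  expect_identical(fit$scores, fit2$scores)
  single <- nmf_fit(X, 2, n_restarts = 1, seed = 3)
  expect_gte(fit$total_ev, single$total_ev)
  expect_equal(fit$restart_ev[1], single$total_ev, tolerance = 1e-12)

  # EV non-decreasing in p on the same data / seed stream
  evs <- vapply(1:3, function(p)
    nmf_fit(X, p, n_restarts = 5, seed = 7, tol = 1e-10, max_iter = 2000)$total_ev, 0)
  expect_true(all(diff(evs) >= -1e-6))

  Xn <- X; Xn[1, 1] <- -0.1
  expect_error(nmf_fit(Xn, 2), "non-negative")
  expect_error(nmf_fit(X, 0), "p must")

  cl <- clip_negatives(Xn)
  expect_equal(attr(cl, "n_clipped"), 1L)
  expect_true(all(cl >= 0))
})

test_that("explained variance follows the centred/raw conventions", {
  set.seed(4)
  X <- matrix(rnorm(15 * 8, mean = 3), 15, 8)
  expect_equal(as.numeric(explained_variance(X, X)), 1)
  Xc <- sweep(X, 2, colMeans(X))
  ctr <- X - Xc
  expect_equal(as.numeric(explained_variance(X, ctr, centered = TRUE)), 0)

  # Eckart-Young: rank-k SVD truncation EV equals the eigenvalue share
  sv <- svd(Xc)
  k <- 3
  Xk <- sv$u[, 1:k] %*% diag(sv$d[1:k]) %*% t(sv$v[, 1:k])
  expect_equal(as.numeric(explained_variance(X, Xk + ctr, centered = TRUE)),
               sum(sv$d[1:k]^2) / sum(sv$d^2), tolerance = 1e-12)

  expect_error(explained_variance(X, X[1:3, ]), "shape")
  expect_error(explained_variance(matrix(0, 3, 3), matrix(0, 3, 3)), "zero-norm")
})

test_that("JADE-ICA separates non-Gaussian sources", {
  recovered <- 0
  for (s in 1:10) {
    set.seed(s)
    S <- cbind(runif(2000) - 0.5, rexp(2000) - 1)
    A <- matrix(rnorm(4), 2, 2)
    fit <- jade_ica(S %*% t(A), 2)
    C <- abs(cor(fit$scores, S))
    if ((C[1, 1] >= 0.99 && C[2, 2] >= 0.99) ||
        (C[1, 2] >= 0.99 && C[2, 1] >= 0.99)) recovered <- recovered + 1
  }
  expect_gte(recovered, 9)

  # whitening preserved: source scatter is the identity
  set.seed(5)
  S <- cbind(runif(800) - 0.5, rexp(800) - 1, rbinom(800, 1, 0.3))
  X <- S %*% matrix(rnorm(9), 3, 3)
  fit <- jade_ica(X, 3)
  expect_equal(crossprod(fit$scores) / (nrow(X) - 1), diag(3),
               tolerance = 1e-8, ignore_attr = TRUE)

  # mixing times sources reproduces the centred data within tolerance
  Xc <- sweep(X, 2, colMeans(X))
  expect_lt(norm(Xc - tcrossprod(fit$scores, fit$loadings), "F") / norm(Xc, "F"),
            1e-6)

  # components ordered by kurtosis magnitude
  expect_true(all(diff(abs(fit$kurtosis)) <= 1e-12))

  # Gaussian-only data are flagged as unidentifiable but still returned
  set.seed(6)
  g <- jade_ica(matrix(rnorm(1000 * 4), 1000, 4), 2)
  expect_true(g$gaussian_warning)
  expect_equal(dim(g$scores), c(1000L, 2L))
  expect_false(fit$gaussian_warning)

  expect_error(jade_ica(outer(1:10, 1:5), 3), "rank")
})

test_that("single-block ComDim equals the eigendecomposition of W", {
  set.seed(1)
  X <- matrix(rnorm(20 * 30), 20, 30)
  cd <- comdim(list(X), p = 5)
  Xc <- sweep(X, 2, colMeans(X))
  Xs <- Xc / sqrt(sum(Xc^2))
  e <- eigen(tcrossprod(Xs), symmetric = TRUE)
  V <- e$vectors[, 1:5]
  for (j in 1:5) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  expect_equal(cd$Q, V, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(unname(cd$saliences[, 1]), e$values[1:5], tolerance = 1e-8)
  expect_equal(crossprod(cd$Q), diag(5), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("ComDim saliences behave: symmetry, ordering, conservation", {
  set.seed(1)
  X <- matrix(rnorm(20 * 30), 20, 30)
  cd2 <- comdim(list(X, X), p = 4)
  expect_equal(unname(cd2$saliences[, 1]), unname(cd2$saliences[, 2]),
               tolerance = 1e-8)
  expect_true(all(cd2$saliences >= 0))

  # structured block dominates a noise block on CC1
  wins <- 0
  for (s in 1:20) {
    set.seed(s)
    A <- outer(rnorm(15), rnorm(40)) + 0.1 * matrix(rnorm(600), 15)
    B <- matrix(rnorm(600), 15, 40)
    cc <- comdim(list(A, B), p = 2)
    if (cc$saliences[1, 1] > cc$saliences[1, 2]) wins <- wins + 1
  }
  expect_gte(wins, 19)

  # exhaustive deflation: saliences sum to the trace of the unit-norm W_k
  cdf <- comdim(list(X), p = 19)
  expect_equal(sum(cdf$saliences), 1, tolerance = 1e-6)
  expect_equal(unname(cdf$block_ev), 1, tolerance = 1e-6)

  expect_error(comdim(list(X), p = 20), "N - 1")
  expect_error(comdim(list(X, X[1:10, ])), "sample count")
})

test_that("ComDim with the ICA inner route still yields orthonormal Q", {
  set.seed(8)
  A <- outer(rexp(18) - 1, rnorm(25)) + 0.2 * matrix(rnorm(450), 18)
  B <- matrix(rnorm(450), 18, 25)
  cc <- comdim(list(A, B), p = 3, inner_method = "ica")
  expect_equal(crossprod(cc$Q), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(cc$saliences >= 0))
  expect_equal(cc$inner_method, "ica")
})

test_that("oblique coordinates implement the scalene trigonometry", {
  expect_equal(inter_axis_angle(c(1, 1), c(1, 1)), 0, tolerance = 1e-5)
  expect_equal(inter_axis_angle(c(1, 0), c(0, 2)), 90)
  expect_equal(inter_axis_angle(c(1, 1), c(1, 0)), 45)
  expect_error(inter_axis_angle(c(0, 0), c(1, 0)), "zero vector")

  sc <- matrix(c(1, 1), 1, 2)
  expect_equal(unname(oblique_scores(sc, 90)), matrix(c(1, 1), 1, 2))
  got <- oblique_scores(sc, 60)
  expect_equal(unname(got), matrix(c(1.5, sqrt(3) / 2), 1, 2), tolerance = 1e-12)
  expect_error(oblique_scores(sc, 0), "alpha")
  expect_error(oblique_scores(sc, 180), "alpha")

  # plotted basis vectors have inner product cos(alpha)
  e1 <- oblique_scores(matrix(c(1, 0), 1, 2), 60)
  e2 <- oblique_scores(matrix(c(0, 1), 1, 2), 60)
  expect_equal(sum(e1 * e2), cos(60 * pi / 180), tolerance = 1e-12)

  # distances in the plot equal the oblique-metric distances
  set.seed(9)
  S <- matrix(rnorm(10), 5, 2)
  alpha <- 72
  G <- matrix(c(1, cos(alpha * pi / 180), cos(alpha * pi / 180), 1), 2, 2)
  P <- oblique_scores(S, alpha)
  for (i in 1:4) {
    dv <- S[i, ] - S[i + 1, ]
    expect_equal(sqrt(sum((P[i, ] - P[i + 1, ])^2)),
                 sqrt(drop(t(dv) %*% G %*% dv)), tolerance = 1e-10)
  }
})

test_that("loading signatures normalise per window across components", {
  # two synthetic loading columns with known window integrals
  grid <- seq(100, 200, by = 0.1)
  fa <- data.frame(modality = "LIBS", colour = "dark", position = grid)
  g <- exp(-log(16) * ((grid - 150) / 2)^2)
  L <- cbind(2 * g, -4 * g)     # window integrals in ratio 2 : -4
  dec <- structure(list(kind = "pca", loadings = L, feature_axis = fa,
                        p = 2), class = c("pca", "decomposition"))
  win <- peak_window("g", 150, 10)
  sig <- loading_signature(dec, win)
  expect_equal(unname(sig[, 1]), c(0.5, -1), tolerance = 1e-9)

  # single component: every window is +/- 1
  dec1 <- dec; dec1$loadings <- L[, 1, drop = FALSE]
  expect_equal(abs(unname(loading_signature(dec1, win)[1, 1])), 1)

  # a component that is zero inside the window scores 0
  L0 <- cbind(g, numeric(length(grid)))
  dec0 <- dec; dec0$loadings <- L0
  expect_equal(unname(loading_signature(dec0, win)[2, 1]), 0)

  expect_error(loading_signature(dec, win[0, ]), "no peak windows")
})
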