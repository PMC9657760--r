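# Cluster-separation silhouettes for labelled score plots.
#
# The b_i used here is the mean distance from point i to ALL points
# outside its cluster -- not the classical nearest-other-cluster minimum.
# With more than two clusters this "all-outside" variant is more lenient
# than the classical one; a classical mode is available for comparison.
# The overall value averages per-cluster mean silhouettes (macro) or all
# points (micro); the two coincide for equal cluster sizes.

#' Silhouette report for labelled points
#'
#' Euclidean distances on the given columns. For each point,
#' `a_i` = mean distance to the other points of its own cluster (0 for a
#' singleton cluster), `b_i` = mean distance to all points outside the
#' cluster, `s_i = (b_i - a_i) / max(a_i, b_i)` (0 when both are 0).
#' `Sil` in \[-1, 1\]: -1 no clustering, 0 overlapping clusters, +1
#' distinct compact clusters.
#'
#' @param points numeric matrix (samples x dimensions) or vector.
#' @param labels cluster labels, one per point; at least two clusters.
#' @param variant `"macro"` (mean over clusters of per-cluster mean s_i;
#'   default) or `"micro"` (mean of s_i over all points).
#' @param classical if TRUE, use the classical nearest-other-cluster
#'   `b_i` instead of the all-outside-points mean.
#' @return object of class `silhouette_report`: per-point table
#'   (`points`: label, a, b, s), `cluster_means`, `sil`, `sil_percent`,
#'   `sil_macro`, `sil_micro`, `variant`, `distance = "euclidean"`.
#' @export
silhouette_report <- function(points, labels, variant = c("macro", "micro"),
                              classical = FALSE) {
  variant <- match.arg(variant)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0) stopf("empty input")
  labels <- as.character(labels)
  if (length(labels) != n) stopf("one label per point is required")
  cls <- unique(labels)
  if (length(cls) < 2) stopf("silhouette needs at least two clusters")
  D <- as.matrix(dist(points))
  a <- b <- s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a[i] <- if (any(own)) mean(D[i, own]) else 0
    if (classical) {
      b[i] <- min(vapply(setdiff(cls, labels[i]),
                         function(cl) mean(D[i, labels == cl]), 0))
    } else {
      b[i] <- mean(D[i, labels != labels[i]])
    }
    m <- max(a[i], b[i])
    s[i] <- if (m == 0) 0 else (b[i] - a[i]) / m
  }
  cluster_means <- vapply(cls, function(cl) mean(s[labels == cl]), 0)
  sil_macro <- mean(cluster_means)
  sil_micro <- mean(s)
  sil <- if (variant == "macro") sil_macro else sil_micro
  structure(list(points = data.frame(label = labels, a = a, b = b, s = s),
                 cluster_means = cluster_means, sil = sil,
                 sil_percent = 100 * sil, sil_macro = sil_macro,
                 sil_micro = sil_micro, variant = variant,
                 classical = classical, distance = "euclidean",
                 n = n, k = length(cls)),
            class = "silhouette_report")
}

#' @export
print.silhouette_report <- function(x, ...) {
  cat(sprintf("<silhouette_report> %d points, %d clusters | Sil (%s%s) = %.4f (%.1f%%)\n",
              x$n, x$k, x$variant,
              if (x$classical) ", classical b_i" else "", x$sil, x$sil_percent))
  cat("per-cluster mean silhouettes:\n")
  print(round(x$cluster_means, 4))
  invisible(x)
}

#' Scan all component planes for the best silhouette
#'
#' Computes the silhouette on every unordered pair of score columns
#' ("planes", e.g. the 2-1 plane) and reports the pair with the largest
#' value; ties break toward the lexicographically smallest pair.
#'
#' @param scores matrix with at least two columns.
#' @param labels cluster labels per row.
#' @param variant passed to [silhouette_report()].
#' @param classical passed to [silhouette_report()].
#' @return object of class `plane_scan`: `table` (i, j, sil) over all
#'   pairs and `best_plane` (list: i, j, sil).
#' @export
scan_planes <- function(scores, labels, variant = "macro", classical = FALSE) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) stopf("plane scan needs at least two score columns")
  prs <- combn(ncol(scores), 2)
  sil <- numeric(ncol(prs))
  for (k in seq_len(ncol(prs)))
    sil[k] <- silhouette_report(scores[, prs[, k]], labels, variant,
                                classical)$sil
  tab <- data.frame(i = prs[1, ], j = prs[2, ], sil = sil)
  best <- tab[order(-tab$sil, tab$i, tab$j), ][1, ]
  structure(list(table = tab,
                 best_plane = list(i = best$i, j = best$j, sil = best$sil),
                 variant = variant),
            class = "plane_scan")
}

#' @export
print.plane_scan <- function(x, ...) {
  cat(sprintf("<plane_scan> %d planes | best plane %d-%d, Sil = %.4f (%.1f%%)\n",
              nrow(x$table), x$best_plane$j, x$best_plane$i,
              x$best_plane$sil, 100 * x$best_plane$sil))
  invisible(x)
}

#' Silhouette in a component subspace
#'
#' Multidimensional silhouette in the Euclidean metric of the selected
#' score columns.
#'
#' @param scores score matrix.
#' @param dims component indices (non-empty, within range).
#' @param labels cluster labels per row.
#' @param variant,classical passed to [silhouette_report()].
#' @return the silhouette value.
#' @export
subspace_silhouette <- function(scores, dims, labels, variant = "macro",
                                classical = FALSE) {
  scores <- as.matrix(scores)
  if (!length(dims)) stopf("dims must be non-empty")
  if (any(dims < 1 | dims > ncol(scores))) stopf("dims out of range")
  silhouette_report(scores[, dims, drop = FALSE], labels, variant, classical)$sil
}

#' Confidence ellipse of a 2-D point cloud
#'
#' Mean-centred covariance ellipse scaled by the chi-square quantile with
#' 2 degrees of freedom at the given level. Degenerate (collinear) point
#' sets return a flagged line-segment fallback.
#'
#' @param points2d matrix with two columns, at least 3 rows.
#' @param level coverage level in (0, 1).
#' @return list: `center`, `semi_axes` (major, minor), `rotation_deg`,
#'   `degenerate` flag and, when degenerate, `segment` (2 x 2 endpoint
#'   matrix).
#' @export
confidence_ellipse <- function(points2d, level = 0.95) {
  P <- as.matrix(points2d)
  if (ncol(P) != 2) stopf("points2d must have two columns")
  if (nrow(P) < 3) stopf("at least 3 points are required")
  if (level <= 0 || level >= 1) stopf("level must lie in (0, 1)")
  ctr <- colMeans(P)
  V <- cov(P)
  e <- eigen(V, symmetric = TRUE)
  scale <- qchisq(level, df = 2)
  vals <- pmax(e$values, 0)
  degenerate <- vals[2] <= vals[1] * 1e-10
  semi <- sqrt(vals * scale)
  rot <- atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi
  out <- list(center = ctr, semi_axes = semi, rotation_deg = rot,
              degenerate = degenerate, level = level)
  if (degenerate) {
    dir <- e$vectors[, 1]
    out$segment <- rbind(ctr - semi[1] * dir, ctr + semi[1] * dir)
  }
  out
}

ellipse_path <- function(ell, n = 100) {
  t <- seq(0, 2 * pi, length.out = n)
  th <- ell$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- cbind(ell$semi_axes[1] * cos(t), ell$semi_axes[2] * sin(t)) %*% t(R)
  sweep(xy, 2, ell$center, "+")
}
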