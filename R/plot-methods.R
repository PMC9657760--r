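# Base-graphics displays: score plots with confidence ellipses (oblique
# axes for non-orthogonal decompositions), saliences, silhouettes and
# spider-diagram loading signatures.

#' Score plot of a decomposition
#'
#' Plots two score columns, coloured by label, optionally with per-label
#' confidence ellipses. For non-orthogonal decompositions set
#' `oblique = TRUE` to draw in scalene coordinates with the inter-axis
#' angle computed from the two latent vectors.
#'
#' @param x a `decomposition`.
#' @param dims two component indices (default `c(1, 2)`).
#' @param labels optional cluster labels (one per sample).
#' @param ellipses draw per-label confidence ellipses.
#' @param level ellipse coverage level.
#' @param oblique use oblique coordinates from the loading pair's
#'   inter-axis angle.
#' @param ... passed to [plot()].
#' @return the plotted coordinates, invisibly.
#' @export
plot.decomposition <- function(x, dims = c(1, 2), labels = NULL,
                               ellipses = FALSE, level = 0.95,
                               oblique = FALSE, ...) {
  sc <- x$scores[, dims, drop = FALSE]
  alpha <- 90
  if (oblique) {
    alpha <- inter_axis_angle(x$loadings[, dims[1]], x$loadings[, dims[2]])
    sc <- oblique_scores(sc, alpha)
  }
  nm <- sprintf("%s C%d", toupper(x$kind), dims)
  if (is.null(labels)) {
    plot(sc, xlab = nm[1], ylab = nm[2], pch = 19, ...)
  } else {
    labels <- factor(labels)
    cols <- rainbow(nlevels(labels))
    plot(sc, xlab = nm[1], ylab = nm[2], pch = 19,
         col = cols[as.integer(labels)], ...)
    legend("topright", legend = levels(labels), col = cols, pch = 19,
           bty = "n", cex = 0.8)
    if (ellipses) {
      for (li in seq_len(nlevels(labels))) {
        pts <- sc[as.integer(labels) == li, , drop = FALSE]
        if (nrow(pts) < 3) next
        ell <- confidence_ellipse(pts, level)
        if (ell$degenerate) {
          segments(ell$segment[1, 1], ell$segment[1, 2],
                   ell$segment[2, 1], ell$segment[2, 2], col = cols[li])
        } else {
          lines(ellipse_path(ell), col = cols[li])
        }
      }
    }
  }
  if (oblique)
    title(sub = sprintf("inter-axis angle %.1f°", alpha))
  invisible(sc)
}

#' Salience plot of a ComDim result
#'
#' @param x a `comdim` object.
#' @param ... passed to [graphics::stars()]; unused otherwise.
#' @return invisibly, the salience matrix.
#' @export
plot.comdim <- function(x, ...) {
  s <- x$saliences
  graphics::barplot(t(s), beside = TRUE, names.arg = paste0("CC", seq_len(nrow(s))),
                    legend.text = colnames(s), ylab = "salience",
                    main = sprintf("ComDim (%s) saliences", x$inner_method))
  invisible(s)
}

#' Spider diagram of loading signatures
#'
#' @param x a `loading_signature` matrix.
#' @param ... passed to [graphics::stars()].
#' @return invisibly, `x`.
#' @export
plot.loading_signature <- function(x, ...) {
  m <- unclass(x)
  attr(m, "by_colour") <- NULL
  stars(pmax(m, 0) + 0.05, key.loc = c(ncol(m) + 1, 1), draw.segments = FALSE,
        labels = rownames(m), main = "loading signatures", ...)
  invisible(x)
}

#' Per-point silhouette display
#'
#' @param x a `silhouette_report`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.silhouette_report <- function(x, ...) {
  ord <- order(x$points$label, -x$points$s)
  graphics::barplot(x$points$s[ord], col = factor(x$points$label[ord]),
                    ylab = expression(s[i]), border = NA,
                    main = sprintf("Sil = %.3f (%s)", x$sil, x$variant))
  abline(h = 0)
  invisible(x)
}
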