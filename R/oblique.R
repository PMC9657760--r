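# Oblique (scalene) score coordinates for non-orthogonal decompositions,
# and spider-diagram loading signatures over selected peak windows.

#' Angle between two latent vectors
#'
#' `alpha = arccos( <u, v> / (||u|| ||v||) )`, in degrees. Non-orthogonal
#' decompositions (NMF, ICA) have inter-axis angles other than 90 degrees,
#' and their score plots must use scalene coordinates.
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return angle in degrees, in \[0, 180\].
#' @export
inter_axis_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stopf("zero vector has no direction")
  ca <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, ca))) * 180 / pi
}

#' Map two score columns into oblique plotting coordinates
#'
#' `(s1, s2) -> (s1 + s2 cos(alpha), s2 sin(alpha))`: Euclidean distance in
#' the plot equals the oblique-metric distance induced by two latent
#' vectors with inter-axis angle `alpha`. At `alpha = 90` this is the
#' identity.
#'
#' @param scores two-column matrix of scores.
#' @param alpha inter-axis angle in degrees, strictly between 0 and 180.
#' @return two-column matrix of plotting coordinates.
#' @export
oblique_scores <- function(scores, alpha) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 2) stopf("scores must have exactly two columns")
  if (alpha <= 0 || alpha >= 180) stopf("alpha must lie strictly in (0, 180)")
  a <- alpha * pi / 180
  cbind(x = scores[, 1] + scores[, 2] * cos(a), y = scores[, 2] * sin(a))
}

#' Loading signatures over selected peak windows (spider-diagram table)
#'
#' For every component and window, integrates the loading (net of the
#' straight baseline joining the window's endpoints) over each colour
#' sub-spectrum and sums the colours; each window's column is then divided
#' by its maximum absolute value over all components, so values lie in
#' \[-1, 1\] with at least one +/- 1 per window.
#'
#' @param decomposition a fitted decomposition carrying `feature_axis`
#'   metadata (fit on a `data_block`).
#' @param windows data frame of [peak_window()] rows.
#' @param modality which modality's features to integrate (default
#'   `"LIBS"`).
#' @return components x windows matrix of class `loading_signature`;
#'   attribute `"by_colour"` holds the unnormalised per-colour integrals
#'   (component x window x colour).
#' @export
loading_signature <- function(decomposition, windows, modality = "LIBS") {
  if (!nrow(windows)) stopf("no peak windows given")
  fa <- decomposition$feature_axis
  if (is.null(fa)) stopf("decomposition carries no feature-axis metadata")
  L <- decomposition$loadings
  colours <- unique(fa$colour)
  p <- ncol(L)
  W <- nrow(windows)
  by_colour <- array(0, dim = c(p, W, length(colours)),
                     dimnames = list(paste0("C", seq_len(p)), windows$label, colours))
  for (ci in seq_along(colours)) {
    sel <- fa$colour == colours[ci] & fa$modality == modality
    pos <- fa$position[sel]
    if (!length(pos)) next
    sub <- L[sel, , drop = FALSE]
    ord <- order(pos)
    pos <- pos[ord]; sub <- sub[ord, , drop = FALSE]
    for (w in seq_len(W)) {
      lo <- windows$center[w] - windows$half_width[w]
      hi <- windows$center[w] + windows$half_width[w]
      idx <- which(pos >= lo & pos <= hi)
      if (length(idx) < 2) next
      x <- pos[idx]
      n <- length(idx)
      for (j in seq_len(p)) {
        y <- sub[idx, j]
        base <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
        by_colour[j, w, ci] <- pracma::trapz(x, y - base)
      }
    }
  }
  M <- apply(by_colour, c(1, 2), sum)
  if (is.null(dim(M))) M <- matrix(M, nrow = p, ncol = W,
                                   dimnames = list(paste0("C", seq_len(p)),
                                                   windows$label))
  for (w in seq_len(W)) {
    mx <- max(abs(M[, w]))
    if (mx > 0) M[, w] <- M[, w] / mx
  }
  structure(M, by_colour = by_colour, class = c("loading_signature", "matrix"))
}
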