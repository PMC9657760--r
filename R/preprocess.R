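# Spot-level preprocessing: peak integration, iterative Grubbs outlier
# filtering, spot averaging, total-intensity normalisation, region masking,
# colour chaining and Frobenius-norm block fusion.

#' Define an integration window around a spectral peak
#'
#' @param label peak name.
#' @param center window centre, axis units.
#' @param half_width half width of the window, axis units, > 0.
#' @return one-row data frame (label, center, half_width).
#' @export
peak_window <- function(label, center, half_width) {
  if (half_width <= 0) stopf("half_width must be > 0")
  data.frame(label = label, center = center, half_width = half_width,
             stringsAsFactors = FALSE)
}

#' Default peak windows for the outlier filter
#'
#' The emission lines the filter is applied to, in order: Li I 610.3 nm,
#' C I 247.8 nm, Na I 568.3 nm, Ca II 396.8 nm and the C2 band head at
#' 473.6 nm, each with a +/- 0.5 nm window.
#'
#' @return data frame of peak windows.
#' @export
default_peak_windows <- function() {
  rbind(peak_window("Li I 610.3", 610.3, 0.5),
        peak_window("C I 247.8", 247.8, 0.5),
        peak_window("Na I 568.3", 568.3, 0.5),
        peak_window("Ca II 396.8", 396.8, 0.5),
        peak_window("C2 473.6", 473.6, 0.5))
}

#' Net integrated intensity of a peak
#'
#' Trapezoidal integral of the intensities over
#' \[center - half_width, center + half_width\] after subtracting the
#' straight line joining the window's endpoint intensities. May be
#' negative for noise-only windows.
#'
#' @param spectrum a `spot_spectrum`.
#' @param window a one-row [peak_window()] data frame (or list).
#' @return net peak area (axis units x intensity).
#' @export
integrate_peak <- function(spectrum, window) {
  a <- spectrum$axis
  if (window$center < a[1] || window$center > a[length(a)])
    stopf("peak window '%s' is outside the spectral axis", window$label)
  lo <- window$center - window$half_width
  hi <- window$center + window$half_width
  idx <- which(a >= lo & a <= hi)
  if (length(idx) < 2) stopf("peak window '%s' covers < 2 grid points", window$label)
  x <- a[idx]
  y <- spectrum$intensities[idx]
  n <- length(idx)
  base <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
  pracma::trapz(x, y - base)
}

# Two-sided Grubbs critical value at significance alpha for sample size n.
grubbs_critical <- function(n, alpha) {
  t2 <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Iterative two-sided Grubbs outlier test
#'
#' Repeatedly computes G = max |x_i - mean| / sd over the remaining
#' values and removes the most extreme point while G exceeds the
#' t-distribution critical value G_crit(n, alpha). The test is undefined
#' below n = 3, so removal stops once fewer than 3 values remain
#' (a 3-value group may lose one point). Zero-variance input keeps
#' everything.
#'
#' @param values numeric vector.
#' @param alpha two-sided significance level (default 0.05).
#' @return logical keep-mask, same length as `values`.
#' @export
grubbs_outliers <- function(values, alpha = 0.05) {
  if (length(values) == 0) stopf("empty input")
  if (any(!is.finite(values))) stopf("non-finite values in input")
  keep <- rep(TRUE, length(values))
  repeat {
    idx <- which(keep)
    n <- length(idx)
    if (n < 3) break
    x <- values[idx]
    s <- sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    if (g > grubbs_critical(n, alpha)) {
      keep[idx[which.max(dev)]] <- FALSE
    } else break
  }
  keep
}

spot_key <- function(s) paste(s$sample_id, s$colour, s$modality, sep = "|")

#' Filter replicate spots by sequential Grubbs tests on peak intensities
#'
#' For each window, in the listed order, the net integrated peak
#' intensities of the currently kept spots are screened with
#' [grubbs_outliers()]; a spot removed at any stage stays removed. At
#' least one spot always survives.
#'
#' @param spots list of `spot_spectrum` sharing sample, colour, modality
#'   and axis.
#' @param windows data frame of [peak_window()] rows.
#' @param alpha Grubbs significance level.
#' @return list of the kept `spot_spectrum` objects, with the keep-mask in
#'   attribute `"keep"`.
#' @export
filter_spots <- function(spots, windows = default_peak_windows(), alpha = 0.05) {
  if (!length(spots)) stopf("no spots to filter")
  keys <- vapply(spots, spot_key, "")
  if (length(unique(keys)) != 1)
    stopf("spots mix samples, colours or modalities: %s",
          paste(unique(keys), collapse = "; "))
  keep <- rep(TRUE, length(spots))
  if (length(spots) >= 3 && nrow(windows)) {
    for (w in seq_len(nrow(windows))) {
      idx <- which(keep)
      if (length(idx) < 3) break
      vals <- vapply(spots[idx], integrate_peak, 0, window = windows[w, ])
      keep[idx] <- grubbs_outliers(vals, alpha)
    }
  }
  if (!any(keep)) keep[1] <- TRUE  # unreachable with the n >= 3 rule; safety net
  structure(spots[keep], keep = keep)
}

#' Average replicate spots pointwise
#'
#' @param spots list of `spot_spectrum` on a common axis, same sample,
#'   colour and modality.
#' @return the mean `spot_spectrum`.
#' @export
average_spots <- function(spots) {
  if (!length(spots)) stopf("no spots to average")
  a <- spots[[1]]$axis
  for (s in spots[-1])
    if (length(s$axis) != length(a) || any(s$axis != a)) stopf("axis mismatch")
  m <- rowMeans(vapply(spots, function(s) s$intensities, numeric(length(a))))
  out <- spots[[1]]
  out$intensities <- m
  out$planted_outlier <- FALSE
  out$spot_id <- NA
  out
}

#' Normalise a spectrum to unit total intensity
#'
#' Divides the intensities by their sum; idempotent and scale-invariant.
#'
#' @param spectrum a `spot_spectrum` with positive total intensity.
#' @return the normalised `spot_spectrum` (intensities sum to 1).
#' @export
normalize_total <- function(spectrum) {
  tot <- sum(spectrum$intensities)
  if (!is.finite(tot) || tot <= 0) stopf("non-positive total intensity")
  spectrum$intensities <- spectrum$intensities / tot
  spectrum
}

#' Define a spectral region to discard
#'
#' @param lo,hi region bounds in axis units, `lo < hi`.
#' @param reason free-text justification, recorded in mask provenance.
#' @param modality `"LIBS"`, `"Raman"` or `NA` (applies to any modality).
#'   Restricting by modality keeps a wavelength region from also deleting
#'   Raman features at numerically equal shift positions in a fused block.
#' @return one-row data frame (lo, hi, reason, modality).
#' @export
mask_region <- function(lo, hi, reason = "", modality = "LIBS") {
  if (lo >= hi) stopf("mask region requires lo < hi")
  data.frame(lo = lo, hi = hi, reason = reason, modality = modality,
             stringsAsFactors = FALSE)
}

#' Default resonance-line mask regions
#'
#' Strongly self-absorbed resonance lines discarded before decomposition:
#' Na I 588.995/589.592, K I 766.49/769.90, Ca II 393.37/396.85 and
#' Mg II 279.55/280.27 nm, each +/- 0.5 nm.
#'
#' @return data frame of [mask_region()] rows.
#' @export
default_mask_regions <- function() {
  centers <- c(`Na I 589.0` = 588.995, `Na I 589.6` = 589.592,
               `K I 766.5` = 766.49, `K I 769.9` = 769.90,
               `Ca II 393.4` = 393.37, `Ca II 396.8` = 396.85,
               `Mg II 279.6` = 279.55, `Mg II 280.3` = 280.27)
  do.call(rbind, lapply(names(centers), function(nm)
    mask_region(centers[[nm]] - 0.5, centers[[nm]] + 0.5,
                reason = paste("resonance line", nm), modality = "LIBS")))
}

#' Mask regions covering the Li I lines
#'
#' Windows around 610.4 and 670.8 nm, used to test whether lithium drives
#' the classification.
#'
#' @param half_width half width of each region in nm.
#' @return data frame of [mask_region()] rows.
#' @export
li_mask_regions <- function(half_width = 0.5) {
  rbind(mask_region(610.4 - half_width, 610.4 + half_width, "Li I 610.4", "LIBS"),
        mask_region(670.8 - half_width, 670.8 + half_width, "Li I 670.8", "LIBS"))
}

#' Discard spectral regions from a spectrum or data block
#'
#' Drops every grid point (spectrum) or feature column (block) whose axis
#' position falls inside any region of matching modality. Provenance is
#' recorded: blocks accumulate a `mask_log`, spectra a `masked_regions`
#' attribute. Masking a block and masking spectra before assembly commute.
#'
#' @param x a `spot_spectrum` or `data_block`.
#' @param regions data frame of [mask_region()] rows.
#' @return the shortened object.
#' @export
apply_mask <- function(x, regions) UseMethod("apply_mask")

.mask_hits <- function(position, modality, regions) {
  hit <- rep(FALSE, length(position))
  for (r in seq_len(nrow(regions))) {
    m <- regions$modality[r]
    sel <- position >= regions$lo[r] & position <= regions$hi[r]
    if (!is.na(m)) sel <- sel & modality == m
    hit <- hit | sel
  }
  hit
}

#' @export
apply_mask.spot_spectrum <- function(x, regions) {
  if (!nrow(regions)) return(x)
  hit <- .mask_hits(x$axis, x$modality, regions)
  if (all(hit)) stopf("mask regions cover the entire axis")
  x$axis <- x$axis[!hit]
  x$intensities <- x$intensities[!hit]
  attr(x, "masked_regions") <- rbind(attr(x, "masked_regions"), regions)
  x
}

#' @export
apply_mask.data_block <- function(x, regions) {
  if (!nrow(regions)) return(x)
  hit <- .mask_hits(x$feature_axis$position, x$feature_axis$modality, regions)
  if (all(hit)) stopf("mask regions cover the entire feature axis")
  x$matrix <- x$matrix[, !hit, drop = FALSE]
  x$feature_axis <- x$feature_axis[!hit, , drop = FALSE]
  rownames(x$feature_axis) <- NULL
  if (isTRUE(x$frobenius_norm_applied)) {
    # restore the fusion contract (unit Frobenius norm per sub-block), so
    # masking before and after fusion commute
    for (m in unique(x$feature_axis$modality)) {
      cols <- x$feature_axis$modality == m
      nrm <- sqrt(sum(x$matrix[, cols]^2))
      if (nrm > 0) x$matrix[, cols] <- x$matrix[, cols] / nrm
    }
  }
  regions$n_removed <- NA_integer_
  regions$n_removed[1] <- sum(hit)
  x$mask_log <- rbind(x$mask_log, regions)
  x
}

#' Chain the three colour spectra of one sample into a feature vector
#'
#' Concatenation in the fixed order dark || medium || light; the output
#' length is three times the axis length and the feature metadata keeps
#' (modality, colour, position) per entry.
#'
#' @param dark,medium,light `spot_spectrum` objects of the same sample and
#'   modality on a common axis.
#' @return object of class `chained_spectrum`: list(values, feature_axis,
#'   sample_id, modality).
#' @export
chain_colours <- function(dark, medium, light) {
  sp <- list(dark = dark, medium = medium, light = light)
  if (any(vapply(sp, is.null, TRUE))) stopf("all three colours are required")
  mod <- dark$modality
  a <- dark$axis
  for (s in sp)
    if (s$modality != mod || length(s$axis) != length(a) || any(s$axis != a))
      stopf("colour spectra must share modality and axis")
  ids <- unique(vapply(sp, function(s) as.character(s$sample_id), ""))
  if (length(ids) > 1) stopf("colour spectra belong to different samples")
  values <- c(dark$intensities, medium$intensities, light$intensities)
  feature_axis <- data.frame(
    modality = mod,
    colour = rep(c("dark", "medium", "light"), each = length(a)),
    position = rep(a, 3),
    stringsAsFactors = FALSE)
  structure(list(values = values, feature_axis = feature_axis,
                 sample_id = ids, modality = mod),
            class = "chained_spectrum")
}

new_data_block <- function(matrix, row_ids, feature_axis, block_name,
                           frobenius_norm_applied = FALSE, mask_log = NULL) {
  if (anyNA(matrix)) stopf("data block contains missing values")
  if (nrow(feature_axis) != ncol(matrix))
    stopf("feature_axis length must equal the column count")
  if (anyDuplicated(row_ids)) stopf("duplicate sample ids in block")
  rownames(matrix) <- row_ids
  structure(list(matrix = matrix, row_ids = row_ids,
                 feature_axis = feature_axis, block_name = block_name,
                 frobenius_norm_applied = frobenius_norm_applied,
                 mask_log = mask_log),
            class = "data_block")
}

#' @export
print.data_block <- function(x, ...) {
  cat(sprintf("<data_block> '%s': %d samples x %d features%s%s\n",
              x$block_name, nrow(x$matrix), ncol(x$matrix),
              if (x$frobenius_norm_applied) " | Frobenius-scaled" else "",
              if (!is.null(x$mask_log)) sprintf(" | %d mask regions applied",
                                                nrow(x$mask_log)) else ""))
  invisible(x)
}

#' Assemble chained sample vectors into a samples x features block
#'
#' @param chained list of `chained_spectrum` objects of equal length with
#'   unique sample ids.
#' @param block_name label for the block.
#' @return a `data_block`.
#' @export
assemble_block <- function(chained, block_name = "block") {
  if (!length(chained)) stopf("no sample vectors to assemble")
  lens <- vapply(chained, function(x) length(x$values), 0L)
  if (length(unique(lens)) != 1) stopf("chained vectors differ in length")
  ids <- vapply(chained, function(x) as.character(x$sample_id), "")
  if (anyDuplicated(ids)) stopf("duplicate sample ids")
  m <- do.call(rbind, lapply(chained, function(x) x$values))
  new_data_block(m, ids, chained[[1]]$feature_axis, block_name)
}

#' Fuse data blocks by Frobenius-norm scaling and column concatenation
#'
#' Each block's matrix is divided by its Frobenius norm (so every scaled
#' sub-block has unit norm) and the blocks are column-concatenated in the
#' given order -- low-level data fusion.
#'
#' @param blocks list of `data_block` objects with identical `row_ids` in
#'   identical order.
#' @param block_name name of the fused block.
#' @return a `data_block` with `frobenius_norm_applied = TRUE`.
#' @export
fuse_blocks <- function(blocks, block_name = NULL) {
  if (!length(blocks)) stopf("no blocks to fuse")
  ids <- blocks[[1]]$row_ids
  mats <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    if (!identical(as.character(b$row_ids), as.character(ids)))
      stopf("blocks disagree in sample ids or order")
    nrm <- sqrt(sum(b$matrix^2))
    if (nrm == 0) stopf("block '%s' has zero Frobenius norm", b$block_name)
    mats[[k]] <- b$matrix / nrm
  }
  fa <- do.call(rbind, lapply(blocks, function(b) b$feature_axis))
  rownames(fa) <- NULL
  ml <- do.call(rbind, lapply(blocks, function(b) b$mask_log))
  nm <- block_name %||% paste(vapply(blocks, function(b) b$block_name, ""),
                              collapse = "+")
  new_data_block(do.call(cbind, mats), ids, fa, nm,
                 frobenius_norm_applied = TRUE, mask_log = ml)
}

#' Preprocess a spot dataset into per-modality data blocks
#'
#' Runs the standard chain per (sample, colour, modality) group: Grubbs
#' peak-intensity filtering of replicate LIBS spots, total-intensity
#' normalisation of Raman spots, pointwise averaging, then colour chaining
#' (dark || medium || light) and block assembly per modality.
#'
#' @param dataset a `spot_dataset` from [generate_dataset()] or
#'   [read_dataset()].
#' @param windows LIBS peak windows for the outlier filter.
#' @param alpha Grubbs significance level.
#' @param normalize_raman normalise each Raman spot to unit total
#'   intensity before averaging (default TRUE).
#' @return list with `LIBS` and `Raman` data blocks, the number of
#'   averaged spectra (`n_averaged`), and the removed-spot ids
#'   (`removed_spots`).
#' @export
blocks_from_dataset <- function(dataset, windows = default_peak_windows(),
                                alpha = 0.05, normalize_raman = TRUE) {
  meta <- dataset$meta
  blocks <- list()
  n_averaged <- 0L
  removed <- character(0)
  for (mod in c("LIBS", "Raman")) {
    sel <- meta$modality == mod
    sample_ids <- unique(meta$sample_id[sel])
    chained <- vector("list", length(sample_ids))
    for (i in seq_along(sample_ids)) {
      sid <- sample_ids[i]
      per_colour <- list()
      for (col in c("dark", "medium", "light")) {
        idx <- which(sel & meta$sample_id == sid & meta$colour == col)
        spots <- dataset$spectra[idx]
        if (mod == "LIBS") {
          kept <- filter_spots(spots, windows, alpha)
          km <- attr(kept, "keep")
          removed <- c(removed, meta$spot_id[idx][!km])
          spots <- kept
        } else if (normalize_raman) {
          spots <- lapply(spots, normalize_total)
        }
        per_colour[[col]] <- average_spots(spots)
        n_averaged <- n_averaged + 1L
      }
      chained[[i]] <- chain_colours(per_colour$dark, per_colour$medium,
                                    per_colour$light)
    }
    blocks[[mod]] <- assemble_block(chained, block_name = mod)
  }
  list(LIBS = blocks$LIBS, Raman = blocks$Raman,
       n_averaged = n_averaged, removed_spots = removed)
}
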