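# End-to-end orchestration: generate -> filter/average/normalise -> mask
# -> chain -> assemble -> fuse -> decompose -> silhouette, over the full
# comparison grid of methods x datasets x masking strata, emitting a
# one-row-per-cell report.

PIPELINE_METHODS <- c("PCA", "NMF", "ComDim-PCA", "ComDim-ICA")
PIPELINE_DATASETS <- c("LIBS", "Raman", "LIBS+Raman")
LABEL_SCHEMES <- c("four-taxa", "crustacea-merged", "calanoida-vs-euphausiacea")

#' Build a run configuration
#'
#' @param design a [study_design()].
#' @param grubbs_alpha significance level for the spot outlier filter.
#' @param peak_windows windows the filter is applied to, in order.
#' @param mask_regions regions discarded in the "shortened" stratum.
#' @param methods subset of `PCA`, `NMF`, `ComDim-PCA`, `ComDim-ICA`.
#' @param datasets subset of `LIBS`, `Raman`, `LIBS+Raman`.
#' @param masking strata to run: `raw` (no masking) and/or `shortened`.
#' @param n_components components per decomposition (>= 2).
#' @param nmf_restarts,nmf_tol,nmf_max_iter NMF settings.
#' @param silhouette_variant `"macro"` or `"micro"`.
#' @param label_schemes named list dataset -> label scheme. The defaults
#'   mirror the study: the subtle Calanoida/Euphausiacea split is not
#'   resolvable from Raman spectra, so Raman silhouettes use the merged
#'   Crustacea cluster, while LIBS and fused data compare Calanoida
#'   against Euphausiacea only.
#' @param seed root seed; every stage derives its own stream from it.
#' @param out_dir if non-NULL, artifacts (report.csv, blocks) are written
#'   there.
#' @param keep_models if TRUE the fitted decompositions are kept in the
#'   result (`$models[[stratum]][[dataset]][[method]]`).
#' @param verbose log one line per stage.
#' @return a `run_config` list.
#' @export
run_config <- function(design = study_design(),
                       grubbs_alpha = 0.05,
                       peak_windows = default_peak_windows(),
                       mask_regions = default_mask_regions(),
                       methods = PIPELINE_METHODS,
                       datasets = PIPELINE_DATASETS,
                       masking = c("raw", "shortened"),
                       n_components = 6L,
                       nmf_restarts = 20L, nmf_tol = 1e-6, nmf_max_iter = 500L,
                       silhouette_variant = "macro",
                       label_schemes = list(
                         "LIBS" = "calanoida-vs-euphausiacea",
                         "Raman" = "crustacea-merged",
                         "LIBS+Raman" = "calanoida-vs-euphausiacea"),
                       seed = NULL,
                       out_dir = NULL,
                       keep_models = FALSE,
                       verbose = FALSE) {
  methods <- match.arg(methods, PIPELINE_METHODS, several.ok = TRUE)
  datasets <- match.arg(datasets, PIPELINE_DATASETS, several.ok = TRUE)
  masking <- match.arg(masking, c("raw", "shortened"), several.ok = TRUE)
  if (n_components < 2) stopf("n_components must be >= 2")
  seed <- seed %||% design$seed
  if (is.null(seed)) stopf("a seed is required")
  structure(list(design = design, grubbs_alpha = grubbs_alpha,
                 peak_windows = peak_windows, mask_regions = mask_regions,
                 methods = methods, datasets = datasets, masking = masking,
                 n_components = as.integer(n_components),
                 nmf_restarts = as.integer(nmf_restarts),
                 nmf_tol = nmf_tol, nmf_max_iter = as.integer(nmf_max_iter),
                 silhouette_variant = silhouette_variant,
                 label_schemes = label_schemes, seed = as.integer(seed),
                 out_dir = out_dir, keep_models = keep_models,
                 verbose = verbose),
            class = "run_config")
}

#' Map taxa to cluster labels under a labelling scheme
#'
#' `four-taxa` keeps the four taxa (the mixed sample is dropped);
#' `crustacea-merged` pools Calanoida and Euphausiacea into `Crustacea`;
#' `calanoida-vs-euphausiacea` keeps only those two taxa.
#'
#' @param taxa character vector of taxon names.
#' @param scheme one of the schemes above.
#' @return character labels with `NA` for samples excluded by the scheme.
#' @export
labels_for_scheme <- function(taxa, scheme = LABEL_SCHEMES) {
  scheme <- match.arg(scheme)
  lab <- as.character(taxa)
  lab[lab == "Mixed"] <- NA
  if (scheme == "crustacea-merged") {
    lab[lab %in% c("Calanoida", "Euphausiacea")] <- "Crustacea"
  } else if (scheme == "calanoida-vs-euphausiacea") {
    lab[!lab %in% c("Calanoida", "Euphausiacea")] <- NA
  }
  lab
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[specfuse] ", fmt), ...))
}

fit_cell <- function(method, dataset, blocks, config, stage_seed) {
  pick <- function(ds) switch(ds,
    "LIBS" = list(blocks$LIBS), "Raman" = list(blocks$Raman),
    "LIBS+Raman" = list(blocks$LIBS, blocks$Raman))
  bl <- pick(dataset)
  p <- config$n_components
  if (method == "PCA") {
    # single-block PCA, or SUM-PCA on the Frobenius-scaled fused block
    x <- if (length(bl) == 1) bl[[1]] else fuse_blocks(bl)
    fit <- pca_fit(x, p)
    list(fit = fit, scores = fit$scores, total_ev = fit$total_ev)
  } else if (method == "NMF") {
    x <- if (length(bl) == 1) bl[[1]] else fuse_blocks(bl)
    x <- clip_negatives(x)
    fit <- nmf_fit(x, p, n_restarts = config$nmf_restarts, seed = stage_seed,
                   tol = config$nmf_tol, max_iter = config$nmf_max_iter)
    list(fit = fit, scores = fit$scores, total_ev = fit$total_ev)
  } else {
    inner <- if (method == "ComDim-PCA") "pca" else "ica"
    fit <- comdim(bl, p, inner_method = inner)
    list(fit = fit, scores = fit$Q, total_ev = mean(fit$block_ev))
  }
}

#' Run the full comparison pipeline
#'
#' Generates (or takes) a spot dataset, preprocesses it into per-modality
#' blocks, then for every masking stratum, dataset and method computes the
#' decomposition, the silhouette over all component planes and the
#' multidimensional subspace silhouette, returning a one-row-per-cell
#' report. PCA on the fused block is SUM-PCA. Deterministic under the
#' config seed; artifacts (report.csv, block CSV + JSON) are written when
#' `out_dir` is set.
#'
#' @param config a [run_config()].
#' @param dataset optionally, a pre-generated `spot_dataset` (the config
#'   design is then ignored for generation).
#' @return object of class `pipeline_result`: `report` (data frame:
#'   method, dataset, masking, total_ev, best_plane_i/j,
#'   best_plane_sil_pct, subspace_sil_pct), `n_averaged`,
#'   `removed_spots`, `blocks` (per stratum), optionally `models`, and
#'   `config`.
#' @export
run_pipeline <- function(config = run_config(seed = 1L), dataset = NULL) {
  stopifnot(inherits(config, "run_config"))
  v <- config$verbose
  if (is.null(dataset)) {
    log_stage(v, "generate: %d samples, seed %d",
              sum(config$design$taxon_counts), config$seed)
    dataset <- generate_dataset(config$design)
  }
  log_stage(v, "preprocess: %d spot spectra", nrow(dataset$meta))
  pre <- blocks_from_dataset(dataset, config$peak_windows, config$grubbs_alpha)
  log_stage(v, "preprocess: %d averaged spectra, %d spots removed",
            pre$n_averaged, length(pre$removed_spots))

  meta1 <- dataset$meta[!duplicated(dataset$meta$sample_id), ]
  taxa <- meta1$taxon[match(pre$LIBS$row_ids, meta1$sample_id)]

  rows <- list()
  models <- list()
  blocks_by_stratum <- list()
  for (stratum in config$masking) {
    blocks <- pre[c("LIBS", "Raman")]
    if (stratum == "shortened" && nrow(config$mask_regions)) {
      blocks <- lapply(blocks, apply_mask, regions = config$mask_regions)
      log_stage(v, "mask (%s): LIBS %d cols, Raman %d cols", stratum,
                ncol(blocks$LIBS$matrix), ncol(blocks$Raman$matrix))
    }
    blocks_by_stratum[[stratum]] <- blocks
    for (ds in config$datasets) {
      scheme <- config$label_schemes[[ds]] %||% "four-taxa"
      lab <- labels_for_scheme(taxa, scheme)
      keep <- !is.na(lab)
      for (method in config$methods) {
        stage_seed <- derive_seed(config$seed,
                                  1e4 + match(method, PIPELINE_METHODS) * 100 +
                                    match(ds, PIPELINE_DATASETS) * 10 +
                                    match(stratum, c("raw", "shortened")))
        cell <- fit_cell(method, ds, blocks, config, stage_seed)
        sc <- cell$scores[keep, , drop = FALSE]
        ps <- scan_planes(sc, lab[keep], config$silhouette_variant)
        sub_sil <- subspace_silhouette(sc, seq_len(ncol(sc)), lab[keep],
                                       config$silhouette_variant)
        log_stage(v, "%s | %s | %s: EV %.3f, best plane %d-%d Sil %.1f%%",
                  stratum, ds, method, cell$total_ev, ps$best_plane$j,
                  ps$best_plane$i, 100 * ps$best_plane$sil)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, dataset = ds, masking = stratum,
          total_ev = cell$total_ev,
          best_plane_i = ps$best_plane$i, best_plane_j = ps$best_plane$j,
          best_plane_sil_pct = 100 * ps$best_plane$sil,
          subspace_sil_pct = 100 * sub_sil,
          stringsAsFactors = FALSE)
        if (config$keep_models) models[[stratum]][[ds]][[method]] <- cell$fit
      }
    }
  }
  report <- do.call(rbind, rows)
  out <- structure(list(report = report, n_averaged = pre$n_averaged,
                        removed_spots = pre$removed_spots,
                        blocks = blocks_by_stratum,
                        models = if (config$keep_models) models else NULL,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(report, file.path(config$out_dir, "report.csv"),
              row.names = FALSE)
    bd <- file.path(config$out_dir, "blocks")
    dir.create(bd, showWarnings = FALSE)
    for (stratum in names(blocks_by_stratum))
      for (mod in c("LIBS", "Raman"))
        write_block(blocks_by_stratum[[stratum]][[mod]],
                    file.path(bd, sprintf("%s_%s.csv", mod, stratum)))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d report rows | %d averaged spectra | %d spots removed\n",
              nrow(x$report), x$n_averaged, length(x$removed_spots)))
  print(x$report, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Lithium-masking experiment
#'
#' Runs the pipeline on the shortened stratum with and without additional
#' mask regions over the Li I 610.4 / 670.8 nm lines and reports the
#' signed silhouette difference per method and dataset -- a direct test of
#' whether lithium drives the classification.
#'
#' @param config a [run_config()]; its masking is forced to `shortened`.
#' @param dataset optional pre-generated `spot_dataset` shared by both
#'   arms.
#' @return list: `base` and `li_masked` pipeline results and `delta`
#'   (per-cell Sil% differences, masked minus base).
#' @export
mask_li_experiment <- function(config = run_config(seed = 1L), dataset = NULL) {
  config$masking <- "shortened"
  if (is.null(dataset)) dataset <- generate_dataset(config$design)
  base <- run_pipeline(config, dataset)
  cfg2 <- config
  cfg2$mask_regions <- rbind(config$mask_regions, li_mask_regions())
  li <- run_pipeline(cfg2, dataset)
  delta <- base$report[, c("method", "dataset")]
  delta$best_plane_sil_pct_delta <-
    li$report$best_plane_sil_pct - base$report$best_plane_sil_pct
  delta$subspace_sil_pct_delta <-
    li$report$subspace_sil_pct - base$report$subspace_sil_pct
  list(base = base, li_masked = li, delta = delta)
}

#' Multi-seed study of the dataset / masking silhouette ordering
#'
#' Repeats the PCA route of the pipeline over `n_seeds` independently
#' seeded synthetic datasets and collects the best-plane silhouette for
#' every dataset (LIBS, Raman, fused) and masking stratum. Used to check
#' the directional claims: fused >= LIBS >= Raman in median best-plane
#' silhouette, and masking of resonance lines raises the silhouette.
#'
#' @param n_seeds number of independent replicate datasets.
#' @param config base configuration; `methods` is forced to `PCA`.
#' @param progress print one dot per seed.
#' @return list: `results` (long data frame: seed, dataset, masking,
#'   best_plane_sil_pct), `medians` (dataset x masking median table).
#' @export
fusion_ordering_study <- function(n_seeds = 50L, config = run_config(seed = 1L),
                                  progress = FALSE) {
  config$methods <- "PCA"
  rows <- list()
  for (i in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 20000L + i)
    cfg$design$seed <- cfg$seed
    res <- run_pipeline(cfg)
    r <- res$report
    r$seed <- cfg$seed
    rows[[i]] <- r[, c("seed", "dataset", "masking", "best_plane_sil_pct")]
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  results <- do.call(rbind, rows)
  medians <- aggregate(best_plane_sil_pct ~ dataset + masking, data = results,
                       FUN = median)
  list(results = results, medians = medians)
}
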