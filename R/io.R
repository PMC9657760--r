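# Plain-text interchange: wide CSV per modality (axis column + one
# intensity column per spot), a metadata TSV, data-block CSV with a JSON
# provenance sidecar, and YAML run configurations.

#' Write a spot dataset to disk
#'
#' One wide CSV per modality (`libs.csv`, `raman.csv`: column 1 the axis,
#' one column per spot named by spot id) and `metadata.tsv` (sample_id,
#' taxon, colour, spot_id, modality, planted_outlier).
#'
#' @param dataset a `spot_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (mod in c("LIBS", "Raman")) {
    idx <- which(dataset$meta$modality == mod)
    if (!length(idx)) next
    sp <- dataset$spectra[idx]
    df <- data.frame(axis = sp[[1]]$axis)
    for (s in sp) df[[s$spot_id]] <- s$intensities
    write.csv(df, file.path(dir, paste0(tolower(mod), ".csv")),
              row.names = FALSE)
  }
  write.table(dataset$meta, file.path(dir, "metadata.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a spot dataset written by [write_dataset()]
#'
#' @param dir directory containing `libs.csv` / `raman.csv` and
#'   `metadata.tsv`.
#' @return a `spot_dataset` (without a design).
#' @export
read_dataset <- function(dir) {
  meta <- read.delim(file.path(dir, "metadata.tsv"), stringsAsFactors = FALSE)
  spectra <- vector("list", nrow(meta))
  for (mod in c("LIBS", "Raman")) {
    path <- file.path(dir, paste0(tolower(mod), ".csv"))
    if (!file.exists(path)) next
    df <- read.csv(path, check.names = FALSE)
    axis <- df[[1]]
    rows <- which(meta$modality == mod)
    for (i in rows) {
      sid <- meta$spot_id[i]
      if (!sid %in% names(df)) stopf("spot '%s' missing from %s", sid, path)
      spectra[[i]] <- new_spot_spectrum(axis, df[[sid]], mod,
                                        sample_id = meta$sample_id[i],
                                        taxon = meta$taxon[i],
                                        colour = meta$colour[i],
                                        spot_id = sid,
                                        planted_outlier = isTRUE(meta$planted_outlier[i]))
    }
  }
  structure(list(spectra = spectra, meta = meta, design = NULL),
            class = "spot_dataset")
}

#' Write a data block as CSV plus a JSON provenance sidecar
#'
#' The CSV has one row per sample (first column `sample_id`); the sidecar
#' `<name>.json` records the feature axis, block name, Frobenius-scaling
#' flag and mask log.
#'
#' @param block a `data_block`.
#' @param path CSV path; the sidecar replaces the extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_block <- function(block, path) {
  df <- data.frame(sample_id = block$row_ids, block$matrix,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  meta <- list(block_name = block$block_name,
               frobenius_norm_applied = block$frobenius_norm_applied,
               n_features = ncol(block$matrix),
               feature_axis = block$feature_axis,
               mask_log = block$mask_log)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a data block written by [write_block()]
#' @param path CSV path (sidecar expected alongside).
#' @return a `data_block`.
#' @export
read_block <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  colnames(m) <- NULL
  new_data_block(m, df$sample_id, as.data.frame(meta$feature_axis),
                 meta$block_name,
                 frobenius_norm_applied = isTRUE(meta$frobenius_norm_applied),
                 mask_log = if (is.null(meta$mask_log)) NULL
                            else as.data.frame(meta$mask_log))
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file and merges it over the [run_config()] defaults. The
#' file must specify a `seed`. Design fields live under `design:`
#' (taxon_counts, spots_per_colour, outlier_rate, outlier_scale).
#'
#' @param path YAML file path.
#' @return a `run_config` list.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stopf("the run configuration must specify a seed")
  dz <- y$design %||% list()
  design_args <- list(seed = y$seed)
  for (f in c("spots_per_colour", "outlier_rate", "outlier_scale"))
    if (!is.null(dz[[f]])) design_args[[f]] <- dz[[f]]
  if (!is.null(dz$taxon_counts)) design_args$taxon_counts <- unlist(dz$taxon_counts)
  y$design <- do.call(study_design, design_args)
  do.call(run_config, y[names(y) %in% names(formals(run_config))])
}
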