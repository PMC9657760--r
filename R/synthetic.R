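# Synthetic LIBS / Raman spot spectra with taxon-specific structure.
#
# The generator emulates the geometry of a 29-pellet zooplankton study:
# 4 taxa plus one mixed sample, three visually distinct spot colours per
# pellet, >= 3 spots per colour per modality, full-range LIBS (186-1049 nm,
# 12,275 points) and Raman (450-3150 cm^-1, 2,801 points) grids. Every
# spectrum has known ground truth, so each downstream stage is testable.

MODALITIES <- c("LIBS", "Raman")
COLOURS <- c("dark", "medium", "light")
TAXA <- c("Calanoida", "Euphausiacea", "Parasagitta", "Limacina", "Mixed")

#' Default LIBS wavelength grid (186--1049 nm, 12,275 points)
#' @return numeric vector of wavelengths in nm.
#' @export
libs_grid <- function() seq(186, 1049, length.out = 12275L)

#' Default Raman shift grid (450--3150 cm^-1, 2,801 points)
#' @return numeric vector of Raman shifts in cm^-1.
#' @export
raman_grid <- function() seq(450, 3150, length.out = 2801L)

axis_range <- function(modality) {
  switch(modality, LIBS = c(186, 1049), Raman = c(450, 3150),
         stopf("unknown modality '%s'", modality))
}

#' Create a spectral feature (emission line or vibrational band)
#'
#' @param center axis position: nm for LIBS, cm^-1 for Raman.
#' @param relative_intensity dimensionless peak height, >= 0.
#' @param width full width at half maximum, in axis units, > 0.
#' @param label element / species / band name.
#' @param resonance logical; marks strongly self-absorbed resonance lines
#'   that the default mask regions remove downstream.
#' @return one-row data frame with columns center, relative_intensity,
#'   width, label, resonance.
#' @export
spectral_feature <- function(center, relative_intensity, width, label,
                             resonance = FALSE) {
  if (any(relative_intensity < 0)) stopf("relative_intensity must be >= 0")
  if (any(width <= 0)) stopf("width must be > 0")
  data.frame(center = center, relative_intensity = relative_intensity,
             width = width, label = label, resonance = resonance,
             stringsAsFactors = FALSE)
}

feats <- function(center, ri, width, label, res = FALSE) {
  spectral_feature(center, ri, width, label, res)
}

#' Build a taxon template
#'
#' A template holds the line/band inventory of one taxon for both
#' modalities, the per-colour intensity modulation, smooth background
#' polynomials and the relative noise scale.
#'
#' @param taxon one of `Calanoida`, `Euphausiacea`, `Parasagitta`,
#'   `Limacina`, `Mixed`.
#' @param libs_features,raman_features data frames as produced by
#'   [spectral_feature()] (row-bound).
#' @param colour_modulation named numeric vector over exactly
#'   dark/medium/light, all factors > 0.
#' @param background list with elements `LIBS` and `Raman`: polynomial
#'   coefficients (ascending powers) evaluated on the axis rescaled to
#'   \[0, 1\].
#' @param noise_sd relative heteroscedastic noise scale, >= 0.
#' @param sample_sd named vector (LIBS, Raman): log-normal sigma of the
#'   per-feature sample-level intensity multipliers. The Raman default is
#'   larger: pigment and amino-acid band intensities vary strongly
#'   between individuals, which is what limits Raman discrimination.
#' @param resonance_jitter_sd log-normal sigma of an extra per-spot
#'   multiplier applied to resonance-flagged lines only: strongly
#'   self-absorbed lines saturate erratically with plasma conditions, so
#'   their intensities carry little compositional information.
#' @param background_jitter_sd named vector (LIBS, Raman): log-normal
#'   sigma of a per-spot amplitude factor on the background polynomial
#'   (residual fluorescence varies from spot to spot; LIBS background is
#'   instrument-corrected, hence 0).
#' @return object of class `taxon_template`.
#' @export
taxon_template <- function(taxon, libs_features, raman_features,
                           colour_modulation = c(dark = 1.4, medium = 1, light = 0.65),
                           background = list(LIBS = 0.02,
                                             Raman = c(0.2, 0, 70, -280, 420, -280, 70)),
                           noise_sd = 0.02,
                           sample_sd = c(LIBS = 0.2, Raman = 0.6),
                           resonance_jitter_sd = 0.8,
                           background_jitter_sd = c(LIBS = 0, Raman = 0.5)) {
  taxon <- match.arg(taxon, TAXA)
  if (!setequal(names(colour_modulation), COLOURS))
    stopf("colour_modulation must be defined for exactly dark, medium, light")
  if (any(colour_modulation <= 0)) stopf("colour factors must be > 0")
  for (m in MODALITIES) {
    f <- if (m == "LIBS") libs_features else raman_features
    rng <- axis_range(m)
    if (nrow(f) && any(f$center < rng[1] | f$center > rng[2]))
      stopf("%s feature center outside the %g-%g axis range", m, rng[1], rng[2])
  }
  structure(list(taxon = taxon, libs_features = libs_features,
                 raman_features = raman_features,
                 colour_modulation = colour_modulation[COLOURS],
                 background = background, noise_sd = noise_sd,
                 sample_sd = sample_sd,
                 resonance_jitter_sd = resonance_jitter_sd,
                 background_jitter_sd = background_jitter_sd),
            class = "taxon_template")
}

# LIBS line width: detector FWHM is about 3 pixels on the 12,275-point grid.
.libs_w <- 3 * (1049 - 186) / 12274

# Mineral backbone shared by all taxa; per-taxon intensities scale it.
.libs_backbone <- function(scale) {
  rbind(
    feats(247.86, 1.2 * scale["C"],  .libs_w, "C I 247.8"),
    feats(388.34, 0.8 * scale["CN"], 1.5,     "CN 388.3"),
    feats(473.6,  0.7 * scale["C2"], 1.0,     "C2 473.6"),
    feats(656.28, 0.5 * scale["H"],  .libs_w, "H I 656.3"),
    feats(588.995, 12 * scale["Na"], .libs_w, "Na I 589.0", res = TRUE),
    feats(589.592, 6.0 * scale["Na"], .libs_w, "Na I 589.6", res = TRUE),
    feats(568.3,  0.5 * scale["Na"], .libs_w, "Na I 568.3"),
    feats(766.49, 8.0 * scale["K"],  .libs_w, "K I 766.5", res = TRUE),
    feats(769.90, 4.0 * scale["K"],  .libs_w, "K I 769.9", res = TRUE),
    feats(279.55, 4.0 * scale["Mg"], .libs_w, "Mg II 279.6", res = TRUE),
    feats(280.27, 3.2 * scale["Mg"], .libs_w, "Mg II 280.3", res = TRUE),
    feats(285.21, 0.6 * scale["Mg"], .libs_w, "Mg I 285.2"),
    feats(393.37, 8.0 * scale["Ca"], .libs_w, "Ca II 393.4", res = TRUE),
    feats(396.85, 7.2 * scale["Ca"], .libs_w, "Ca II 396.8", res = TRUE),
    feats(422.67, 1.5 * scale["Ca"], .libs_w, "Ca I 422.7"),
    feats(253.56, 0.4 * scale["P"],  .libs_w, "P I 253.6"),
    feats(407.77, 0.3 * scale["Sr"], .libs_w, "Sr II 407.8"),
    feats(324.75, 0.2 * scale["Cu"], .libs_w, "Cu I 324.8")
  )
}

.raman_fatty <- function(s = 1) {
  rbind(
    feats(1268, 0.6 * s, 12, "fatty acid 1268"),
    feats(1302, 0.8 * s, 12, "fatty acid 1302"),
    feats(1446, 1.0 * s, 14, "fatty acid 1446"),
    feats(1656, 0.9 * s, 14, "fatty acid 1656"),
    feats(2930, 1.1 * s, 25, "CH stretch 2930")
  )
}

.raman_carotenoid <- function(s = 1) {
  rbind(
    feats(1004, 2.5 * s, 10, "carotenoid 1004"),
    feats(1157, 3.0 * s, 12, "carotenoid 1157"),
    feats(1518, 3.5 * s, 14, "carotenoid 1518")
  )
}

#' Default taxon templates
#'
#' Encodes the qualitative spectral narrative of the study organisms:
#' the sea snail *Limacina helicina* (mineralised aragonite shell) has the
#' richest emission spectrum -- dominant Ca I/II with strong Na, K, Mg and
#' CaOH/CaCl molecular bands -- and the weakest Raman spectrum; *Calanoida*
#' copepods carry intense Li I lines at 610.4 and 670.8 nm and strong
#' carotenoid bands at 1004/1157/1518 cm^-1; arrow worms (*Parasagitta*)
#' are the least mineralised, with prominent C2/CN emission and amino-acid
#' Raman features at 755, 945, 486, 503 and 3013 cm^-1; *Euphausiacea*
#' show a phenyl-ring band at 1609 cm^-1. All taxa share fatty-acid bands
#' at 1268, 1302, 1446 and 1656 cm^-1. Relative intensities are free
#' parameters of the generator, not measurements.
#'
#' @return named list of [taxon_template()] objects, one per taxon.
#' @export
default_templates <- function() {
  sc <- function(...) {
    base <- c(C = 1, CN = 1, C2 = 1, H = 1, Na = 1, K = 1, Mg = 1, Ca = 1,
              P = 1, Sr = 1, Cu = 1)
    ov <- c(...)
    base[names(ov)] <- ov
    base
  }

  calanoida_libs <- rbind(
    .libs_backbone(sc(Ca = 1.0, Sr = 1.0)),
    feats(610.4, 2.5, .libs_w, "Li I 610.4"),
    feats(670.8, 3.5, .libs_w, "Li I 670.8")
  )
  calanoida_raman <- rbind(.raman_carotenoid(1), .raman_fatty(1))

  euphausiacea_libs <- .libs_backbone(
    sc(Ca = 1.8, Na = 1.2, K = 1.1, Mg = 1.2, Sr = 3.5, P = 1.5, Cu = 2))
  euphausiacea_raman <- rbind(
    feats(1609, 1.2, 12, "phenyl 1609"),
    .raman_carotenoid(0.2),
    .raman_fatty(0.9)
  )

  parasagitta_libs <- .libs_backbone(
    sc(C = 1.5, CN = 2.5, C2 = 3.6, H = 1.6, Na = 0.5, K = 0.4, Mg = 0.3,
       Ca = 0.35, P = 0.5, Sr = 0.15, Cu = 0.5))
  parasagitta_raman <- rbind(
    feats(755, 1.5, 10, "tryptophan 755"),
    feats(945, 1.2, 10, "valine 945"),
    feats(486, 1.0, 8,  "NH2 486"),
    feats(503, 1.0, 8,  "NH2 503"),
    feats(3013, 0.8, 15, "NH2 3013"),
    .raman_fatty(0.7)
  )

  limacina_libs <- rbind(
    .libs_backbone(sc(Ca = 3.0, Na = 1.7, K = 1.5, Mg = 2.0, Sr = 5,
                      C = 0.8, CN = 0.7, C2 = 0.6, H = 0.8, Cu = 1.5)),
    feats(430.25, 2.0, .libs_w, "Ca I 430.3"),
    feats(443.57, 1.8, .libs_w, "Ca I 443.6"),
    feats(445.48, 1.6, .libs_w, "Ca I 445.5"),
    feats(558.88, 1.0, .libs_w, "Ca I 558.9"),
    feats(554.0,  1.4, 6, "CaOH 554"),
    feats(622.0,  1.1, 6, "CaOH 622"),
    feats(593.5,  0.9, 4, "CaCl 593.5"),
    feats(618.9,  0.7, 4, "CaCl 618.9")
  )
  limacina_raman <- rbind(
    feats(1085, 0.4, 8, "carbonate 1085"),
    .raman_carotenoid(0.06),
    .raman_fatty(0.18)
  )

  mixed_libs <- rbind(
    .libs_backbone(sc(Ca = 1.4, Sr = 1.5, CN = 1.4, C2 = 1.6)),
    feats(610.4, 0.8, .libs_w, "Li I 610.4"),
    feats(670.8, 1.1, .libs_w, "Li I 670.8")
  )
  mixed_raman <- rbind(
    .raman_carotenoid(0.8),
    feats(1609, 0.5, 12, "phenyl 1609"),
    feats(755, 0.4, 10, "tryptophan 755"),
    .raman_fatty(1)
  )

  list(
    Calanoida    = taxon_template("Calanoida", calanoida_libs, calanoida_raman),
    Euphausiacea = taxon_template("Euphausiacea", euphausiacea_libs, euphausiacea_raman),
    Parasagitta  = taxon_template("Parasagitta", parasagitta_libs, parasagitta_raman),
    Limacina     = taxon_template("Limacina", limacina_libs, limacina_raman),
    Mixed        = taxon_template("Mixed", mixed_libs, mixed_raman)
  )
}

#' Study design for the synthetic dataset
#'
#' Defaults reproduce the study geometry: 29 pellets (14 Calanoida,
#' 11 Euphausiacea, 2 Parasagitta, 1 Limacina, 1 mixed), three spot
#' colours, at least 3 spots per colour per modality (>= 18 spot spectra
#' per sample), full instrument grids.
#'
#' @param taxon_counts named integer vector, taxon -> number of samples.
#' @param spots_per_colour spots per colour per modality, >= 3.
#' @param libs_grid,raman_grid axis grids.
#' @param outlier_rate fraction of spots replaced by planted anomalies.
#' @param outlier_scale multiplicative factor (> 1) of planted anomalies.
#' @param seed root seed for the whole dataset.
#' @return object of class `study_design`.
#' @export
study_design <- function(taxon_counts = c(Calanoida = 14, Euphausiacea = 11,
                                          Parasagitta = 2, Limacina = 1, Mixed = 1),
                         spots_per_colour = 3L,
                         libs_grid = specfuse::libs_grid(),
                         raman_grid = specfuse::raman_grid(),
                         outlier_rate = 0.05, outlier_scale = 5,
                         seed = 1L) {
  if (spots_per_colour < 3)
    stopf("spots_per_colour must be >= 3 (the Grubbs test needs n >= 3)")
  if (outlier_rate < 0 || outlier_rate > 1) stopf("outlier_rate must be in [0, 1]")
  if (outlier_rate > 0 && outlier_scale <= 1) stopf("outlier_scale must be > 1")
  if (!all(names(taxon_counts) %in% TAXA)) stopf("unknown taxon in taxon_counts")
  structure(list(taxon_counts = taxon_counts,
                 spots_per_colour = as.integer(spots_per_colour),
                 libs_grid = libs_grid, raman_grid = raman_grid,
                 outlier_rate = outlier_rate, outlier_scale = outlier_scale,
                 seed = as.integer(seed)),
            class = "study_design")
}

new_spot_spectrum <- function(axis, intensities, modality, sample_id = NA,
                              taxon = NA, colour = NA, spot_id = NA,
                              planted_outlier = FALSE) {
  if (length(axis) != length(intensities)) stopf("axis/intensity length mismatch")
  if (is.unsorted(axis, strictly = TRUE)) stopf("axis must be strictly increasing")
  structure(list(axis = axis, intensities = intensities, modality = modality,
                 sample_id = sample_id, taxon = taxon, colour = colour,
                 spot_id = spot_id, planted_outlier = planted_outlier),
            class = "spot_spectrum")
}

#' @export
print.spot_spectrum <- function(x, ...) {
  cat(sprintf("<spot_spectrum> %s %s | sample %s, %s spot %s | %d points [%g, %g]%s\n",
              x$modality, if (is.na(x$taxon)) "" else x$taxon, x$sample_id,
              x$colour, x$spot_id, length(x$axis), min(x$axis), max(x$axis),
              if (isTRUE(x$planted_outlier)) " | planted outlier" else ""))
  invisible(x)
}

eval_poly <- function(coefs, t) {
  y <- numeric(length(t))
  for (j in seq_along(coefs)) y <- y + coefs[j] * t^(j - 1)
  y
}

# Add a Gaussian profile with height h and FWHM w at `center`, evaluated
# only where it is non-negligible.
add_gaussian <- function(y, axis, center, h, w) {
  span <- 6 * w
  i1 <- findInterval(center - span, axis) + 1L
  i2 <- findInterval(center + span, axis)
  if (i2 < i1) return(y)
  idx <- i1:i2
  y[idx] <- y[idx] + h * exp(-log(16) * ((axis[idx] - center) / w)^2)
  y
}

#' Render one spot spectrum from a taxon template
#'
#' Forward model for acquisition: a sum of Gaussian line/band profiles
#' (height = relative intensity x colour factor x per-feature sample-level
#' log-normal multiplier), a smooth background polynomial, and
#' heteroscedastic Gaussian noise, clipped at zero. Deterministic under a
#' fixed seed.
#'
#' @param template a [taxon_template()].
#' @param modality `"LIBS"` or `"Raman"`.
#' @param colour `"dark"`, `"medium"` or `"light"`.
#' @param grid axis grid; defaults to the modality's instrument grid.
#' @param seed RNG seed for this spot.
#' @param sample_factors per-feature multipliers shared by all spots of one
#'   sample; `NULL` draws log-normal(0, 0.2) factors from a seed-derived
#'   stream.
#' @return a `spot_spectrum`.
#' @export
render_spectrum <- function(template, modality = c("LIBS", "Raman"),
                            colour = "medium", grid = NULL, seed = 1L,
                            sample_factors = NULL) {
  modality <- match.arg(modality)
  if (!colour %in% COLOURS)
    stopf("invalid colour '%s' (must be dark, medium or light)", colour)
  if (is.null(grid))
    grid <- if (modality == "LIBS") libs_grid() else raman_grid()
  f <- if (modality == "LIBS") template$libs_features else template$raman_features
  if (is.null(sample_factors)) {
    sample_factors <- if (nrow(f))
      with_seed(derive_seed(seed, 7919L),
                rlnorm(nrow(f), 0, template$sample_sd[[modality]]))
    else numeric(0)
  }
  cf <- template$colour_modulation[[colour]]
  heights <- f$relative_intensity * cf * sample_factors
  # self-absorbed resonance lines fluctuate erratically from spot to spot
  rj <- template$resonance_jitter_sd %||% 0
  if (rj > 0 && any(f$resonance)) {
    jit <- with_seed(derive_seed(seed, 3571L), rlnorm(sum(f$resonance), 0, rj))
    heights[f$resonance] <- heights[f$resonance] * jit
  }
  clean <- numeric(length(grid))
  if (nrow(f)) {
    for (i in seq_len(nrow(f)))
      clean <- add_gaussian(clean, grid, f$center[i], heights[i], f$width[i])
  }
  bg <- template$background[[modality]]
  if (!is.null(bg) && any(bg != 0)) {
    bj <- (template$background_jitter_sd %||% c(LIBS = 0, Raman = 0))[[modality]]
    amp <- if (bj > 0) with_seed(derive_seed(seed, 6007L), rlnorm(1, 0, bj)) else 1
    t <- (grid - grid[1]) / (grid[length(grid)] - grid[1])
    clean <- clean + amp * eval_poly(bg, t)
  }
  y <- clean
  if (template$noise_sd > 0) {
    floor_ <- 0.05 * max(clean, 1e-12)
    noise <- with_seed(derive_seed(seed, 104729L),
                       rnorm(length(grid), 0, template$noise_sd * (clean + floor_)))
    y <- clean + noise
  }
  y <- pmax(y, 0)
  new_spot_spectrum(grid, y, modality, taxon = template$taxon, colour = colour)
}

#' Plant an anomalous spot
#'
#' Multiplies the whole intensity vector by `scale` (> 1) and flags the
#' spot, producing the kind of gross anomaly the Grubbs filter must catch.
#'
#' @param spectrum a `spot_spectrum`.
#' @param scale multiplicative factor, must exceed 1.
#' @return the scaled, flagged `spot_spectrum`.
#' @export
inject_outlier <- function(spectrum, scale) {
  if (scale <= 1) stopf("outlier scale must be > 1")
  spectrum$intensities <- spectrum$intensities * scale
  spectrum$planted_outlier <- TRUE
  spectrum
}

#' Generate the full synthetic spot dataset
#'
#' For every sample: `spots_per_colour` spots per colour per modality
#' (>= 18 spot spectra per sample under the default design). A fraction
#' `outlier_rate` of spots is replaced by planted anomalies of factor
#' `outlier_scale`. Bit-reproducible for a fixed design seed.
#'
#' @param design a [study_design()].
#' @param templates named list of taxon templates; defaults to
#'   [default_templates()].
#' @return object of class `spot_dataset`: list with elements `spectra`
#'   (list of `spot_spectrum`), `meta` (data frame: sample_id, taxon,
#'   colour, spot_id, modality, planted_outlier) and `design`.
#' @export
generate_dataset <- function(design = study_design(),
                             templates = default_templates()) {
  stopifnot(inherits(design, "study_design"))
  counts <- design$taxon_counts
  taxa_seq <- rep(names(counts), times = counts)
  n_samples <- length(taxa_seq)
  sample_ids <- sprintf("S%02d", seq_len(n_samples))

  spectra <- vector("list", 0L)
  meta <- list()
  k <- 0L
  for (si in seq_len(n_samples)) {
    tpl <- templates[[taxa_seq[si]]]
    for (mod in MODALITIES) {
      f <- if (mod == "LIBS") tpl$libs_features else tpl$raman_features
      sfac <- with_seed(derive_seed(design$seed, si * 131L + match(mod, MODALITIES)),
                        rlnorm(max(nrow(f), 0L), 0, tpl$sample_sd[[mod]]))
      grid <- if (mod == "LIBS") design$libs_grid else design$raman_grid
      for (col in COLOURS) {
        for (sp in seq_len(design$spots_per_colour)) {
          k <- k + 1L
          spot_seed <- derive_seed(design$seed,
                                   ((si * 10L + match(mod, MODALITIES)) * 10L +
                                      match(col, COLOURS)) * 100L + sp)
          s <- render_spectrum(tpl, mod, col, grid = grid, seed = spot_seed,
                               sample_factors = sfac)
          planted <- design$outlier_rate > 0 &&
            with_seed(derive_seed(spot_seed, 577L), runif(1)) < design$outlier_rate
          if (planted) s <- inject_outlier(s, design$outlier_scale)
          s$sample_id <- sample_ids[si]
          s$spot_id <- sprintf("%s_%s_%s_%d", sample_ids[si], mod, col, sp)
          spectra[[k]] <- s
          meta[[k]] <- data.frame(sample_id = sample_ids[si],
                                  taxon = taxa_seq[si], colour = col,
                                  spot_id = s$spot_id, modality = mod,
                                  planted_outlier = planted,
                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  structure(list(spectra = spectra, meta = meta, design = design),
            class = "spot_dataset")
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("<spot_dataset> %d spot spectra | %d samples | %d planted outliers\n",
              nrow(x$meta), length(unique(x$meta$sample_id)),
              sum(x$meta$planted_outlier)))
  print(table(taxon = x$meta$taxon[!duplicated(x$meta$sample_id)]))
  invisible(x)
}
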