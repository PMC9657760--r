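# Shared fixtures and independent oracles. Everything here is generated in
# code at test time; no stored data.

# Brute-force O(n^2) silhouette with the all-outside-points b_i, written
# as plain loops so it is independent of the package implementation.
brute_silhouette <- function(points, labels, variant = "macro") {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    ain <- c(); bout <- c()
    for (j in seq_len(n)) {
      if (j == i) next
      if (labels[j] == labels[i]) ain <- c(ain, d(i, j)) else bout <- c(bout, d(i, j))
    }
    a <- if (length(ain)) mean(ain) else 0
    b <- if (length(bout)) mean(bout) else 0
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  if (variant == "micro") return(mean(s))
  mean(vapply(unique(labels), function(cl) mean(s[labels == cl]), 0))
}

# Independent statement of the two-sided Grubbs critical value.
ref_grubbs_crit <- function(n, alpha) {
  t <- qt(1 - alpha / (2 * n), n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

# A tiny two-feature template on the full axis ranges for fast rendering.
tiny_template <- function(noise_sd = 0, resonance_jitter_sd = 0,
                          background = list(LIBS = 0, Raman = 0),
                          sample_sd = c(LIBS = 0, Raman = 0)) {
  taxon_template(
    "Calanoida",
    libs_features = rbind(spectral_feature(400, 2, 0.5, "lineA"),
                          spectral_feature(700, 1, 0.5, "lineB")),
    raman_features = rbind(spectral_feature(1000, 2, 10, "bandA"),
                           spectral_feature(1500, 1, 10, "bandB")),
    background = background, noise_sd = noise_sd,
    sample_sd = sample_sd, resonance_jitter_sd = resonance_jitter_sd,
    background_jitter_sd = c(LIBS = 0, Raman = 0))
}

# Bare spot spectrum on an arbitrary axis (bypasses the renderer).
raw_spot <- function(intensities, axis = seq_along(intensities),
                     modality = "LIBS", sample_id = "S01", colour = "medium",
                     spot_id = "sp1") {
  specfuse:::new_spot_spectrum(axis, intensities, modality,
                               sample_id = sample_id, colour = colour,
                               spot_id = spot_id)
}

# Chained sample vectors on the full instrument grids, built from cheap
# random spectra -- used for geometry checks without running the renderer.
full_geometry_chained <- function(n_samples, modality, seed = 1) {
  grid <- if (modality == "LIBS") libs_grid() else raman_grid()
  set.seed(seed)
  lapply(seq_len(n_samples), function(i) {
    sid <- sprintf("S%02d", i)
    sp <- lapply(c("dark", "medium", "light"), function(col)
      raw_spot(runif(length(grid)), grid, modality, sid, col))
    chain_colours(sp[[1]], sp[[2]], sp[[3]])
  })
}

# Small design for pipeline tests: full study geometry but coarse grids,
# so end-to-end runs stay fast.
small_design <- function(seed = 1, ...) {
  study_design(libs_grid = seq(186, 1049, length.out = 3000),
               raman_grid = seq(450, 3150, length.out = 800),
               seed = seed, ...)
}

# Lazily cached default-design pipeline products shared across tests.
.fixture_env <- new.env(parent = emptyenv())
default_dataset <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- generate_dataset(study_design(seed = 101))
  .fixture_env$ds
}
default_blocks <- function() {
  if (is.null(.fixture_env$blocks))
    .fixture_env$blocks <- blocks_from_dataset(default_dataset())
  .fixture_env$blocks
}
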