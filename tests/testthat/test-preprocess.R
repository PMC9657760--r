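# Preprocessing: peak integration, Grubbs filtering, averaging,
# normalisation, masking, chaining and fusion.

test_that("net peak integration subtracts the endpoint baseline", {
  ax <- seq(300, 500, by = 0.05)
  w <- peak_window("w", 400, 5)

  expect_equal(integrate_peak(raw_spot(numeric(length(ax)), ax), w), 0)

  # a purely linear spectrum integrates to ~0 net area
  lin <- raw_spot(0.5 + 0.02 * ax, ax)
  expect_equal(integrate_peak(lin, w), 0, tolerance = 1e-9)

  # isolated unit-height Gaussian of FWHM fw inside the window: area
  # matches a dense quadrature oracle and the closed form 1.0645 * fw
  fw <- 1.2
  g <- exp(-log(16) * ((ax - 400) / fw)^2)
  oracle <- pracma::trapz(ax, g)
  got <- integrate_peak(raw_spot(g, ax), w)
  expect_equal(got, oracle, tolerance = 1e-6)
  expect_equal(got, 1.0645 * fw, tolerance = 0.001)

  expect_error(integrate_peak(raw_spot(g, ax), peak_window("far", 900, 5)),
               "outside")
})

test_that("iterative Grubbs matches an independent critical-value check", {
  expect_equal(grubbs_outliers(c(1, 1, 1, 1)), rep(TRUE, 4))   # zero variance
  expect_equal(grubbs_outliers(c(1, 5)), c(TRUE, TRUE))        # undefined n < 3
  expect_error(grubbs_outliers(numeric(0)), "empty")
  expect_error(grubbs_outliers(c(1, NA, 3)), "non-finite")

  x <- c(1, 2, 3, 100)
  g <- max(abs(x - mean(x))) / sd(x)
  expect_gt(g, ref_grubbs_crit(4, 0.05))       # the oracle agrees 100 is out
  expect_equal(grubbs_outliers(x, 0.05), c(TRUE, TRUE, TRUE, FALSE))

  # after removal the remaining three points are homogeneous
  expect_equal(grubbs_outliers(c(1, 2, 3), 0.05), rep(TRUE, 3))

  # critical values agree with the reference formula over a grid
  for (n in c(3, 5, 10, 30)) for (a in c(0.01, 0.05, 0.1))
    expect_equal(specfuse:::grubbs_critical(n, a), ref_grubbs_crit(n, a),
                 tolerance = 1e-12)
})

test_that("retention is monotone non-increasing in alpha", {
  set.seed(7)
  x <- c(rnorm(8), 4, -3.5)
  kept <- vapply(c(1e-6, 1e-3, 0.01, 0.05, 0.1, 0.3),
                 function(a) sum(grubbs_outliers(x, a)), 0)
  expect_equal(sum(grubbs_outliers(x, 1e-12)), length(x))  # alpha -> 0 keeps all
  expect_true(all(diff(kept) <= 0))
})

test_that("spot filtering removes a planted outlier and nothing else needed", {
  tpl <- tiny_template(noise_sd = 0.02)
  spots <- lapply(1:5, function(i)
    render_spectrum(tpl, "LIBS", "medium", seed = 100 + i, sample_factors = c(1, 1)))
  spots[[4]] <- inject_outlier(spots[[4]], 5)
  win <- rbind(peak_window("lineA", 400, 2), peak_window("lineB", 700, 2))
  kept <- filter_spots(spots, win)
  expect_false(attr(kept, "keep")[4])
  expect_true(all(attr(kept, "keep")[-4]))

  # single spot passes through untouched
  one <- filter_spots(spots[1], win)
  expect_length(one, 1)
  expect_identical(one[[1]], spots[[1]])

  # mixing modalities is refused
  bad <- c(spots[1:2], list(render_spectrum(tpl, "Raman", "medium", seed = 1)))
  expect_error(filter_spots(bad, win), "mix")
})

test_that("spot averaging is the pointwise mean", {
  a <- raw_spot(c(1, 2, 3))
  b <- raw_spot(c(3, 2, 1))
  expect_equal(average_spots(list(a, a))$intensities, a$intensities)
  expect_equal(average_spots(list(a, b))$intensities, c(2, 2, 2))
  expect_error(average_spots(list(a, raw_spot(c(1, 2, 3), axis = c(1, 2, 4)))),
               "axis mismatch")

  # SD of the mean of n i.i.d. noise spectra shrinks like sigma / sqrt(n)
  n <- 8; sigma <- 1
  devs <- vapply(1:200, function(s) {
    set.seed(s)
    spots <- lapply(1:n, function(i) raw_spot(rnorm(50, 10, sigma)))
    sd(average_spots(spots)$intensities - 10)
  }, 0)
  expect_equal(mean(devs), sigma / sqrt(n), tolerance = 0.05)
})

test_that("total-intensity normalisation is idempotent and scale invariant", {
  sp <- raw_spot(runif(100) + 0.1)
  n1 <- normalize_total(sp)
  expect_equal(sum(n1$intensities), 1, tolerance = 1e-12)
  expect_equal(normalize_total(n1)$intensities, n1$intensities)
  sp7 <- sp; sp7$intensities <- 7 * sp$intensities
  expect_equal(normalize_total(sp7)$intensities, n1$intensities)
  expect_error(normalize_total(raw_spot(numeric(10))), "total intensity")
})

test_that("masking drops exactly the grid points inside the regions", {
  grid <- libs_grid()
  sp <- raw_spot(runif(length(grid)), grid, "LIBS")
  expect_identical(apply_mask(sp, default_mask_regions()[0, ]), sp)

  reg <- mask_region(589, 590, "Na test", "LIBS")
  n_in <- sum(grid >= 589 & grid <= 590)
  masked <- apply_mask(sp, reg)
  expect_equal(length(masked$axis), length(grid) - n_in)
  expect_true(n_in > 0)

  # a Raman-tagged region leaves a LIBS spectrum alone
  expect_equal(length(apply_mask(sp, mask_region(589, 590, "", "Raman"))$axis),
               length(grid))

  expect_error(apply_mask(sp, mask_region(100, 2000, "all", "LIBS")),
               "entire")
})

test_that("colour chaining concatenates dark, medium, light in order", {
  grid <- libs_grid()
  mk <- function(col, val) raw_spot(rep(val, length(grid)), grid, "LIBS",
                                    sample_id = "S01", colour = col)
  ch <- chain_colours(mk("dark", 1), mk("medium", 2), mk("light", 3))
  expect_length(ch$values, 3 * 12275)
  expect_equal(unique(ch$feature_axis$colour), c("dark", "medium", "light"))
  expect_equal(ch$values[1], 1)
  expect_equal(ch$values[12276], 2)
  expect_equal(ch$values[2 * 12275 + 1], 3)

  rg <- raman_grid()
  mkr <- function(col) raw_spot(runif(length(rg)), rg, "Raman", colour = col)
  expect_length(chain_colours(mkr("dark"), mkr("medium"), mkr("light"))$values,
                3 * 2801)

  # three identical spectra give a 3-fold periodic vector
  s <- mk("dark", 0); s$intensities <- runif(length(grid))
  ch3 <- chain_colours(s, s, s)
  expect_equal(ch3$values[1:12275], ch3$values[12276:(2 * 12275)])

  expect_error(chain_colours(mk("dark", 1), NULL, mk("light", 3)), "three colours")
  other <- mk("medium", 2); other$sample_id <- "S02"
  expect_error(chain_colours(mk("dark", 1), other, mk("light", 3)),
               "different samples")
})

test_that("block assembly and Frobenius fusion give the fused geometry", {
  libs_ch <- full_geometry_chained(29, "LIBS", seed = 1)
  raman_ch <- full_geometry_chained(29, "Raman", seed = 2)
  bl <- assemble_block(libs_ch, "LIBS")
  br <- assemble_block(raman_ch, "Raman")
  expect_equal(dim(bl$matrix), c(29L, 36825L))
  expect_equal(dim(br$matrix), c(29L, 8403L))

  fused <- fuse_blocks(list(bl, br))
  expect_equal(dim(fused$matrix), c(29L, 45228L))
  expect_true(fused$frobenius_norm_applied)
  # each scaled sub-block has unit Frobenius norm
  expect_equal(sum(fused$matrix[, 1:36825]^2), 1, tolerance = 1e-12)
  expect_equal(sum(fused$matrix[, 36826:45228]^2), 1, tolerance = 1e-12)

  # single-block fusion is a unit-norm copy
  f1 <- fuse_blocks(list(bl))
  expect_equal(f1$matrix, bl$matrix / sqrt(sum(bl$matrix^2)))

  # identical blocks come out identical after scaling
  f2 <- fuse_blocks(list(bl, bl))
  expect_equal(f2$matrix[, 1:36825], f2$matrix[, 36826:(2 * 36825)])

  expect_error(assemble_block(list()), "no sample")
  expect_error(assemble_block(c(libs_ch[1], libs_ch[1])), "duplicate")
  short <- libs_ch[[2]]; short$values <- short$values[-1]
  short$feature_axis <- short$feature_axis[-1, ]
  expect_error(assemble_block(list(libs_ch[[1]], short)), "length")
  zb <- bl; zb$matrix[] <- 0
  expect_error(fuse_blocks(list(zb)), "zero Frobenius")
  br2 <- br; br2$row_ids <- rev(br2$row_ids); rownames(br2$matrix) <- br2$row_ids
  expect_error(fuse_blocks(list(bl, br2)), "ids")
})

test_that("masking commutes with fusion", {
  libs_ch <- full_geometry_chained(6, "LIBS", seed = 3)
  raman_ch <- full_geometry_chained(6, "Raman", seed = 4)
  bl <- assemble_block(libs_ch, "LIBS")
  br <- assemble_block(raman_ch, "Raman")
  regions <- rbind(mask_region(589, 590, "", "LIBS"),
                   mask_region(760, 775, "", "LIBS"),
                   mask_region(1000, 1010, "", "Raman"))
  a <- fuse_blocks(list(apply_mask(bl, regions), apply_mask(br, regions)))
  b <- apply_mask(fuse_blocks(list(bl, br)), regions)
  expect_equal(a$matrix, b$matrix, tolerance = 1e-12)
  expect_equal(a$feature_axis$position, b$feature_axis$position)
})

test_that("dataset preprocessing is deterministic and counts 174 spectra", {
  ds <- generate_dataset(small_design(seed = 31))
  p1 <- blocks_from_dataset(ds)
  p2 <- blocks_from_dataset(ds)
  expect_identical(p1$LIBS$matrix, p2$LIBS$matrix)
  expect_identical(p1$Raman$matrix, p2$Raman$matrix)
  expect_equal(p1$n_averaged, 174L)
  expect_equal(nrow(p1$LIBS$matrix), 29L)
  # Raman rows are chains of three unit-sum spectra
  expect_equal(unname(rowSums(p1$Raman$matrix)), rep(3, 29), tolerance = 1e-9)
})
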