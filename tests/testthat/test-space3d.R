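# Grid binning, occupancy statistics, property table and HSL color coding.

test_that("build_grid uses one global bin size and closed top edges", {
  coords <- rbind(c(-2, 0, 1), c(8, 3, -1), c(8, 8, 8), c(-2, -2, -2))
  g <- build_grid(coords, n_bins = 10)
  expect_equal(g$pc_min, -2)
  expect_equal(g$pc_max, 8)
  expect_equal(g$bin_size, 1)
  # global min on all axes -> (0,0,0); global max -> 9 not 10
  expect_equal(unname(g$cell_index[4, ]), c(0L, 0L, 0L))
  expect_equal(unname(g$cell_index[3, ]), c(9L, 9L, 9L))
  expect_equal(unname(g$cell_index[2, 1]), 9L)
  # identical rows share a cell
  g2 <- build_grid(rbind(c(0, 0, 0), c(1, 1, 1), c(1, 1, 1)), n_bins = 5)
  expect_equal(length(g2$cells), 2)
  expect_equal(max(lengths(g2$cells)), 2)
  expect_error(build_grid(coords, n_bins = 0), "n_bins")
})

test_that("cell membership conserves the molecule count", {
  withr::local_seed(21)
  coords <- matrix(rnorm(200 * 3), 200, 3)
  g <- build_grid(coords, n_bins = 50)
  expect_equal(sum(lengths(g$cells)), 200)
  expect_true(all(g$cell_index >= 0 & g$cell_index <= 49))
})

test_that("occupancy statistics match hand counts", {
  g <- build_grid(rbind(c(0, 0, 0), c(5, 5, 5), c(9, 9, 9)), n_bins = 10)
  expect_equal(occupancy_stats(g), 1)
  g <- build_grid(matrix(1, 4, 3), n_bins = 10)
  expect_equal(occupancy_stats(g), 0)
  g <- build_grid(rbind(c(0, 0, 0), c(0.01, 0.01, 0.01), c(9, 9, 9)),
                  n_bins = 10)
  expect_equal(occupancy_stats(g), 1 / 3)
})

test_that("unique fingerprint fraction matches hand counts", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  expect_equal(unique_fp_fraction(rbind(a, b, a + 10)), 1)
  expect_equal(unique_fp_fraction(rbind(a, a, a)), 0)
  expect_equal(unique_fp_fraction(rbind(a, a, b)), 1 / 3)
  expect_error(unique_fp_fraction(matrix(0, 0, 3)), "empty")
})

test_that("2D pixel statistic uses the same construction", {
  expect_equal(pixel_stats_2d(rbind(c(0, 0), c(1, 1), c(2, 2)), 10), 1)
  expect_equal(pixel_stats_2d(matrix(c(0, 0, 1, 1, 0, 0, 1, 1), 4, 2,
                                     byrow = TRUE), 10), 0)
})

test_that("3D single-occupancy >= 2D on the default construction", {
  withr::local_seed(22)
  coords <- matrix(rnorm(500 * 3), 500, 3)
  s3 <- occupancy_stats(build_grid(coords, 300))
  s2 <- pixel_stats_2d(coords[, 1:2], 300)
  expect_gte(s3, s2)
})

test_that("compute_properties matches manual counts", {
  lib <- standardize_library(parse_lines(c(
    "c1ccccc1 benzene", "CCCCCC hexane", "Nc1ccccc1 aniline")))
  p <- compute_properties(lib)
  expect_equal(p["benzene", "ringcount"], 1)
  expect_equal(p["benzene", "aromatic_c"], 6)
  expect_equal(p["benzene", "frac_aromatic"], 1)
  expect_equal(p["hexane", "aromatic_c"], 0)
  expect_equal(p["hexane", "frac_aromatic"], 0)
  expect_equal(p["hexane", "ringcount"], 0)
  expect_gte(p["aniline", "ncc_count"], 1)
  expect_gte(p["aniline", "hba_count"], 1)
  expect_equal(p["aniline", "hac"], 7)
  expect_true(all(as.matrix(p) >= 0))
  expect_true(all(p$frac_aromatic >= 0 & p$frac_aromatic <= 1))
})

test_that("color_cells anchors the hue ramp and bounds saturation", {
  withr::local_seed(23)
  coords <- matrix(runif(60 * 3), 60, 3)
  g <- build_grid(coords, n_bins = 20)
  vals <- data.frame(x = seq_len(60))
  cc <- color_cells(g, vals, "x")
  # minimum-mean cell at blue (240), maximum at magenta (-60 == 300)
  expect_equal(cc$hue[which.min(cc$mean_property)], 240)
  expect_equal(cc$hue[which.max(cc$mean_property)] %% 360, 300)
  expect_true(all(cc$saturation >= 0 & cc$saturation <= 1))
  expect_true(all(cc$lightness == 0.5))
  # hue decreases monotonically with the cell mean
  o <- order(cc$mean_property)
  expect_true(all(diff(cc$hue[o]) <= 1e-9))
  # rgb sanity at the anchors, on fully saturated cells (radius 0 keeps
  # single-member neighborhoods at zero spread, hence saturation 1)
  cc0 <- color_cells(g, vals, "x", radius = 0)
  lo <- which.min(cc0$mean_property); hi <- which.max(cc0$mean_property)
  expect_gt(cc0$b[lo], cc0$r[lo])
  expect_gt(cc0$r[hi], cc0$g[hi])

  # constant descriptor: same hue everywhere, saturation 1, local_std 0
  const <- data.frame(x = rep(3, 60))
  cc2 <- color_cells(g, const, "x")
  expect_equal(unique(cc2$hue), 240)
  expect_true(all(cc2$saturation == 1))
  expect_true(all(cc2$local_std == 0))
  expect_error(color_cells(g, vals, "nope"), "unknown descriptor")
})

test_that("saturation drops where the neighborhood gradient is strong", {
  # two molecules in adjacent cells with wildly different values ->
  # local std equals global std -> saturation 0 there
  coords <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(10, 10, 10))
  g <- build_grid(coords, n_bins = 10)
  vals <- data.frame(x = c(0, 100, 50))
  cc <- color_cells(g, vals, "x", radius = 5)
  expect_lt(min(cc$saturation), 1)
})

test_that("HSL to RGB conversion hits the standard anchors", {
  expect_equal(chemspace3d:::hsl_to_rgb(0, 1, 0.5), c(255L, 0L, 0L))
  expect_equal(chemspace3d:::hsl_to_rgb(120, 1, 0.5), c(0L, 255L, 0L))
  expect_equal(chemspace3d:::hsl_to_rgb(240, 1, 0.5), c(0L, 0L, 255L))
  expect_equal(chemspace3d:::hsl_to_rgb(-60, 1, 0.5), c(255L, 0L, 255L))
  expect_equal(chemspace3d:::hsl_to_rgb(60, 0, 0.5), c(128L, 128L, 128L))
})
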