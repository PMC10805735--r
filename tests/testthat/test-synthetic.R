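test_that("condition presets encode the intended radial laws", {
  d_in <- seq(0.005, 0.5, by = 0.005)
  d_out <- seq(1.5, 2, by = 0.005)
  ctrl <- condition_preset("control", rho = 3)$channel_laws$target
  expect_equal(mean(ctrl$f(d_in)) / mean(ctrl$f(d_out)), 3)
  flat <- condition_preset("RNAPI_inhibited_like")$channel_laws$target
  expect_equal(mean(flat$f(d_in)) / mean(flat$f(d_out)), 1)
  blm <- condition_preset("BLM_like", reduction = 0.5)$channel_laws$target
  dd <- seq(0, 2, by = 0.01)
  expect_equal(blm$f(dd), 0.5 * ctrl$f(dd))
  expect_equal(blm$baseline, 0.5 * ctrl$baseline)
  g4 <- condition_preset("G4_ligand_like")
  ctrl_shell <- condition_preset("control")$channel_laws$shell_marker
  expect_equal(g4$channel_laws$shell_marker$f(0.9), 0.5 * ctrl_shell$f(0.9))
  expect_error(condition_preset("nonsense"), "valid presets")
})

test_that("shell-marker law peaks in the shell annulus", {
  law <- condition_preset("control", shell_thickness = 0.25)$channel_laws$shell_marker
  expect_gt(law$f(0.9), law$f(0.5))
  expect_gt(law$f(0.8), law$f(1.1))
  expect_equal(law$f(0.74), law$f(0.1))  # core is uniform
})

test_that("noiseless step law renders exactly inside and outside disks", {
  spec <- do.call(synthetic_spec, noiseless_args(
    image_shape = c(160, 160), nucleus_radius = c(60, 0),
    nucleolus_radius = c(12, 0), nucleoli_per_nucleus = c(2, 2),
    channel_laws = list(target = law_step(1, 0, baseline = 0)),
    seed = 5))
  sim <- generate_field(spec)
  img <- sim$field$pixels$target
  lab <- sim$truth$nucleolus_mask$labels
  cen <- sim$truth$centroids
  R <- sim$truth$boundary_radius
  # strict interior (d clearly < 1) is 1; d clearly > 1 is 0
  for (j in 1:2) {
    rows <- matrix(0:159, 160, 160); cols <- t(rows)
    d <- sqrt((rows - cen[j, 1])^2 + (cols - cen[j, 2])^2) / R[j]
    expect_true(all(img[d < 0.98] == 1))
    other <- sqrt((rows - cen[-j, 1])^2 + (cols - cen[-j, 2])^2) / R[-j]
    expect_true(all(img[d > 1.02 & other > 1.02] == 0))
  }
  # truth mask matches the analytic disk membership
  expect_true(all(img[lab > 0 & img != 1] != 1) || all(img[lab > 0] == 1))
})

test_that("uniform law gives a constant nucleus interior before noise", {
  spec <- do.call(synthetic_spec, noiseless_args(
    image_shape = c(128, 128), nucleus_radius = c(50, 0),
    nucleolus_radius = c(10, 0), nucleoli_per_nucleus = c(1, 1),
    channel_laws = list(target = law_constant(3.5)), seed = 2))
  sim <- generate_field(spec)
  inside <- sim$truth$nucleus_mask$labels > 0
  expect_true(all(sim$field$pixels$target[inside] == 3.5))
  expect_true(all(sim$field$pixels$target[!inside] == 0))
})

test_that("identical spec and seed give bit-identical output", {
  spec <- synthetic_spec(image_shape = c(128, 128),
                         nucleus_radius = c(50, 2),
                         nucleolus_radius = c(9, 1),
                         nucleoli_per_nucleus = c(2, 3), seed = 7)
  a <- generate_field(spec)
  b <- generate_field(spec)
  expect_identical(a$field$pixels, b$field$pixels)
  expect_identical(a$truth$nucleolus_mask$labels, b$truth$nucleolus_mask$labels)
  expect_identical(a$truth$centroids, b$truth$centroids)
  expect_identical(a$truth$jitter, b$truth$jitter)
})

test_that("infeasible placement raises an explicit error", {
  spec <- synthetic_spec(image_shape = c(128, 128),
                         nucleus_radius = c(40, 0),
                         nucleolus_radius = c(15, 0),
                         nucleoli_per_nucleus = c(6, 6), seed = 1)
  expect_error(generate_field(spec), "placement failure")
})

test_that("radial law fidelity: analytic-d binning recovers the law", {
  spec <- do.call(synthetic_spec, noiseless_args(
    image_shape = c(256, 256), nucleus_radius = c(100, 0),
    nucleolus_radius = c(20, 0), nucleoli_per_nucleus = c(1, 1),
    condition = "control", seed = 3))
  sim <- generate_field(spec)
  cen <- sim$truth$centroids[1, ]
  orc <- pixel_binning_oracle(sim$field$pixels$target, cen,
                              sim$truth$boundary_radius[1])
  law <- sim$truth$channel_laws$target
  # bins aligned with the step edge: every bin mean equals the law value
  expect_equal(orc$mean[orc$n > 0],
               law$f(orc$bin_centers)[orc$n > 0], tolerance = 1e-12)
})

test_that("Poisson noise has unit variance-to-mean ratio on photon counts", {
  lambda <- 0.8; scale <- 150
  spec <- do.call(synthetic_spec, noiseless_args(
    image_shape = c(360, 360), nucleus_radius = c(170, 0),
    nucleolus_radius = c(10, 0), nucleoli_per_nucleus = c(1, 1),
    channel_laws = list(target = law_constant(lambda)),
    poisson_scale = scale, seed = 11))
  sim <- generate_field(spec)
  inside <- sim$truth$nucleus_mask$labels > 0
  counts <- sim$field$pixels$target[inside] * scale
  expect_gt(sum(inside), 5e4)
  expect_gt(stats::var(counts) / mean(counts), 0.9)
  expect_lt(stats::var(counts) / mean(counts), 1.1)
})

test_that("boundary irregularity perturbs the outline but keeps truth consistent", {
  spec <- do.call(synthetic_spec, noiseless_args(
    image_shape = c(160, 160), nucleus_radius = c(65, 0),
    nucleolus_radius = c(20, 0), nucleoli_per_nucleus = c(1, 1),
    irregularity = 0.15, seed = 9))
  sim <- generate_field(spec)
  lab <- sim$truth$nucleolus_mask$labels
  px <- which(lab == 1, arr.ind = TRUE) - 1
  cen <- sim$truth$centroids[1, ]
  dist <- sqrt((px[, 1] - cen[1])^2 + (px[, 2] - cen[2])^2)
  # radii vary beyond rounding: genuinely non-circular
  expect_gt(max(dist) - stats::quantile(dist, 0.99, names = FALSE), -1)
  expect_gt(diff(range(dist)), 3)
  # centroid still inside the region
  expect_equal(lab[round(cen[1]) + 1, round(cen[2]) + 1], 1L)
})

test_that("synthetic assay tables honour noiseless ground truth and seed", {
  tabs <- generate_assay_tables(seed = 4, params = list(gel_noise_cv = 0,
                                                        ct_noise_sd = 0))
  f <- crosslink_fraction_table(tabs$gel)
  expect_equal(f$fraction, f$true_fraction)
  # IP with true percent input equal to the aliquot fraction has Ct_IP = Ct_input
  pct <- chip_percent_input(tabs$chip)
  npm_water <- pct[pct$antibody == "NPM" & pct$condition == "water", ]
  expect_equal(npm_water$percent_input, rep(2, nrow(npm_water)))
  tabs2 <- generate_assay_tables(seed = 4, params = list(gel_noise_cv = 0,
                                                         ct_noise_sd = 0))
  expect_identical(tabs, tabs2)
  expect_error(generate_assay_tables(1, params = list(base_total = -5)))
})

test_that("no-psoralen control lanes protect almost nothing", {
  tabs <- generate_assay_tables(seed = 8)
  f <- crosslink_fraction_table(tabs$gel)
  expect_lt(mean(f$fraction[!f$psoralen]), 0.05)
  expect_gt(mean(f$fraction[f$psoralen & f$uv & f$condition == "underwound"]),
            0.5)
})
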