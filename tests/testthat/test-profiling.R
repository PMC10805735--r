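test_that("flat fields give flat profiles and equal window means", {
  dk <- make_disk_field(20, function(d) rep(4.2, length(d)), baseline = 4.2)
  p <- profile_nucleolus(dk$field, dk$mask, 1, role = "target")
  expect_true(all(abs(p$mean_intensity[!is.na(p$mean_intensity)] - 4.2) < 1e-6))
  wm <- window_means(p)
  expect_equal(wm$inside_mean, 4.2, tolerance = 1e-6)
  expect_equal(wm$outside_mean, 4.2, tolerance = 1e-6)
})

test_that("boundary radius is recovered within half a pixel on disks", {
  for (R in c(10, 25, 60)) {
    dk <- make_disk_field(R, function(d) ifelse(d <= 1, 1, 0))
    p <- profile_nucleolus(dk$field, dk$mask, 1, role = "target")
    rb <- p$boundary_radius[!is.na(p$boundary_radius)]
    expect_length(rb, p$params$n_rays)
    expect_lte(max(abs(rb - R)), 0.5)
  }
})

test_that("linear law is recovered within 0.02 of the per-pixel oracle", {
  dk <- make_disk_field(30, function(d) 1 - d / 2)
  p <- profile_nucleolus(dk$field, dk$mask, 1, role = "target")
  orc <- pixel_binning_oracle(dk$field$pixels$target, dk$center, dk$radius)
  ok <- orc$n >= 1 & p$n_samples >= 1
  expect_gt(sum(ok), 35)
  expect_lt(max(abs(p$mean_intensity[ok] - orc$mean[ok])), 0.02)
  # and within 0.02 of the analytic line itself
  expect_lt(max(abs(p$mean_intensity[ok] - (1 - p$bin_centers[ok] / 2))), 0.02)
})

test_that("step-law boundary crossing sits within one bin width of d = 1", {
  for (R in c(10, 20, 40, 60)) {
    dk <- make_disk_field(R, function(d) ifelse(d <= 1, 1, 0))
    p <- profile_nucleolus(dk$field, dk$mask, 1, role = "target")
    cross <- profile_midpoint_crossing(p$bin_centers, p$mean_intensity)
    expect_lt(abs(cross - 1), 0.05)
  }
})

test_that("samples outside the parent nucleus and inside neighbours are discarded", {
  spec <- do.call(synthetic_spec, noiseless_args(
    image_shape = c(200, 200), nucleus_radius = c(80, 0),
    nucleolus_radius = c(12, 0), nucleoli_per_nucleus = c(2, 2),
    condition = "control", seed = 5))
  sim <- generate_field(spec)
  p <- profile_nucleolus(sim$field, sim$truth$nucleolus_mask, 1,
                         nuclei = sim$truth$nucleus_mask)
  # noiseless control: every valid sample equals the law exactly, so no
  # sample can carry another nucleolus's core value at d > 1
  law <- sim$truth$channel_laws$target
  s <- p$samples
  expect_true(all(abs(s$intensity[s$d > 1.05] - law$baseline) < 0.51 * diff(range(law$f(c(0, 2))))))
  expect_true(all(s$d <= 2))
})

test_that("smoothing: identity window, constant invariance, convolution oracle", {
  dk <- make_disk_field(20, function(d) 1 - d / 2)
  p <- profile_nucleolus(dk$field, dk$mask, 1)
  expect_equal(smooth_profile(p, 1)$mean_intensity, p$mean_intensity)
  expect_error(smooth_profile(p, 4), "odd")

  pc <- p; pc$mean_intensity <- rep(2.5, length(pc$mean_intensity))
  expect_equal(smooth_profile(pc, 5)$mean_intensity, pc$mean_intensity)

  set.seed(1)
  pa <- p; pa$mean_intensity <- rnorm(40)
  sm <- smooth_profile(pa, 5)$mean_intensity
  conv <- stats::filter(pa$mean_intensity, rep(1 / 5, 5), sides = 2)
  core <- 3:38
  expect_equal(sm[core], as.numeric(conv)[core])

  # missing bins stay missing and are skipped, not imputed
  pm <- pa; pm$mean_intensity[10] <- NA
  smm <- smooth_profile(pm, 5)$mean_intensity
  expect_true(is.na(smm[10]))
  expect_equal(smm[12], mean(pm$mean_intensity[10:14], na.rm = TRUE))
})

test_that("aggregation across nucleoli uses the nucleolus as sampling unit", {
  dk <- make_disk_field(20, function(d) 1 - d / 2)
  p1 <- profile_nucleolus(dk$field, dk$mask, 1)
  s <- aggregate_profiles(list(p1, p1))
  expect_equal(s$mean, p1$mean_intensity)
  expect_true(all(s$sd[s$n_per_bin >= 2] == 0))
  expect_equal(s$n_nucleoli, 2)

  p2 <- p1
  p1$mean_intensity[] <- 1
  p2$mean_intensity[] <- 3
  s2 <- aggregate_profiles(list(p1, p2))
  expect_true(all(abs(s2$mean - 2) < 1e-12))
  expect_true(all(abs(s2$sd - sqrt(2)) < 1e-12))

  p3 <- p2
  p3$bin_centers <- p3$bin_centers + 0.01
  expect_error(aggregate_profiles(list(p1, p3)), "bin grid")
})

test_that("window means follow noiseless laws and the preset ratio", {
  dk <- make_disk_field(25, function(d) ifelse(d <= 1, 1, 0))
  wm <- window_means(profile_nucleolus(dk$field, dk$mask, 1))
  expect_equal(wm$inside_mean, 1, tolerance = 1e-9)
  expect_equal(wm$outside_mean, 0, tolerance = 1e-9)

  spec <- do.call(synthetic_spec, noiseless_args(
    image_shape = c(200, 200), nucleus_radius = c(80, 0),
    nucleolus_radius = c(15, 0), nucleoli_per_nucleus = c(1, 1),
    condition = "control", seed = 4))
  sim <- generate_field(spec)
  p <- profile_nucleolus(sim$field, sim$truth$nucleolus_mask, 1,
                         nuclei = sim$truth$nucleus_mask)
  wm2 <- window_means(p)
  expect_lt(abs(wm2$inside_mean / wm2$outside_mean - 3), 0.15)
})

test_that("overlapping or out-of-range windows are rejected", {
  dk <- make_disk_field(15, function(d) rep(1, length(d)))
  p <- profile_nucleolus(dk$field, dk$mask, 1)
  expect_error(window_means(p, inner = c(0, 1.6), outer = c(1.5, 2)),
               "overlap")
  expect_error(window_means(p, inner = c(0, 0.5), outer = c(1.5, 2.5)),
               "within")
})

test_that("undetectable boundaries exclude the nucleolus with a warning", {
  # mask whose indicator never drops below 0.5 along most rays: a label
  # filling the whole (tiny) image
  m <- matrix(1L, 21, 21)
  f <- image_field(list(target = matrix(1, 21, 21)), pixel_size = 0.1)
  expect_warning(
    p <- profile_nucleolus(f, labeled_mask(m), 1),
    "excluded")
  expect_null(p)
})

test_that("normalization modes behave as documented", {
  dk <- make_disk_field(20, function(d) 1 - d / 2, baseline = 0)
  p <- profile_nucleolus(dk$field, dk$mask, 1)
  s <- aggregate_profiles(list(p, p))
  expect_equal(normalize_summary(s, "none"), s)

  s2 <- s
  s2$mean <- 2 + 4 * (s$mean - min(s$mean)) / diff(range(s$mean))  # spans [2, 6]
  s2$sd <- rep(0.4, length(s2$sd))
  n2 <- normalize_summary(s2, "minmax")
  expect_equal(range(n2$mean), c(0, 1))
  expect_equal(n2$sd, s2$sd / 4)

  s3 <- s
  out_sel <- s$bin_centers >= 1.5 & s$bin_centers <= 2
  om <- mean(s3$mean[out_sel])
  n3 <- normalize_summary(s3, "mean_outside")
  expect_equal(n3$mean, s3$mean / om)

  s4 <- s; s4$mean[] <- 1
  expect_error(normalize_summary(s4, "minmax"), "degenerate")
})

test_that("profiles are stable under ray and step refinement", {
  spec <- do.call(synthetic_spec, c(compact_args(seed = 41,
                                                 nucleoli_per_nucleus = c(2, 2)),
                                    list(condition = "control")))
  sim <- generate_field(spec)
  base <- profile_nucleolus(sim$field, sim$truth$nucleolus_mask, 1,
                            nuclei = sim$truth$nucleus_mask,
                            n_rays = 180, step = 0.25)
  fine <- profile_nucleolus(sim$field, sim$truth$nucleolus_mask, 1,
                            nuclei = sim$truth$nucleus_mask,
                            n_rays = 360, step = 0.125)
  ok <- !is.na(base$mean_intensity) & !is.na(fine$mean_intensity)
  rel <- abs(base$mean_intensity[ok] - fine$mean_intensity[ok]) /
    max(abs(base$mean_intensity[ok]))
  expect_lt(max(rel), 0.01)
})

test_that("1-px mask dilation shifts the apparent boundary by at most 1.5 bins", {
  dk <- make_disk_field(20, function(d) ifelse(d <= 1, 1, 0))
  p0 <- profile_nucleolus(dk$field, dk$mask, 1)
  c0 <- profile_midpoint_crossing(p0$bin_centers, p0$mean_intensity)
  dil <- dk$mask
  dil$labels <- matrix(as.integer(
    EBImage::dilate(dk$mask$labels > 0, EBImage::makeBrush(3, "box"))),
    nrow(dk$mask$labels))
  p1 <- profile_nucleolus(dk$field, dil, 1)
  c1 <- profile_midpoint_crossing(p1$bin_centers, p1$mean_intensity)
  expect_lt(abs(c1 - c0), 1.5 * 0.05)
})
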