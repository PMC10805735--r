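test_that("well-separated bright nuclei are recovered with high IoU", {
  spec <- do.call(synthetic_spec, noiseless_args(
    image_shape = c(300, 300), n_cells = 2, nucleus_radius = c(60, 3),
    nucleolus_radius = c(10, 1), nucleoli_per_nucleus = c(1, 1),
    gaussian_noise_sd = 0.005, seed = 21))
  sim <- generate_field(spec)
  nuc <- segment_nuclei(sim$field)
  expect_length(mask_labels(nuc), 2)
  iou <- mask_iou(sim$truth$nucleus_mask, nuc)
  expect_true(all(iou$iou >= 0.95))
})

test_that("constant image raises a no-regions error", {
  f <- image_field(list(nucleus_marker = matrix(5, 64, 64)), pixel_size = 0.1)
  expect_error(segment_nuclei(f), "no regions")
})

test_that("segmentation is idempotent on a binary truth image", {
  spec <- do.call(synthetic_spec, noiseless_args(
    image_shape = c(200, 200), nucleus_radius = c(70, 0),
    nucleolus_radius = c(12, 1), nucleoli_per_nucleus = c(2, 2), seed = 3))
  sim <- generate_field(spec)
  binary <- (sim$truth$nucleus_mask$labels > 0) * 1
  f <- image_field(list(nucleus_marker = binary), pixel_size = 0.063)
  nuc <- segment_nuclei(f)
  expect_identical(nuc$labels > 0, sim$truth$nucleus_mask$labels > 0)
})

test_that("nucleoli are recovered inside nuclei with correct count and parent", {
  spec <- do.call(synthetic_spec, c(compact_args(seed = 31),
                                    list(condition = "control")))
  sim <- generate_field(spec)
  nuc <- segment_nuclei(sim$field, min_area = 5000)
  nol <- segment_nucleoli(sim$field, nuc, min_area = pi * 16)
  truth_n <- length(mask_labels(sim$truth$nucleolus_mask))
  expect_length(mask_labels(nol), truth_n)
  iou <- mask_iou(sim$truth$nucleolus_mask, nol)
  expect_gt(mean(iou$iou), 0.85)
  expect_true(all(nol$parent == 1L))
  # labels consecutive and no label spans two nuclei
  expect_identical(mask_labels(nol), seq_len(truth_n))
  for (l in mask_labels(nol)) {
    parents <- unique(nuc$labels[nol$labels == l])
    expect_length(parents[parents > 0], 1)
  }
})

test_that("zero shell signal yields zero labels without error", {
  spec <- do.call(synthetic_spec, noiseless_args(
    image_shape = c(160, 160), nucleus_radius = c(60, 0),
    nucleolus_radius = c(10, 0), nucleoli_per_nucleus = c(1, 1),
    channel_laws = list(nucleus_marker = law_constant(1),
                        shell_marker = law_constant(0.2)),
    gaussian_noise_sd = 0.01, seed = 2))
  sim <- generate_field(spec)
  nuc <- segment_nuclei(sim$field)
  nol <- segment_nucleoli(sim$field, nuc)
  expect_length(mask_labels(nol), 0)
})

test_that("hollow ring shell marker is filled: core pixels are inside the label", {
  spec <- do.call(synthetic_spec, noiseless_args(
    image_shape = c(200, 200), nucleus_radius = c(80, 0),
    nucleolus_radius = c(18, 0), nucleoli_per_nucleus = c(1, 1),
    channel_laws = list(
      nucleus_marker = law_constant(1),
      shell_marker = law_core_shell(core = 0.02, shell = 1,
                                    nucleoplasm = 0.02)),
    gaussian_noise_sd = 0.005, seed = 6))
  sim <- generate_field(spec)
  nuc <- segment_nuclei(sim$field)
  nol <- segment_nucleoli(sim$field, nuc)
  expect_length(mask_labels(nol), 1)
  cen <- sim$truth$centroids[1, ]
  # analytic core disk (d < 0.7) must be inside the filled label
  n <- 200
  rows <- matrix(0:(n - 1), n, n); cols <- t(rows)
  d <- sqrt((rows - cen[1])^2 + (cols - cen[2])^2) /
    sim$truth$boundary_radius[1]
  expect_true(all(nol$labels[d < 0.7] == 1L))
})

test_that("centroid matches symmetry, enumeration and single pixels", {
  m <- matrix(0L, 200, 160)
  rows <- matrix(0:199, 200, 160); cols <- matrix(0:159, 200, 160, byrow = TRUE)
  m[(rows - 100)^2 + (cols - 60)^2 <= 20^2] <- 1L
  disk <- labeled_mask(m)
  expect_lt(max(abs(centroid(disk, 1) - c(100, 60))), 0.5)

  lshape <- matrix(0L, 10, 10)
  px <- rbind(c(2, 2), c(3, 2), c(4, 2), c(4, 3), c(4, 4))  # 1-based
  lshape[px] <- 1L
  expect_equal(unname(centroid(labeled_mask(lshape), 1)),
               colMeans(px) - 1)

  single <- matrix(0L, 8, 8); single[4, 6] <- 1L
  expect_equal(unname(centroid(labeled_mask(single), 1)), c(3, 5))
  expect_error(centroid(labeled_mask(single), 2), "label 2")
})

test_that("3D masks give 3D centroids and labeling works across planes", {
  a <- array(0L, c(16, 16, 5))
  a[6:10, 6:10, 2:4] <- 1L
  m <- labeled_mask(a)
  expect_equal(unname(centroid(m, 1)), c(7, 7, 2))
  lab <- nucleoprofile:::label_components(a > 0)
  expect_equal(max(lab), 1L)
  a[1:2, 1:2, 1] <- 1L
  lab2 <- nucleoprofile:::label_components(a > 0)
  expect_equal(max(lab2), 2L)
})

test_that("nuclear mean intensity is exact on piecewise-constant fields", {
  lab <- matrix(0L, 60, 60)
  lab[10:20, 10:20] <- 1L
  lab[35:50, 30:50] <- 2L
  img <- matrix(0, 60, 60)
  img[lab == 1] <- 1; img[lab == 2] <- 3
  f <- image_field(list(target = img), pixel_size = 0.1)
  tab <- nuclear_mean_intensity(f, labeled_mask(lab), "target")
  expect_equal(tab$mean_intensity, c(1, 3))
  f2 <- image_field(list(target = matrix(7, 60, 60)), pixel_size = 0.1)
  expect_equal(nuclear_mean_intensity(f2, labeled_mask(lab),
                                      "target")$mean_intensity, c(7, 7))
})

test_that("noisy per-nucleus means stay within 3 standard errors of truth", {
  base <- 0.5
  spec <- synthetic_spec(image_shape = c(200, 200),
                         nucleus_radius = c(80, 0),
                         nucleolus_radius = c(10, 0),
                         nucleoli_per_nucleus = c(1, 1),
                         channel_laws = list(nucleus_marker = law_constant(1),
                                             target = law_constant(base)),
                         blur_sigma = 0, poisson_scale = 200,
                         gaussian_noise_sd = 0.01,
                         intensity_jitter_cv = 0, seed = 17)
  sim <- generate_field(spec)
  nuc <- segment_nuclei(sim$field)
  m <- nuclear_mean_intensity(sim$field, nuc, "target")$mean_intensity
  n_px <- sum(nuc$labels > 0)
  se <- sqrt(base / 200 + 0.01^2) / sqrt(n_px)
  expect_lt(abs(m - base), 3 * se)
})

test_that("raising the minimum-area filter never increases region count", {
  spec <- do.call(synthetic_spec, c(compact_args(seed = 12),
                                    list(condition = "control")))
  sim <- generate_field(spec)
  nuc <- segment_nuclei(sim$field, min_area = 5000)
  counts <- vapply(c(10, 50, 150, 300, 600), function(a)
    length(mask_labels(segment_nucleoli(sim$field, nuc, min_area = a))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("border-touching nuclei are flagged", {
  img <- matrix(0, 80, 80)
  img[1:20, 30:50] <- 1    # touches row border
  img[40:60, 30:50] <- 1   # interior
  f <- image_field(list(nucleus_marker = img), pixel_size = 0.1)
  nuc <- segment_nuclei(f, min_area = 100)
  expect_length(mask_labels(nuc), 2)
  expect_length(nuc$border, 1)
})
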