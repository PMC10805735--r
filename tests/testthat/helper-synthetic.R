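# Shared fixtures: everything is generated in code at test time.

# Compact geometry for simulation-heavy checks: same core-shell structure
# and SNR regime as the default spec, scaled down for speed.
compact_args <- function(...) {
  utils::modifyList(
    list(image_shape = c(200, 200), nucleus_radius = c(85, 4),
         nucleolus_radius = c(9, 1), nucleoli_per_nucleus = c(6, 6),
         blur_sigma = 1.2),
    list(...))
}

# Noise-free spec overrides (blur, shot/read noise and brightness jitter
# all off) for analytic-law tests.
noiseless_args <- function(...) {
  utils::modifyList(
    list(blur_sigma = 0, poisson_scale = NA, gaussian_noise_sd = 0,
         intensity_jitter_cv = 0),
    list(...))
}

# Hand-built single-disk field: intensity = f(dist / R) for d <= 2,
# baseline beyond; mask is the analytic disk. Returns field, mask, center,
# radius.
make_disk_field <- function(R, f, baseline = 0, pad = 2.4) {
  half <- ceiling(pad * R) + 2
  n <- 2 * half + 1
  cen <- c(half, half)  # 0-based center
  rows <- matrix(0:(n - 1), n, n)
  cols <- matrix(0:(n - 1), n, n, byrow = TRUE)
  dist <- sqrt((rows - cen[1])^2 + (cols - cen[2])^2)
  d <- dist / R
  img <- matrix(baseline, n, n)
  img[d <= 2] <- f(d[d <= 2])
  mask <- matrix(0L, n, n)
  mask[dist <= R] <- 1L
  list(field = image_field(list(target = img), pixel_size = 0.063,
                           field_id = sprintf("disk-R%g", R)),
       mask = labeled_mask(mask, source_role = "synthetic"),
       center = cen, radius = R)
}

# Independent per-pixel binning oracle: bins every pixel of the channel by
# its analytic normalized distance to the disk center.
pixel_binning_oracle <- function(img, center, R, n_bins = 40, d_max = 2) {
  n <- nrow(img)
  rows <- matrix(0:(n - 1), n, ncol(img))
  cols <- matrix(0:(ncol(img) - 1), n, ncol(img), byrow = TRUE)
  d <- sqrt((rows - center[1])^2 + (cols - center[2])^2) / R
  sel <- d <= d_max & d > 0
  width <- d_max / n_bins
  bin <- pmin(ceiling(d[sel] / width), n_bins)
  means <- rep(NA_real_, n_bins)
  agg <- tapply(img[sel], bin, mean)
  means[as.integer(names(agg))] <- agg
  counts <- rep(0L, n_bins)
  tb <- table(bin)
  counts[as.integer(names(tb))] <- as.integer(tb)
  list(bin_centers = width * (seq_len(n_bins) - 0.5), mean = means,
       n = counts)
}

# d at which a profile crosses the midpoint of its own range (linear
# interpolation between bin centers); locates the boundary of a step law.
profile_midpoint_crossing <- function(bin_centers, y) {
  ok <- !is.na(y)
  bc <- bin_centers[ok]; y <- y[ok]
  mid <- (max(y) + min(y)) / 2
  below <- which(y <= mid)
  i <- below[1]
  if (i == 1) return(bc[1])
  x0 <- bc[i - 1]; x1 <- bc[i]
  y0 <- y[i - 1]; y1 <- y[i]
  x0 + (y0 - mid) / (y0 - y1) * (x1 - x0)
}

# End-to-end dataset for one condition: simulate fields, segment, profile,
# return the first `n` per-nucleolus window means.
gen_condition_windows <- function(cond, seed, n = 60, n_rays = 72,
                                  step = 0.4, spec_args = compact_args()) {
  wml <- list(); fi <- 0
  while (sum(vapply(wml, nrow, 0L)) < n) {
    fi <- fi + 1
    spec <- do.call(synthetic_spec,
                    c(spec_args, list(condition = cond,
                                      seed = seed * 1000 + fi)))
    sim <- generate_field(spec)
    nuc <- segment_nuclei(sim$field, min_area = 5000)
    nol <- segment_nucleoli(sim$field, nuc, min_area = pi * 16)
    pf <- profile_field(sim$field, nol, nuc, n_rays = n_rays, step = step)
    wml[[fi]] <- window_means_table(pf$profiles)
  }
  out <- do.call(rbind, wml)[seq_len(n), ]
  attr(out, "profile_params") <- attr(wml[[1]], "profile_params")
  out
}
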