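# Boundary-normalized radial intensity profiling.
#
# For each nucleolus, rays are cast from the binary centroid; the boundary
# radius r_b(theta) is the first inside->outside crossing of the label
# indicator (sub-pixel, by linear interpolation of the bilinearly sampled
# indicator), and every intensity sample at radius r along that ray gets the
# normalized distance d = r / r_b(theta). d = 1 is the nucleolar outline;
# d in [0, 0.5] is the deep interior, d in [1.5, 2] the surrounding
# nucleoplasm.

#' Boundary-normalized radial profile of one nucleolus
#'
#' Casts `n_rays` equally spaced rays from the region centroid, locates the
#' boundary radius per ray, samples the channel by bilinear interpolation at
#' radial steps, assigns each sample its normalized distance d, and averages
#' samples into a uniform d-bin grid. Samples outside the parent nucleus,
#' inside a different nucleolus label, or outside the image are discarded.
#'
#' For z-stacks the profile is measured in the 2D plane nearest the 3D
#' centroid.
#'
#' @param field An [image_field()].
#' @param nucleoli A [labeled_mask()] of nucleoli.
#' @param label Nucleolus label to profile.
#' @param nuclei Optional [labeled_mask()] of nuclei (enables the
#'   parent-nucleus validity rule).
#' @param role Channel role to sample.
#' @param n_rays Number of ray directions.
#' @param step Radial sampling step in pixels.
#' @param d_max Profile extent in normalized distance.
#' @param n_bins Number of uniform d bins over \[0, d_max\].
#' @return A `radial_profile` (bin centers, per-bin mean intensity with NA
#'   for empty bins, per-bin sample counts, raw valid samples, boundary
#'   radii per ray), or NULL when the boundary is undetectable on more than
#'   half the rays (the exclusion reason is attached to the returned NULL's
#'   calling context via a warning).
#' @export
profile_nucleolus <- function(field, nucleoli, label, nuclei = NULL,
                              role = "target", n_rays = 180, step = 0.25,
                              d_max = 2, n_bins = 40) {
  stopifnot(inherits(field, "image_field"), inherits(nucleoli, "labeled_mask"),
            is_count(n_rays), step > 0, d_max > 0, is_count(n_bins))
  lab <- nucleoli$labels
  img <- get_channel(field, role)
  is3d <- length(dim(img)) == 3
  cen_full <- centroid(nucleoli, label)
  if (is3d) {
    z <- as.integer(round(cen_full[3])) + 1L
    img <- img[, , z]
    lab <- lab[, , z]
    nlab <- if (!is.null(nuclei)) nuclei$labels[, , z]
  } else {
    nlab <- if (!is.null(nuclei)) nuclei$labels
  }
  cen <- cen_full[1:2]
  if (!isTRUE(nearest_px(lab, cen[1], cen[2]) == label))
    stopf("centroid of label %d lies outside its region (concave shape); exclude this nucleolus",
          label)

  ind <- (lab == label) * 1
  px <- which(lab == label, arr.ind = TRUE) - 1
  r_search <- sqrt(max((px[, 1] - cen[1])^2 + (px[, 2] - cen[2])^2)) + 2
  theta <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  dirs <- cbind(cos(theta), sin(theta))
  rr <- seq(step, r_search, by = step)
  nr <- length(rr)

  rows <- outer(dirs[, 1], rr) + cen[1]
  cols <- outer(dirs[, 2], rr) + cen[2]
  M <- matrix(bilinear(ind, as.numeric(rows), as.numeric(cols)),
              n_rays, nr)
  Mna <- is.na(M)  # sample fell outside the image
  M[Mna] <- 0
  inside <- M >= 0.5

  rb <- rep(NA_real_, n_rays)
  for (i in seq_len(n_rays)) {
    if (!inside[i, 1]) next  # centroid pixel edge case: ray starts outside
    j <- which(!inside[i, ])[1]
    if (is.na(j)) next
    if (Mna[i, j]) next  # ray left the image while still inside the label
    m0 <- M[i, j - 1]; m1 <- M[i, j]
    rb[i] <- rr[j - 1] + step * (m0 - 0.5) / (m0 - m1)
  }
  n_ok <- sum(!is.na(rb))
  if (n_ok < n_rays / 2) {
    warning(sprintf("nucleolus %d excluded: boundary undetectable on %d/%d rays",
                    label, n_rays - n_ok, n_rays), call. = FALSE)
    return(NULL)
  }

  parent_lab <- if (!is.null(nucleoli$parent))
    nucleoli$parent[[as.character(label)]]
  else if (!is.null(nlab)) nearest_px(nlab, cen[1], cen[2])

  # sample all rays with a detected boundary
  samp <- vector("list", n_rays)
  for (i in seq_len(n_rays)) {
    if (is.na(rb[i])) next
    s <- seq(step, d_max * rb[i], by = step)
    if (!length(s)) next
    samp[[i]] <- cbind(r = s, row = cen[1] + dirs[i, 1] * s,
                       col = cen[2] + dirs[i, 2] * s, d = s / rb[i])
  }
  samp <- do.call(rbind, samp)
  inten <- bilinear(img, samp[, "row"], samp[, "col"])
  valid <- !is.na(inten)
  if (!is.null(nlab) && !is.null(parent_lab)) {
    nl_at <- nearest_px(nlab, samp[, "row"], samp[, "col"])
    valid <- valid & !is.na(nl_at) & nl_at == parent_lab
  }
  other <- nearest_px(lab, samp[, "row"], samp[, "col"])
  valid <- valid & !is.na(other) & (other == 0 | other == label)

  d <- samp[valid, "d"]
  v <- inten[valid]
  width <- d_max / n_bins
  bin <- pmin(pmax(ceiling(d / width), 1L), n_bins)
  sums <- rep(0, n_bins); cnt <- rep(0L, n_bins)
  agg <- rowsum(v, bin)
  cnt_t <- table(bin)
  idx <- as.integer(rownames(agg))
  sums[idx] <- agg[, 1]
  cnt[as.integer(names(cnt_t))] <- as.integer(cnt_t)
  meanv <- ifelse(cnt > 0, sums / pmax(cnt, 1L), NA_real_)

  structure(list(
    nucleolus_id = label,
    field_id = field$field_id,
    cell_id = if (!is.null(parent_lab)) as.integer(parent_lab) else NA_integer_,
    condition = field$condition,
    bin_centers = width * (seq_len(n_bins) - 0.5),
    mean_intensity = meanv,
    n_samples = cnt,
    rays_used = n_ok,
    boundary_radius = rb,
    samples = data.frame(d = d, intensity = v),
    params = list(role = role, n_rays = n_rays, step = step, d_max = d_max,
                  n_bins = n_bins, smoothed = 0L)),
    class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat("Radial profile: nucleolus ", x$nucleolus_id, " (cell ", x$cell_id,
      ", field '", x$field_id, "')\n", sep = "")
  cat("  ", length(x$bin_centers), " bins over d in [0, ",
      x$params$d_max, "], ", nrow(x$samples), " valid samples, ",
      x$rays_used, "/", x$params$n_rays, " rays\n", sep = "")
  invisible(x)
}

#' Profile every nucleolus in a field
#'
#' Convenience wrapper looping [profile_nucleolus()] over all labels,
#' collecting exclusions (undetectable boundary, border-touching parent)
#' with machine-readable reasons.
#'
#' @inheritParams profile_nucleolus
#' @param exclude_border_nuclei Drop nucleoli whose parent nucleus touches
#'   the image border.
#' @param ... Passed to [profile_nucleolus()].
#' @return List with `profiles` (list of `radial_profile`) and `exclusions`
#'   (data frame label/reason).
#' @export
profile_field <- function(field, nucleoli, nuclei = NULL, role = "target",
                          exclude_border_nuclei = FALSE, ...) {
  profiles <- list()
  excl <- list()
  for (l in mask_labels(nucleoli)) {
    if (exclude_border_nuclei && !is.null(nucleoli$parent) &&
        !is.null(nuclei) &&
        nucleoli$parent[[as.character(l)]] %in% nuclei$border) {
      excl[[length(excl) + 1L]] <- data.frame(label = l, reason = "border")
      next
    }
    p <- withCallingHandlers(
      profile_nucleolus(field, nucleoli, l, nuclei = nuclei, role = role, ...),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(p)) {
      excl[[length(excl) + 1L]] <- data.frame(label = l, reason = "no-boundary")
    } else {
      profiles[[length(profiles) + 1L]] <- p
    }
  }
  list(profiles = profiles,
       exclusions = if (length(excl)) do.call(rbind, excl)
       else data.frame(label = integer(0), reason = character(0)))
}

#' Moving-average smoothing of a radial profile
#'
#' Centered moving average over bins with the window shrinking symmetrically
#' at the edges. Missing bins are skipped, not imputed: they stay missing
#' and do not contribute to their neighbours' averages.
#'
#' @param profile A `radial_profile`.
#' @param window Odd window length in bins (1 = identity).
#' @return The smoothed `radial_profile`.
#' @export
smooth_profile <- function(profile, window = 5) {
  stopifnot(inherits(profile, "radial_profile"))
  if (window %% 2 == 0) stopf("smoothing window must be odd, got %d", window)
  y <- profile$mean_intensity
  n <- length(y)
  h <- (window - 1) / 2
  out <- y
  for (i in seq_len(n)) {
    if (is.na(y[i])) next
    hi <- min(h, i - 1, n - i)  # symmetric shrink at edges
    win <- y[(i - hi):(i + hi)]
    out[i] <- mean(win, na.rm = TRUE)
  }
  profile$mean_intensity <- out
  profile$params$smoothed <- as.integer(window)
  profile
}

#' Aggregate radial profiles across nucleoli
#'
#' Per-bin mean and sample standard deviation across nucleoli (each
#' nucleolus contributes one number per bin; the nucleolus is the sampling
#' unit, pooled across cells). Bins to which fewer than two nucleoli
#' contribute have their s.d. marked missing.
#'
#' @param profiles List of `radial_profile` sharing one bin grid.
#' @return A `profile_summary` with per-bin `mean`, `sd`, `n_per_bin`, and
#'   counts `n_nucleoli`, `n_cells`.
#' @export
aggregate_profiles <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  for (p in profiles) stopifnot(inherits(p, "radial_profile"))
  bc <- profiles[[1]]$bin_centers
  for (p in profiles[-1])
    if (!isTRUE(all.equal(p$bin_centers, bc)))
      stopf("profiles do not share one bin grid")
  B <- do.call(rbind, lapply(profiles, function(p) p$mean_intensity))
  n_per_bin <- colSums(!is.na(B))
  m <- colMeans(B, na.rm = TRUE)
  m[n_per_bin == 0] <- NA_real_
  s <- apply(B, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2) NA_real_ else stats::sd(col)
  })
  cells <- unique(vapply(profiles, function(p)
    paste(p$field_id, p$cell_id, sep = "/"), ""))
  conds <- unique(vapply(profiles, function(p) p$condition, ""))
  structure(list(bin_centers = bc, mean = m, sd = s, n_per_bin = n_per_bin,
                 n_nucleoli = length(profiles), n_cells = length(cells),
                 condition = paste(conds, collapse = "+"),
                 normalization = "none",
                 params = profiles[[1]]$params),
            class = "profile_summary")
}

#' @export
print.profile_summary <- function(x, ...) {
  cat("Profile summary (", x$condition, "): n = ", x$n_nucleoli,
      " nucleoli / ", x$n_cells, " cells, ", length(x$bin_centers),
      " bins, normalization: ", x$normalization, "\n", sep = "")
  invisible(x)
}

#' Inside/outside window means for one nucleolus
#'
#' Means of the raw valid samples (never the smoothed bins) over the deep
#' interior window d in \[0, 0.5\] and the nucleoplasm window d in
#' \[1.5, 2.0\], window edges inclusive. A nucleolus with an empty window is
#' excluded (NULL return).
#'
#' @param profile A `radial_profile`.
#' @param inner,outer Window bounds in d.
#' @return One-row data frame (`field_id`, `cell_id`, `nucleolus_id`,
#'   `condition`, `inside_mean`, `outside_mean`, `n_inside`, `n_outside`)
#'   or NULL if a window has no valid sample.
#' @export
window_means <- function(profile, inner = c(0, 0.5), outer = c(1.5, 2)) {
  stopifnot(inherits(profile, "radial_profile"),
            length(inner) == 2, length(outer) == 2,
            inner[1] < inner[2], outer[1] < outer[2])
  if (inner[2] > outer[1] && outer[2] > inner[1])
    stopf("inside and outside windows overlap")
  dmx <- profile$params$d_max
  if (inner[1] < 0 || outer[2] > dmx)
    stopf("windows must lie within [0, %g]", dmx)
  s <- profile$samples
  ins <- s$intensity[s$d >= inner[1] & s$d <= inner[2]]
  out <- s$intensity[s$d >= outer[1] & s$d <= outer[2]]
  if (!length(ins) || !length(out)) return(NULL)
  data.frame(field_id = profile$field_id, cell_id = profile$cell_id,
             nucleolus_id = profile$nucleolus_id,
             condition = profile$condition,
             inside_mean = mean(ins), outside_mean = mean(out),
             n_inside = length(ins), n_outside = length(out))
}

#' Window means for a list of profiles
#'
#' @param profiles List of `radial_profile`.
#' @inheritParams window_means
#' @return Data frame of per-nucleolus window means with profiling
#'   parameters attached as `attr(, "profile_params")` and exclusions as
#'   `attr(, "exclusions")`.
#' @export
window_means_table <- function(profiles, inner = c(0, 0.5), outer = c(1.5, 2)) {
  rows <- list(); excl <- list()
  for (p in profiles) {
    wm <- window_means(p, inner, outer)
    if (is.null(wm)) {
      excl[[length(excl) + 1L]] <- data.frame(
        field_id = p$field_id, nucleolus_id = p$nucleolus_id,
        reason = "empty-window")
    } else rows[[length(rows) + 1L]] <- wm
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(field_id = character(0), cell_id = integer(0),
               nucleolus_id = integer(0), condition = character(0),
               inside_mean = numeric(0), outside_mean = numeric(0),
               n_inside = integer(0), n_outside = integer(0))
  rownames(out) <- NULL
  attr(out, "profile_params") <- if (length(profiles))
    c(profiles[[1]]$params[c("n_rays", "step", "d_max", "n_bins")],
      list(inner = inner, outer = outer))
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl)
  out
}

#' Normalize an aggregated profile summary
#'
#' `none` is the identity; `minmax` affinely maps the mean curve to
#' \[0, 1\] and scales the s.d. band by the same factor; `mean_outside`
#' divides the curve by its mean over the outside window. The mode is
#' recorded in the summary.
#'
#' @param summary A `profile_summary`.
#' @param mode One of `none`, `minmax`, `mean_outside`.
#' @param outer Outside window used by `mean_outside`.
#' @return The normalized `profile_summary`.
#' @export
normalize_summary <- function(summary, mode = c("none", "minmax",
                                                "mean_outside"),
                              outer = c(1.5, 2)) {
  stopifnot(inherits(summary, "profile_summary"))
  mode <- match.arg(mode)
  if (mode == "none") { summary$normalization <- "none"; return(summary) }
  if (mode == "minmax") {
    rng <- range(summary$mean, na.rm = TRUE)
    if (diff(rng) == 0)
      stopf("minmax normalization degenerate: curve is constant (%g)", rng[1])
    summary$mean <- (summary$mean - rng[1]) / diff(rng)
    summary$sd <- summary$sd / diff(rng)
  } else {
    sel <- summary$bin_centers >= outer[1] & summary$bin_centers <= outer[2]
    om <- mean(summary$mean[sel], na.rm = TRUE)
    if (!is.finite(om) || om == 0)
      stopf("mean_outside normalization degenerate: outside mean is %g", om)
    summary$mean <- summary$mean / om
    summary$sd <- summary$sd / om
  }
  summary$normalization <- mode
  summary
}
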