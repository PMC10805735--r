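#' Radial intensity laws
#'
#' A radial law describes the noiseless expected intensity of one channel as
#' a function of the boundary-normalized distance `d` from a nucleolar
#' centroid (`d = 1` at the nucleolar outline), defined on `d` in \[0, 2\],
#' together with a nucleoplasm baseline used at `d > 2` inside the nucleus.
#'
#' @param value,inside,outside,core,shell,nucleoplasm Intensity levels
#'   (arbitrary units).
#' @param edge Normalized distance at which a step law switches level.
#' @param intercept,slope Coefficients of a linear law `intercept + slope*d`.
#' @param baseline Nucleoplasm intensity outside the `d <= 2` annulus.
#' @param shell_thickness Shell width as a fraction of the nucleolar radius;
#'   the shell occupies `d` in (1 - shell_thickness, 1\].
#' @param law A `radial_law` to rescale.
#' @param factor Multiplicative factor applied to both the law and its
#'   baseline.
#' @return A `radial_law`: a list with elements `f` (vectorized function of
#'   d) and `baseline`.
#' @name radial_law
NULL

radial_law <- function(f, baseline) {
  stopifnot(is.function(f), is.numeric(baseline), length(baseline) == 1,
            baseline >= 0)
  structure(list(f = f, baseline = baseline), class = "radial_law")
}

#' @rdname radial_law
#' @export
law_constant <- function(value, baseline = value) {
  force(value)
  radial_law(function(d) rep(value, length(d)), baseline)
}

#' @rdname radial_law
#' @export
law_step <- function(inside, outside, edge = 1, baseline = outside) {
  force(inside); force(outside); force(edge)
  radial_law(function(d) ifelse(d <= edge, inside, outside), baseline)
}

#' @rdname radial_law
#' @export
law_linear <- function(intercept, slope, baseline = 0) {
  force(intercept); force(slope)
  radial_law(function(d) intercept + slope * d, baseline)
}

#' @rdname radial_law
#' @export
law_core_shell <- function(core, shell, nucleoplasm, shell_thickness = 0.25) {
  force(core); force(shell); force(nucleoplasm); force(shell_thickness)
  radial_law(function(d) {
    ifelse(d <= 1 - shell_thickness, core,
           ifelse(d <= 1, shell, nucleoplasm))
  }, nucleoplasm)
}

#' @rdname radial_law
#' @export
law_scale <- function(law, factor) {
  stopifnot(inherits(law, "radial_law"), is.numeric(factor), factor >= 0)
  f0 <- law$f
  radial_law(function(d) factor * f0(d), factor * law$baseline)
}

#' Condition presets for the synthetic generator
#'
#' Returns the channel laws (nucleus marker, shell marker, target) emulating
#' one experimental condition:
#' \describe{
#'   \item{control}{target core-enriched: inside/outside intensity ratio
#'     `rho` (> 1), shell marker with a bright granular-component ring.}
#'   \item{BLM_like}{strand breaks relax underwound DNA globally: the
#'     control target law multiplied by `reduction` at every d.}
#'   \item{RNAPI_inhibited_like}{transcription inhibition flattens the core
#'     enrichment: target ratio forced to 1, nucleoplasm unchanged.}
#'   \item{G4_ligand_like}{shell anchoring blocked: target flattened as
#'     above and the shell marker reduced by `shell_reduction`.}
#' }
#'
#' @param name Preset name.
#' @param rho Control inside/outside target ratio (default 3).
#' @param reduction Multiplicative target reduction for `BLM_like`.
#' @param base Nucleoplasm target level (arbitrary units).
#' @param shell_level,core_level,shell_baseline Shell-marker levels in the
#'   shell ring, the core, and the nucleoplasm.
#' @param shell_thickness Shell width as a fraction of the nucleolar radius.
#' @param shell_reduction Shell-marker reduction factor for `G4_ligand_like`.
#' @return A list with `channel_laws` (named list of `radial_law`) and
#'   `condition_label`.
#' @export
condition_preset <- function(name, rho = 3, reduction = 0.5, base = 0.2,
                             shell_level = 1, core_level = 0.35,
                             shell_baseline = 0.08, shell_thickness = 0.25,
                             shell_reduction = 0.5) {
  valid <- c("control", "BLM_like", "RNAPI_inhibited_like", "G4_ligand_like")
  if (!is.character(name) || length(name) != 1 || !(name %in% valid))
    stopf("unknown preset '%s'; valid presets: %s",
          as.character(name)[1], paste(valid, collapse = ", "))
  stopifnot(rho > 0, reduction > 0, base > 0)
  shell <- law_core_shell(core_level, shell_level, shell_baseline,
                          shell_thickness)
  target <- switch(name,
    control = law_step(rho * base, base),
    BLM_like = law_scale(law_step(rho * base, base), reduction),
    RNAPI_inhibited_like = law_constant(base, baseline = base),
    G4_ligand_like = law_constant(base, baseline = base))
  if (name == "G4_ligand_like") shell <- law_scale(shell, shell_reduction)
  list(channel_laws = list(nucleus_marker = law_constant(1),
                           shell_marker = shell,
                           target = target),
       condition_label = name)
}

#' Specification of a synthetic core-shell condensate field
#'
#' Describes one multi-channel field: nuclei containing core-shell nucleoli
#' whose channel intensities follow known radial laws, plus the optical blur
#' and noise model. Identical (spec, seed) pairs generate bit-identical
#' output.
#'
#' @param image_shape Pixels, `c(height, width)` or `c(height, width, nz)`
#'   for a z-stack.
#' @param pixel_size Lateral pixel size in micrometres.
#' @param z_spacing Plane spacing in micrometres (z-stacks only).
#' @param n_cells Number of nuclei to place.
#' @param nucleus_radius `c(mean, sd)` of the nuclear radius in pixels.
#' @param nucleoli_per_nucleus Integer range `c(min, max)` of nucleoli per
#'   nucleus.
#' @param nucleolus_radius `c(mean, sd)` of the nucleolar radius in pixels.
#' @param shell_thickness Shell width as a fraction of the nucleolar radius,
#'   in (0, 1).
#' @param channel_laws Named list of `radial_law`, one per channel; names
#'   are the channel roles. Defaults to `condition_preset(condition)`.
#' @param condition Preset name used when `channel_laws` is NULL.
#' @param preset_args Extra arguments passed to [condition_preset()].
#' @param blur_sigma Gaussian PSF sigma in pixels (0 disables blur).
#' @param poisson_scale Photons per intensity unit for shot noise (NA
#'   disables).
#' @param gaussian_noise_sd Additive read-noise s.d. in intensity units
#'   (0 disables).
#' @param irregularity Amplitude of low-order angular harmonics perturbing
#'   the nucleolar boundary (0 = perfect disks; 2D only).
#' @param annulus_inside If TRUE (default), nucleoli are placed so their
#'   whole `d <= 2` annulus lies inside the nucleus, keeping the outside
#'   window measurable; if FALSE only the nucleolar body must fit.
#' @param separation Pairwise nucleolus placement rule: `annuli` (default)
#'   keeps the `d <= 2` annuli of different nucleoli disjoint
#'   (center distance >= 2(r_i + r_j) + 2 px); `body` uses the minimal rule
#'   that one nucleolus's annulus never overlaps another's body
#'   (>= 2 max(r_i, r_j) + 2 px), allowing crowded fields.
#' @param intensity_jitter_cv Coefficient of variation of a per-nucleolus
#'   log-normal brightness factor applied to the `jitter_role` channel over
#'   the nucleolus's `d <= 2` annulus, emulating nucleolus-to-nucleolus
#'   staining variability (0 disables).
#' @param jitter_role Channel role the brightness jitter applies to.
#' @param condition_label Free-text label stored with the field.
#' @param seed Integer seed; the only source of randomness.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(image_shape = c(512, 512), pixel_size = 0.063,
                           z_spacing = 0.3, n_cells = 1,
                           nucleus_radius = c(120, 8),
                           nucleoli_per_nucleus = c(1, 3),
                           nucleolus_radius = c(18, 2),
                           shell_thickness = 0.25,
                           channel_laws = NULL, condition = "control",
                           preset_args = list(),
                           blur_sigma = 1.5, poisson_scale = 200,
                           gaussian_noise_sd = 0.01, irregularity = 0,
                           annulus_inside = TRUE,
                           separation = c("annuli", "body"),
                           intensity_jitter_cv = 0.1, jitter_role = "target",
                           condition_label = NULL, seed = 1) {
  separation <- match.arg(separation)
  if (is.null(channel_laws)) {
    preset <- do.call(condition_preset, c(list(name = condition,
                                               shell_thickness = shell_thickness),
                                          preset_args))
    channel_laws <- preset$channel_laws
    if (is.null(condition_label)) condition_label <- preset$condition_label
  }
  if (is.null(condition_label)) condition_label <- condition
  stopifnot(length(image_shape) %in% c(2, 3), all(image_shape >= 16),
            pixel_size > 0, z_spacing > 0, is_count(n_cells),
            length(nucleus_radius) == 2, nucleus_radius[1] > 0,
            nucleus_radius[2] >= 0,
            length(nucleoli_per_nucleus) == 2,
            nucleoli_per_nucleus[1] >= 1,
            nucleoli_per_nucleus[2] >= nucleoli_per_nucleus[1],
            length(nucleolus_radius) == 2, nucleolus_radius[1] > 0,
            nucleolus_radius[2] >= 0,
            shell_thickness > 0, shell_thickness < 1,
            blur_sigma >= 0, gaussian_noise_sd >= 0,
            irregularity >= 0, irregularity < 0.3,
            intensity_jitter_cv >= 0, intensity_jitter_cv < 1,
            is.list(channel_laws), length(channel_laws) >= 1,
            !is.null(names(channel_laws)), all(nzchar(names(channel_laws))),
            length(seed) == 1, is.finite(seed))
  if (!is.na(poisson_scale)) stopifnot(poisson_scale > 0)
  for (l in channel_laws) stopifnot(inherits(l, "radial_law"))
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, z_spacing = z_spacing,
                 n_cells = as.integer(n_cells),
                 nucleus_radius = nucleus_radius,
                 nucleoli_per_nucleus = as.integer(nucleoli_per_nucleus),
                 nucleolus_radius = nucleolus_radius,
                 shell_thickness = shell_thickness,
                 channel_laws = channel_laws,
                 blur_sigma = blur_sigma, poisson_scale = poisson_scale,
                 gaussian_noise_sd = gaussian_noise_sd,
                 irregularity = irregularity,
                 annulus_inside = isTRUE(annulus_inside),
                 separation = separation,
                 intensity_jitter_cv = intensity_jitter_cv,
                 jitter_role = jitter_role,
                 condition_label = condition_label,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  dims <- paste(x$image_shape, collapse = " x ")
  cat("Synthetic field spec:", dims, "px,", x$n_cells, "nuclei,",
      paste(x$nucleoli_per_nucleus, collapse = "-"),
      "nucleoli/nucleus\n")
  cat("  condition:", x$condition_label, " channels:",
      paste(names(x$channel_laws), collapse = ", "), "\n")
  cat("  blur sigma:", x$blur_sigma, "px; poisson scale:", x$poisson_scale,
      "; gaussian sd:", x$gaussian_noise_sd, "; seed:", x$seed, "\n")
  invisible(x)
}

# Rejection-sample `n` centers in a disk of radius `rmax_each[i]` around
# `center` with pairwise separation >= sep_fun(i, j); 0-based coordinates.
# Dart-throwing with whole-configuration restarts: a greedy sequence that
# dead-ends (early darts blocking the rest) is abandoned rather than
# retried forever.
place_points <- function(n, center, rmax_each, sep_fun, max_attempts = 1e4,
                         tries_per_point = 100L) {
  attempts <- 0L
  repeat {
    pts <- matrix(NA_real_, n, length(center))
    placed <- 0L
    stuck <- FALSE
    while (placed < n && !stuck) {
      tries <- 0L
      repeat {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stopf(paste("placement failure: could not place %d non-overlapping",
                      "nucleoli after %d attempts; reduce count or radius"),
                n, max_attempts)
        tries <- tries + 1L
        if (tries > tries_per_point) { stuck <- TRUE; break }
        u <- stats::runif(length(center), -1, 1)
        cand <- center + u * rmax_each[placed + 1L]
        if (sqrt(sum((cand - center)^2)) > rmax_each[placed + 1L]) next
        ok <- TRUE
        if (placed > 0) {
          for (j in seq_len(placed)) {
            if (sqrt(sum((cand - pts[j, ])^2)) < sep_fun(placed + 1L, j)) {
              ok <- FALSE; break
            }
          }
        }
        if (ok) {
          placed <- placed + 1L
          pts[placed, ] <- cand
          break
        }
      }
    }
    if (placed == n) return(pts)
  }
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic multi-channel field with ground truth
#'
#' Renders the noiseless channels from the spec's radial laws on analytic
#' disk (2D) or sphere (3D) geometry, applies Gaussian PSF blur, then
#' Poisson shot noise and additive Gaussian read noise. Ground-truth masks
#' are the pre-blur analytic regions; each pixel's normalized distance d is
#' its distance to the owning nucleolar centroid divided by the boundary
#' radius along that direction.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `field` (an `image_field`) and `truth` (a
#'   `synthetic_truth`: labeled nucleus/nucleolus masks, per-nucleolus
#'   centroids and boundary radii, the channel laws used).
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  sh <- spec$image_shape
  is3d <- length(sh) == 3
  h <- sh[1]; w <- sh[2]; nz <- if (is3d) sh[3] else 1L
  az <- spec$z_spacing / spec$pixel_size  # z anisotropy in px per plane

  # --- nuclei -------------------------------------------------------------
  ncl <- spec$n_cells
  r_fit <- (min(h, w) - 6) / 2  # nucleus must fit the field with margin
  if (spec$nucleus_radius[1] * 0.5 > r_fit)
    stopf("nucleus radius %g does not fit a %d x %d image",
          spec$nucleus_radius[1], h, w)
  nuc_r <- rtrunc_norm(ncl, spec$nucleus_radius[1], spec$nucleus_radius[2],
                       0.5 * spec$nucleus_radius[1],
                       min(1.5 * spec$nucleus_radius[1], r_fit))
  nuc_c <- matrix(NA_real_, ncl, 2)
  attempts <- 0L
  for (i in seq_len(ncl)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > 1e4)
        stopf("placement failure: could not place %d nuclei of radius ~%g in a %d x %d image",
              ncl, spec$nucleus_radius[1], h, w)
      cand <- c(stats::runif(1, nuc_r[i] + 2, h - 1 - nuc_r[i] - 2),
                stats::runif(1, nuc_r[i] + 2, w - 1 - nuc_r[i] - 2))
      ok <- TRUE
      if (i > 1) for (j in seq_len(i - 1)) {
        if (sqrt(sum((cand - nuc_c[j, ])^2)) < nuc_r[i] + nuc_r[j] + 4) {
          ok <- FALSE; break
        }
      }
      if (ok) { nuc_c[i, ] <- cand; break }
    }
  }
  nuc_z <- rep((nz - 1) / 2, ncl)  # nuclei centered in z

  # --- nucleoli -----------------------------------------------------------
  lo <- spec$nucleoli_per_nucleus[1]; hi <- spec$nucleoli_per_nucleus[2]
  counts <- if (lo == hi) rep(lo, ncl) else sample(lo:hi, ncl, replace = TRUE)
  ncl_total <- sum(counts)
  no_r <- rtrunc_norm(ncl_total, spec$nucleolus_radius[1],
                      spec$nucleolus_radius[2],
                      max(3, spec$nucleolus_radius[1] -
                            2.5 * spec$nucleolus_radius[2]),
                      spec$nucleolus_radius[1] +
                        2.5 * spec$nucleolus_radius[2])
  parent <- rep(seq_len(ncl), counts)
  no_c <- matrix(NA_real_, ncl_total, 2)
  idx0 <- 0L
  margin_mult <- if (spec$annulus_inside) 2 else 1
  for (i in seq_len(ncl)) {
    k <- counts[i]
    rk <- no_r[idx0 + seq_len(k)]
    rmax_each <- nuc_r[i] - margin_mult * rk - 2
    if (any(rmax_each <= 0))
      stopf("placement failure: nucleolus radius %g too large for nucleus radius %g",
            max(rk), nuc_r[i])
    sep_fun <- if (spec$separation == "annuli")
      function(a, b) 2 * (rk[a] + rk[b]) + 2
    else function(a, b) 2 * max(rk[a], rk[b]) + 2
    pts <- place_points(k, nuc_c[i, ], rmax_each, sep_fun)
    no_c[idx0 + seq_len(k), ] <- pts
    idx0 <- idx0 + k
  }
  no_z <- rep((nz - 1) / 2, ncl_total)

  # per-nucleolus brightness jitter on the target-like channel
  jitter <- rep(1, ncl_total)
  if (spec$intensity_jitter_cv > 0) {
    sdlog <- sqrt(log(1 + spec$intensity_jitter_cv^2))
    jitter <- exp(stats::rnorm(ncl_total, -sdlog^2 / 2, sdlog))
  }

  # boundary irregularity: r_b(theta) = r * (1 + sum a_m cos(m theta + phi_m))
  harm <- NULL
  if (spec$irregularity > 0 && !is3d) {
    harm <- lapply(seq_len(ncl_total), function(j) {
      m <- 2:4
      amp <- stats::runif(3, 0.3, 1) * spec$irregularity / seq_along(m)
      list(m = m, amp = amp, phase = stats::runif(3, 0, 2 * pi))
    })
  }

  # --- per-pixel geometry -------------------------------------------------
  # nucleus label and, for pixels in any d<=2 annulus, the owning nucleolus
  # (the one with smallest d) and its d.
  render_plane <- function(z) {
    nuc_lab <- matrix(0L, h, w)
    rows <- matrix(0:(h - 1), h, w)
    cols <- matrix(0:(w - 1), h, w, byrow = TRUE)
    for (i in seq_len(ncl)) {
      dz2 <- if (is3d) ((z - nuc_z[i]) * az)^2 else 0
      d2 <- (rows - nuc_c[i, 1])^2 + (cols - nuc_c[i, 2])^2 + dz2
      nuc_lab[d2 <= nuc_r[i]^2] <- i
    }
    dmin <- matrix(Inf, h, w)
    owner <- matrix(0L, h, w)
    for (j in seq_len(ncl_total)) {
      dz2 <- if (is3d) ((z - no_z[j]) * az)^2 else 0
      reach <- 2 * no_r[j] * 1.35 + 2
      if (is3d && dz2 > reach^2) next
      r0 <- max(0, floor(no_c[j, 1] - reach)); r1 <- min(h - 1, ceiling(no_c[j, 1] + reach))
      c0 <- max(0, floor(no_c[j, 2] - reach)); c1 <- min(w - 1, ceiling(no_c[j, 2] + reach))
      ri <- r0:r1; ci <- c0:c1
      dy <- matrix(ri - no_c[j, 1], length(ri), length(ci))
      dx <- matrix(ci - no_c[j, 2], length(ri), length(ci), byrow = TRUE)
      dist <- sqrt(dy^2 + dx^2 + dz2)
      rb <- no_r[j]
      if (!is.null(harm)) {
        th <- atan2(dx, dy)
        pert <- 1
        hj <- harm[[j]]
        for (q in seq_along(hj$m))
          pert <- pert + hj$amp[q] * cos(hj$m[q] * th + hj$phase[q])
        rb <- no_r[j] * pert
      }
      d <- dist / rb
      sub_r <- ri + 1L; sub_c <- ci + 1L
      upd <- d < dmin[sub_r, sub_c]
      dsub <- dmin[sub_r, sub_c]; osub <- owner[sub_r, sub_c]
      dsub[upd] <- d[upd]; osub[upd] <- j
      dmin[sub_r, sub_c] <- dsub; owner[sub_r, sub_c] <- osub
    }
    list(nuc = nuc_lab, dmin = dmin, owner = owner)
  }

  planes <- lapply(seq_len(nz) - 1, render_plane)

  # --- noiseless channels + truth masks ------------------------------------
  roles <- names(spec$channel_laws)
  mk_channel <- function(law, jittered) {
    ch <- lapply(planes, function(p) {
      img <- matrix(0, h, w)
      inn <- p$nuc > 0
      img[inn] <- law$baseline
      sel <- inn & p$owner > 0 & p$dmin <= 2
      if (any(sel)) {
        v <- law$f(p$dmin[sel])
        if (jittered) v <- v * jitter[p$owner[sel]]
        img[sel] <- v
      }
      img
    })
    if (is3d) array(unlist(ch), dim = c(h, w, nz)) else ch[[1]]
  }
  channels <- lapply(roles, function(role)
    mk_channel(spec$channel_laws[[role]], role == spec$jitter_role))
  names(channels) <- roles

  mk_mask <- function(get) {
    ms <- lapply(planes, get)
    if (is3d) array(unlist(ms), dim = c(h, w, nz)) else ms[[1]]
  }
  nuc_mask <- mk_mask(function(p) p$nuc)
  nol_mask <- mk_mask(function(p) {
    m <- p$owner
    m[p$dmin > 1] <- 0L
    m
  })

  # --- blur + noise --------------------------------------------------------
  blur1 <- function(m) {
    if (spec$blur_sigma <= 0) return(m)
    as.matrix(EBImage::gblur(m, sigma = spec$blur_sigma))
  }
  channels <- lapply(channels, function(ch) {
    if (is3d) {
      for (z in seq_len(nz)) ch[, , z] <- blur1(ch[, , z])
      ch
    } else blur1(ch)
  })
  channels <- lapply(channels, function(ch) {
    v <- as.numeric(ch)
    if (!is.na(spec$poisson_scale))
      v <- stats::rpois(length(v), pmax(v, 0) * spec$poisson_scale) /
        spec$poisson_scale
    if (spec$gaussian_noise_sd > 0)
      v <- v + stats::rnorm(length(v), 0, spec$gaussian_noise_sd)
    array(v, dim = dim(ch) %||% c(h, w))
  })
  names(channels) <- roles

  field <- image_field(pixels = channels,
                       pixel_size = spec$pixel_size,
                       z_spacing = if (is3d) spec$z_spacing else NA_real_,
                       field_id = sprintf("sim-seed%d", spec$seed),
                       condition = spec$condition_label)

  centroids <- if (is3d) cbind(no_c, no_z) else no_c
  colnames(centroids) <- if (is3d) c("r", "c", "z") else c("r", "c")
  truth <- structure(list(
    nucleus_mask = labeled_mask(nuc_mask, source_role = "nucleus_marker"),
    nucleolus_mask = labeled_mask(nol_mask, source_role = "shell_marker",
                                  parent = stats::setNames(parent,
                                                           seq_len(ncl_total))),
    centroids = centroids,
    boundary_radius = no_r,
    nucleus_centers = nuc_c,
    nucleus_radius = nuc_r,
    channel_laws = spec$channel_laws,
    jitter = jitter,
    harmonics = harm), class = "synthetic_truth")
  list(field = field, truth = truth)
}

#' Generate synthetic assay tables (gel bands and qPCR Ct values)
#'
#' Produces the two small tables the assay module consumes: per-lane gel
#' band intensities for the in vitro crosslink-protection assay, and a long
#' Ct table for ChIP-qPCR over the five rDNA target regions (PQS-1..PQS-4,
#' Non-PQS).
#'
#' Gel lanes carry a true protected fraction per condition; both bands get
#' multiplicative log-normal noise. The qPCR table encodes true percent
#' input per (region, antibody, condition); the IP Ct is derived from a
#' shared input Ct assuming doubling efficiency, plus Gaussian Ct noise.
#'
#' @param seed Integer seed.
#' @param params Optional overrides: `gel` (data.frame with columns
#'   `condition`, `psoralen`, `uv`, `true_fraction`, `n_lanes`),
#'   `gel_noise_cv`, `base_total`, `chip_truth` (data.frame with
#'   `target_region`, `antibody`, `condition`, `true_percent_input`),
#'   `n_reps`, `input_fraction`, `ct_noise_sd`, `input_ct_base`.
#' @return List with `gel` and `chip` data frames.
#' @export
generate_assay_tables <- function(seed = 1, params = list()) {
  set.seed(seed)
  gel_design <- params[["gel"]] %||% data.frame(
    condition = c("underwound", "relaxed", "underwound", "underwound"),
    psoralen = c(TRUE, TRUE, FALSE, TRUE),
    uv = c(TRUE, TRUE, TRUE, FALSE),
    true_fraction = c(0.7, 0.25, 0.02, 0.02),
    n_lanes = 3)
  gel_noise_cv <- params[["gel_noise_cv"]] %||% 0.05
  base_total <- params[["base_total"]] %||% 1000
  if (any(gel_design$true_fraction < 0) || base_total <= 0)
    stopf("gel true fractions and base intensity must be non-negative")
  gel <- do.call(rbind, lapply(seq_len(nrow(gel_design)), function(i) {
    g <- gel_design[i, ]
    n <- g$n_lanes
    total <- base_total * exp(stats::rnorm(n, 0, gel_noise_cv))
    nond <- g$true_fraction * base_total * exp(stats::rnorm(n, 0, gel_noise_cv))
    data.frame(lane_id = sprintf("%s%s%s-%d", g$condition,
                                 ifelse(g$psoralen, "+pso", "-pso"),
                                 ifelse(g$uv, "+uv", "-uv"), seq_len(n)),
               condition = g$condition, psoralen = g$psoralen, uv = g$uv,
               true_fraction = g$true_fraction,
               band_nondenatured = nond, band_total = total)
  }))

  regions <- c(paste0("PQS-", 1:4), "Non-PQS")
  chip_truth <- params[["chip_truth"]] %||% {
    ratio <- ifelse(regions == "Non-PQS", 1, 0.4)
    rbind(
      data.frame(target_region = regions, antibody = "NPM",
                 condition = "water", true_percent_input = 2),
      data.frame(target_region = regions, antibody = "NPM",
                 condition = "TMPyP4", true_percent_input = 2 * ratio),
      data.frame(target_region = regions, antibody = "H3",
                 condition = rep(c("water", "TMPyP4"), each = length(regions)),
                 true_percent_input = 5),
      data.frame(target_region = regions, antibody = "IgG",
                 condition = rep(c("water", "TMPyP4"), each = length(regions)),
                 true_percent_input = 0.05))
  }
  if (any(chip_truth$true_percent_input <= 0))
    stopf("true percent input must be positive")
  n_reps <- params[["n_reps"]] %||% 3
  input_fraction <- params[["input_fraction"]] %||% 0.02
  ct_noise_sd <- params[["ct_noise_sd"]] %||% 0.15
  input_ct_base <- params[["input_ct_base"]] %||% 24
  stopifnot(input_fraction > 0, input_fraction < 1, ct_noise_sd >= 0)

  combos <- unique(chip_truth[, c("target_region", "condition")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    reg <- combos$target_region[i]; cond <- combos$condition[i]
    for (rep_i in seq_len(n_reps)) {
      input_ct <- stats::rnorm(1, input_ct_base, 0.5)
      rows[[length(rows) + 1L]] <- data.frame(
        target_region = reg, antibody = "input", condition = cond,
        replicate = rep_i, ct = input_ct, input_fraction = input_fraction)
      abs_here <- chip_truth[chip_truth$target_region == reg &
                               chip_truth$condition == cond, ]
      for (j in seq_len(nrow(abs_here))) {
        pct <- abs_here$true_percent_input[j]
        ip_ct <- input_ct - log2(pct / (100 * input_fraction)) +
          stats::rnorm(1, 0, ct_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          target_region = reg, antibody = abs_here$antibody[j],
          condition = cond, replicate = rep_i, ct = ip_ct,
          input_fraction = input_fraction)
      }
    }
  }
  chip <- do.call(rbind, rows)
  rownames(chip) <- NULL
  list(gel = gel, chip = chip)
}
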