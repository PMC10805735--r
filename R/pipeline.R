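# End-to-end orchestration: simulate -> segment -> profile -> window means
# -> group comparison, with serializable configuration, per-stage manifest
# counts, and deterministic outputs for a given (config, seed).

#' Pipeline run configuration
#'
#' A fully serializable description of one end-to-end run over synthetic
#' conditions. Validated on construction; [write_run_config()] /
#' [read_run_config()] round-trip it losslessly through YAML or JSON.
#'
#' @param conditions Character vector of [condition_preset()] names.
#' @param n_fields Fields to simulate per condition.
#' @param spec_args Named list of overrides passed to [synthetic_spec()]
#'   (geometry, noise, ...).
#' @param seg_args Named list: `min_area_nucleus`, `min_area_nucleolus`.
#' @param profile_args Named list: `n_rays`, `step`, `d_max`, `n_bins`,
#'   `smooth_window`.
#' @param windows List with `inner` and `outer` d-windows.
#' @param use_truth_masks Profile on ground-truth masks instead of
#'   segmenting (for oracle runs).
#' @param write_images Write field/mask TIFFs (CSV outputs are always
#'   written).
#' @param seed Integer master seed; all randomness derives from it.
#' @return A `run_config` object.
#' @export
run_config <- function(conditions = c("control", "RNAPI_inhibited_like"),
                       n_fields = 2, spec_args = list(),
                       seg_args = list(), profile_args = list(),
                       windows = list(inner = c(0, 0.5), outer = c(1.5, 2)),
                       use_truth_masks = FALSE, write_images = TRUE,
                       seed = 1) {
  stopifnot(is.character(conditions), length(conditions) >= 1,
            is_count(n_fields), is.list(windows),
            length(windows$inner) == 2, length(windows$outer) == 2,
            length(seed) == 1, is.finite(seed))
  if (windows$inner[2] > windows$outer[1] && windows$outer[2] > windows$inner[1])
    stopf("config invalid: inside and outside windows overlap")
  pa <- utils::modifyList(list(n_rays = 180, step = 0.25, d_max = 2,
                               n_bins = 40, smooth_window = 5), profile_args)
  sa <- utils::modifyList(list(min_area_nucleus = 2000,
                               min_area_nucleolus = pi * 25), seg_args)
  if (windows$outer[2] > pa$d_max)
    stopf("config invalid: outside window exceeds d_max")
  structure(list(conditions = conditions, n_fields = as.integer(n_fields),
                 spec_args = spec_args, seg_args = sa, profile_args = pa,
                 windows = windows,
                 use_truth_masks = isTRUE(use_truth_masks),
                 write_images = isTRUE(write_images),
                 seed = as.integer(seed),
                 version = as.character(utils::packageVersion("nucleoprofile"))),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path Output path; format chosen by extension (.yaml/.yml or
#'   .json).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config(conditions = unlist(x$conditions),
                    n_fields = x$n_fields,
                    spec_args = x$spec_args %||% list(),
                    seg_args = x$seg_args %||% list(),
                    profile_args = x$profile_args %||% list(),
                    windows = list(inner = unlist(x$windows$inner),
                                   outer = unlist(x$windows$outer)),
                    use_truth_masks = isTRUE(x$use_truth_masks),
                    write_images = isTRUE(x$write_images),
                    seed = x$seed)
  cfg
}

field_seed <- function(master, cond_idx, field_idx) {
  as.integer((as.numeric(master) * 1009 + cond_idx * 101 + field_idx) %%
               2147483647)
}

#' Run the full synthetic pipeline
#'
#' Simulates fields for each condition, segments nuclei and nucleoli,
#' computes boundary-normalized radial profiles and inside/outside window
#' means, and compares conditions with the appropriate nonparametric test.
#' All CSV/JSON outputs plus a machine-readable manifest (per-stage counts
#' and exclusions with reasons) are written to `out_dir`; a rerun with the
#' same config is byte-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `window_means` (per-condition list),
#'   `stats` (comparison table), `summaries` (per-condition
#'   `profile_summary`), and `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "config.json"))
  pa <- config$profile_args
  manifest <- list(version = config$version, seed = config$seed,
                   conditions = list())
  wm_by_cond <- list()
  profiles_all <- list()
  summaries <- list()
  for (ci in seq_along(config$conditions)) {
    cond <- config$conditions[ci]
    cond_profiles <- list()
    n_nuclei <- 0L
    exclusions <- list()
    for (fi in seq_len(config$n_fields)) {
      spec <- do.call(synthetic_spec,
                      utils::modifyList(config$spec_args,
                                        list(condition = cond,
                                             seed = field_seed(config$seed,
                                                               ci, fi))))
      sim <- generate_field(spec)
      field <- sim$field
      field$field_id <- sprintf("%s-f%02d", cond, fi)
      if (config$write_images)
        write_field(field, file.path(out_dir,
                                     paste0(field$field_id, ".tif")))
      if (config$use_truth_masks) {
        nuclei <- sim$truth$nucleus_mask
        nucleoli <- sim$truth$nucleolus_mask
      } else {
        nuclei <- segment_nuclei(field,
                                 min_area = config$seg_args$min_area_nucleus)
        nucleoli <- segment_nucleoli(field, nuclei,
                                     min_area = config$seg_args$min_area_nucleolus)
      }
      if (config$write_images)
        write_mask(nucleoli, file.path(out_dir,
                                       paste0(field$field_id, "_nucleoli.tif")))
      n_nuclei <- n_nuclei + length(mask_labels(nuclei))
      pf <- profile_field(field, nucleoli, nuclei, role = "target",
                          n_rays = pa$n_rays, step = pa$step,
                          d_max = pa$d_max, n_bins = pa$n_bins)
      cond_profiles <- c(cond_profiles, pf$profiles)
      if (nrow(pf$exclusions)) {
        pf$exclusions$field_id <- field$field_id
        exclusions[[length(exclusions) + 1L]] <- pf$exclusions
      }
    }
    wm <- window_means_table(cond_profiles, inner = config$windows$inner,
                             outer = config$windows$outer)
    wm_excl <- attr(wm, "exclusions")
    wm_by_cond[[cond]] <- wm
    profiles_all <- c(profiles_all, cond_profiles)
    if (length(cond_profiles)) {
      sm <- aggregate_profiles(lapply(cond_profiles, smooth_profile,
                                      window = pa$smooth_window))
      summaries[[cond]] <- sm
    }
    manifest$conditions[[cond]] <- list(
      n_fields = config$n_fields, n_nuclei = n_nuclei,
      n_nucleoli_profiled = length(cond_profiles),
      n_window_means = nrow(wm),
      exclusions = c(
        if (length(exclusions)) lapply(do.call(rbind, exclusions), as.vector),
        if (!is.null(wm_excl)) list(empty_window = nrow(wm_excl))))
  }
  write_profiles(profiles_all, file.path(out_dir, "profiles.csv"))
  wm_all <- do.call(rbind, lapply(wm_by_cond, identity))
  rownames(wm_all) <- NULL
  utils::write.csv(wm_all, file.path(out_dir, "window_means.csv"),
                   row.names = FALSE)
  if (length(summaries)) {
    sm_rows <- do.call(rbind, lapply(names(summaries), function(cd) {
      s <- summaries[[cd]]
      data.frame(condition = cd, d_bin_center = s$bin_centers,
                 mean = s$mean, sd = s$sd, n_per_bin = s$n_per_bin,
                 n_nucleoli = s$n_nucleoli, n_cells = s$n_cells)
    }))
    utils::write.csv(sm_rows, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  }
  stats_tab <- NULL
  if (length(wm_by_cond) >= 2 && all(vapply(wm_by_cond, nrow, 0L) >= 2)) {
    stats_tab <- compare_conditions(wm_by_cond)
    utils::write.csv(stats_tab, file.path(out_dir, "stats.csv"),
                     row.names = FALSE)
    jsonlite::write_json(stats_tab, file.path(out_dir, "stats.json"),
                         digits = NA, dataframe = "rows")
  }
  manifest$partial <- is.null(stats_tab) && length(config$conditions) >= 2
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(window_means = wm_by_cond, stats = stats_tab,
                 summaries = summaries, manifest = manifest))
}

#' Intensity line profile between two points
#'
#' Bilinearly interpolated intensities at unit-pixel spacing along the
#' segment, for each requested channel role, on a shared physical position
#' axis.
#'
#' @param field An [image_field()] (2D).
#' @param from,to Endpoints, 0-based `(r, c)` pixel coordinates.
#' @param roles Channel roles to sample (default: all).
#' @return Data frame with `position_um` and one column per role.
#' @export
line_profile <- function(field, from, to, roles = NULL) {
  stopifnot(inherits(field, "image_field"), length(from) == 2,
            length(to) == 2)
  roles <- roles %||% names(field$pixels)
  d <- dim(field$pixels[[1]])
  if (length(d) != 2) stopf("line_profile expects a 2D field")
  for (p in list(from, to))
    if (p[1] < 0 || p[1] > d[1] - 1 || p[2] < 0 || p[2] > d[2] - 1)
      stopf("endpoint (%g, %g) outside image", p[1], p[2])
  len <- sqrt(sum((to - from)^2))
  t <- seq(0, len, by = 1)
  if (t[length(t)] < len) t <- c(t, len)
  fr <- from[1] + (to[1] - from[1]) * t / max(len, .Machine$double.eps)
  fc <- from[2] + (to[2] - from[2]) * t / max(len, .Machine$double.eps)
  out <- data.frame(position_um = t * field$pixel_size)
  for (role in roles)
    out[[role]] <- bilinear(get_channel(field, role), fr, fc)
  out
}
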