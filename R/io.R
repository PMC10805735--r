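# TIFF / CSV / JSON readers and writers. Fields are plain multi-page TIFFs
# (one page per channel in 2D; one file per channel for z-stacks) with a
# JSON sidecar recording channel roles and pixel size; label masks are
# 16-bit TIFFs plus a regions CSV.

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write an image field as TIFF plus JSON sidecar
#'
#' @param field An [image_field()].
#' @param path Output TIFF path (2D: one multi-page file, one page per
#'   channel; 3D: one file per channel, suffixed with the role name).
#' @return Invisibly, the paths written.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "image_field"))
  is3d <- length(dim(field$pixels[[1]])) == 3
  paths <- character(0)
  # TIFF pages hold [0, 1]; each channel is affinely rescaled and the
  # (offset, scale) transform recorded in the sidecar.
  scales <- lapply(field$pixels, function(ch) {
    rng <- range(ch)
    list(offset = rng[1], scale = max(diff(rng), .Machine$double.eps))
  })
  norm1 <- function(ch, sc) (ch - sc$offset) / sc$scale
  if (!is3d) {
    pages <- Map(norm1, field$pixels, scales)
    tiff::writeTIFF(unname(pages), path, bits.per.sample = 32)
    paths <- path
  } else {
    for (role in names(field$pixels)) {
      p <- sub("(\\.tiff?)$", paste0("_", role, "\\1"), path)
      arr <- norm1(field$pixels[[role]], scales[[role]])
      tiff::writeTIFF(lapply(seq_len(dim(arr)[3]), function(z) arr[, , z]),
                      p, bits.per.sample = 32)
      paths <- c(paths, p)
    }
  }
  meta <- list(field_id = field$field_id, condition = field$condition,
               pixel_size_um = field$pixel_size,
               z_spacing_um = field$z_spacing,
               channel_roles = as.list(field$channel_roles),
               channel_scales = scales,
               layout = if (is3d) "one_file_per_channel" else
                 "one_page_per_channel")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(c(paths, sidecar_path(path)))
}

#' Read an image field written by [write_field()]
#'
#' @param path TIFF path given to [write_field()].
#' @return An [image_field()].
#' @export
read_field <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path))
  roles <- names(meta$channel_roles)
  if (identical(meta$layout, "one_page_per_channel")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    pixels <- stats::setNames(pages[unlist(meta$channel_roles)], roles)
  } else {
    pixels <- stats::setNames(lapply(roles, function(role) {
      p <- sub("(\\.tiff?)$", paste0("_", role, "\\1"), path)
      pages <- tiff::readTIFF(p, all = TRUE)
      array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    }), roles)
  }
  if (!is.null(meta$channel_scales)) {
    pixels <- stats::setNames(lapply(roles, function(role) {
      sc <- meta$channel_scales[[role]]
      pixels[[role]] * sc$scale + sc$offset
    }), roles)
  }
  image_field(pixels, pixel_size = meta$pixel_size_um,
              z_spacing = meta$z_spacing_um %||% NA_real_,
              field_id = meta$field_id, condition = meta$condition %||% "")
}

#' Write a label mask as 16-bit TIFF plus regions CSV
#'
#' @param mask A [labeled_mask()].
#' @param path Output TIFF path; the regions CSV (label, parent, area_px,
#'   centroid, border_flag) goes next to it with suffix `_regions.csv`.
#' @return Invisibly, the paths written.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "labeled_mask"))
  lab <- mask$labels
  if (max(lab) > 65535) stopf("more than 65535 labels")
  is3d <- length(dim(lab)) == 3
  pages <- if (is3d) lapply(seq_len(dim(lab)[3]), function(z) lab[, , z] / 65535)
  else list(lab / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  labs <- mask_labels(mask)
  cen <- t(vapply(labs, function(l) {
    x <- centroid(mask, l)
    c(x, rep(NA_real_, 3 - length(x)))
  }, numeric(3)))
  regions <- data.frame(label = labs,
                        parent = if (!is.null(mask$parent))
                          as.integer(mask$parent[as.character(labs)])
                        else NA_integer_,
                        area_px = vapply(labs, function(l) sum(lab == l), 0),
                        centroid_r = cen[, 1], centroid_c = cen[, 2],
                        centroid_z = cen[, 3],
                        border_flag = labs %in% mask$border)
  csv <- paste0(sub("\\.tiff?$", "", path), "_regions.csv")
  utils::write.csv(regions, csv, row.names = FALSE)
  invisible(c(path, csv))
}

#' Read a label mask written by [write_mask()]
#'
#' @param path TIFF path given to [write_mask()].
#' @param source_role Channel role to record on the mask.
#' @return A [labeled_mask()].
#' @export
read_mask <- function(path, source_role = NA_character_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  to_int <- function(m) {
    out <- as.integer(round(m * 65535))
    array(out, dim = dim(m))
  }
  lab <- if (length(pages) == 1) to_int(pages[[1]])
  else array(unlist(lapply(pages, to_int)),
             dim = c(dim(pages[[1]]), length(pages)))
  csv <- paste0(sub("\\.tiff?$", "", path), "_regions.csv")
  parent <- NULL; border <- integer(0)
  if (file.exists(csv)) {
    regions <- utils::read.csv(csv)
    if (!all(is.na(regions$parent)))
      parent <- stats::setNames(regions$parent, regions$label)
    border <- regions$label[regions$border_flag]
  }
  labeled_mask(lab, source_role = source_role, parent = parent,
               border = border)
}

#' Write radial profiles to a tidy CSV
#'
#' One row per (nucleolus, bin): `field_id`, `cell_id`, `nucleolus_id`,
#' `condition`, `d_bin_center`, `mean_intensity`, `n_samples`.
#'
#' @param profiles List of `radial_profile`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p)
    data.frame(field_id = p$field_id, cell_id = p$cell_id,
               nucleolus_id = p$nucleolus_id, condition = p$condition,
               d_bin_center = p$bin_centers,
               mean_intensity = p$mean_intensity,
               n_samples = p$n_samples))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
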