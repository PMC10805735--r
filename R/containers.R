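#' Multi-channel image field
#'
#' The raw object every analysis stage consumes: a named list of co-shaped
#' intensity arrays (2D matrices or 3D `[h, w, nz]` arrays), one per channel
#' role, with pixel-size metadata. Standard roles are `nucleus_marker`
#' (DAPI-like), `shell_marker` (NPM-like granular-component marker) and
#' `target` (the signal being profiled).
#'
#' @param pixels Named list of numeric matrices/arrays sharing one shape;
#'   names are the channel roles.
#' @param pixel_size Lateral pixel size in micrometres.
#' @param z_spacing Plane spacing in micrometres (NA for 2D).
#' @param field_id,condition Free-text identifiers.
#' @return An `image_field` object.
#' @export
image_field <- function(pixels, pixel_size, z_spacing = NA_real_,
                        field_id = "field", condition = "") {
  stopifnot(is.list(pixels), length(pixels) >= 1,
            !is.null(names(pixels)), all(nzchar(names(pixels))),
            !anyDuplicated(names(pixels)), pixel_size > 0)
  dims <- lapply(pixels, function(p) dim(p) %||% length(p))
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stopf("all channels must share one shape")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 z_spacing = z_spacing, field_id = field_id,
                 condition = condition,
                 channel_roles = stats::setNames(seq_along(pixels),
                                                 names(pixels))),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  d <- dim(x$pixels[[1]])
  cat("Image field '", x$field_id, "': ", paste(d, collapse = " x "),
      " px, ", length(x$pixels), " channel(s) [",
      paste(names(x$pixels), collapse = ", "), "]\n", sep = "")
  cat("  pixel size ", x$pixel_size, " um",
      if (!is.na(x$z_spacing)) paste0(", z spacing ", x$z_spacing, " um"),
      if (nzchar(x$condition)) paste0("; condition: ", x$condition),
      "\n", sep = "")
  invisible(x)
}

#' Extract one channel of an image field by role
#'
#' @param field An [image_field()].
#' @param role Channel role name.
#' @return The channel's numeric matrix or array.
#' @export
get_channel <- function(field, role) {
  stopifnot(inherits(field, "image_field"))
  if (!role %in% names(field$pixels))
    stopf("channel role '%s' not present (have: %s)", role,
          paste(names(field$pixels), collapse = ", "))
  field$pixels[[role]]
}

#' Integer-labeled region mask
#'
#' Labels are consecutive integers 1..K over a 0 background. `parent`
#' optionally maps each nucleolus label to the nucleus label containing it;
#' `border` flags labels touching the image border.
#'
#' @param labels Integer matrix/array; 0 = background.
#' @param source_role Channel role the mask was derived from.
#' @param parent Named integer vector mapping label -> parent nucleus label,
#'   or NULL.
#' @param border Integer vector of border-touching labels.
#' @return A `labeled_mask` object.
#' @export
labeled_mask <- function(labels, source_role = NA_character_, parent = NULL,
                         border = integer(0)) {
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, source_role = source_role,
                 parent = parent, border = as.integer(border)),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  k <- max(x$labels)
  cat("Labeled mask: ", k, " region(s) from '", x$source_role, "' over ",
      paste(dim(x$labels), collapse = " x "), " px", sep = "")
  if (length(x$border)) cat("; ", length(x$border), " touching border")
  cat("\n")
  invisible(x)
}

#' Labels present in a mask
#' @param mask A [labeled_mask()].
#' @return Integer vector of region labels (excluding background).
#' @export
mask_labels <- function(mask) {
  stopifnot(inherits(mask, "labeled_mask"))
  sort(unique(as.integer(mask$labels[mask$labels > 0])))
}
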