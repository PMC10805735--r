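# Threshold-based segmentation of nuclei and nucleoli.
#
# Nuclei: global Otsu on the nucleus-marker channel. Nucleoli: Otsu computed
# per nucleus on the shell-marker histogram inside that nucleus, then hole
# filling so the returned outline is the filled shell territory (ring plus
# enclosed core), not the ring alone.

otsu_threshold <- function(v) {
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1]) || diff(rng) == 0) return(NA_real_)
  norm <- (v - rng[1]) / diff(rng)
  th <- EBImage::otsu(matrix(norm, ncol = 1), range = c(0, 1))
  rng[1] + th * diff(rng)
}

# Connected-component labeling, 2D via EBImage, 3D via 6-neighbour BFS.
label_components <- function(bw) {
  if (length(dim(bw)) == 2)
    return(matrix(as.integer(EBImage::bwlabel(bw * 1)), nrow(bw), ncol(bw)))
  d <- dim(bw)
  lab <- array(0L, d)
  cur <- 0L
  idx_all <- which(bw)
  off <- c(-1L, 1L, -d[1], d[1], -d[1] * d[2], d[1] * d[2])
  n <- prod(d)
  coord_ok <- function(from, to, axis_off) {
    # guard row wrap for +/-1 offsets
    if (abs(axis_off) == 1) {
      r_from <- (from - 1L) %% d[1]
      !(r_from == 0L && axis_off == -1L) && !(r_from == d[1] - 1L && axis_off == 1L)
    } else TRUE
  }
  for (s in idx_all) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in off) {
        q <- p + o
        if (q < 1L || q > n) next
        if (!coord_ok(p, q, o)) next
        if (abs(o) == d[1]) {
          c_from <- ((p - 1L) %/% d[1]) %% d[2]
          if ((c_from == 0L && o < 0) || (c_from == d[2] - 1L && o > 0)) next
        }
        if (bw[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

fill_holes <- function(bw) {
  if (length(dim(bw)) == 2)
    return(as.matrix(EBImage::fillHull(bw * 1)) > 0)
  d <- dim(bw)
  out <- bw
  for (z in seq_len(d[3]))
    out[, , z] <- as.matrix(EBImage::fillHull(bw[, , z] * 1)) > 0
  out
}

region_areas <- function(lab) {
  t <- tabulate(lab[lab > 0])
  stats::setNames(t, seq_along(t))
}

border_labels <- function(lab) {
  d <- dim(lab)
  edge <- if (length(d) == 2) {
    c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]])
  } else {
    c(lab[1, , ], lab[d[1], , ], lab[, 1, ], lab[, d[2], ])
  }
  sort(unique(edge[edge > 0]))
}

relabel_consecutive <- function(lab, keep) {
  map <- integer(max(lab, 1L))
  map[keep] <- seq_along(keep)
  out <- lab
  pos <- lab > 0
  out[pos] <- ifelse(lab[pos] %in% keep, map[lab[pos]], 0L)
  out
}

#' Segment nuclei from the nucleus-marker channel
#'
#' Global Otsu threshold (or a fixed override), hole filling,
#' connected-component labeling and minimum-area filtering. Regions touching
#' the image border are kept but flagged so downstream stages can exclude
#' them.
#'
#' @param field An [image_field()] with a `nucleus_marker` channel (or the
#'   role named by `role`).
#' @param role Channel role to threshold.
#' @param threshold Fixed threshold overriding Otsu, or NULL.
#' @param min_area Minimum region area in pixels (voxels if 3D).
#' @param fill If TRUE, fill holes before labeling.
#' @return A [labeled_mask()] with consecutive labels and `border` flags.
#' @export
segment_nuclei <- function(field, role = "nucleus_marker", threshold = NULL,
                           min_area = 2000, fill = TRUE) {
  img <- get_channel(field, role)
  th <- threshold %||% otsu_threshold(as.numeric(img))
  if (is.na(th))
    stopf("no regions: '%s' channel is constant, threshold degenerate", role)
  bw <- img > th
  if (!any(bw)) stopf("no regions: nothing above threshold %g", th)
  if (fill) bw <- fill_holes(bw)
  lab <- label_components(bw)
  areas <- region_areas(lab)
  keep <- as.integer(names(areas))[areas >= min_area]
  if (!length(keep))
    stopf("no regions: all %d candidate(s) below min_area %g",
          length(areas), min_area)
  lab <- relabel_consecutive(lab, keep)
  labeled_mask(lab, source_role = role, border = border_labels(lab))
}

solidity2d <- function(lab, label) {
  px <- which(lab == label, arr.ind = TRUE)
  if (nrow(px) < 4) return(1)
  hull <- grDevices::chull(px)
  hp <- px[hull, , drop = FALSE]
  n <- nrow(hp)
  area_hull <- abs(sum(hp[, 1] * hp[c(2:n, 1), 2] -
                         hp[c(2:n, 1), 1] * hp[, 2])) / 2
  if (area_hull <= 0) return(1)
  min(1, nrow(px) / area_hull)
}

#' Segment nucleoli within nuclei from the shell-marker channel
#'
#' For each nucleus, an Otsu threshold is computed on the shell-marker
#' histogram restricted to that nucleus; candidate regions are hole-filled
#' (the nucleolar outline is the filled shell territory), labeled, and
#' cleaned by minimum area and minimum solidity. Each surviving nucleolus is
#' assigned its parent nucleus. A field with no shell signal yields zero
#' labels without error.
#'
#' @param field An [image_field()].
#' @param nuclei A [labeled_mask()] of nuclei.
#' @param role Channel role of the shell marker.
#' @param threshold Fixed threshold overriding per-nucleus Otsu, or NULL.
#' @param min_area Minimum nucleolus area in pixels (default pi * 5^2).
#' @param min_solidity Minimum area / convex-hull-area (2D planes only).
#' @param min_contrast Minimum separation between the Otsu threshold and the
#'   within-nucleus median, in units of the median absolute deviation;
#'   nuclei with weaker contrast (no real shell signal, only noise) yield no
#'   candidates. 0 disables the guard.
#' @param fill If TRUE, fill holes (keeps ring-shaped shells filled).
#' @return A [labeled_mask()] with consecutive labels, `parent` mapping to
#'   nucleus labels, and an `attr(, "log")` listing excluded candidates.
#' @export
segment_nucleoli <- function(field, nuclei, role = "shell_marker",
                             threshold = NULL, min_area = pi * 25,
                             min_solidity = 0.7, min_contrast = 2,
                             fill = TRUE) {
  stopifnot(inherits(nuclei, "labeled_mask"))
  img <- get_channel(field, role)
  nlab <- nuclei$labels
  stopifnot(all(dim(img) == dim(nlab)))
  is3d <- length(dim(img)) == 3
  out <- array(0L, dim(img))
  parent <- integer(0)
  log <- list(dropped_small = 0L, dropped_solidity = 0L,
              dropped_outside = 0L, empty_nuclei = 0L)
  nxt <- 0L
  for (nl in mask_labels(nuclei)) {
    inside <- nlab == nl
    vals <- img[inside]
    th <- threshold %||% otsu_threshold(vals)
    if (is.na(th)) { log$empty_nuclei <- log$empty_nuclei + 1L; next }
    if (is.null(threshold) && min_contrast > 0 &&
        th - stats::median(vals) < min_contrast * stats::mad(vals)) {
      log$empty_nuclei <- log$empty_nuclei + 1L; next
    }
    bw <- array(FALSE, dim(img))
    bw[inside] <- img[inside] > th
    if (!any(bw)) { log$empty_nuclei <- log$empty_nuclei + 1L; next }
    if (fill) {
      bw <- fill_holes(bw)
      bw <- bw & inside  # hole fill cannot escape the nucleus
    }
    lab <- label_components(bw)
    areas <- region_areas(lab)
    for (k in as.integer(names(areas))) {
      if (areas[[k]] < min_area) { log$dropped_small <- log$dropped_small + 1L; next }
      if (!is3d && min_solidity > 0 && solidity2d(lab, k) < min_solidity) {
        log$dropped_solidity <- log$dropped_solidity + 1L; next
      }
      nxt <- nxt + 1L
      out[lab == k] <- nxt
      parent[as.character(nxt)] <- nl
    }
  }
  m <- labeled_mask(out, source_role = role,
                    parent = if (nxt > 0) stats::setNames(as.integer(parent),
                                                          names(parent)),
                    border = border_labels(out))
  attr(m, "log") <- log
  m
}

#' Binary centroid of a labeled region
#'
#' Unweighted mean of the 0-based pixel coordinates of the region, computed
#' in 3D when the mask is 3D.
#'
#' @param mask A [labeled_mask()].
#' @param label Region label.
#' @return Numeric vector `(r, c)` or `(r, c, z)` in 0-based pixel
#'   coordinates.
#' @export
centroid <- function(mask, label) {
  stopifnot(inherits(mask, "labeled_mask"))
  px <- which(mask$labels == label, arr.ind = TRUE)
  if (nrow(px) == 0) stopf("label %s not present in mask", label)
  cen <- colMeans(px) - 1
  names(cen) <- c("r", "c", "z")[seq_along(cen)]
  cen
}

#' Per-nucleus mean intensity of one channel
#'
#' Arithmetic mean of a channel over each labeled nucleus, the quantity used
#' to compare nuclear signal levels between conditions. Border-touching
#' nuclei are flagged in the output.
#'
#' @param field An [image_field()].
#' @param nuclei A [labeled_mask()] of nuclei.
#' @param role Channel role to average.
#' @return Data frame with columns `nucleus`, `mean_intensity`, `area_px`,
#'   `border`.
#' @export
nuclear_mean_intensity <- function(field, nuclei, role = "target") {
  img <- get_channel(field, role)
  stopifnot(inherits(nuclei, "labeled_mask"),
            all(dim(img) == dim(nuclei$labels)))
  labs <- mask_labels(nuclei)
  means <- vapply(labs, function(l) mean(img[nuclei$labels == l]), 0)
  areas <- vapply(labs, function(l) sum(nuclei$labels == l), 0)
  data.frame(nucleus = labs, mean_intensity = means, area_px = areas,
             border = labs %in% nuclei$border)
}

#' Intersection-over-union between two label masks
#'
#' Matches each reference label to the test label with the largest overlap
#' and reports per-reference IoU; used to score segmentation against
#' synthetic ground truth.
#'
#' @param truth,test [labeled_mask()] objects on the same grid.
#' @return Data frame with columns `truth_label`, `matched_label`, `iou`.
#' @export
mask_iou <- function(truth, test) {
  tl <- truth$labels; sl <- test$labels
  stopifnot(all(dim(tl) == dim(sl)))
  res <- lapply(mask_labels(truth), function(l) {
    sel <- tl == l
    cand <- sl[sel]
    cand <- cand[cand > 0]
    if (!length(cand))
      return(data.frame(truth_label = l, matched_label = NA_integer_, iou = 0))
    m <- as.integer(names(which.max(table(cand))))
    inter <- sum(sel & sl == m)
    union <- sum(sel | sl == m)
    data.frame(truth_label = l, matched_label = m, iou = inter / union)
  })
  do.call(rbind, res)
}
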