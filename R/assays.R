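# Table-based assay quantification: gel crosslink-protection fractions and
# ChIP-qPCR percent input with control normalization.

#' Crosslink-protection fraction from gel band intensities
#'
#' Fraction of crosslinked (heat-protected) DNA: non-denatured band divided
#' by the total band, clipped to \[0, 1\] (noise can push the raw ratio
#' slightly above 1; clipping is flagged, not an error).
#'
#' @param band_nondenatured,band_total Band intensities (vectorized).
#' @return Numeric fractions with attribute `clipped` (logical vector).
#' @export
crosslink_fraction <- function(band_nondenatured, band_total) {
  stopifnot(length(band_nondenatured) == length(band_total))
  if (any(!is.finite(band_total)) || any(band_total <= 0))
    stopf("band_total must be positive")
  if (any(band_nondenatured < 0))
    stopf("band intensities must be non-negative")
  raw <- band_nondenatured / band_total
  clipped <- raw > 1
  structure(pmin(raw, 1), clipped = clipped)
}

#' Crosslink fractions for a gel lane table
#'
#' @param gel Data frame with columns `band_nondenatured`, `band_total`
#'   (e.g. from [generate_assay_tables()]).
#' @return The table with `fraction` and `clipped` columns appended.
#' @export
crosslink_fraction_table <- function(gel) {
  stopifnot(all(c("band_nondenatured", "band_total") %in% names(gel)))
  f <- crosslink_fraction(gel$band_nondenatured, gel$band_total)
  gel$fraction <- as.numeric(f)
  gel$clipped <- attr(f, "clipped")
  gel
}

#' ChIP-qPCR percent input
#'
#' `percent_input = 100 * input_fraction * efficiency^(input_ct - ip_ct)`:
#' the
#' IP signal expressed as a percentage of total input chromatin, assuming a
#' fixed amplification efficiency (2 = perfect doubling). Equivalent to the
#' adjusted-input formulation in which the input Ct is corrected by
#' `log2(1/input_fraction)`.
#'
#' @param ip_ct,input_ct Ct values (vectorized).
#' @param input_fraction Fraction of chromatin set aside as input
#'   (default 0.02 for a 2 percent aliquot).
#' @param efficiency Per-cycle amplification factor.
#' @return Percent input values.
#' @export
percent_input <- function(ip_ct, input_ct, input_fraction = 0.02,
                          efficiency = 2) {
  stopifnot(input_fraction > 0, input_fraction < 1, efficiency > 1)
  if (any(!is.finite(ip_ct)) || any(!is.finite(input_ct)))
    stopf("Ct values must be finite")
  100 * input_fraction * efficiency^(input_ct - ip_ct)
}

#' Percent input for a long Ct table
#'
#' Pairs each IP row with the `input` row of the same (region, condition,
#' replicate) and computes [percent_input()].
#'
#' @param chip Long Ct table with columns `target_region`, `antibody`
#'   (including `input` rows), `condition`, `replicate`, `ct`,
#'   `input_fraction`.
#' @param efficiency Per-cycle amplification factor.
#' @return Data frame with one row per IP measurement and a `percent_input`
#'   column.
#' @export
chip_percent_input <- function(chip, efficiency = 2) {
  need <- c("target_region", "antibody", "condition", "replicate", "ct",
            "input_fraction")
  stopifnot(all(need %in% names(chip)))
  inputs <- chip[chip$antibody == "input", ]
  ips <- chip[chip$antibody != "input", ]
  key <- function(d) paste(d$target_region, d$condition, d$replicate)
  m <- match(key(ips), key(inputs))
  if (anyNA(m))
    stopf("missing input Ct for %s",
          paste(unique(key(ips)[is.na(m)]), collapse = "; "))
  ips$percent_input <- percent_input(ips$ct, inputs$ct[m],
                                     ips$input_fraction, efficiency)
  rownames(ips) <- NULL
  ips
}

#' Normalize percent input by the control condition
#'
#' Divides each percent-input value by the matched control value for the
#' same (region, antibody, replicate); control entries become exactly 1,
#' ready for a one-sample t-test against 1. Normalization is within
#' replicate; tests are across replicates.
#'
#' @param tab Data frame with columns `target_region`, `antibody`,
#'   `condition`, `replicate`, `percent_input`.
#' @param control_condition Condition used as the denominator.
#' @return The table with a `normalized` column appended.
#' @export
normalize_percent_input <- function(tab, control_condition = "water") {
  need <- c("target_region", "antibody", "condition", "replicate",
            "percent_input")
  stopifnot(all(need %in% names(tab)))
  ctrl <- tab[tab$condition == control_condition, ]
  key <- function(d) paste(d$target_region, d$antibody, d$replicate)
  m <- match(key(tab), key(ctrl))
  bad <- is.na(m) | ctrl$percent_input[m] == 0
  if (any(bad)) {
    miss <- unique(paste0("(", tab$target_region[bad], ", ",
                          tab$antibody[bad], ")"))
    stopf("missing or zero control '%s' percent input for %s",
          control_condition, paste(miss, collapse = ", "))
  }
  tab$normalized <- tab$percent_input / ctrl$percent_input[m]
  tab
}

#' One-sample t-tests of normalized percent input against 1
#'
#' For each (region, antibody) in the treated condition, tests whether the
#' control-normalized percent input differs from the null expectation of 1
#' across replicates.
#'
#' @param tab Output of [normalize_percent_input()].
#' @param condition Treated condition to test.
#' @return Data frame with `target_region`, `antibody`, `mean_normalized`,
#'   `statistic`, `p_value`, `n`.
#' @export
chip_tests <- function(tab, condition) {
  stopifnot("normalized" %in% names(tab))
  d <- tab[tab$condition == condition, ]
  combos <- unique(d[, c("target_region", "antibody")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- d$target_region == combos$target_region[i] &
      d$antibody == combos$antibody[i]
    x <- d$normalized[sel]
    r <- one_sample_t(x, 1)
    data.frame(target_region = combos$target_region[i],
               antibody = combos$antibody[i],
               mean_normalized = mean(x), statistic = r$statistic,
               p_value = r$p_value, n = length(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
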