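# Nonparametric group comparisons for window means and nuclear intensities:
# two-sided Mann-Whitney U (exact by enumeration for small tie-free samples,
# otherwise normal approximation with continuity correction and tie-corrected
# variance) and the two-sided Steel-Dwass all-pairs test referred to the
# studentized-range distribution with infinite degrees of freedom. Both are
# implemented here directly; paired and one-sample t wrap stats::t.test.

#' Test result container
#'
#' @param test_name Test identity.
#' @param statistic Test statistic.
#' @param p_value Two-sided p-value.
#' @param n_per_group Integer group sizes.
#' @param method_variant One of `exact`, `normal_tie_corrected`,
#'   `studentized_range`, `permutation`, `t`.
#' @param pair Optional character pair of group labels.
#' @param flags Character flags (e.g. `degenerate`).
#' @return A `test_result` object.
#' @export
test_result <- function(test_name, statistic, p_value, n_per_group,
                        method_variant, pair = NULL, flags = character(0)) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, n_per_group = as.integer(n_per_group),
                 method_variant = method_variant, pair = pair,
                 flags = flags),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$test_name,
      if (!is.null(x$pair)) paste0(" [", paste(x$pair, collapse = " vs "), "]"),
      ": statistic = ", signif(x$statistic, 5),
      ", p = ", signif(x$p_value, 4),
      " (", x$method_variant, "; n = ",
      paste(x$n_per_group, collapse = ", "), ")",
      if (length(x$flags)) paste0(" flags: ", paste(x$flags, collapse = ",")),
      "\n", sep = "")
  invisible(x)
}

mw_exact_cap <- 14L

#' Two-sided Mann-Whitney U test
#'
#' U is computed from mid-ranks. In `auto` mode the exact two-sided p-value
#' is obtained by full enumeration of rank assignments when
#' `n_x + n_y <= 14` and there are no ties; otherwise the normal
#' approximation with continuity correction and tie-corrected variance is
#' used. Two-sided p is `min(1, 2 * min-tail)`. Samples with zero pooled
#' variance give p = 1 with a `degenerate` flag.
#'
#' @param x,y Numeric samples.
#' @param mode `auto`, `exact` (forced enumeration, capped at a pooled size
#'   of 14), or `approx`.
#' @param correct Apply the continuity correction in the normal
#'   approximation.
#' @return A [test_result()] with statistic U (for `x`).
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx"),
                           correct = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(x) >= 1, length(y) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- as.integer(table(pooled))
  has_ties <- any(ties > 1)

  if (length(unique(pooled)) == 1)
    return(test_result("Mann-Whitney U", U1, 1, c(n1, n2),
                       "normal_tie_corrected", flags = "degenerate"))

  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = N <= mw_exact_cap && !has_ties)
  if (use_exact && N > mw_exact_cap)
    stopf("exact enumeration capped at pooled n = %d (got %d)",
          mw_exact_cap, N)

  if (use_exact) {
    combos <- utils::combn(N, n1)
    Us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(Us <= U1), mean(Us >= U1)))
    return(test_result("Mann-Whitney U", U1, p, c(n1, n2), "exact"))
  }

  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0)
    return(test_result("Mann-Whitney U", U1, 1, c(n1, n2),
                       "normal_tie_corrected", flags = "degenerate"))
  dev <- U1 - mu
  cc <- if (correct) sign(dev) * min(0.5, abs(dev)) else 0
  z <- (dev - cc) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  test_result("Mann-Whitney U", U1, p, c(n1, n2), "normal_tie_corrected")
}

#' Survival function of the studentized range (infinite df)
#'
#' `P(Q_{k,inf} >= q)` for the range of k independent standard normals,
#' evaluated by numerical integration of the normal kernel
#' (`1 - k * Integral phi(z) [Phi(z) - Phi(z - q)]^(k-1) dz`) to absolute
#' tolerance 1e-8. Used to refer Steel-Dwass pairwise statistics.
#'
#' @param q Quantile (scalar).
#' @param k Number of groups.
#' @param abs_tol Absolute integration tolerance.
#' @return Upper-tail probability in \[0, 1\].
#' @export
sr_survival <- function(q, k, abs_tol = 1e-8) {
  stopifnot(length(q) == 1, is_count(k), k >= 2)
  if (!is.finite(q)) return(if (q > 0) 0 else 1)
  if (q <= 0) return(1)
  integrand <- function(z)
    k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q))^(k - 1)
  cdf <- stats::integrate(integrand, -Inf, Inf,
                          abs.tol = abs_tol / 10, rel.tol = 1e-10,
                          subdivisions = 400L)$value
  min(1, max(0, 1 - cdf))
}

sd_pair_stat <- function(xi, xj) {
  ni <- length(xi); nj <- length(xj); N <- ni + nj
  pooled <- c(xi, xj)
  r <- rank(pooled, ties.method = "average")
  Ri <- sum(r[seq_len(ni)])
  Ei <- ni * (N + 1) / 2
  ties <- as.integer(table(pooled))
  V <- ni * nj / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  list(t = if (V > 0) (Ri - Ei) / sqrt(V) else 0, V = V, ni = ni, nj = nj)
}

#' Two-sided Steel-Dwass all-pairs test
#'
#' For every pair of groups, mid-ranks are computed within the pooled pair,
#' the standardized rank-sum statistic t uses the tie-corrected variance,
#' and the two-sided p-value is `P(Q_{k,inf} >= sqrt(2) |t|)` with
#' `Q_{k,inf}` the studentized range for k groups at infinite degrees of
#' freedom ([sr_survival()]). This controls the family-wise error over all
#' pairs without a preceding omnibus test. At k = 2 it reduces to the
#' two-sided normal-approximation Mann-Whitney test (no continuity
#' correction).
#'
#' A `permutation` method is available as a reference: pairwise p is the
#' probability that the maximum absolute standardized pair statistic over
#' relabelings reaches the observed |t|.
#'
#' @param groups Named list of numeric samples (k >= 2).
#' @param method `studentized_range` (default) or `permutation`.
#' @param n_perm Number of resamples for the permutation method.
#' @return A `steel_dwass_result`: list of [test_result()], one per pair.
#' @export
steel_dwass <- function(groups, method = c("studentized_range", "permutation"),
                        n_perm = 1e5) {
  method <- match.arg(method)
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 0L) >= 1))
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_along(groups))
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  obs <- apply(pairs, 2, function(ij)
    sd_pair_stat(groups[[ij[1]]], groups[[ij[2]]]))

  if (method == "permutation") {
    pooled <- unlist(groups, use.names = FALSE)
    sizes <- vapply(groups, length, 0L)
    grp_idx <- rep(seq_len(k), sizes)
    tmax <- numeric(n_perm)
    npairs <- ncol(pairs)
    for (b in seq_len(n_perm)) {
      perm <- sample(grp_idx)
      tb <- 0
      for (pc in seq_len(npairs)) {
        i <- pairs[1, pc]; j <- pairs[2, pc]
        st <- sd_pair_stat(pooled[perm == i], pooled[perm == j])
        tb <- max(tb, abs(st$t))
      }
      tmax[b] <- tb
    }
    res <- lapply(seq_len(ncol(pairs)), function(pc) {
      st <- obs[[pc]]
      p <- mean(tmax >= abs(st$t) - 1e-12)
      flags <- if (st$V == 0) "degenerate" else character(0)
      if (st$V == 0) p <- 1
      test_result("Steel-Dwass", st$t, p, c(st$ni, st$nj), "permutation",
                  pair = names(groups)[pairs[, pc]], flags = flags)
    })
  } else {
    res <- lapply(seq_len(ncol(pairs)), function(pc) {
      st <- obs[[pc]]
      if (st$V == 0)
        return(test_result("Steel-Dwass", 0, 1, c(st$ni, st$nj),
                           "studentized_range",
                           pair = names(groups)[pairs[, pc]],
                           flags = "degenerate"))
      p <- sr_survival(sqrt(2) * abs(st$t), k)
      test_result("Steel-Dwass", st$t, p, c(st$ni, st$nj),
                  "studentized_range", pair = names(groups)[pairs[, pc]])
    })
  }
  structure(res, class = "steel_dwass_result", k = k)
}

#' @export
print.steel_dwass_result <- function(x, ...) {
  cat("Steel-Dwass all-pairs comparison (k =", attr(x, "k"), "groups):\n")
  for (r in x) { cat("  "); print(r) }
  invisible(x)
}

#' Two-sided paired t-test
#'
#' @param x,y Paired numeric samples of equal length >= 2.
#' @return A [test_result()].
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  d <- x - y
  if (stats::sd(d) == 0)
    stopf("paired t undefined: differences have zero variance")
  tt <- stats::t.test(x, y, paired = TRUE)
  test_result("paired t", unname(tt$statistic), tt$p.value,
              c(length(x), length(y)), "t")
}

#' Two-sided one-sample t-test
#'
#' @param x Numeric sample, n >= 2.
#' @param mu0 Null-hypothesis mean (1 for control-normalized percent input).
#' @return A [test_result()].
#' @export
one_sample_t <- function(x, mu0 = 1) {
  stopifnot(length(x) >= 2, all(is.finite(x)), is.finite(mu0))
  if (stats::sd(x) == 0)
    stopf("one-sample t undefined: sample has zero variance")
  tt <- stats::t.test(x, mu = mu0)
  test_result("one-sample t", unname(tt$statistic), tt$p.value, length(x), "t")
}

#' Compare window means across conditions
#'
#' For the inside and outside windows separately, runs a two-sided
#' Mann-Whitney U test (two conditions) or the Steel-Dwass all-pairs test
#' (three or more). Refuses to compare window means computed with different
#' profiling parameters.
#'
#' @param wm Named list of window-means data frames (from
#'   [window_means_table()]), one per condition, or a single data frame
#'   with a `condition` column.
#' @param design `auto` picks by the number of conditions; `two_group` and
#'   `k_group` force the corresponding test.
#' @return Data frame with one row per (window, pair): `window`, `test`,
#'   `group1`, `group2`, `n1`, `n2`, `statistic`, `p_value`, `variant`,
#'   `flags`; per-condition nucleolus/cell counts in
#'   `attr(, "group_sizes")`.
#' @export
compare_conditions <- function(wm, design = c("auto", "two_group", "k_group")) {
  design <- match.arg(design)
  if (is.data.frame(wm)) wm <- split(wm, wm$condition)
  stopifnot(is.list(wm), length(wm) >= 2)
  pp <- lapply(wm, attr, "profile_params")
  pp <- pp[!vapply(pp, is.null, TRUE)]
  if (length(pp) > 1) {
    for (q in pp[-1]) if (!isTRUE(all.equal(pp[[1]], q)))
      stopf("window means were computed with different profiling parameters")
  }
  k <- length(wm)
  use_sd <- design == "k_group" || (design == "auto" && k > 2)
  if (design == "two_group" && k != 2)
    stopf("two_group design requires exactly 2 conditions, got %d", k)
  rows <- list()
  for (win in c("inside", "outside")) {
    col <- paste0(win, "_mean")
    groups <- lapply(wm, function(d) d[[col]])
    if (use_sd) {
      sdres <- steel_dwass(groups)
      for (r in sdres)
        rows[[length(rows) + 1L]] <- data.frame(
          window = win, test = r$test_name, group1 = r$pair[1],
          group2 = r$pair[2], n1 = r$n_per_group[1], n2 = r$n_per_group[2],
          statistic = r$statistic, p_value = r$p_value,
          variant = r$method_variant,
          flags = paste(r$flags, collapse = ","))
    } else {
      nm <- names(wm)
      for (i in 1:(k - 1)) for (j in (i + 1):k) {
        r <- mann_whitney_u(groups[[i]], groups[[j]])
        rows[[length(rows) + 1L]] <- data.frame(
          window = win, test = r$test_name, group1 = nm[i], group2 = nm[j],
          n1 = r$n_per_group[1], n2 = r$n_per_group[2],
          statistic = r$statistic, p_value = r$p_value,
          variant = r$method_variant,
          flags = paste(r$flags, collapse = ","))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "group_sizes") <- data.frame(
    condition = names(wm),
    n_nucleoli = vapply(wm, nrow, 0L),
    n_cells = vapply(wm, function(d)
      length(unique(paste(d$field_id, d$cell_id))), 0L))
  out
}
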