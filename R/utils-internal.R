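# Internal numeric helpers shared across modules.
#
# Coordinate convention (used everywhere in this package): pixel centers sit
# at integer 0-based (row, col[, plane]) coordinates; matrix element [i, j]
# is the pixel at (i - 1, j - 1).

# Vectorized bilinear interpolation of a matrix at continuous 0-based
# coordinates. Points outside [0, nrow-1] x [0, ncol-1] give NA.
bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(r))
  ok <- r >= 0 & r <= nr - 1 & c >= 0 & c <= nc - 1 &
    is.finite(r) & is.finite(c)
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nr - 2); c0 <- pmin(floor(c), nc - 2)
  r0 <- pmax(r0, 0); c0 <- pmax(c0, 0)
  fr <- r - r0; fc <- c - c0
  i <- r0 + 1L; j <- c0 + 1L
  v00 <- img[cbind(i, j)]
  v10 <- img[cbind(i + 1L, j)]
  v01 <- img[cbind(i, j + 1L)]
  v11 <- img[cbind(i + 1L, j + 1L)]
  out[ok] <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
  out
}

# Nearest-pixel lookup at continuous 0-based coordinates; NA outside.
nearest_px <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  i <- as.integer(round(r)) + 1L
  j <- as.integer(round(c)) + 1L
  out <- rep(NA_real_, length(r))
  ok <- !is.na(i) & !is.na(j) & i >= 1L & i <= nr & j >= 1L & j <= nc
  out[ok] <- img[cbind(i[ok], j[ok])]
  out
}

# Midranks with tie bookkeeping: returns list(ranks, tie_sizes).
midranks <- function(x) {
  r <- rank(x, ties.method = "average")
  list(ranks = r, ties = as.integer(table(x)))
}

is_count <- function(x) length(x) == 1 && is.finite(x) && x == round(x) && x > 0

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
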