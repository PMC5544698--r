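# Internal numerical helpers shared across modules.

# Bilinear sample of matrix `m` at fractional (row, col) positions.
# Returns NA outside [1, nrow] x [1, ncol].
bilinear_sample <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc & !is.na(r) & !is.na(c)
  out <- rep(NA_real_, length(r))
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  r0 <- pmax(r0, 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * nr + r0
  v <- (1 - fr) * (1 - fc) * m[i00] +
    fr * (1 - fc) * m[i00 + 1] +
    (1 - fr) * fc * m[i00 + nr] +
    fr * fc * m[i00 + nr + 1]
  out[ok] <- v
  out
}

# Linear interpolation along each row of `m` at per-pixel fractional
# column offsets: result[r, c] = m[r, c + shift[r, c]]; NA out of range.
row_shift_sample <- function(m, shift) {
  nr <- nrow(m); nc <- ncol(m)
  cq <- matrix(rep(seq_len(nc), each = nr), nr, nc) + shift
  out <- matrix(NA_real_, nr, nc)
  ok <- !is.na(cq) & cq >= 1 & cq <= nc
  if (!any(ok)) return(out)
  rr <- row(m)[ok]; cc <- cq[ok]
  c0 <- pmax(pmin(floor(cc), nc - 1L), 1L)
  f <- cc - c0
  i0 <- (c0 - 1) * nr + rr
  out[ok] <- (1 - f) * m[i0] + f * m[i0 + nr]
  out
}

# Cubic B-spline interpolation coefficients of each row (recursive
# causal/anticausal prefilter, pole sqrt(3) - 2, truncated-horizon
# initialization). Prefiltered B-spline warping has an even-dominant
# interpolation error, so — unlike linear or Catmull-Rom interpolation —
# it does not bias sub-pixel displacement estimates.
bspline_row_coef <- function(m) {
  z <- sqrt(3) - 2
  nc <- ncol(m)
  c6 <- 6 * m
  h <- min(nc, ceiling(log(1e-12) / log(abs(z))))
  cp <- matrix(0, nrow(m), nc)
  cp[, 1] <- c6[, seq_len(h), drop = FALSE] %*% z^(seq_len(h) - 1)
  for (i in 2:nc) cp[, i] <- c6[, i] + z * cp[, i - 1]
  cm <- matrix(0, nrow(m), nc)
  cm[, nc] <- (z / (z^2 - 1)) * (cp[, nc] + z * cp[, nc - 1])
  for (i in (nc - 1):1) cm[, i] <- z * (cm[, i + 1] - cp[, i])
  cm
}

# Evaluate the row-wise B-spline interpolant at per-pixel fractional
# column offsets: result[r, c] ~= m[r, c + shift[r, c]]; NA out of range.
bspline_row_sample <- function(cf, shift) {
  nr <- nrow(cf); nc <- ncol(cf)
  cq <- matrix(rep(seq_len(nc), each = nr), nr, nc) + shift
  out <- matrix(NA_real_, nr, nc)
  ok <- !is.na(cq) & cq >= 1 & cq <= nc
  if (!any(ok)) return(out)
  rr <- row(cf)[ok]; cc <- cq[ok]
  i0 <- floor(cc); t <- cc - i0
  w <- list((1 - t)^3 / 6,
            (4 - 6 * t^2 + 3 * t^3) / 6,
            (1 + 3 * t + 3 * t^2 - 3 * t^3) / 6,
            t^3 / 6)
  acc <- 0
  for (k in 0:3) {
    idx <- pmin(pmax(i0 - 1L + k, 1L), nc)     # replicate boundary
    acc <- acc + w[[k + 1]] * cf[rr + (idx - 1) * nr]
  }
  out[ok] <- acc
  out
}

# Separable Gaussian smoothing with replicate (clamped) borders.
smooth_gauss <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (j in -h:h) {                       # along columns
    idx <- pmin(pmax(seq_len(nc) + j, 1L), nc)
    out <- out + k[j + h + 1] * m[, idx, drop = FALSE]
  }
  m2 <- matrix(0, nr, nc)
  for (j in -h:h) {                       # along rows
    idx <- pmin(pmax(seq_len(nr) + j, 1L), nr)
    m2 <- m2 + k[j + h + 1] * out[idx, , drop = FALSE]
  }
  m2
}

# Sum over a k x k neighborhood (k odd), truncated at the borders.
boxsum <- function(m, k) {
  h <- (k - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  hi <- pmin(seq_len(nr) + h, nr) + 1L
  lo <- pmax(seq_len(nr) - h, 1L)
  m1 <- cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  cs <- cbind(0, t(apply(m1, 1, cumsum)))
  hi <- pmin(seq_len(nc) + h, nc) + 1L
  lo <- pmax(seq_len(nc) - h, 1L)
  cs[, hi, drop = FALSE] - cs[, lo, drop = FALSE]
}

# Central difference along columns (spatial axis), one-sided at borders.
col_gradient <- function(m) {
  nc <- ncol(m)
  g <- (m[, pmin(seq_len(nc) + 1L, nc), drop = FALSE] -
          m[, pmax(seq_len(nc) - 1L, 1L), drop = FALSE])
  div <- rep(2, nc); div[c(1L, nc)] <- 1
  sweep(g, 2, div, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
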