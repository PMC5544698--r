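# Shear alignment to the moving growth cone, velocity-versus-distance
# profiles, transition-zone alignment, across-cell averaging, and the
# regression utilities.

#' Track the growth cone across a kymograph
#'
#' `method = "edge"` takes, per frame, the most distal (rightmost)
#' column whose intensity exceeds an Otsu-derived threshold, fills
#' frames with no supra-threshold pixel by linear interpolation
#' (erroring when more than half the frames are empty), and median-
#' filters the track. `method = "trace"` uses a supplied polyline
#' (frame, position) instead. The growth-cone velocity is the
#' calibrated least-squares slope of position versus time.
#'
#' @param kymo a [kymograph()].
#' @param method `"edge"` or `"trace"`.
#' @param trace data frame with columns `frame`, `position` (required
#'   for `method = "trace"`).
#' @param median_k window of the median filter (odd).
#' @return An object of class `gc_track`: `position` (per-frame column,
#'   px), `velocity_um_h`, and the calibration used.
#' @export
estimate_gc_track <- function(kymo, method = c("edge", "trace"),
                              trace = NULL, median_k = 9L) {
  method <- match.arg(method)
  nr <- nrow(kymo$grid)
  if (method == "trace") {
    if (is.null(trace)) stopf("`trace` required for method = 'trace'")
    pos <- approx(trace$frame, trace$position, xout = seq_len(nr),
                  rule = 2)$y
  } else {
    g <- kymo$grid
    # clip the brightest 0.5% (overlapping speckles, fast events) so a
    # few hot pixels cannot compress the histogram under the threshold
    g <- pmin(g, quantile(g, 0.995))
    rng <- range(g)
    gn <- (g - rng[1]) / max(rng[2] - rng[1], 1e-12)
    # Otsu bisects the speckle and background modes; half of it still
    # clears the noise floor while catching dim individual speckles at
    # the leading edge
    thr <- EBImage::otsu(EBImage::Image(gn), range = c(0, 1)) / 2
    pos <- apply(gn > thr, 1, function(row) {
      w <- which(row)
      if (length(w)) max(w) else NA_real_
    })
    if (mean(is.na(pos)) > 0.5)
      stopf("growth-cone detection failed: >50%% of frames have no signal")
    if (anyNA(pos))
      pos <- approx(seq_len(nr)[!is.na(pos)], pos[!is.na(pos)],
                    xout = seq_len(nr), rule = 2)$y
    if (nr >= median_k) pos <- runmed(pos, median_k)
  }
  t_h <- (seq_len(nr) - 1) * kymo$frame_interval_s / 3600
  slope_px_h <- unname(coef(lm(pos ~ t_h))[2])
  structure(list(position = as.numeric(pos),
                 velocity_um_h = slope_px_h * kymo$pixel_size_um,
                 pixel_size_um = kymo$pixel_size_um,
                 frame_interval_s = kymo$frame_interval_s),
            class = "gc_track")
}

#' Shear-align a velocity grid to a moving growth cone
#'
#' Translates row `t` horizontally by `-(position[t] - position[1])` so
#' the growth cone occupies a constant column over time. The default
#' nearest-pixel shift moves pixels without rescaling their values, so
#' the multiset of valid velocities is preserved (interpolating across
#' the sharp retrograde/anterograde transition would fabricate
#' intermediate velocities); `interp = "linear"` is available when the
#' grid holds smooth intensities rather than velocities. Pixels shifted
#' out of range become `NA` (invalid).
#'
#' @param grid numeric matrix (e.g. a calibrated flow map from
#'   [calibrate_flow()]); `NA` marks invalid pixels.
#' @param track a `gc_track` (or numeric vector of per-frame positions,
#'   one per row).
#' @param interp `"nearest"` or `"linear"`.
#' @return The sheared matrix, same shape, `NA` outside the data.
#' @export
shear_align <- function(grid, track, interp = c("nearest", "linear")) {
  interp <- match.arg(interp)
  pos <- if (inherits(track, "gc_track")) track$position else as.numeric(track)
  if (length(pos) != nrow(grid))
    stopf("track must cover all %d rows (got %d)", nrow(grid), length(pos))
  shift <- pos - pos[1]
  if (interp == "nearest") shift <- round(shift)
  out <- row_shift_sample(grid, matrix(shift, nrow(grid), ncol(grid)))
  out
}

#' Column-wise velocity-versus-distance profile of a flow grid
#'
#' Averages each column of a (sheared) calibrated velocity grid over
#' its valid (non-`NA`) pixels. Distance is measured in micrometres
#' from the distal (growth-cone) edge of the grid toward the axon, so
#' the profile reads distal-to-proximal; empty columns are dropped.
#' `ci95 = 1.96 * sd / sqrt(n)` per column.
#'
#' @param grid calibrated velocity matrix (um/h) with `NA` invalid.
#' @param pixel_size_um micrometres per column.
#' @param max_speed_umh speed cutoff: pixels with `|v|` above it are
#'   excluded from the bulk profile. Bulk translocation is slow
#'   (1-100 um/h); motor-driven transport events run at um/s scales and
#'   would otherwise leak large velocities into the column means. The
#'   default `Inf` applies no cutoff.
#' @return An object of class `velocity_profile`: data frame with
#'   columns `distance_um`, `mean_umh`, `ci95_umh`, `n`, distances
#'   strictly increasing; attribute `aligned = FALSE`.
#' @export
profile_from_flow <- function(grid, pixel_size_um, max_speed_umh = Inf) {
  grid[!is.na(grid) & abs(grid) > max_speed_umh] <- NA_real_
  nc <- ncol(grid)
  n <- colSums(!is.na(grid))
  mean_v <- colMeans(grid, na.rm = TRUE)
  sd_v <- apply(grid, 2, sd, na.rm = TRUE)
  ci <- ifelse(n > 1, 1.96 * sd_v / sqrt(n), 0)
  dist <- (nc - seq_len(nc)) * pixel_size_um
  keep <- n >= 1
  prof <- data.frame(distance_um = dist[keep], mean_umh = mean_v[keep],
                     ci95_umh = ci[keep], n = n[keep])
  prof <- prof[order(prof$distance_um), ]
  rownames(prof) <- NULL
  if (!nrow(prof)) stopf("no valid pixels in any column")
  structure(prof, class = c("velocity_profile", "data.frame"),
            aligned = FALSE)
}

#' Align a velocity profile at the transition zone
#'
#' Locates, scanning from the distal end, the first transition from
#' retrograde (negative) to anterograde (positive) mean velocity - the
#' growth cone's transition zone - and shifts the distance axis so this
#' zero crossing sits at 0. Detection scans a 3-bin moving mean (robust
#' to single noisy bins); the crossing itself is interpolated linearly
#' between the raw values of the bracketing bins, so reported distances
#' are never computed from smoothed values. Bin spacing is unchanged
#' (pure translation of the axis). The aligned axis is negative in the
#' peripheral (retrograde) domain and positive toward the axon.
#'
#' @param profile a `velocity_profile`.
#' @return The profile with shifted `distance_um` and attribute
#'   `aligned = TRUE`; on failure (no retrograde-to-anterograde sign
#'   change) the profile is returned unchanged with
#'   `aligned = FALSE` and a warning.
#' @export
align_tzone <- function(profile) {
  v <- profile$mean_umh
  d <- profile$distance_um
  n <- length(v)
  if (n >= 3) {
    sm <- vapply(seq_len(n), function(i) {
      mean(v[max(1, i - 1):min(n, i + 1)])
    }, numeric(1))
  } else sm <- v
  cand <- which(sm[-n] < 0 & sm[-1] >= 0)
  cross_at <- function(i) d[i] + (0 - v[i]) * (d[i + 1] - d[i]) / (v[i + 1] - v[i])
  i_raw <- NA_integer_
  if (length(cand)) {
    # search for the raw sign change near the first smoothed crossing
    i0 <- cand[1]
    near <- intersect(seq(i0 - 1L, i0 + 1L), seq_len(n - 1L))
    hit <- near[v[near] < 0 & v[near + 1L] >= 0]
    if (length(hit)) i_raw <- hit[1]
  }
  if (is.na(i_raw)) {
    raw <- which(v[-n] < 0 & v[-1] >= 0)
    if (length(raw)) i_raw <- raw[1]
  }
  if (is.na(i_raw)) {
    warning("no retrograde-to-anterograde transition found; ",
            "profile returned unaligned")
    attr(profile, "aligned") <- FALSE
    return(profile)
  }
  x0 <- cross_at(i_raw)
  profile$distance_um <- profile$distance_um - x0
  attr(profile, "aligned") <- TRUE
  attr(profile, "tzone_distance_um") <- x0
  profile
}

#' Average aligned velocity profiles across cells
#'
#' Interpolates every profile onto a shared 1-um distance grid and
#' reports, per bin, the across-cell mean, the across-cell 95%
#' confidence interval (`1.96 * sd / sqrt(n)`), and the number of cells
#' contributing. Bins covered by no profile are dropped; bins with a
#' single cell keep `ci95 = NA`.
#'
#' @param profiles list of (aligned) `velocity_profile` objects,
#'   at least two.
#' @param grid_step_um shared grid spacing (um).
#' @return A `velocity_profile` whose `n` counts cells per bin.
#' @export
average_profiles <- function(profiles, grid_step_um = 1) {
  if (length(profiles) < 2L) stopf("need at least 2 profiles to average")
  lims <- vapply(profiles, function(p) range(p$distance_um), numeric(2))
  lo <- max(lims[1, ]); hi <- min(lims[2, ])
  if (lo > hi) stopf("profiles have disjoint distance supports")
  grid <- seq(floor(min(lims[1, ])), ceiling(max(lims[2, ])),
              by = grid_step_um)
  vals <- vapply(profiles, function(p) {
    approx(p$distance_um, p$mean_umh, xout = grid, rule = 1)$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  n <- rowSums(!is.na(vals))
  keep <- n >= 1
  m <- rowMeans(vals, na.rm = TRUE)
  s <- apply(vals, 1, sd, na.rm = TRUE)
  ci <- ifelse(n > 1, 1.96 * s / sqrt(n), NA_real_)
  structure(data.frame(distance_um = grid[keep], mean_umh = m[keep],
                       ci95_umh = ci[keep], n = n[keep]),
            class = c("velocity_profile", "data.frame"),
            aligned = all(vapply(profiles, attr, logical(1), "aligned")))
}

#' @export
plot.velocity_profile <- function(x, shade = TRUE, ...) {
  plot(x$distance_um, x$mean_umh, type = "n",
       xlab = "distance from T-zone (um)", ylab = "velocity (um/h)", ...)
  if (shade && any(is.finite(x$ci95_umh))) {
    ok <- is.finite(x$ci95_umh)
    polygon(c(x$distance_um[ok], rev(x$distance_um[ok])),
            c(x$mean_umh[ok] + x$ci95_umh[ok],
              rev(x$mean_umh[ok] - x$ci95_umh[ok])),
            col = "grey85", border = NA)
  }
  lines(x$distance_um, x$mean_umh, lwd = 2)
  abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Ordinary least-squares regression with a 95% slope interval
#'
#' Thin wrapper around [stats::lm()] reporting the quantities used for
#' the coupling analyses (e.g. axonal microtubule velocity against
#' growth-cone velocity): slope with normal-theory 95% CI, intercept,
#' r-squared, and the two-sided p-value for slope = 0.
#'
#' @param x,y numeric vectors, `n >= 3`, `x` non-degenerate.
#' @return An object of class `regression_result`: `slope`,
#'   `slope_ci95` (half-width), `intercept`, `r_squared`, `p_value`,
#'   `n`.
#' @export
linregress <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stopf("need at least 3 finite (x, y) pairs")
  if (sd(x) == 0) stopf("x has zero variance; regression is degenerate")
  if (sd(y) == 0)                     # flat response: no fit to speak of
    return(structure(list(slope = 0, slope_ci95 = 0, intercept = y[1],
                          r_squared = 0, p_value = NA_real_,
                          n = length(x)),
                     class = "regression_result"))
  fit <- lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(coef(fit)[2])
  ci <- confint(fit, "x", level = 0.95)
  p <- if (nrow(sm$coefficients) >= 2 && ncol(sm$coefficients) >= 4)
    sm$coefficients[2, 4] else NA_real_
  structure(list(slope = slope,
                 slope_ci95 = unname(slope - ci[1]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = p,
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("slope %.3g +/- %.3g (95%% CI), intercept %.3g, r^2 %.3g, p %.3g, n %d\n",
              x$slope, x$slope_ci95, x$intercept, x$r_squared, x$p_value,
              x$n))
  invisible(x)
}

#' Endpoint (time-averaged) velocity of a trace
#'
#' The velocity implied by a straight line connecting the first and
#' last vertex of a trace - the classic rapid way of measuring motion
#' on a kymograph: `(last position - first position) / elapsed time`,
#' calibrated to um/h with the anterograde-positive sign convention.
#' This equals the duration-weighted mean of the instantaneous segment
#' slopes (a telescoping identity), so it is exact for uniform motion
#' and a time-average otherwise.
#'
#' @param trace data frame with columns `frame`, `position` spanning at
#'   least 2 frames.
#' @param pixel_size_um,frame_interval_s calibration.
#' @return Velocity in um/h.
#' @export
endpoint_velocity <- function(trace, pixel_size_um, frame_interval_s) {
  check_calibration(pixel_size_um, frame_interval_s)
  n <- nrow(trace)
  if (n < 2L) stopf("trace must span at least 2 frames")
  dt <- (trace$frame[n] - trace$frame[1]) * frame_interval_s
  if (dt <= 0) stopf("trace spans zero elapsed time")
  dx <- (trace$position[n] - trace$position[1]) * pixel_size_um
  dx / dt * 3600
}
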