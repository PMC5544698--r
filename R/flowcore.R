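# Optical flow on kymographs: Lucas-Kanade baseline and the
# rotation-augmented estimator.

#' Parameters of the kymograph flow estimators
#'
#' @param window odd local-neighborhood size (pixels) for the
#'   least-squares gradient fit; at least 3.
#' @param smoothing_sigma sd (pixels) of the Gaussian pre-smoothing
#'   applied before differentiation.
#' @param rotations rotation angles (degrees) of the augmented
#'   estimator's branches; must contain 0 and 90 when combining
#'   (90 degrees is the lossless axis swap).
#' @param switch_threshold speed (p/f) at which the combined map prefers
#'   the rotated branch over the unrotated one; 1 p/f is the symmetry
#'   point between the two branches.
#' @param hysteresis relative half-width of the band around
#'   `switch_threshold` in which the two branch estimates are averaged.
#' @param min_gradient mean squared spatial-gradient energy below which
#'   a pixel's estimate is marked invalid.
#' @param n_iter warp-refinement iterations of the least-squares kernel.
#' @param max_residual normalized brightness-constancy residual
#'   (misalignment energy over signal energy) above which a branch's
#'   estimate at a pixel is considered unhealthy - a stalled estimator
#'   leaves the warped row visibly misaligned, which is how fast motion
#'   misread as slow is recognized when branches are combined.
#' @return An object of class `flow_params`.
#' @export
flow_params <- function(window = 9L, smoothing_sigma = 1,
                        rotations = c(0, 90), switch_threshold = 1,
                        hysteresis = 0.2, min_gradient = 1e-4,
                        n_iter = 3L, max_residual = 0.02) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stopf("`window` must be odd and >= 3")
  if (switch_threshold <= 0) stopf("`switch_threshold` must be > 0")
  structure(list(window = window, smoothing_sigma = smoothing_sigma,
                 rotations = rotations, switch_threshold = switch_threshold,
                 hysteresis = hysteresis, min_gradient = min_gradient,
                 n_iter = as.integer(n_iter),
                 max_residual = max_residual),
            class = "flow_params")
}

new_flow_map <- function(velocity, valid, residual, window, source) {
  structure(list(velocity = velocity, valid = valid, residual = residual,
                 window = window, source = source),
            class = "flow_map")
}

#' @export
print.flow_map <- function(x, ...) {
  v <- x$velocity[x$valid]
  cat(sprintf("flow_map (%s): %d x %d, %.1f%% valid\n", x$source,
              nrow(x$velocity), ncol(x$velocity),
              100 * mean(x$valid)))
  if (length(v))
    cat(sprintf("  velocity p/f: median %.3g, range [%.3g, %.3g]\n",
                median(v), min(v), max(v)))
  invisible(x)
}

#' Lucas-Kanade style one-dimensional flow on a kymograph
#'
#' Estimates, for every pixel, the signed horizontal velocity (pixels
#' per frame) that best explains the brightness change between a row
#' and the next row under the brightness-constancy assumption. The
#' least-squares solution over a `window x window` neighborhood of
#' Gaussian-smoothed spatial (column) and temporal (row) derivatives is
#' refined by iterative warping: the next row is resampled at the
#' current estimate (prefiltered cubic B-spline interpolation, whose
#' even-dominant error does not bias sub-pixel displacements) and the
#' residual displacement re-estimated, which removes the first-order
#' bias of the gradient solution for sub-pixel motion. Like all gradient-based estimators it fails once the true
#' displacement per frame exceeds a few times the smoothing scale - the
#' update stalls and the estimate collapses; see [kymoflow()] for the
#' rotation augmentation that removes this limit.
#'
#' Pixels whose mean spatial-gradient energy falls below
#' `params$min_gradient` (featureless regions) are marked invalid, as is
#' the last row (no next frame). Invalid pixels are excluded from all
#' downstream statistics, never zero-filled.
#'
#' @param kymo a [kymograph()].
#' @param params a [flow_params()].
#' @return A `flow_map`: `velocity` (p/f, positive = anterograde),
#'   logical `valid`, normalized brightness-constancy `residual`,
#'   `window`, `source = "baseline"`.
#' @export
lk_flow <- function(kymo, params = flow_params()) {
  A <- kymo$grid
  nr <- nrow(A); nc <- ncol(A)
  if (nr < params$window || nc < params$window)
    stopf("kymograph (%d x %d) smaller than the %d-px window",
          nr, nc, params$window)
  I <- smooth_gauss(A, params$smoothing_sigma)
  Ix <- col_gradient(I)
  I1 <- I[-nr, , drop = FALSE]      # row t
  I2 <- I[-1, , drop = FALSE]       # row t + 1
  Ix1 <- Ix[-nr, , drop = FALSE]
  k <- params$window
  v <- matrix(0, nr - 1L, nc)
  gxx <- boxsum(Ix1^2, k)
  wcount <- boxsum(matrix(1, nr - 1L, nc), k)
  cf2 <- bspline_row_coef(I2)   # prefilter once; warped per iteration
  for (it in seq_len(params$n_iter)) {
    Iw <- bspline_row_sample(cf2, v)
    It <- Iw - I1
    bad <- is.na(It)
    It[bad] <- 0
    gxt <- boxsum(Ix1 * It, k)
    dv <- -gxt / pmax(gxx, 1e-12)
    dv[!is.finite(dv)] <- 0
    # gradient steps are only trustworthy inside the smoothing scale;
    # larger true displacements make the iteration stall, which is the
    # characteristic failure of gradient flow on fast motion
    dv <- pmax(pmin(dv, 1.5), -1.5)
    v <- v + dv
  }
  Iw <- bspline_row_sample(cf2, v)
  It <- Iw - I1
  m <- !is.na(It)
  It[!m] <- 0
  sse <- boxsum(It^2, k)
  sig <- boxsum(I1^2 * m, k)
  residual <- sse / pmax(sig, 1e-12)
  valid <- (gxx / wcount) >= params$min_gradient & m
  # last row has no following frame: carry shape, mark invalid
  velocity <- rbind(v, v[nr - 1L, ])
  valid <- rbind(valid, rep(FALSE, nc))
  residual <- rbind(residual, residual[nr - 1L, ])
  velocity[!valid] <- NA_real_
  new_flow_map(velocity, valid, residual, k, "baseline")
}

#' Rotate a kymograph's time and distance axes
#'
#' A 90-degree rotation is implemented as the lossless axis swap
#' (matrix transpose, no interpolation): a feature moving at `v` p/f
#' appears at `1/v` p/f in the rotated frame with its sign preserved,
#' which is exactly the property the rotation augmentation relies on.
#' The swap also exchanges the spatial and temporal calibration.
#' Arbitrary angles use bilinear resampling and are intended for
#' visualization, not for the combined estimator.
#'
#' @param kymo a [kymograph()].
#' @param degrees rotation angle; 90 (or -90) selects the axis swap.
#' @return A [kymograph()] with attribute `"rotation"` recording the
#'   cumulative rotation applied.
#' @export
rotate_kymo <- function(kymo, degrees = 90) {
  prev <- attr(kymo, "rotation") %||% 0
  if (degrees %% 180 != 0 && degrees %% 90 == 0) {
    out <- kymograph(t(kymo$grid),
                     frame_interval_s = kymo$frame_interval_s,
                     pixel_size_um = kymo$pixel_size_um,
                     origin_label = kymo$origin_label)
  } else if (degrees %% 360 == 0) {
    out <- kymo
  } else {
    img <- EBImage::rotate(EBImage::Image(kymo$grid), degrees,
                           filter = "bilinear", bg.col = 0)
    out <- kymograph(EBImage::imageData(img), kymo$frame_interval_s,
                     kymo$pixel_size_um, kymo$origin_label)
  }
  attr(out, "rotation") <- (prev + degrees) %% 360
  out
}

#' Rotation-augmented kymograph flow ("KymoFlow" estimator)
#'
#' Runs the Lucas-Kanade kernel ([lk_flow()]) on the kymograph and on
#' its 90-degree axis-swapped copy. In the swapped frame a velocity `v`
#' becomes `1/v`, so fast motion - where gradient-based flow stalls -
#' becomes sub-pixel motion, the regime where the kernel is most
#' accurate. The rotated branch's velocities are back-transformed
#' (`v <- 1/v`, sign preserved by the axis swap, coordinates mapped back
#' by transposition) and the two branches merged per pixel. A branch is
#' *healthy* at a pixel when its estimate is valid and its normalized
#' brightness-constancy residual is below `params$max_residual` (a
#' stalled estimator leaves the warped row visibly misaligned). Then:
#'
#' * a healthy unrotated estimate below
#'   `switch_threshold * (1 - hysteresis)` wins outright - slow,
#'   well-explained motion is never overridden by the rotated branch,
#'   whose back-transform `1/v` amplifies any misestimate;
#' * a healthy unrotated estimate above
#'   `switch_threshold * (1 + hysteresis)` defers to a healthy rotated
#'   estimate (the spec regime of the rotated branch); in the
#'   hysteresis band between, the two healthy branches are averaged;
#' * where only one branch is healthy, it is used; where neither is,
#'   the pixel is invalid.
#'
#' Back-transformed velocities with `|v_rot| < 1e-6` p/f are clamped to
#' invalid rather than emitted as huge velocities (the near-stationary
#' rotated branch carries no information about near-infinite speed).
#'
#' @param kymo a [kymograph()].
#' @param params a [flow_params()]; `rotations` must include 90.
#' @return A `flow_map` with `source = "combined"`; validity is the
#'   union of the contributing branches.
#' @export
kymoflow <- function(kymo, params = flow_params()) {
  if (!any(params$rotations %% 180 == 90))
    stopf("`params$rotations` must include 90 for the combined estimator")
  f0 <- lk_flow(kymo, params)
  f90 <- lk_flow(rotate_kymo(kymo, 90), params)
  v0 <- f0$velocity
  vr_raw <- t(f90$velocity)
  valid_b <- t(f90$valid) & !is.na(vr_raw) & abs(vr_raw) >= 1e-6
  vb <- ifelse(valid_b, 1 / vr_raw, NA_real_)
  res0 <- f0$residual
  resb <- t(f90$residual)
  healthy0 <- f0$valid & res0 <= params$max_residual & !is.na(v0)
  healthyb <- valid_b & resb <= params$max_residual

  lo <- params$switch_threshold * (1 - params$hysteresis)
  hi <- params$switch_threshold * (1 + params$hysteresis)
  v <- matrix(NA_real_, nrow(v0), ncol(v0))
  slow0 <- healthy0 & abs(v0) < lo
  use0 <- slow0 | (healthy0 & !healthyb)
  band <- healthy0 & healthyb & !slow0 & abs(v0) <= hi
  fastb <- healthy0 & healthyb & abs(v0) > hi
  onlyb <- healthyb & !healthy0
  v[use0] <- v0[use0]
  v[band] <- (v0[band] + vb[band]) / 2
  v[fastb] <- vb[fastb]
  v[onlyb] <- vb[onlyb]
  valid <- healthy0 | healthyb
  residual <- pmin(res0, resb)
  new_flow_map(v, valid, residual, params$window, "combined")
}

#' Calibrate a flow map to micrometres per hour
#'
#' `v_um_h = v_pf * pixel_size_um / frame_interval_s * 3600`; the sign
#' (anterograde positive) is preserved and invalid pixels become `NA`.
#'
#' @param flow a `flow_map` from [lk_flow()] or [kymoflow()].
#' @param kymo the [kymograph()] the flow was computed on (carries the
#'   calibration).
#' @return A numeric matrix of velocities in um/h with `NA` at invalid
#'   pixels.
#' @export
calibrate_flow <- function(flow, kymo) {
  check_calibration(kymo$pixel_size_um, kymo$frame_interval_s)
  out <- flow$velocity * pf_to_umh(kymo)
  out[!flow$valid] <- NA_real_
  out
}

#' Display a flow map as a color-coded velocity image
#'
#' @param x a `flow_map`.
#' @param zlim symmetric velocity range for the color scale; default
#'   spans the valid velocities.
#' @param ... passed to [graphics::image()].
#' @export
plot.flow_map <- function(x, zlim = NULL, ...) {
  v <- x$velocity
  v[!x$valid] <- NA
  if (is.null(zlim)) {
    m <- max(abs(v), na.rm = TRUE)
    zlim <- c(-m, m)
  }
  image(x = seq_len(ncol(v)), y = seq_len(nrow(v)),
        z = t(v[rev(seq_len(nrow(v))), , drop = FALSE]),
        zlim = zlim, col = hcl.colors(65, "Blue-Red 3"),
        xlab = "position (px)", ylab = "frame (reversed)",
        useRaster = TRUE, ...)
  invisible(x)
}
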