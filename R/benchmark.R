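# Ground-truth validation harness: velocity <-> angle conversion,
# per-image statistics, average absolute angular error, algorithm
# comparison.

#' Convert kymograph velocities to motion angles (and back)
#'
#' On a kymograph a velocity `v` (p/f) corresponds to a line at angle
#' `atan(v) * 180 / pi - 90` degrees from the distance axis: 0 deg is
#' horizontal (infinitely fast), -45 deg is 1 p/f, and -90 deg is
#' vertical (stationary). Negative velocities carry their sign into the
#' quadrant below -90 deg. The angle metric is better behaved than the
#' velocity metric at the fast end, where small angle changes map to
#' enormous velocity changes.
#'
#' @param v velocity in pixels per frame (finite).
#' @return Angle in degrees (`velocity_to_angle`), or velocity in p/f
#'   (`angle_to_velocity`).
#' @export
velocity_to_angle <- function(v) {
  atan(v) * 180 / pi - 90
}

#' @rdname velocity_to_angle
#' @param angle angle in degrees.
#' @export
angle_to_velocity <- function(angle) {
  tanpi((angle + 90) / 180)
}

#' Per-image accuracy statistics of a flow map against ground truth
#'
#' Statistics are computed over the pixels in the evaluation domain:
#' by default the ground-truth line support intersected with the flow
#' map's validity mask (the background carries no ground-truth motion).
#' The mean estimated angle is compared with the true angle;
#' `abs_err = |mean_angle - true_angle|`.
#'
#' @param flow a `flow_map`.
#' @param truth a `ground_truth` from [make_line_kymograph()].
#' @param stat_domain `"line"` (support and valid), `"valid"` (all valid
#'   pixels), or `"all"` (every finite estimate).
#' @return A list `(mean_v, sd_v, mean_angle, abs_err, n)`; `n = 0`
#'   flags an image with no admissible pixels (excluded upstream).
#' @export
image_stats <- function(flow, truth, stat_domain = c("line", "valid", "all")) {
  stat_domain <- match.arg(stat_domain)
  dom <- switch(stat_domain,
                line = truth$support & flow$valid,
                valid = flow$valid,
                all = is.finite(flow$velocity))
  v <- flow$velocity[dom]
  v <- v[is.finite(v)]
  if (!length(v))
    return(list(mean_v = NA_real_, sd_v = NA_real_, mean_angle = NA_real_,
                abs_err = NA_real_, n = 0L))
  ang <- velocity_to_angle(v)
  mean_angle <- mean(ang)
  abs_err <- if (is.finite(truth$true_angle))
    abs(mean_angle - truth$true_angle) else NA_real_
  list(mean_v = mean(v), sd_v = sd(v), mean_angle = mean_angle,
       abs_err = abs_err, n = length(v))
}

#' Run a flow algorithm over the rotated-line benchmark
#'
#' Generates (or accepts) the single-line benchmark set, runs the chosen
#' estimator on every kymograph, and collects per-angle velocity and
#' angle statistics plus two summary errors: `aae_full`, the average
#' absolute angular error over all angles from -1 to -90 deg (0 deg is
#' excluded: its true velocity is infinite), and `aae_restricted`, the
#' same over -3 to -90 deg, the range most relevant to experimental
#' data. Velocity statistics are tabulated for -1 to -89 deg, where the
#' true velocity is finite and nonzero.
#'
#' @param algorithm `"kymoflow"` (rotation-augmented) or `"lk"`
#'   (baseline).
#' @param spec a [line_benchmark_spec()].
#' @param params a [flow_params()].
#' @param stat_domain see [image_stats()].
#' @return An object of class `benchmark_result`: data frame
#'   `per_angle` with columns `true_angle`, `true_velocity`, `mean_v`,
#'   `sd_v`, `mean_angle`, `abs_err`, `n`; scalars `aae_full`,
#'   `aae_restricted`; `algorithm` label.
#' @export
run_benchmark <- function(algorithm = c("kymoflow", "lk"),
                          spec = line_benchmark_spec(),
                          params = flow_params(),
                          stat_domain = "line") {
  algorithm <- match.arg(algorithm)
  fn <- if (algorithm == "kymoflow") kymoflow else lk_flow
  rows <- lapply(make_benchmark_set(spec), function(item) {
    fl <- fn(item$kymo, params)
    st <- image_stats(fl, item$truth, stat_domain = stat_domain)
    data.frame(true_angle = item$truth$true_angle,
               true_velocity = item$truth$true_velocity,
               mean_v = st$mean_v, sd_v = st$sd_v,
               mean_angle = st$mean_angle, abs_err = st$abs_err,
               n = st$n)
  })
  per_angle <- do.call(rbind, rows)
  full <- per_angle$true_angle <= -1 & !is.na(per_angle$abs_err)
  restricted <- per_angle$true_angle <= -3 & !is.na(per_angle$abs_err)
  structure(list(per_angle = per_angle,
                 aae_full = mean(per_angle$abs_err[full]),
                 aae_restricted = mean(per_angle$abs_err[restricted]),
                 algorithm = algorithm),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result [%s]: %d angles\n", x$algorithm,
              nrow(x$per_angle)))
  cat(sprintf("  AAE full set: %.3g deg; restricted (-3..-90): %.3g deg\n",
              x$aae_full, x$aae_restricted))
  invisible(x)
}

#' Compare the angular accuracy of two benchmark runs
#'
#' Paired two-tailed t-test on the per-angle absolute angular errors of
#' two algorithms evaluated on the same angle set.
#'
#' @param a,b `benchmark_result` objects over identical angle sets.
#' @return The two-sided p-value.
#' @export
compare_algorithms <- function(a, b) {
  if (!isTRUE(all.equal(a$per_angle$true_angle, b$per_angle$true_angle)))
    stopf("benchmark results cover different angle sets")
  ea <- a$per_angle$abs_err
  eb <- b$per_angle$abs_err
  keep <- !is.na(ea) & !is.na(eb)
  if (sum(keep) < 2L) stopf("need at least 2 paired angles for a t-test")
  if (isTRUE(all.equal(ea[keep], eb[keep]))) return(1)
  t.test(ea[keep], eb[keep], paired = TRUE)$p.value
}
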