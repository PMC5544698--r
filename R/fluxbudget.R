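# Fast-speckle velocity, directional flux counting, and the
# microtubule mass budget.

#' Regression velocity of a speckle trace in micrometres per second
#'
#' Least-squares slope of position versus time over all vertices of the
#' trace (more robust than the endpoint slope when a path was traced
#' with many clicks), calibrated to um/s; positive = anterograde.
#'
#' @param trace data frame with columns `frame`, `position` spanning at
#'   least 2 frames.
#' @param pixel_size_um,frame_interval_s calibration.
#' @return Velocity in um/s.
#' @export
speckle_velocity <- function(trace, pixel_size_um, frame_interval_s) {
  check_calibration(pixel_size_um, frame_interval_s)
  if (nrow(trace) < 2L || diff(range(trace$frame)) <= 0)
    stopf("trace must span at least 2 frames")
  t_s <- trace$frame * frame_interval_s
  x_um <- trace$position * pixel_size_um
  unname(coef(lm(x_um ~ t_s))[2])
}

#' Classify a velocity as fast (motor-driven) transport
#'
#' Bulk translocation is slow (1-100 um/h); motor-driven transport of
#' individual cargoes runs at 0.05-5 um/s. The default threshold of
#' 0.05 um/s sits at the bottom of the motor range; the comparison is
#' inclusive and sign-blind.
#'
#' @param velocity_um_s signed velocity, um/s.
#' @param threshold_um_s fast threshold (default 0.05 um/s).
#' @return Logical: `abs(velocity) >= threshold`.
#' @export
classify_fast <- function(velocity_um_s, threshold_um_s = 0.05) {
  abs(velocity_um_s) >= threshold_um_s
}

#' Count directional fast flux across the kymograph center
#'
#' A trace contributes one count if (a) any consecutive vertex pair
#' straddles `center_col` and (b) its regression velocity classifies as
#' fast; its direction is the sign of that velocity. A trace wandering
#' across the center several times still counts once - the quantity is
#' speckles per minute, not crossings per minute - and re-sampling a
#' polyline more densely cannot change its count.
#'
#' @param traces a [trace_set()].
#' @param center_col reference column (px); default the grid midline.
#' @param duration_min observation period in minutes (> 0).
#' @param pixel_size_um,frame_interval_s calibration.
#' @param threshold_um_s fast threshold for [classify_fast()].
#' @param n_cols kymograph width, used only for the default center.
#' @return Named vector `c(antero_flux, retro_flux)` in MT/min.
#' @export
count_flux <- function(traces, center_col = NULL, duration_min,
                       pixel_size_um, frame_interval_s,
                       threshold_um_s = 0.05, n_cols = NULL) {
  if (duration_min <= 0) stopf("`duration_min` must be > 0")
  if (is.null(center_col)) {
    if (is.null(n_cols)) stopf("supply `center_col` or `n_cols`")
    center_col <- (n_cols + 1) / 2
  }
  antero <- 0L; retro <- 0L
  for (tr in traces$traces) {
    p <- tr$position
    straddles <- any((p[-length(p)] - center_col) * (p[-1] - center_col) <= 0)
    if (!straddles) next
    v <- speckle_velocity(tr, pixel_size_um, frame_interval_s)
    if (!classify_fast(v, threshold_um_s)) next
    if (v > 0) antero <- antero + 1L else retro <- retro + 1L
  }
  c(antero_flux = antero / duration_min, retro_flux = retro / duration_min)
}

#' Microtubule transport mass budget
#'
#' Converts directional fast-microtubule flux into its contribution to
#' axonal growth: net flux is anterograde minus retrograde flux;
#' multiplying the hourly net flux by the average length of transported
#' microtubules gives the transported polymer length per hour; dividing
#' by the average number of microtubules per axonal cross-section gives
#' the equivalent axon elongation rate. The mean interval between net
#' anterograde microtubules is `1 / net_flux`.
#'
#' All stored values are unrounded; the print method displays them at
#' the conventional table precision (flux to 2 decimals, MT/h to 1,
#' transported length to the nearest um/h when >= 10, growth to 1
#' decimal).
#'
#' @param antero_flux,retro_flux directional flux, MT/min (>= 0).
#' @param mt_length average transported microtubule length, um (> 0).
#' @param mt_per_cross_section average microtubules per axonal
#'   cross-section (> 0).
#' @return An object of class `flux_budget` with fields `antero_flux`,
#'   `retro_flux`, `net_flux` (MT/min), `net_flux_h` (MT/h),
#'   `mt_length` (um), `mt_per_cross_section`, `transported_length`
#'   (um/h), `net_axonal_growth` (um/h), `mean_interval` (min; `NA`
#'   unless net flux is positive).
#' @export
mass_budget <- function(antero_flux, retro_flux, mt_length,
                        mt_per_cross_section) {
  if (mt_length <= 0 || mt_per_cross_section <= 0 ||
      antero_flux < 0 || retro_flux < 0)
    stopf("fluxes must be >= 0 and mt_length / mt_per_cross_section > 0")
  net <- antero_flux - retro_flux
  net_h <- 60 * net
  transported <- net_h * mt_length
  growth <- transported / mt_per_cross_section
  structure(list(antero_flux = antero_flux, retro_flux = retro_flux,
                 net_flux = net, net_flux_h = net_h,
                 mt_length = mt_length,
                 mt_per_cross_section = mt_per_cross_section,
                 transported_length = transported,
                 net_axonal_growth = growth,
                 mean_interval = if (net > 0) 1 / net else NA_real_),
            class = "flux_budget")
}

# Display rounding: 2 d.p. for flux, 1 d.p. for MT/h and growth,
# integer um/h for transported length >= 10 else 1 d.p.
format_budget_value <- function(name, value) {
  if (is.na(value)) return("-")
  switch(name,
         antero_flux = , retro_flux = , net_flux = sprintf("%.2f", value),
         net_flux_h = , net_axonal_growth = sprintf("%.1f", value),
         transported_length = if (abs(value) >= 10)
           sprintf("%.0f", value) else sprintf("%.1f", value),
         mean_interval = sprintf("%.1f", value),
         format(value))
}

#' @export
print.flux_budget <- function(x, ...) {
  lab <- c(antero_flux = "Anterograde flux (MT/min)",
           retro_flux = "Retrograde flux (MT/min)",
           net_flux = "Net flux (MT/min)",
           net_flux_h = "Net flux (MT/h)",
           mt_length = "Average MT length (um)",
           transported_length = "Transported MT length (um/h)",
           mt_per_cross_section = "Ave. # of MT per cross section",
           net_axonal_growth = "Net Axonal Growth (um/h)",
           mean_interval = "Mean interval between net anterograde MTs (min)")
  for (nm in names(lab)) {
    cat(sprintf("%-48s %s\n", lab[nm], format_budget_value(nm, x[[nm]])))
  }
  invisible(x)
}

#' @export
as.data.frame.flux_budget <- function(x, ...) {
  data.frame(quantity = names(unclass(x)),
             value = as.numeric(unclass(x)), row.names = NULL)
}

#' Net flux implied by an event interval and a directional fraction
#'
#' When fast events are observed once every `event_interval_min`
#' minutes with a fraction `antero_fraction` of them anterograde, the
#' implied net flux is `(2 * antero_fraction - 1) / event_interval_min`
#' MT/min (the balanced case, fraction 0.5, gives zero).
#'
#' @param event_interval_min mean minutes between events (> 0).
#' @param antero_fraction fraction of events moving anterogradely, in
#'   `[0, 1]`.
#' @return Net flux in MT/min.
#' @export
net_flux_from_rate_fraction <- function(event_interval_min, antero_fraction) {
  if (event_interval_min <= 0) stopf("`event_interval_min` must be > 0")
  if (antero_fraction < 0 || antero_fraction > 1)
    stopf("`antero_fraction` must lie in [0, 1]")
  (2 * antero_fraction - 1) / event_interval_min
}
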