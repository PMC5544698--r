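# Synthetic ground-truth kymographs: the rotated-line benchmark and a
# configurable simulated neurite (bulk anterograde translocation,
# growth-cone retrograde flow, fast transport events).

#' Specification of the single-line benchmark
#'
#' Describes a family of kymographs each containing one straight
#' anti-aliased line through the grid center at a known angle, so the
#' true velocity of every line is known analytically. Angles are
#' measured from the distance (horizontal) axis: 0 deg is horizontal
#' (infinitely fast motion), -90 deg is vertical (stationary), and an
#' angle of `a` corresponds to a velocity of `cot(|a|)` pixels/frame.
#'
#' @param angles angles in degrees, each in `[-90, 0]`. Default: 0 to
#'   -90 in one-degree increments (91 kymographs).
#' @param size (rows, cols) of each kymograph; at least (16, 16).
#' @param line_width stroke width in pixels (Gaussian cross-section of
#'   sd `line_width / 2`); non-binary edges are required by
#'   gradient-based flow.
#' @param intensity peak line intensity (arbitrary units).
#' @param noise_sd sd of additive Gaussian noise (0 = noise-free).
#' @param seed integer seed for the noise.
#' @return An object of class `line_benchmark_spec`.
#' @export
line_benchmark_spec <- function(angles = seq(0, -90, by = -1),
                                size = c(128L, 128L),
                                line_width = 2, intensity = 1,
                                noise_sd = 0, seed = 1L) {
  if (any(angles < -90 | angles > 0))
    stopf("benchmark angles must lie in [-90, 0] degrees")
  if (any(size < 16)) stopf("benchmark size must be at least 16 x 16")
  structure(list(angles = angles, size = as.integer(size),
                 line_width = line_width, intensity = intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "line_benchmark_spec")
}

#' Render one benchmark line kymograph with known ground truth
#'
#' The line passes through the grid center with a Gaussian cross-section
#' perpendicular to its direction. Ground truth velocity is
#' `cot(|angle|)` p/f (positive, anterograde) on the line support and
#' undefined elsewhere; -90 deg gives 0 p/f and 0 deg is flagged as
#' infinite.
#'
#' @param angle angle in degrees in `[-90, 0]`.
#' @param spec a [line_benchmark_spec()].
#' @return A list with elements `kymo` (a [kymograph()], native
#'   calibration 1 um/px and 1 s/frame) and `truth` (class
#'   `ground_truth`: per-pixel `flow` in p/f with `NA` off the line
#'   support, logical `support`, `true_velocity`, `true_angle`).
#' @export
make_line_kymograph <- function(angle, spec = line_benchmark_spec()) {
  if (length(angle) != 1L || is.na(angle) || angle < -90 || angle > 0)
    stopf("`angle` must be a single value in [-90, 0] degrees")
  nr <- spec$size[1]; nc <- spec$size[2]
  theta <- abs(angle) * pi / 180
  # Unit direction along the line: (dx, dt) = (cos theta, sin theta);
  # signed perpendicular distance of each pixel from the line.
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  t_off <- matrix(seq_len(nr) - cr, nr, nc)
  x_off <- matrix(rep(seq_len(nc) - cc, each = nr), nr, nc)
  d <- cos(theta) * t_off - sin(theta) * x_off
  sigma <- spec$line_width / 2
  grid <- spec$intensity * exp(-d^2 / (2 * sigma^2))
  if (spec$noise_sd > 0) {
    set.seed(spec$seed + round(abs(angle)))
    grid <- grid + matrix(rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
  }
  v <- if (theta == 0) Inf
       else if (abs(angle) == 90) 0
       else cos(theta) / sin(theta)                        # cot

  support <- abs(d) <= spec$line_width
  flow <- matrix(NA_real_, nr, nc)
  flow[support] <- v
  kymo <- kymograph(grid, frame_interval_s = 1, pixel_size_um = 1,
                    origin_label = sprintf("line %g deg", angle))
  truth <- structure(list(flow = flow, support = support,
                          true_velocity = v, true_angle = angle,
                          infinite = !is.finite(v)),
                     class = "ground_truth")
  list(kymo = kymo, truth = truth)
}

#' Generate the full rotated-line benchmark set
#'
#' One kymograph per angle in `spec$angles`; the default specification
#' yields 91 kymographs covering 0 to -90 degrees in one-degree steps.
#'
#' @param spec a [line_benchmark_spec()].
#' @return A list of `list(kymo, truth)` pairs, one per angle.
#' @export
make_benchmark_set <- function(spec = line_benchmark_spec()) {
  lapply(spec$angles, make_line_kymograph, spec = spec)
}

# ---------------------------------------------------------------------------
# Simulated neurite

#' Specification of a simulated neurite kymograph
#'
#' Emulates the motion regimes seen in growing neurons: slow coherent
#' (bulk) anterograde translocation of speckles along the axon at
#' micrometres-per-hour rates, rapid retrograde flow in the growth-cone
#' peripheral domain, an advancing growth cone, and sparse fast
#' motor-driven transport events at micrometres-per-second speeds that
#' cross the paths of the slower speckles.
#'
#' Defaults reflect measured values in rapidly growing sensory neurons:
#' growth-cone advance 24 um/h, retrograde flow -97 um/h, bulk axonal
#' transport coupled 1:1 to growth-cone advance with a gentle
#' friction-like decay away from the growth cone, fast events at
#' 0.5/min anterograde and 0.38/min retrograde with speeds
#' ~ Normal(0.1, 0.05) um/s truncated at zero.
#'
#' @param gc_velocity growth-cone advance velocity, um/h.
#' @param axon_profile function mapping distance behind the transition
#'   zone (um, >= 0) to bulk velocity (um/h); default
#'   `gc_velocity * exp(-d / 150)`, a friction-like decay with a 150 um
#'   length scale.
#' @param retro_velocity retrograde flow velocity in the peripheral
#'   domain, um/h (negative).
#' @param p_domain_width width of the peripheral (retrograde) domain, um.
#' @param fast_event_rate_antero,fast_event_rate_retro Poisson rates of
#'   fast transport events crossing the kymograph center, events/min.
#' @param fast_speed_mean,fast_speed_sd normal distribution of fast
#'   event speeds, um/s, truncated at 0.
#' @param speckle_density fluorescent speckles per um along the neurite.
#' @param noise_sd sd of additive Gaussian noise (intensity units).
#' @param duration recording length, minutes.
#' @param n_cols kymograph width in pixels.
#' @param pixel_size_um,frame_interval_s calibration.
#' @param gc_start_frac initial growth-cone position as a fraction of
#'   the field width.
#' @param seed integer seed.
#' @return An object of class `neurite_sim_spec`.
#' @export
neurite_sim_spec <- function(gc_velocity = 24,
                             axon_profile = NULL,
                             retro_velocity = -97,
                             p_domain_width = 5,
                             fast_event_rate_antero = 0.5,
                             fast_event_rate_retro = 0.38,
                             fast_speed_mean = 0.1,
                             fast_speed_sd = 0.05,
                             speckle_density = 2,
                             noise_sd = 0.02,
                             duration = 40,
                             n_cols = 384L,
                             pixel_size_um = 0.1,
                             frame_interval_s = 5,
                             gc_start_frac = 0.35,
                             seed = 1L) {
  if (fast_event_rate_antero < 0 || fast_event_rate_retro < 0)
    stopf("event rates must be >= 0")
  if (duration <= 0) stopf("duration must be > 0")
  if (p_domain_width < 0) stopf("p_domain_width must be >= 0")
  if (is.null(axon_profile)) {
    force(gc_velocity)
    axon_profile <- function(d) gc_velocity * exp(-d / 150)
  }
  structure(list(gc_velocity = gc_velocity, axon_profile = axon_profile,
                 retro_velocity = retro_velocity,
                 p_domain_width = p_domain_width,
                 fast_event_rate_antero = fast_event_rate_antero,
                 fast_event_rate_retro = fast_event_rate_retro,
                 fast_speed_mean = fast_speed_mean,
                 fast_speed_sd = fast_speed_sd,
                 speckle_density = speckle_density,
                 noise_sd = noise_sd, duration = duration,
                 n_cols = as.integer(n_cols),
                 pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 gc_start_frac = gc_start_frac,
                 seed = as.integer(seed)),
            class = "neurite_sim_spec")
}

sim_n_frames <- function(spec) {
  max(2L, as.integer(round(spec$duration * 60 / spec$frame_interval_s)))
}

# Lab-frame bulk velocity field (um/h) at positions x (um) and time t (h),
# given the growth-cone leading edge g(t) (um).
bulk_velocity_um_h <- function(x, g, spec) {
  tz <- g - spec$p_domain_width
  v <- ifelse(x > g, 0,
              ifelse(x > tz, spec$retro_velocity,
                     spec$axon_profile(pmax(tz - x, 0))))
  v
}

#' Draw the fast transport events of a simulated neurite
#'
#' Events are Poisson-distributed center-line crossings: counts per
#' direction are `Poisson(rate * duration)`, each event crosses the
#' kymograph center column at a uniformly random frame with a speed
#' drawn from `Normal(fast_speed_mean, fast_speed_sd)` truncated at
#' zero, signed by direction.
#'
#' @param spec a [neurite_sim_spec()].
#' @return A data frame with columns `direction` ("antero"/"retro"),
#'   `velocity_um_s` (signed), and `crossing_frame`.
#' @export
draw_fast_events <- function(spec) {
  set.seed(spec$seed)
  n_frames <- sim_n_frames(spec)
  counts <- c(antero = rpois(1, spec$fast_event_rate_antero * spec$duration),
              retro = rpois(1, spec$fast_event_rate_retro * spec$duration))
  draw_speed <- function(n) {
    s <- rnorm(n, spec$fast_speed_mean, spec$fast_speed_sd)
    while (any(bad <- s <= 0))                      # truncate at zero
      s[bad] <- rnorm(sum(bad), spec$fast_speed_mean, spec$fast_speed_sd)
    s
  }
  dirs <- rep(c("antero", "retro"), counts)
  n <- length(dirs)
  if (n == 0L)
    return(data.frame(direction = character(), velocity_um_s = numeric(),
                      crossing_frame = numeric()))
  data.frame(direction = dirs,
             velocity_um_s = draw_speed(n) * ifelse(dirs == "antero", 1, -1),
             crossing_frame = runif(n, 1, n_frames))
}

#' Convert simulated fast events to a trace set
#'
#' Each event becomes a straight polyline through
#' `(crossing_frame, center column)` with the event's slope, clipped to
#' the kymograph bounds and to a visible path of `path_length_um`
#' (fast-transported microtubules are short, so only a finite stretch
#' of the path is visible).
#'
#' @param events data frame from [draw_fast_events()] (or the `events`
#'   element of a simulation's ground truth).
#' @param n_frames,n_cols kymograph shape.
#' @param pixel_size_um,frame_interval_s calibration.
#' @param path_length_um visible path length, um.
#' @return A [trace_set()].
#' @export
traces_from_events <- function(events, n_frames, n_cols,
                               pixel_size_um, frame_interval_s,
                               path_length_um = 8) {
  center <- (n_cols + 1) / 2
  trs <- list()
  for (i in seq_len(nrow(events))) {
    v_pf <- events$velocity_um_s[i] * frame_interval_s / pixel_size_um
    half <- (path_length_um / pixel_size_um) / 2      # px either side
    df <- abs(half / v_pf)                            # frames either side
    f0 <- max(1, events$crossing_frame[i] - df)
    f1 <- min(n_frames, events$crossing_frame[i] + df)
    fr <- unique(round(seq(f0, f1, length.out = max(2, ceiling(f1 - f0 + 1)))))
    if (length(fr) < 2L) next
    pos <- center + (fr - events$crossing_frame[i]) * v_pf
    keep <- pos >= 1 & pos <= n_cols
    if (sum(keep) < 2L) next
    trs[[length(trs) + 1L]] <- data.frame(frame = fr[keep],
                                          position = pos[keep])
  }
  trace_set(trs, label = "fast events")
}

#' Simulate a neurite kymograph with known ground truth
#'
#' Speckles are seeded at `speckle_density` per um along the neurite and
#' advected through the bulk velocity field (anterograde along the axon,
#' retrograde in the peripheral domain, discontinuity at the transition
#' zone, the whole pattern advancing with the growth cone). New speckles
#' are spawned near the leading edge and in density deficits, emulating
#' continuous assembly. Fast transport events are superimposed on (not
#' replacing) the bulk speckles, and Gaussian noise is added last.
#'
#' @param spec a [neurite_sim_spec()].
#' @return A list with `kymo` (a [kymograph()]) and `truth` (class
#'   `ground_truth`): `flow` = per-pixel true bulk velocity in p/f,
#'   `events` = fast-event table ([draw_fast_events()]), `gc_track` =
#'   per-frame growth-cone column (px), `tz_track` = per-frame
#'   transition-zone column (px), `speckle_tracks` = per-frame positions
#'   (um) of the bulk speckles (matrix frames x speckles, NA when
#'   absent).
#' @export
simulate_neurite_kymograph <- function(spec = neurite_sim_spec()) {
  n_frames <- sim_n_frames(spec)
  nc <- spec$n_cols
  px <- spec$pixel_size_um
  dt_h <- spec$frame_interval_s / 3600
  width_um <- nc * px
  events <- draw_fast_events(spec)           # also sets the seed
  g0 <- spec$gc_start_frac * width_um
  g <- g0 + spec$gc_velocity * dt_h * (seq_len(n_frames) - 1)
  g <- pmin(g, width_um - 2 * px)            # never leave the field

  # -- advect bulk speckles -------------------------------------------------
  n0 <- max(3L, round(spec$speckle_density * g0))
  pos <- runif(n0, 0, g0)
  amp <- runif(n0, 0.6, 1)
  tracks <- matrix(NA_real_, n_frames, length(pos))
  for (f in seq_len(n_frames)) {
    # spawn to maintain density and keep a speckle near the leading edge
    target <- round(spec$speckle_density * g[f])
    deficit <- target - sum(!is.na(pos) & pos <= g[f])
    new_pos <- numeric(0)
    if (deficit > 0) new_pos <- runif(deficit, 0, g[f])
    if (!any(!is.na(pos) & pos > g[f] - 0.75 & pos <= g[f]))
      new_pos <- c(new_pos, g[f] - runif(1, 0, 0.5))
    if (length(new_pos)) {
      pos <- c(pos, new_pos)
      amp <- c(amp, runif(length(new_pos), 0.6, 1))
      tracks <- cbind(tracks,
                      matrix(NA_real_, n_frames, length(new_pos)))
    }
    tracks[f, ] <- pos
    tz <- g[f] - spec$p_domain_width
    was_p <- !is.na(pos) & pos > tz
    v <- bulk_velocity_um_h(pos, g[f], spec)           # um/h
    pos <- pos + v * dt_h
    # retrograde-flow material is recycled at the transition zone:
    # speckles carried out of the peripheral domain terminate there
    # (within one retrograde step, so none ride the advancing boundary)
    recycled <- was_p & pos <= tz + abs(spec$retro_velocity) * dt_h
    gone <- is.na(pos) | pos < 0 | pos > width_um | recycled
    pos[gone] <- NA_real_
  }

  # -- render ---------------------------------------------------------------
  cols <- seq_len(nc)
  sigma_px <- 0.75
  grid <- matrix(0, n_frames, nc)
  for (f in seq_len(n_frames)) {
    p <- tracks[f, ] / px + 0.5
    keep <- !is.na(p)
    if (any(keep)) {
      d2 <- outer(cols, p[keep], "-")^2
      grid[f, ] <- as.vector(exp(-d2 / (2 * sigma_px^2)) %*% amp[keep])
    }
  }
  # fast events: straight bright paths through the center column
  if (nrow(events)) {
    center <- (nc + 1) / 2
    half_px <- (8 / px) / 2
    for (i in seq_len(nrow(events))) {
      v_pf <- events$velocity_um_s[i] * spec$frame_interval_s / px
      df <- abs(half_px / v_pf)
      fr <- seq(max(1, ceiling(events$crossing_frame[i] - df)),
                min(n_frames, floor(events$crossing_frame[i] + df)))
      if (!length(fr)) next
      p <- center + (fr - events$crossing_frame[i]) * v_pf
      keep <- p >= 1 & p <= nc & p <= g[fr] / px + 0.5   # inside the cell
      fr <- fr[keep]; p <- p[keep]
      for (k in seq_along(fr)) {
        w <- exp(-(cols - p[k])^2 / (2 * sigma_px^2))
        grid[fr[k], ] <- pmax(grid[fr[k], ], w)
      }
    }
  }
  if (spec$noise_sd > 0)
    grid <- grid + matrix(rnorm(length(grid), sd = spec$noise_sd),
                          n_frames, nc)

  # -- ground truth ---------------------------------------------------------
  x_um <- (cols - 0.5) * px
  flow <- t(vapply(seq_len(n_frames), function(f) {
    bulk_velocity_um_h(x_um, g[f], spec) * dt_h / px   # p/f
  }, numeric(nc)))
  kymo <- kymograph(grid, spec$frame_interval_s, spec$pixel_size_um,
                    origin_label = "simulated neurite")
  truth <- structure(list(flow = flow, events = events,
                          gc_track = g / px + 0.5,
                          tz_track = (g - spec$p_domain_width) / px + 0.5,
                          speckle_tracks = tracks, spec = spec),
                     class = "ground_truth")
  list(kymo = kymo, truth = truth)
}
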