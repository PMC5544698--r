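test_that("growth-cone tracking from a supplied trace is exact arithmetic", {
  k <- kymograph(matrix(runif(400), 20, 20), frame_interval_s = 5,
                 pixel_size_um = 0.1)
  tr <- data.frame(frame = c(1, 20), position = c(2, 2 + 19 * 0.5))
  trk <- estimate_gc_track(k, method = "trace", trace = tr)
  expect_equal(trk$velocity_um_h, 0.5 * 0.1 / 5 * 3600)  # s * calibration
  expect_length(trk$position, 20)
})

test_that("edge tracking recovers growth-cone motion from simulations", {
  sp <- neurite_sim_spec(duration = 15, seed = 7,
                         fast_event_rate_antero = 0,
                         fast_event_rate_retro = 0)
  sim <- simulate_neurite_kymograph(sp)
  trk <- estimate_gc_track(sim$kymo)
  expect_equal(trk$velocity_um_h, 24, tolerance = 2)
  expect_lt(max(abs(trk$position - sim$truth$gc_track)), 10)

  static <- simulate_neurite_kymograph(
    neurite_sim_spec(gc_velocity = 0, retro_velocity = 0,
                     axon_profile = function(d) 0 * d,
                     fast_event_rate_antero = 0, fast_event_rate_retro = 0,
                     duration = 10, seed = 8))
  expect_equal(estimate_gc_track(static$kymo)$velocity_um_h, 0,
               tolerance = 0.5)
})

test_that("shearing aligns a linear track and is invertible", {
  g <- matrix(rnorm(40 * 60), 40, 60)
  expect_equal(shear_align(g, rep(10, 40)), g)       # constant track
  track <- 5 + (seq_len(40) - 1) * 0.5
  sh <- shear_align(g, track)
  back <- shear_align(sh, 2 * track[1] - track)      # opposite shifts
  reg <- !is.na(back)
  expect_gt(sum(reg), 0.5 * length(g))
  expect_equal(back[reg], g[reg], tolerance = 1e-12)
  expect_error(shear_align(g, rep(1, 10)), "cover all")
})

test_that("shearing preserves the multiset of valid velocities", {
  g <- matrix(sample(1:7, 50 * 30, replace = TRUE) * 10, 50, 30)
  g[sample(length(g), 100)] <- NA
  track <- cumsum(c(10, runif(49, -2, 2)))
  sh <- shear_align(g, track)
  expect_true(all(table(sh[!is.na(sh)]) <= table(g[!is.na(g)])))
})

test_that("re-detecting the growth cone on a sheared grid gives a constant column", {
  sp <- neurite_sim_spec(duration = 15, seed = 13,
                         fast_event_rate_antero = 0,
                         fast_event_rate_retro = 0)
  sim <- simulate_neurite_kymograph(sp)
  trk <- estimate_gc_track(sim$kymo)
  sheared <- shear_align(sim$kymo$grid, trk, interp = "linear")
  sheared[is.na(sheared)] <- 0
  k2 <- kymograph(sheared, sim$kymo$frame_interval_s, sim$kymo$pixel_size_um)
  trk2 <- estimate_gc_track(k2)
  expect_lt(diff(range(trk2$position)), 6)
  expect_equal(trk2$velocity_um_h, 0, tolerance = 1)
})

test_that("profiles are column means over valid pixels with per-bin CIs", {
  g <- matrix(20, 30, 15)
  p <- profile_from_flow(g, 0.5)
  expect_true(all(p$mean_umh == 20))
  expect_true(all(p$ci95_umh == 0))
  expect_true(all(diff(p$distance_um) > 0))
  # a single valid row passes through unchanged
  g1 <- matrix(NA_real_, 10, 5)
  g1[4, ] <- c(1, 2, 3, 4, 5)
  p1 <- profile_from_flow(g1, 1)
  expect_equal(p1$mean_umh, rev(c(1, 2, 3, 4, 5)))
  expect_true(all(p1$n == 1))
  expect_error(profile_from_flow(matrix(NA_real_, 5, 5), 1), "no valid")
  # the speed cutoff drops fast-transport pixels from the bulk profile
  g2 <- matrix(20, 10, 4); g2[1, ] <- 700
  expect_true(all(profile_from_flow(g2, 1, max_speed_umh = 300)$mean_umh == 20))
})

test_that("T-zone alignment interpolates the retro-to-antero crossing", {
  p <- structure(data.frame(distance_um = c(0, 1, 2, 3),
                            mean_umh = c(-100, -50, 10, 20),
                            ci95_umh = 0, n = 10),
                 class = c("velocity_profile", "data.frame"),
                 aligned = FALSE)
  al <- align_tzone(p)
  expect_true(attr(al, "aligned"))
  expect_equal(al$distance_um, c(-1.833, -0.833, 0.167, 1.167),
               tolerance = 1e-3)
  expect_equal(diff(al$distance_um), diff(p$distance_um))  # pure shift
  allpos <- p; allpos$mean_umh <- c(5, 10, 15, 20)
  expect_warning(unal <- align_tzone(allpos), "no retrograde")
  expect_false(attr(unal, "aligned"))
})

test_that("profiles average across cells on a shared grid", {
  mk <- function(v) structure(
    data.frame(distance_um = 0:10, mean_umh = v, ci95_umh = 0, n = 5),
    class = c("velocity_profile", "data.frame"), aligned = TRUE)
  a <- mk(rep(10, 11)); b <- mk(rep(30, 11))
  avg <- average_profiles(list(a, b))
  expect_true(all(avg$mean_umh == 20))
  same <- average_profiles(list(a, a))
  expect_true(all(same$mean_umh == 10))
  expect_true(all(same$ci95_umh == 0))
  expect_error(average_profiles(list(a)), "at least 2")
  far <- mk(rep(5, 11)); far$distance_um <- far$distance_um + 100
  expect_error(average_profiles(list(a, far)), "disjoint")
})

test_that("linregress reports slope, CI, r-squared and p-value", {
  r <- suppressWarnings(linregress(1:10, 1:10))  # lm flags the exact fit
  expect_equal(r$slope, 1)
  expect_equal(r$r_squared, 1)
  set.seed(2)
  r2 <- suppressWarnings(linregress(1:50, 2 * (1:50) + rnorm(50, 0, 1e-6)))
  expect_equal(r2$slope, 2, tolerance = 1e-6)
  rc <- linregress(1:10, rep(3, 10))
  expect_equal(rc$slope, 0)
  expect_equal(rc$r_squared, 0)
  expect_error(linregress(rep(1, 10), 1:10), "zero variance")
  expect_error(linregress(1:2, 1:2), "at least 3")
})

test_that("endpoint velocity is calibrated displacement over elapsed time", {
  tr <- data.frame(frame = c(0, 180), position = c(0, 30))
  expect_equal(endpoint_velocity(tr, 0.1, 10), 6)   # 3 um / 1800 s
  expect_equal(endpoint_velocity(data.frame(frame = c(0, 10),
                                            position = c(7, 7)), 0.1, 10), 0)
  expect_lt(endpoint_velocity(data.frame(frame = c(0, 10),
                                         position = c(30, 10)), 0.1, 10), 0)
  expect_error(endpoint_velocity(data.frame(frame = 1, position = 1), 1, 1),
               "at least 2")
})

test_that("endpoint velocity equals the duration-weighted mean of segment slopes", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    tr <- data.frame(frame = cumsum(c(1, sample(1:4, n - 1, replace = TRUE))),
                     position = cumsum(rnorm(n)))
    seg_v <- diff(tr$position) / diff(tr$frame)
    w <- diff(tr$frame)
    expect_equal(endpoint_velocity(tr, 0.1, 5),
                 sum(seg_v * w) / sum(w) * 0.1 / 5 * 3600,
                 tolerance = 1e-9)
  }
})
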