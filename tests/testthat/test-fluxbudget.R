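test_that("speckle velocity is the calibrated regression slope", {
  tr <- data.frame(frame = 1:10, position = 5 + 1:10)   # 1 px/frame
  expect_equal(speckle_velocity(tr, 0.5, 5), 0.1)
  vert <- data.frame(frame = 1:10, position = rep(7, 10))
  expect_equal(speckle_velocity(vert, 0.5, 5), 0)
  expect_error(speckle_velocity(data.frame(frame = 1, position = 1), 1, 1),
               "at least 2")
})

test_that("fast classification is inclusive at the motor-velocity floor", {
  expect_true(classify_fast(0.1))
  expect_true(classify_fast(-0.1))
  expect_false(classify_fast(25 / 3600))   # 25 um/h bulk regime
  expect_true(classify_fast(0.05))         # boundary is inclusive
  expect_false(classify_fast(0.049999))
})

test_that("flux counts fast center-straddling traces once each", {
  mk <- function(v_px_f, f0 = 1, n = 20, x0 = 40) {
    data.frame(frame = f0:(f0 + n - 1),
               position = x0 + (0:(n - 1)) * v_px_f)
  }
  # 30 anterograde crossings in 60 min -> 0.5 MT/min
  trs <- trace_set(lapply(1:30, function(i) mk(2, f0 = i, x0 = 30)))
  fx <- count_flux(trs, center_col = 50, duration_min = 60,
                   pixel_size_um = 0.5, frame_interval_s = 5)
  expect_equal(unname(fx), c(0.5, 0))
  # no traces
  expect_equal(unname(count_flux(trace_set(), center_col = 10,
                                 duration_min = 5, pixel_size_um = 1,
                                 frame_interval_s = 1)), c(0, 0))
  # slow straddling traces are not counted; fast non-straddling neither
  slow <- trace_set(list(mk(0.01, x0 = 49.9)))
  expect_equal(sum(count_flux(slow, 50, 60, 0.5, 5)), 0)
  away <- trace_set(list(mk(2, x0 = 100)))
  expect_equal(sum(count_flux(away, 50, 60, 0.5, 5)), 0)
  # a trace wandering across the center still counts once
  wander <- trace_set(list(data.frame(frame = 1:9,
                                      position = 50 + 3 * sin(1:9))))
  expect_lte(sum(count_flux(wander, 50, 10, 0.5, 1) * 10), 1)
})

test_that("crossing counts are invariant to trace re-sampling density", {
  tr <- data.frame(frame = seq(1, 61, by = 10),
                   position = seq(30, 70, length.out = 7))
  dense <- data.frame(frame = 1:61,
                      position = approx(tr$frame, tr$position, 1:61)$y)
  f1 <- count_flux(trace_set(list(tr)), 50, 30, 0.5, 5)
  f2 <- count_flux(trace_set(list(dense)), 50, 30, 0.5, 5)
  expect_equal(f1, f2)
})

test_that("the mass budget reproduces its defining arithmetic exactly", {
  b <- mass_budget(0.5, 0.38, 3.59, 22)
  expect_equal(b$net_flux, 0.12)
  expect_equal(b$net_flux_h, 7.2)
  expect_equal(b$transported_length, 7.2 * 3.59)
  expect_equal(b$net_axonal_growth, 7.2 * 3.59 / 22)
  expect_equal(b$mean_interval, 1 / 0.12)
  # display rounding follows the conventional table precision
  expect_identical(kymoflow:::format_budget_value("net_flux", b$net_flux),
                   "0.12")
  expect_identical(kymoflow:::format_budget_value("transported_length",
                                                  b$transported_length), "26")
  expect_identical(kymoflow:::format_budget_value("net_axonal_growth",
                                                  b$net_axonal_growth), "1.2")
  b2 <- mass_budget(0.56, 0.30, 3.59, 22)
  expect_identical(kymoflow:::format_budget_value("net_axonal_growth",
                                                  b2$net_axonal_growth), "2.5")
  # symmetric transport nets to zero with an undefined interval
  b0 <- mass_budget(0.4, 0.4, 3, 20)
  expect_equal(b0$net_flux, 0)
  expect_equal(b0$net_axonal_growth, 0)
  expect_true(is.na(b0$mean_interval))
  expect_error(mass_budget(0.5, 0.4, -1, 22), "mt_length")
})

test_that("mass-budget identities hold bit-exactly for arbitrary inputs", {
  set.seed(6)
  for (i in 1:50) {
    a <- runif(1, 0, 2); r <- runif(1, 0, 2)
    L <- runif(1, 0.5, 10); n <- sample(5:40, 1)
    b <- mass_budget(a, r, L, n)
    expect_identical(b$net_flux, a - r)
    expect_identical(b$net_flux_h, 60 * (a - r))
    expect_identical(b$transported_length, b$net_flux_h * L)
    expect_identical(b$net_axonal_growth, b$transported_length / n)
    if (b$net_flux > 0) expect_identical(b$mean_interval, 1 / b$net_flux)
  }
})

test_that("interval-and-fraction observations imply the stated net flux", {
  expect_equal(round(net_flux_from_rate_fraction(4.2, 0.87), 2), 0.18)
  expect_equal(net_flux_from_rate_fraction(7, 0.5), 0)
  expect_equal(net_flux_from_rate_fraction(1, 1), 1)
  expect_error(net_flux_from_rate_fraction(0, 0.5), "> 0")
  expect_error(net_flux_from_rate_fraction(1, 1.5), "0, 1")
})

test_that("flux counting recovers simulated event rates", {
  sp <- neurite_sim_spec(duration = 120, seed = 21)
  ev <- draw_fast_events(sp)
  n_frames <- round(sp$duration * 60 / sp$frame_interval_s)
  trs <- traces_from_events(ev, n_frames, sp$n_cols,
                            sp$pixel_size_um, sp$frame_interval_s)
  fx <- count_flux(trs, center_col = (sp$n_cols + 1) / 2,
                   duration_min = sp$duration,
                   pixel_size_um = sp$pixel_size_um,
                   frame_interval_s = sp$frame_interval_s)
  truth_fast <- abs(ev$velocity_um_s) >= 0.05
  expect_equal(unname(fx["antero_flux"]) * sp$duration,
               sum(truth_fast & ev$direction == "antero"))
  expect_equal(unname(fx["retro_flux"]) * sp$duration,
               sum(truth_fast & ev$direction == "retro"))
})
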