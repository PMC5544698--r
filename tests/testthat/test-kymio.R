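test_that("movies round-trip through multi-page TIFF with calibration", {
  td <- withr::local_tempdir()
  st <- point_movie(10)
  path <- file.path(td, "mov.tif")
  write_movie(st, path)
  st2 <- read_movie(path, pixel_size_um = 0.1, frame_interval_s = 5)
  expect_length(st2$frames, 10)
  expect_equal(dim(st2$frames[[1]]), c(64, 64))
  expect_equal(lapply(st2$frames, as.numeric),
               lapply(st$frames, as.numeric), tolerance = 1e-6)

  # single page is a degenerate but legal stack
  tiff::writeTIFF(matrix(runif(16), 4, 4), file.path(td, "one.tif"),
                  bits.per.sample = 32L)
  one <- read_movie(file.path(td, "one.tif"),
                    pixel_size_um = 1, frame_interval_s = 1)
  expect_length(one$frames, 1)

  # garbage bytes are an I/O error, not silent nonsense
  writeLines("not a tiff", file.path(td, "bad.tif"))
  expect_error(read_movie(file.path(td, "bad.tif"),
                          pixel_size_um = 1, frame_interval_s = 1),
               "cannot read")
  expect_error(read_movie(file.path(td, "missing.tif"),
                          pixel_size_um = 1, frame_interval_s = 1),
               "no such file")
})

test_that("calibration precedence is argument > config > tags, never a default", {
  td <- withr::local_tempdir()
  path <- file.path(td, "mov.tif")
  write_movie(point_movie(3), path)
  expect_error(read_movie(path), "calibration missing")
  cfg <- file.path(td, "calib.json")
  jsonlite::write_json(list(pixel_size_um = 0.2, frame_interval_s = 10),
                       cfg, auto_unbox = TRUE)
  st <- read_movie(path, config = cfg)
  expect_equal(st$pixel_size_um, 0.2)
  st <- read_movie(path, pixel_size_um = 0.5, config = cfg)
  expect_equal(st$pixel_size_um, 0.5)      # argument wins
  expect_equal(st$frame_interval_s, 10)    # config fills the rest
})

test_that("build_kymograph reslices along the roi with perpendicular projection", {
  st <- point_movie(10, y = 30, x0 = 10)
  roi <- cbind(x = 5:60, y = rep(30, 56))
  ky <- build_kymograph(st, roi, width = 1, projection = "max")
  expect_equal(nrow(ky$grid), 10)              # one row per frame
  peaks <- apply(ky$grid, 1, which.max)
  expect_equal(unname(coef(lm(peaks ~ seq_along(peaks)))[2]), 1,
               tolerance = 1e-8)               # diagonal of slope 1 p/f
  # projection over a perpendicular band does not move the maximum
  ky3 <- build_kymograph(st, roi, width = 3, projection = "max")
  expect_equal(apply(ky3$grid, 1, which.max), peaks)
  # constant frames give a constant kymograph
  stc <- image_stack(rep(list(matrix(2, 16, 16)), 4), 1, 1)
  kyc <- build_kymograph(stc, cbind(2:14, 8), width = 1)
  expect_true(all(abs(kyc$grid - 2) < 1e-9))
  expect_error(build_kymograph(st, cbind(c(-5, 200), c(1, 1))), "bounds")
})

test_that("drawn trace images are reduced to per-component polylines", {
  k <- kymograph(matrix(0, 60, 60), 1, 1)
  tr <- trace_set(list(data.frame(frame = 1:50,
                                  position = seq(10, 40, length.out = 50))))
  img <- traces_to_flow_input(tr, c(60, 60))
  got <- read_trace_image(img, k)
  expect_length(got, 1)
  expect_gte(nrow(got$traces[[1]]), 50)
  expect_equal(diff(range(got$traces[[1]]$frame)), 49)

  expect_length(read_trace_image(matrix(0, 60, 60), k), 0)

  two <- trace_set(list(
    data.frame(frame = 1:30, position = 5 + (1:30) * 0.5),
    data.frame(frame = 1:30, position = 40 + (1:30) * 0.3)))
  expect_length(read_trace_image(traces_to_flow_input(two, c(60, 60)), k), 2)

  expect_error(read_trace_image(matrix(0, 10, 10), k), "shape")
})

test_that("rasterize / re-skeletonize round-trips within one pixel", {
  k <- kymograph(matrix(0, 80, 80), 1, 1)
  for (slope in c(0.3, 1, 2.5)) {
    n <- min(40L, floor((75 - 10) / slope))
    tr <- trace_set(list(data.frame(frame = 1:n,
                                    position = 10 + (1:n) * slope)))
    img <- traces_to_flow_input(tr, c(80, 80))
    expect_true(all(img >= 0 & img <= 1))
    back <- read_trace_image(img, k)
    expect_length(back, 1)
    ref <- approx(tr$traces[[1]]$frame, tr$traces[[1]]$position,
                  xout = back$traces[[1]]$frame)$y
    expect_lt(max(abs(back$traces[[1]]$position - ref)), 1)
  }
  # empty trace set rasterizes to all zeros
  expect_true(all(traces_to_flow_input(trace_set(), c(20, 20)) == 0))
})

test_that("containers validate their invariants", {
  expect_error(image_stack(list(matrix(0, 4, 4), matrix(0, 5, 4)), 1, 1),
               "inconsistent")
  expect_error(kymograph(matrix(0, 1, 5), 1, 1), "at least 2 x 2")
  expect_error(kymograph(matrix(0, 5, 5), 0, 1), "positive")
  expect_error(trace_set(list(data.frame(frame = c(1, 1), position = 1:2))),
               "strictly increasing")
  expect_error(trace_set(list(data.frame(frame = 1, position = 1))),
               "at least 2")
})

test_that("trace CSV round-trips", {
  td <- withr::local_tempdir()
  two <- trace_set(list(
    data.frame(frame = 1:5, position = c(1, 2, 3, 4, 5)),
    data.frame(frame = 2:6, position = c(9, 8, 7, 6, 5))))
  path <- file.path(td, "tr.csv")
  write_traces_csv(two, path)
  got <- read_traces_csv(path)
  expect_length(got, 2)
  expect_equal(got$traces[[2]]$position, two$traces[[2]]$position)
})
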