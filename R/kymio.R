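# Containers and file-format plumbing: movies, kymographs, traces.

#' Image stack (time-lapse movie)
#'
#' An ordered sequence of equally shaped intensity frames plus the
#' spatial and temporal calibration needed to express velocities in
#' physical units.
#'
#' @param frames list of numeric matrices, all the same shape, in
#'   acquisition order.
#' @param frame_interval_s seconds between consecutive frames (> 0).
#' @param pixel_size_um micrometres per pixel (> 0).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval_s, pixel_size_um) {
  if (!is.list(frames) || length(frames) < 1L)
    stopf("`frames` must be a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("inconsistent frame shapes")
  check_calibration(pixel_size_um, frame_interval_s)
  structure(list(frames = frames,
                 frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um),
            class = "image_stack")
}

check_calibration <- function(pixel_size_um, frame_interval_s) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stopf("`pixel_size_um` must be a single positive number")
  if (!is.numeric(frame_interval_s) || length(frame_interval_s) != 1L ||
      is.na(frame_interval_s) || frame_interval_s <= 0)
    stopf("`frame_interval_s` must be a single positive number")
  invisible(TRUE)
}

#' Kymograph (space-time image)
#'
#' Rows are frames (time increasing downward); columns are positions
#' along the sampling line, with distance increasing toward the growth
#' cone so that positive (rightward) motion is anterograde.
#'
#' @param grid numeric matrix of intensities, at least 2 x 2.
#' @param frame_interval_s seconds per row (> 0).
#' @param pixel_size_um micrometres per column (> 0).
#' @param origin_label free-text label for the distal end of the line.
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(grid, frame_interval_s, pixel_size_um,
                      origin_label = "distal") {
  grid <- as.matrix(grid)
  if (nrow(grid) < 2L || ncol(grid) < 2L)
    stopf("kymograph grid must be at least 2 x 2")
  storage.mode(grid) <- "double"
  check_calibration(pixel_size_um, frame_interval_s)
  structure(list(grid = grid,
                 frame_interval_s = frame_interval_s,
                 pixel_size_um = pixel_size_um,
                 origin_label = origin_label),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d frames x %d positions\n",
              nrow(x$grid), ncol(x$grid)))
  cat(sprintf("  calibration: %.4g um/px, %.4g s/frame (1 p/f = %.4g um/h)\n",
              x$pixel_size_um, x$frame_interval_s, pf_to_umh(x)))
  invisible(x)
}

#' @export
dim.kymograph <- function(x) dim(x$grid)

# Conversion factor from pixels/frame to um/h for a kymograph.
pf_to_umh <- function(kymo) {
  kymo$pixel_size_um / kymo$frame_interval_s * 3600
}

#' Set of motion traces on a kymograph
#'
#' Each trace is a polyline in (frame, position) coordinates with frame
#' indices strictly increasing; it represents the hand-tracked path of
#' one moving object.
#'
#' @param traces list of data frames (or 2-column matrices) with columns
#'   `frame` and `position`.
#' @param label free-text label.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(traces = list(), label = "") {
  traces <- lapply(traces, function(tr) {
    tr <- as.data.frame(tr)
    names(tr)[1:2] <- c("frame", "position")
    if (nrow(tr) < 2L) stopf("each trace needs at least 2 vertices")
    if (any(diff(tr$frame) <= 0))
      stopf("frame indices must be strictly increasing within a trace")
    tr[c("frame", "position")]
  })
  structure(list(traces = traces, label = label), class = "trace_set")
}

#' @export
length.trace_set <- function(x) length(x$traces)

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set '%s': %d trace(s)\n", x$label, length(x$traces)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# TIFF / CSV / JSON I/O

# Calibration precedence: explicit arguments > JSON config > TIFF tags.
# A movie or kymograph is never given silent default calibration.
resolve_calibration <- function(pixel_size_um, frame_interval_s,
                                config = NULL, tags = NULL) {
  cfg <- list()
  if (!is.null(config)) {
    cfg <- if (is.character(config)) jsonlite::read_json(config) else config
  }
  px <- pixel_size_um %||% cfg$pixel_size_um %||% tags$pixel_size_um
  dt <- frame_interval_s %||% cfg$frame_interval_s %||% tags$frame_interval_s
  if (is.null(px) || is.null(dt))
    stopf(paste("calibration missing: supply pixel_size_um and",
                "frame_interval_s as arguments, in a JSON config, or in",
                "TIFF metadata"))
  list(pixel_size_um = as.numeric(px), frame_interval_s = as.numeric(dt))
}

# Pull calibration out of TIFF attributes when present (ImageJ-style
# description "finterval=..." and x.resolution in pixels per unit).
tiff_calibration_tags <- function(frame) {
  tags <- list()
  res <- attr(frame, "x.resolution")
  unit <- attr(frame, "resolution.unit")
  if (!is.null(res) && is.numeric(res) && res > 0 && !is.null(unit)) {
    per_um <- switch(as.character(unit),
                     "inch" = res / 25400, "cm" = res / 10000, NULL)
    if (!is.null(per_um) && per_um > 0) tags$pixel_size_um <- 1 / per_um
  }
  desc <- attr(frame, "description")
  if (!is.null(desc)) {
    m <- regmatches(desc, regexec("finterval=([0-9.eE+-]+)", desc))[[1]]
    if (length(m) == 2) tags$frame_interval_s <- as.numeric(m[2])
  }
  tags
}

as_gray <- function(fr) {
  if (length(dim(fr)) == 3L) fr <- apply(fr, c(1, 2), mean)
  fr
}

#' Read a multi-page TIFF movie
#'
#' @param path path to a (possibly single-page) TIFF file.
#' @param pixel_size_um,frame_interval_s calibration overrides; when
#'   `NULL` the values are looked up in `config`, then in the TIFF tags.
#' @param config optional path to a JSON file (or a list) with fields
#'   `pixel_size_um` and `frame_interval_s`.
#' @param flip_x,flip_t set `TRUE` to mirror the spatial axis / reverse
#'   frame order so that the package convention (time down, anterograde
#'   rightward) holds for movies acquired in other orientations.
#' @return An [image_stack()].
#' @export
read_movie <- function(path, pixel_size_um = NULL, frame_interval_s = NULL,
                       config = NULL, flip_x = FALSE, flip_t = FALSE) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  frames <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                     error = function(e) stopf("cannot read '%s': %s",
                                               path, conditionMessage(e)))
  if (!is.list(frames)) frames <- list(frames)
  tags <- tiff_calibration_tags(frames[[1]])
  cal <- resolve_calibration(pixel_size_um, frame_interval_s, config, tags)
  frames <- lapply(frames, as_gray)
  if (flip_x) frames <- lapply(frames, function(f) f[, rev(seq_len(ncol(f))), drop = FALSE])
  if (flip_t) frames <- rev(frames)
  image_stack(frames, cal$frame_interval_s, cal$pixel_size_um)
}

#' Write an image stack to a multi-page 32-bit TIFF
#'
#' TIFF storage covers the unit interval; data outside `[0, 1]` are
#' rescaled affinely onto it before writing (the velocity estimators
#' are invariant to affine intensity changes, so this is lossless for
#' analysis purposes).
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(stack, path) {
  rng <- range(unlist(lapply(stack$frames, range)))
  tiff::writeTIFF(lapply(stack$frames, norm01, rng = rng), path,
                  bits.per.sample = 32L)
  invisible(path)
}

norm01 <- function(m, rng = range(m)) {
  if (rng[1] >= 0 && rng[2] <= 1) return(m)
  (m - rng[1]) / max(rng[2] - rng[1], 1e-12)
}

#' Read a kymograph from a single-page TIFF or a CSV grid
#'
#' @inheritParams read_movie
#' @return A [kymograph()].
#' @export
read_kymograph <- function(path, pixel_size_um = NULL,
                           frame_interval_s = NULL, config = NULL,
                           flip_x = FALSE, flip_t = FALSE) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    grid <- as.matrix(read.csv(path, header = FALSE))
    tags <- NULL
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    tags <- tiff_calibration_tags(pages[[1]])
    grid <- as_gray(pages[[1]])
  }
  cal <- resolve_calibration(pixel_size_um, frame_interval_s, config, tags)
  if (flip_x) grid <- grid[, rev(seq_len(ncol(grid))), drop = FALSE]
  if (flip_t) grid <- grid[rev(seq_len(nrow(grid))), , drop = FALSE]
  kymograph(grid, cal$frame_interval_s, cal$pixel_size_um)
}

#' Write a kymograph grid to a 32-bit TIFF (or CSV)
#'
#' CSV output stores the raw grid; TIFF output rescales data outside
#' `[0, 1]` onto the unit interval (see [write_movie()]).
#'
#' @param kymo a [kymograph()].
#' @param path output path; a `.csv` suffix selects CSV output.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    write.table(kymo$grid, path, sep = ",", row.names = FALSE,
                col.names = FALSE)
  } else {
    tiff::writeTIFF(norm01(kymo$grid), path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read / write traces as CSV (columns trace_id, frame, position)
#' @param path CSV path.
#' @param label label for the resulting set.
#' @return A [trace_set()].
#' @export
read_traces_csv <- function(path, label = basename(path)) {
  df <- read.csv(path)
  need <- c("trace_id", "frame", "position")
  if (!all(need %in% names(df)))
    stopf("trace CSV must have columns %s", paste(need, collapse = ", "))
  trs <- lapply(split(df[c("frame", "position")], df$trace_id),
                function(d) d[order(d$frame), ])
  trace_set(unname(trs), label = label)
}

#' @rdname read_traces_csv
#' @param traces a [trace_set()].
#' @export
write_traces_csv <- function(traces, path) {
  rows <- lapply(seq_along(traces$traces), function(i) {
    cbind(trace_id = i, traces$traces[[i]])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Kymograph construction (reslice + z-project)

#' Build a kymograph from a movie along a sampling line
#'
#' Reslices the movie along a polyline region of interest: the polyline
#' is resampled at one-pixel arc-length steps (linear interpolation);
#' the value at each arc position and frame is the maximum (or mean)
#' over `width` samples taken perpendicular to the line, which projects
#' a band of the movie onto the line.
#'
#' @param stack an [image_stack()].
#' @param roi matrix or data frame of (x, y) pixel points (x = column,
#'   y = row in the frame) tracing the sampling line from the proximal
#'   end toward the growth cone.
#' @param width odd number of perpendicular samples to project (>= 1).
#' @param projection `"max"` or `"mean"`.
#' @return A [kymograph()] with one row per frame and one column per
#'   arc-length step.
#' @export
build_kymograph <- function(stack, roi, width = 1L,
                            projection = c("max", "mean")) {
  projection <- match.arg(projection)
  roi <- as.matrix(roi)
  if (ncol(roi) < 2L || nrow(roi) < 2L)
    stopf("`roi` must be a polyline of at least two (x, y) points")
  if (width < 1L) stopf("`width` must be >= 1")
  nr <- nrow(stack$frames[[1]]); nc <- ncol(stack$frames[[1]])
  if (any(roi[, 1] < 1 | roi[, 1] > nc | roi[, 2] < 1 | roi[, 2] > nr))
    stopf("roi lies outside the frame bounds")
  p <- resample_polyline(roi[, 1], roi[, 2], step = 1)
  # Perpendicular offsets, centered on the line.
  off <- seq_len(width) - (width + 1) / 2
  rows <- lapply(stack$frames, function(fr) {
    vals <- vapply(off, function(d) {
      bilinear_sample(fr, r = p$y + d * p$nx, c = p$x - d * p$ny)
    }, numeric(length(p$x)))
    vals <- matrix(vals, nrow = length(p$x))
    if (projection == "max") apply(vals, 1, max, na.rm = TRUE)
    else rowMeans(vals, na.rm = TRUE)
  })
  grid <- do.call(rbind, rows)
  grid[!is.finite(grid)] <- 0
  if (nrow(grid) < 2L)  # degenerate single-frame stack: duplicate the row
    grid <- rbind(grid, grid)
  kymograph(grid, stack$frame_interval_s, stack$pixel_size_um)
}

# Resample a polyline at fixed arc-length steps; returns positions and
# unit tangents (tx, ty) / normals.
resample_polyline <- function(x, y, step = 1) {
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  s <- seq(0, total, by = step)
  xs <- approx(arc, x, xout = s)$y
  ys <- approx(arc, y, xout = s)$y
  tx <- c(diff(xs), tail(diff(xs), 1))
  ty <- c(diff(ys), tail(diff(ys), 1))
  n <- sqrt(tx^2 + ty^2); n[n == 0] <- 1
  list(x = xs, y = ys, s = s, nx = tx / n, ny = ty / n)
}

# ---------------------------------------------------------------------------
# Hand-drawn trace images

#' Extract traces from a drawn trace image
#'
#' Hand-drawn motion traces arrive as images the same shape as the
#' kymograph, one drawing layer per file, with the strokes as nonzero
#' pixels. Each connected stroke is reduced to a polyline by taking the
#' intensity-weighted centroid column of its pixels in every row it
#' touches (traces are monotone in time, so the row-wise centroid is an
#' exact skeleton for such curves). Components spanning fewer than two
#' rows are dropped.
#'
#' @param img a numeric matrix, or a path to a TIFF the same shape as
#'   `kymo$grid`. Any nonzero value is foreground.
#' @param kymo the [kymograph()] the traces were drawn on.
#' @param label label for the resulting set.
#' @return A [trace_set()].
#' @export
read_trace_image <- function(img, kymo, label = "") {
  if (is.character(img)) {
    pages <- tiff::readTIFF(img, all = TRUE)
    if (is.list(pages)) pages <- pages[[1]]
    img <- as_gray(pages)
  }
  img <- as.matrix(img)
  if (!all(dim(img) == dim(kymo$grid)))
    stopf("trace image shape (%d x %d) does not match kymograph (%d x %d)",
          nrow(img), ncol(img), nrow(kymo$grid), ncol(kymo$grid))
  bin <- img != 0
  if (!any(bin)) return(trace_set(list(), label = label))
  # Label on a 1-px dilation so diagonal strokes stay connected, then
  # read the labels back at the original foreground pixels.
  dil <- EBImage::dilate(EBImage::Image(bin * 1),
                         EBImage::makeBrush(3, shape = "box"))
  lab <- EBImage::bwlabel(dil)
  lab <- EBImage::imageData(lab) * bin
  trs <- list()
  for (id in setdiff(sort(unique(as.vector(lab))), 0)) {
    px <- which(lab == id, arr.ind = TRUE)
    w <- img[px]
    rows <- sort(unique(px[, 1]))
    if (length(rows) < 2L) next
    pos <- vapply(rows, function(r) {
      sel <- px[, 1] == r
      sum(px[sel, 2] * w[sel]) / sum(w[sel])
    }, numeric(1))
    trs[[length(trs) + 1L]] <- data.frame(frame = rows, position = pos)
  }
  trace_set(trs, label = label)
}

#' Rasterize traces into a flow-estimation input grid
#'
#' Draws each polyline as an anti-aliased one-pixel stroke on a grid of
#' the kymograph's shape (bilinear splatting along the path, sampled at
#' half-pixel arc steps). Overlapping traces take the pixel-wise
#' maximum, so stroke intensity stays bounded by `intensity`.
#'
#' @param traces a [trace_set()].
#' @param shape integer vector (rows, cols) of the target grid.
#' @param intensity stroke intensity.
#' @return A numeric matrix of the requested shape.
#' @export
traces_to_flow_input <- function(traces, shape, intensity = 1) {
  out <- matrix(0, shape[1], shape[2])
  for (tr in traces$traces) {
    if (any(tr$frame < 1 | tr$frame > shape[1] |
            tr$position < 1 | tr$position > shape[2]))
      stopf("trace vertices outside the target shape")
    p <- resample_polyline(tr$position, tr$frame, step = 0.5)
    layer <- matrix(0, shape[1], shape[2])
    r0 <- floor(p$y); c0 <- floor(p$x)
    fr <- p$y - r0; fc <- p$x - c0
    for (k in seq_along(p$x)) {
      for (dr in 0:1) for (dc in 0:1) {
        r <- r0[k] + dr; c <- c0[k] + dc
        if (r < 1 || r > shape[1] || c < 1 || c > shape[2]) next
        w <- (if (dr) fr[k] else 1 - fr[k]) * (if (dc) fc[k] else 1 - fc[k])
        layer[r, c] <- max(layer[r, c], intensity * w)
      }
    }
    out <- pmax(out, layer)
  }
  out
}
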