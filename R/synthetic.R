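#' Describe one synthetic plant
#'
#' A foliage blob for the scene renderer: an ellipse (broadleaf canopy) or a
#' needle cluster (radiating thin blades), placed fronto-parallel at a fixed
#' height above the tray. Foliage pixels get per-pixel HSV colors sampled
#' inside the stated ranges, plus multiplicative value jitter of +/-10% so
#' the stereo matcher has texture to correlate (flat color would make block
#' matching degenerate).
#'
#' @param center `c(row, col)` blob center in left-image pixels (1-based).
#' @param size for an ellipse, radii `c(ry, rx)` in pixels; for a needle
#'   cluster, `c(needle_length, needle_half_width)`.
#' @param height_mm plant height above the tray surface.
#' @param shape `"ellipse"` or `"needle_cluster"`.
#' @param hue,sat,val foliage sampling ranges (hue in degrees; `val` is the
#'   pre-jitter range). Defaults sit well inside the default green
#'   [hsv_segment()] so that segmentation reproduces the ground-truth mask
#'   exactly even after 8-bit quantization.
#' @param n_needles needles per cluster.
#' @return an object of class `scene_plant`.
#' @export
scene_plant <- function(center, size, height_mm,
                        shape = c("ellipse", "needle_cluster"),
                        hue = c(75, 160), sat = c(0.35, 0.9),
                        val = c(0.3, 0.8), n_needles = 12) {
  shape <- match.arg(shape)
  if (length(center) != 2L || length(size) < 1L)
    tv_data_error("scene_plant: center must be c(row, col), size a radius pair")
  if (length(size) == 1L) size <- c(size, if (shape == "ellipse") size else 1.5)
  if (any(size <= 0) || height_mm < 0)
    tv_data_error("scene_plant: sizes must be positive and height_mm >= 0")
  structure(list(shape = shape, center = as.numeric(center),
                 size = as.numeric(size), height_mm = as.numeric(height_mm),
                 hue = hue, sat = sat, val = val,
                 n_needles = as.integer(n_needles)),
            class = "scene_plant")
}

#' Describe a synthetic stereo tray scene
#'
#' Full specification of a ground-truthed scene: canvas size, a textured
#' soil/peat background plane at height 0, a set of [scene_plant()] blobs,
#' and the [stereo_rig()] whose pinhole geometry dictates each layer's
#' disparity. The soil palette and every plant's foliage ranges are
#' validated against `segment` (soil hue at least 5 degrees outside the
#' arc, foliage inside it with margins) so that segmenting the rendered
#' left image reproduces the ground-truth mask exactly.
#'
#' @param rows,cols canvas size in pixels.
#' @param plants list of [scene_plant()]s; blobs must lie inside the canvas
#'   and below the camera (`height_mm < cam_height_mm`).
#' @param rig a [stereo_rig()].
#' @param soil soil palette: list with `hue`, `sat`, `val` ranges.
#' @param texture_seed integer seed driving every random draw of the
#'   renderer; identical specs render bit-identical scenes.
#' @param segment the [hsv_segment()] the scene is built to satisfy.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(rows, cols, plants, rig,
                       soil = list(hue = c(20, 40), sat = c(0.3, 0.6),
                                   val = c(0.2, 0.5)),
                       texture_seed = 0, segment = hsv_segment()) {
  stopifnot(inherits(rig, "stereo_rig"))
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) tv_data_error("scene_spec: empty canvas")
  if (segment$hue_min > segment$hue_max)
    tv_data_error("scene_spec: wraparound scene segments are not supported")
  marg_h <- 5; marg_sv <- 0.03
  if (soil$hue[2] >= segment$hue_min - marg_h && soil$hue[1] <= segment$hue_max + marg_h)
    tv_data_error("scene_spec: soil hue range too close to the plant segment arc")
  for (p in plants) {
    if (!inherits(p, "scene_plant"))
      tv_data_error("scene_spec: plants must be scene_plant objects")
    if (p$height_mm >= rig$cam_height_mm)
      tv_data_error("scene_spec: plant height must stay below the camera")
    ext <- if (p$shape == "ellipse") p$size else rep(sum(p$size), 2L)
    if (p$center[1] - ext[1] < 1 || p$center[1] + ext[1] > rows ||
        p$center[2] - ext[2] < 1 || p$center[2] + ext[2] > cols)
      tv_data_error("scene_spec: plant blob extends off the canvas")
    if (p$hue[1] < segment$hue_min + marg_h || p$hue[2] > segment$hue_max - marg_h ||
        p$sat[1] < segment$sat_min + marg_sv || p$sat[2] > segment$sat_max ||
        p$val[1] * 0.9 < segment$val_min + marg_sv || p$val[2] * 1.1 > 1)
      tv_data_error("scene_spec: foliage HSV ranges must sit inside the segment with margin")
  }
  structure(list(rows = rows, cols = cols, plants = plants, rig = rig,
                 soil = soil, texture_seed = as.integer(texture_seed),
                 segment = segment),
            class = "scene_spec")
}

# continuous-coordinate membership test for a blob; rv/xv vectors (row, col)
blob_membership <- function(p, angles = NULL) {
  if (p$shape == "ellipse") {
    function(rv, xv)
      ((rv - p$center[1]) / p$size[1])^2 + ((xv - p$center[2]) / p$size[2])^2 <= 1
  } else {
    len <- p$size[1]; hw <- p$size[2]
    function(rv, xv) {
      dr <- rv - p$center[1]; dx <- xv - p$center[2]
      inside <- rep(FALSE, length(rv))
      for (th in angles) {
        ux <- cos(th); uy <- sin(th)
        t <- pmin(pmax(dr * uy + dx * ux, 0), len)
        d2 <- (dr - t * uy)^2 + (dx - t * ux)^2
        inside <- inside | d2 <= hw^2
      }
      inside
    }
  }
}

# sample an HSV texture rectangle and return list(r, g, b) float matrices
sample_texture <- function(nr, nc, hue, sat, val, v_jitter = 0) {
  n <- nr * nc
  h <- runif(n, hue[1], hue[2])
  s <- runif(n, sat[1], sat[2])
  v <- runif(n, val[1], val[2])
  if (v_jitter > 0) v <- pmin(v * runif(n, 1 - v_jitter, 1 + v_jitter), 1)
  rgb <- hsv_to_rgb_channels(h, s, v) * 255
  list(r = matrix(rgb[, 1], nr, nc), g = matrix(rgb[, 2], nr, nc),
       b = matrix(rgb[, 3], nr, nc))
}

# linear interpolation of texture channels at fractional columns xq (vector),
# rows iq (vector of same length); tex columns indexed from x_origin
interp_tex <- function(tex, iq, xq, x_origin) {
  x0 <- floor(xq)
  w <- xq - x0
  j0 <- x0 - x_origin + 1L
  nr <- nrow(tex$r)
  id0 <- (j0 - 1L) * nr + iq
  id1 <- j0 * nr + iq
  lapply(tex, function(ch) (1 - w) * ch[id0] + w * ch[id1])
}

#' Render a ground-truthed stereo tray scene
#'
#' Renders the left view (textured soil plane plus foliage blobs, nearest
#' blob winning where they overlap) and the geometrically consistent right
#' view, in which every layer is shifted left by its pinhole disparity
#' `d = focal_px * baseline / (cam_height - height)`; fractional shifts are
#' resolved by linear interpolation of the layer texture, and nearer layers
#' overwrite farther content. Truth fields come from the rendered geometry
#' itself, not from re-analysis: the plant mask and per-pixel heights of
#' the left view, the plant-pixel count and exact greenness, and an
#' occlusion flag for left pixels whose counterpart in the right view is
#' hidden by a nearer layer or off-canvas (where matching is expected to
#' fail and the height-recovery accounting excludes).
#'
#' The truth also flags a `discontinuity` band: pixels within
#' `edge_guard_px` of a height step between two overlapping plants. Inside
#' that band a window-based matcher straddles two disparities over
#' statistically identical foliage texture, so the scene carries no
#' information to disambiguate them; stereo accuracy benchmarks
#' conventionally score such discontinuity regions separately, and the
#' height-recovery accounting here excludes them alongside occlusions.
#' (Plant-soil borders are not flagged: the black background makes the
#' silhouette itself a strong match feature at the correct disparity.)
#'
#' @param spec a [scene_spec()].
#' @param edge_guard_px half-width of the flagged band around plant-plant
#'   height discontinuities, in pixels; the default covers the support
#'   radius of the default 9x9 matching window plus the subpixel
#'   interpolation margin.
#' @return an object of class `scene_truth`: `left`, `right` (color
#'   rasters), `mask`, `height_truth` (a `height_field`), `occluded`,
#'   `discontinuity`, `plant_pixel_count`, `greenness_truth`,
#'   `disparity_soil_px`, `disparity_plants_px`, plus the `segment` and
#'   `rig` used.
#' @export
render_scene <- function(spec, edge_guard_px = 5) {
  stopifnot(inherits(spec, "scene_spec"))
  rig <- spec$rig
  fpx <- focal_px(rig)
  nr <- spec$rows; nc <- spec$cols
  d_soil <- fpx * rig$baseline_mm / rig$cam_height_mm
  d_k <- vapply(spec$plants, function(p)
    fpx * rig$baseline_mm / (rig$cam_height_mm - p$height_mm), 0)
  with_seed(spec$texture_seed, {
    ord <- order(vapply(spec$plants, `[[`, 0, "height_mm"))
    angles <- lapply(spec$plants, function(p) {
      if (p$shape == "needle_cluster")
        sort(runif(p$n_needles, 0, 2 * pi)) else NULL
    })

    # soil plane, sampled wide enough to feed the shifted right view
    we <- nc + as.integer(ceiling(d_soil)) + 2L
    soil_tex <- sample_texture(nr, we, spec$soil$hue, spec$soil$sat,
                               spec$soil$val)
    ch_left <- lapply(soil_tex, function(m) m[, seq_len(nc), drop = FALSE])
    iq <- rep(seq_len(nr), nc)
    xq <- rep(seq_len(nc), each = nr) + d_soil
    ch_right <- lapply(interp_tex(soil_tex, iq, xq, 1L),
                       function(v) matrix(v, nr, nc))
    left_h <- matrix(0, nr, nc); right_h <- matrix(0, nr, nc)
    left_owner <- matrix(0L, nr, nc)

    for (k in ord) {
      p <- spec$plants[[k]]
      member <- blob_membership(p, angles[[k]])
      ext <- if (p$shape == "ellipse") p$size else rep(sum(p$size), 2L)
      rlo <- max(1L, floor(p$center[1] - ext[1])); rhi <- min(nr, ceiling(p$center[1] + ext[1]))
      clo <- max(1L, floor(p$center[2] - ext[2])); chi <- min(nc, ceiling(p$center[2] + ext[2]))
      xlo <- clo - 1L; xhi <- chi + 1L
      tex <- sample_texture(rhi - rlo + 1L, xhi - xlo + 1L,
                            p$hue, p$sat, p$val, v_jitter = 0.1)

      # left view: integer-pixel coverage
      ii <- rep(rlo:rhi, times = chi - clo + 1L)
      jj <- rep(clo:chi, each = rhi - rlo + 1L)
      inb <- member(ii, jj)
      if (any(inb)) {
        idx <- (jj[inb] - 1L) * nr + ii[inb]
        ti <- (jj[inb] - xlo) * (rhi - rlo + 1L) + (ii[inb] - rlo + 1L)
        ch_left$r[idx] <- tex$r[ti]
        ch_left$g[idx] <- tex$g[ti]
        ch_left$b[idx] <- tex$b[ti]
        left_h[idx] <- p$height_mm
        left_owner[idx] <- k
      }

      # right view: blob shifted left by its disparity, subpixel shape
      crlo <- max(1L, floor(clo - d_k[k])); crhi <- min(nc, ceiling(chi - d_k[k]))
      if (crlo <= crhi) {
        ii <- rep(rlo:rhi, times = crhi - crlo + 1L)
        jj <- rep(crlo:crhi, each = rhi - rlo + 1L)
        xs <- jj + d_k[k]
        ok <- xs >= xlo & xs + 1 <= xhi
        inb <- ok & member(ii, xs)
        if (any(inb)) {
          idx <- (jj[inb] - 1L) * nr + ii[inb]
          col <- interp_tex(tex, ii[inb] - rlo + 1L, xs[inb], xlo)
          ch_right$r[idx] <- col$r
          ch_right$g[idx] <- col$g
          ch_right$b[idx] <- col$b
          right_h[idx] <- p$height_mm
        }
      }
    }
  })

  to_raster <- function(ch) {
    out <- array(0L, dim = c(nr, nc, 3L))
    out[, , 1] <- pmin(pmax(as.integer(round(ch$r)), 0L), 255L)
    out[, , 2] <- pmin(pmax(as.integer(round(ch$g)), 0L), 255L)
    out[, , 3] <- pmin(pmax(as.integer(round(ch$b)), 0L), 255L)
    out
  }

  mask <- left_owner > 0L
  heights <- ifelse(mask, left_h, NA_real_)

  # occlusion: the left pixel's counterpart column in the right view is
  # covered by a nearer layer (or falls off-canvas)
  own_d <- matrix(d_soil, nr, nc)
  if (length(spec$plants)) own_d[mask] <- d_k[left_owner[mask]]
  xr <- matrix(rep(seq_len(nc), each = nr), nr, nc) - own_d
  j0 <- floor(xr); j1 <- ceiling(xr)
  occ <- xr < 1 | xr > nc
  iall <- rep(seq_len(nr), nc)
  inb0 <- !occ & j0 >= 1
  occ[inb0] <- right_h[(j0[inb0] - 1L) * nr + iall[inb0]] > left_h[inb0] + 1e-9
  inb1 <- !occ & j1 <= nc & j1 >= 1
  occ[inb1] <- right_h[(j1[inb1] - 1L) * nr + iall[inb1]] > left_h[inb1] + 1e-9

  # band around plant-plant height steps (see details)
  shift_neq <- function(h, m, dr, dc) {
    nr <- nrow(h); nc <- ncol(h)
    out <- matrix(FALSE, nr, nc)
    r1 <- max(1, 1 + dr):min(nr, nr + dr); r0 <- r1 - dr
    c1 <- max(1, 1 + dc):min(nc, nc + dc); c0 <- c1 - dc
    out[r0, c0] <- m[r0, c0] & m[r1, c1] & abs(h[r0, c0] - h[r1, c1]) > 1e-6
    out
  }
  disc <- shift_neq(left_h, mask, 0, 1) | shift_neq(left_h, mask, 0, -1) |
    shift_neq(left_h, mask, 1, 0) | shift_neq(left_h, mask, -1, 0)
  if (any(disc) && edge_guard_px > 0) {
    for (i in seq_len(edge_guard_px)) {
      d2 <- disc
      d2[-1, ] <- d2[-1, ] | disc[-nr, ]
      d2[-nr, ] <- d2[-nr, ] | disc[-1, ]
      d2[, -1] <- d2[, -1] | disc[, -nc]
      d2[, -nc] <- d2[, -nc] | disc[, -1]
      disc <- d2
    }
  }

  structure(list(
    left = to_raster(ch_left), right = to_raster(ch_right),
    mask = mask,
    height_truth = structure(list(heights_mm = heights, valid = mask),
                             class = "height_field"),
    occluded = occ,
    discontinuity = disc,
    plant_pixel_count = sum(mask),
    greenness_truth = 100 * sum(mask) / (nr * nc),
    disparity_soil_px = d_soil, disparity_plants_px = d_k,
    segment = spec$segment, rig = rig), class = "scene_truth")
}

#' Random tray scene of textured elliptical plants
#'
#' Convenience builder for benchmark scenes: `n_plants` elliptical blobs
#' with radii 18-42 px and heights drawn uniformly from `height_range_mm`,
#' scattered over the canvas (margins keep every blob on-canvas), above a
#' textured soil plane, under the reference rig at the given working
#' distance.
#'
#' @param n_plants number of plants.
#' @param rows,cols canvas size (defaults: the reference camera format).
#' @param cam_height_mm camera-to-tray distance.
#' @param height_range_mm plant height range, mm.
#' @param seed scene seed (drives placement and all texture).
#' @return a [scene_spec()].
#' @export
random_scene_spec <- function(n_plants = 20, rows = 1024, cols = 1280,
                              cam_height_mm = 500,
                              height_range_mm = c(10, 100), seed = 1) {
  # smaller canvases are treated as crops of the reference sensor format,
  # so focal_px (and hence the disparity scale) stays that of the real rig
  rig <- stereo_rig(cam_height_mm = cam_height_mm)
  plants <- with_seed(seed, {
    lapply(seq_len(n_plants), function(i) {
      ry <- runif(1, 18, 42); rx <- runif(1, 18, 42)
      scene_plant(center = c(runif(1, ry + 2, rows - ry - 1),
                             runif(1, rx + 2, cols - rx - 1)),
                  size = c(ry, rx),
                  height_mm = runif(1, height_range_mm[1], height_range_mm[2]))
    })
  })
  scene_spec(rows, cols, plants, rig, texture_seed = seed)
}

#' Simulate a growth time-series from a model
#'
#' Draws `value(t) = predict(model, t) * exp(e)`, `e ~ N(0, noise_sigma^2)`
#' (multiplicative lognormal noise), at the given sampling days. With
#' `noise_sigma = 0` the curve values are exact, which is what the
#' round-trip tests of the fitters rely on.
#'
#' @param model a `growth_model`.
#' @param times sampling days, positive.
#' @param noise_sigma lognormal noise scale, >= 0.
#' @param seed RNG seed.
#' @param species species label passed to the result.
#' @return a [growth_series()].
#' @export
simulate_series <- function(model, times, noise_sigma = 0, seed = 0,
                            species = "") {
  stopifnot(inherits(model, "growth_model"))
  if (noise_sigma < 0) tv_data_error("simulate_series: noise_sigma must be >= 0")
  if (any(times <= 0)) tv_data_error("simulate_series: times must be positive")
  mu <- predict(model, times)
  eps <- if (noise_sigma > 0)
    with_seed(seed, rnorm(length(times), 0, noise_sigma)) else 0
  growth_series(times, mu * exp(eps), variable = model$y_label,
                species = species)
}

#' Write a rendered scene to disk
#'
#' Writes the stereo pair as 8-bit RGB PNGs, the ground-truth mask as an
#' 8-bit grayscale PNG (255 = plant), the true heights through
#' [write_height_png()], and a JSON sidecar with the counts, exact
#' greenness, layer disparities and the segment used.
#'
#' @param truth a `scene_truth`.
#' @param dir output directory (created if missing).
#' @param basename file stem.
#' @return the sidecar path, invisibly.
#' @export
write_scene <- function(truth, dir, basename = "scene") {
  stopifnot(inherits(truth, "scene_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(suffix) file.path(dir, paste0(basename, suffix))
  write_image_png(truth$left, p("_left.png"))
  write_image_png(truth$right, p("_right.png"))
  png::writePNG(truth$mask * 1, p("_mask.png"))
  write_height_png(truth$height_truth, p("_height_truth.png"))
  sidecar <- list(plant_pixel_count = truth$plant_pixel_count,
                  greenness_truth = truth$greenness_truth,
                  disparity_soil_px = truth$disparity_soil_px,
                  disparity_plants_px = truth$disparity_plants_px,
                  segment = unclass(truth$segment),
                  rig = unclass(truth$rig))
  jsonlite::write_json(sidecar, p("_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(p("_truth.json"))
}
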