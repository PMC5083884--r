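# fixtures built in code; no binary files ship with the tests

# uniform-color raster
flat_raster <- function(rows, cols, rgb) {
  as_color_raster(array(rep(as.integer(rgb), each = rows * cols),
                        dim = c(rows, cols, 3L)))
}

# seeded random-texture raster with channel values in [lo, hi]
noise_raster <- function(rows, cols, seed, lo = 40, hi = 220) {
  set.seed(seed)
  as_color_raster(array(sample(lo:hi, rows * cols * 3L, replace = TRUE),
                        dim = c(rows, cols, 3L)))
}

# shift a raster left by `s` columns (the geometry of a farther camera),
# filling the exposed right margin with the wrapped columns so the frame
# stays fully textured
shift_left <- function(image, s) {
  nc <- dim(image)[2]
  image[, c((s + 1):nc, seq_len(s)), , drop = FALSE]
}

# small default-geometry scene used by several stereo tests
small_scene <- function(seed = 7, n_plants = 3, rows = 220, cols = 320,
                        heights = c(20, 80)) {
  render_scene(random_scene_spec(n_plants = n_plants, rows = rows,
                                 cols = cols, cam_height_mm = 500,
                                 height_range_mm = heights, seed = seed))
}

# reference rig of the bench at 500 mm working distance
bench_rig <- function() stereo_rig(cam_height_mm = 500)

# independent per-pixel integer-disparity ZNCC scan, plain R loops; used as
# the oracle for the compiled matcher
oracle_zncc_scan <- function(gl, gr, r, c, d_range, block = 9) {
  h <- block %/% 2
  scores <- sapply(d_range, function(d) {
    wl <- gl[(r - h):(r + h), (c - h):(c + h)]
    wr <- gr[(r - h):(r + h), (c - d - h):(c - d + h)]
    wl <- wl - mean(wl); wr <- wr - mean(wr)
    den <- sqrt(sum(wl^2) * sum(wr^2))
    if (den <= 0) -1 else sum(wl * wr) / den
  })
  d_range[which.max(scores)]
}

gray_of <- function(image) {
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}
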