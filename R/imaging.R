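#' Color rasters
#'
#' A color raster is the package's in-memory form of an 8-bit RGB top-view
#' image: an integer array of dimension `rows x cols x 3` with channel values
#' in `[0, 255]`. [read_image_png()] and [write_image_png()] convert between
#' this form and RGB PNG files.
#'
#' @param x object to validate or coerce.
#' @return `as_color_raster()` returns the validated integer array.
#' @export
as_color_raster <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    tv_data_error("a color raster must be a rows x cols x 3 array")
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    tv_data_error("empty raster: need at least one row and one column")
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    tv_data_error("channel values must lie in [0, 255]")
  storage.mode(x) <- "integer"
  x
}

#' Read / write 8-bit RGB PNG images
#'
#' @param path file path.
#' @param image a color raster (see [as_color_raster()]).
#' @return `read_image_png()` returns a color raster; `write_image_png()`
#'   returns `path` invisibly.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) tv_data_error(paste0("cannot read image: ", path))
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  as_color_raster(array(as.integer(round(px[, , 1:3] * 255)),
                        dim = c(dim(px)[1:2], 3L)))
}

#' @rdname read_image_png
#' @export
write_image_png <- function(image, path) {
  image <- as_color_raster(image)
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Convert an RGB raster to HSV
#'
#' Per-pixel conversion of an 8-bit RGB raster to hue-saturation-value, the
#' space in which foliage selection is done. Hue is in degrees `[0, 360)`
#' (achromatic pixels get hue 0 by convention); saturation and value are in
#' `[0, 1]`.
#'
#' @param image a color raster.
#' @return a numeric array `rows x cols x 3` holding H, S, V planes.
#' @seealso [hsv_to_rgb_raster()] for the inverse, [segment_plant()].
#' @export
rgb_to_hsv_raster <- function(image) {
  image <- as_color_raster(image)
  d <- dim(image)
  m <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
             as.vector(image[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  out <- array(0, dim = d)
  out[, , 1] <- (hsv[1, ] * 360) %% 360
  out[, , 2] <- hsv[2, ]
  out[, , 3] <- hsv[3, ]
  out
}

#' Convert an HSV raster back to 8-bit RGB
#'
#' Inverse of [rgb_to_hsv_raster()] (standard sector formula, vectorized);
#' also used by the synthetic scene renderer to turn sampled foliage/soil
#' colors into image pixels.
#'
#' @param hsv numeric array `rows x cols x 3`: H in degrees, S and V in
#'   `[0, 1]`.
#' @return a color raster.
#' @export
hsv_to_rgb_raster <- function(hsv) {
  if (!is.array(hsv) || length(dim(hsv)) != 3L || dim(hsv)[3] != 3L)
    tv_data_error("hsv raster must be a rows x cols x 3 array")
  rgb <- hsv_to_rgb_channels(as.vector(hsv[, , 1]), as.vector(hsv[, , 2]),
                             as.vector(hsv[, , 3]))
  as_color_raster(array(as.integer(round(rgb * 255)),
                        dim = c(dim(hsv)[1:2], 3L)))
}

# h in degrees, s/v in [0,1]; returns cbind(r,g,b) in [0,1]
hsv_to_rgb_channels <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

#' Cylindrical HSV selection segment
#'
#' The region of HSV color space whose member pixels count as plant: a hue
#' arc crossed with a saturation band and a value band. All bounds are
#' inclusive. `hue_min > hue_max` is legal and denotes a wraparound arc
#' through 0 degrees, needed for red-brown foliage.
#'
#' The default segment is a generous green arc that excludes dark peat/soil
#' and specular highlights; per-camera overrides normally come from an INI
#' file (see [read_ini()]).
#'
#' @param hue_min,hue_max hue bounds in degrees, each in `[0, 360)`.
#' @param sat_min,sat_max saturation bounds in `[0, 1]`.
#' @param val_min,val_max value bounds in `[0, 1]`.
#' @return an object of class `hsv_segment`.
#' @export
hsv_segment <- function(hue_min = 60, hue_max = 180,
                        sat_min = 0.15, sat_max = 1,
                        val_min = 0.15, val_max = 1) {
  num1 <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
      tv_data_error(sprintf("hsv_segment: %s must be a number in [%g, %g]",
                            nm, lo, hi))
    as.numeric(x)
  }
  seg <- list(hue_min = num1(hue_min, 0, 360 - 1e-9, "hue_min"),
              hue_max = num1(hue_max, 0, 360 - 1e-9, "hue_max"),
              sat_min = num1(sat_min, 0, 1, "sat_min"),
              sat_max = num1(sat_max, 0, 1, "sat_max"),
              val_min = num1(val_min, 0, 1, "val_min"),
              val_max = num1(val_max, 0, 1, "val_max"))
  if (seg$sat_min > seg$sat_max)
    tv_data_error("hsv_segment: sat_min must not exceed sat_max")
  if (seg$val_min > seg$val_max)
    tv_data_error("hsv_segment: val_min must not exceed val_max")
  structure(seg, class = "hsv_segment")
}

#' @export
print.hsv_segment <- function(x, ...) {
  wrap <- if (x$hue_min > x$hue_max) " (wraparound through 0)" else ""
  cat(sprintf("HSV segment: hue [%g, %g]%s deg, sat [%g, %g], val [%g, %g]\n",
              x$hue_min, x$hue_max, wrap, x$sat_min, x$sat_max,
              x$val_min, x$val_max))
  invisible(x)
}

# membership of hue values (degrees) in a possibly wrapping closed arc
hue_in_arc <- function(h, hue_min, hue_max) {
  if (hue_min <= hue_max) h >= hue_min & h <= hue_max
  else h >= hue_min | h <= hue_max
}

#' Select plant pixels inside an HSV segment
#'
#' Flags each pixel of an HSV raster as plant when its hue lies on the
#' segment's (possibly wrapping) arc and its saturation and value fall in
#' the segment's bands, all bounds inclusive. Achromatic pixels (S = 0,
#' hue 0 by convention) can only be selected when `sat_min` is 0.
#'
#' @param hsv an HSV raster from [rgb_to_hsv_raster()].
#' @param segment an [hsv_segment()].
#' @return a logical `rows x cols` plant mask.
#' @export
segment_plant <- function(hsv, segment = hsv_segment()) {
  if (!is.array(hsv) || length(dim(hsv)) != 3L || dim(hsv)[3] != 3L)
    tv_data_error("segment_plant: hsv must be a rows x cols x 3 array")
  if (!inherits(segment, "hsv_segment"))
    tv_data_error("segment_plant: segment must be an hsv_segment")
  h <- hsv[, , 1]; s <- hsv[, , 2]; v <- hsv[, , 3]
  mask <- hue_in_arc(h, segment$hue_min, segment$hue_max) &
    s >= segment$sat_min & s <= segment$sat_max &
    v >= segment$val_min & v <= segment$val_max
  dim(mask) <- dim(hsv)[1:2]
  mask
}

#' Black out everything but the plant
#'
#' Produces the "green-only" image: plant pixels keep their original RGB
#' values, every other pixel becomes bit-exact black `(0, 0, 0)`. The
#' green-only pair is also what the stereo matcher consumes, so that soil
#' texture cannot distract the correlation.
#'
#' @param image a color raster.
#' @param mask a logical plant mask of matching shape.
#' @return a color raster.
#' @export
apply_green_only <- function(image, mask) {
  image <- as_color_raster(image)
  if (!is.logical(mask) || !identical(dim(mask), dim(image)[1:2]))
    tv_data_error("apply_green_only: mask shape must match the image")
  keep <- array(rep(mask, 3L), dim = dim(image))
  image[!keep] <- 0L
  image
}

#' Percentage greenness
#'
#' The fraction of pixels classified as plant, as a percentage of the image
#' (or of a rectangular region of interest): the top-view proxy for green
#' ground coverage by foliage.
#'
#' @param mask a logical plant mask.
#' @param roi optional region of interest `c(row_start, row_end, col_start,
#'   col_end)`, 0-based, origin top-left, half-open on the upper bounds
#'   (`row_start <= row < row_end`). Default: the whole mask.
#' @return greenness in `[0, 100]`.
#' @export
greenness <- function(mask, roi = NULL) {
  if (!is.logical(mask) || !is.matrix(mask))
    tv_data_error("greenness: mask must be a logical matrix")
  if (!is.null(roi)) {
    if (length(roi) != 4L || anyNA(roi))
      tv_data_error("greenness: roi must be c(row_start, row_end, col_start, col_end)")
    roi <- as.integer(roi)
    if (roi[1] < 0L || roi[3] < 0L || roi[2] > nrow(mask) || roi[4] > ncol(mask) ||
        roi[1] >= roi[2] || roi[3] >= roi[4])
      tv_data_error("greenness: roi is empty or outside the mask bounds")
    mask <- mask[(roi[1] + 1L):roi[2], (roi[3] + 1L):roi[4], drop = FALSE]
  }
  100 * sum(mask) / length(mask)
}
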