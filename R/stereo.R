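#' Stereo rig geometry
#'
#' Pinhole-pair geometry of the imaging bench: two identical cameras mounted
#' side by side above the seedling tray. Defaults describe the reference
#' bench (1/1.8" CMOS, 1280 x 1024 px on a 6.79 x 5.43 mm sensor, 5 mm fixed
#' focal length, ~55 mm baseline). The camera-to-tray distance
#' `cam_height_mm` depends on how the bench is set up and must always be
#' supplied explicitly.
#'
#' @param baseline_mm center-to-center camera separation (mm).
#' @param focal_mm lens focal length (mm).
#' @param sensor_w_mm,sensor_h_mm sensor dimensions (mm).
#' @param px_w,px_h pixel counts.
#' @param cam_height_mm distance from the optical centers to the tray
#'   surface plane (mm); no default.
#' @return an object of class `stereo_rig`.
#' @export
stereo_rig <- function(cam_height_mm, baseline_mm = 55, focal_mm = 5,
                       sensor_w_mm = 6.79, sensor_h_mm = 5.43,
                       px_w = 1280, px_h = 1024) {
  if (missing(cam_height_mm) || is.null(cam_height_mm) || is.na(cam_height_mm))
    tv_usage_error("stereo_rig: cam_height_mm is required (no default)")
  vals <- c(cam_height_mm = cam_height_mm, baseline_mm = baseline_mm,
            focal_mm = focal_mm, sensor_w_mm = sensor_w_mm,
            sensor_h_mm = sensor_h_mm, px_w = px_w, px_h = px_h)
  if (any(!is.finite(vals)) || any(vals <= 0))
    tv_data_error("stereo_rig: all geometry values must be strictly positive")
  structure(as.list(vals), class = "stereo_rig")
}

#' @rdname stereo_rig
#' @param rig a `stereo_rig`.
#' @return `focal_px()` returns the focal length expressed in horizontal
#'   pixels, `focal_mm * px_w / sensor_w_mm`.
#' @export
focal_px <- function(rig) {
  stopifnot(inherits(rig, "stereo_rig"))
  rig$focal_mm * rig$px_w / rig$sensor_w_mm
}

#' @export
print.stereo_rig <- function(x, ...) {
  cat(sprintf(paste0("Stereo rig: baseline %g mm, focal %g mm (%.2f px), ",
                     "sensor %g x %g mm, %d x %d px, camera height %g mm\n"),
              x$baseline_mm, x$focal_mm, focal_px(x), x$sensor_w_mm,
              x$sensor_h_mm, x$px_w, x$px_h, x$cam_height_mm))
  invisible(x)
}

# luminance for matching; green-only inputs keep soil pixels at 0
raster_to_gray <- function(image) {
  image <- as_color_raster(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Plant-masked disparity map
#'
#' Block-matching stereo on a rectified pair. Disparities are computed only
#' at mask-true pixels of the left image (the point of removing the soil
#' background first: less work and no spurious correlation against soil
#' texture). The matching cost is zero-mean normalized cross-correlation
#' over square windows, the winner refined to subpixel precision by
#' parabolic interpolation of the score over its two neighbors. Pixels
#' failing the confidence test (`min_corr`), winning at a search-range
#' boundary, or lacking texture are invalid. Equal scores resolve to the
#' smallest disparity (the farthest surface).
#'
#' Matching the green-only images (see [apply_green_only()]) of both views
#' rather than the raw frames is recommended and is what [cmd_heightmap()]
#' does.
#'
#' With `lr_check = TRUE` (the default) a second matching pass is run with
#' the cameras' roles swapped and a left pixel is kept only when the right
#' view matches back to it within `lr_tol` pixels — the standard
#' left-right consistency filter that removes mismatches in the
#' half-occluded strips at blob borders. The second pass doubles
#' `cost_evals`.
#'
#' @param left,right color rasters of the rectified pair (same shape).
#' @param mask logical plant mask for the left image.
#' @param search integer disparity search range `c(d_min, d_max)`, in
#'   pixels. A positive disparity `d` matches left column `c` to right
#'   column `c - d`; negative values are permitted so that a zero-disparity
#'   surface can sit in the interior of the range.
#' @param block odd matching window side, >= 3.
#' @param min_corr peak-correlation confidence threshold in `(-1, 1]`.
#' @param lr_check run the left-right consistency pass.
#' @param mask_right plant mask of the right image for the consistency
#'   pass; default: every non-black right pixel (appropriate for
#'   green-only input).
#' @param lr_tol consistency tolerance in pixels.
#' @return an object of class `disparity_map` with fields `values` (numeric
#'   matrix, `NA` where invalid), `valid` (logical matrix), `search`,
#'   `block`, and `cost_evals` (total window evaluations performed).
#' @export
compute_disparity <- function(left, right, mask, search = c(4, 256),
                              block = 9, min_corr = 0.5, lr_check = TRUE,
                              mask_right = NULL, lr_tol = 1) {
  gl <- raster_to_gray(left)
  gr <- raster_to_gray(right)
  if (!identical(dim(gl), dim(gr)))
    tv_data_error("compute_disparity: left and right shapes differ")
  if (!is.logical(mask) || !identical(dim(mask), dim(gl)))
    tv_data_error("compute_disparity: mask shape must match the left image")
  search <- as.integer(search)
  if (length(search) != 2L || anyNA(search) || search[1] > search[2])
    tv_data_error("compute_disparity: empty search range")
  if (search[2] >= ncol(gl))
    tv_data_error("compute_disparity: search range exceeds image width")
  block <- as.integer(block)
  if (is.na(block) || block < 3L || block %% 2L == 0L)
    tv_data_error("compute_disparity: block size must be odd and >= 3")
  res <- bm_zncc(gl, gr, mask, search[1], search[2], block, min_corr)
  evals <- res$evals
  if (lr_check) {
    nr <- nrow(gl); nc <- ncol(gl)
    if (is.null(mask_right)) mask_right <- gr > 0
    if (!is.logical(mask_right) || !identical(dim(mask_right), dim(gr)))
      tv_data_error("compute_disparity: mask_right shape must match the right image")
    mirror <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
    rev_pass <- bm_zncc(mirror(gr), mirror(gl), mirror(mask_right),
                        search[1], search[2], block, min_corr)
    evals <- evals + rev_pass$evals
    d_right <- mirror(rev_pass$values)      # indexed by right-image column
    idx <- which(res$valid)
    if (length(idx)) {
      rr <- ((idx - 1L) %% nr) + 1L
      cc <- ((idx - 1L) %/% nr) + 1L
      dl <- res$values[idx]
      cr <- as.integer(round(cc - dl))
      ok <- cr >= 1L & cr <= nc
      dr <- rep(NA_real_, length(idx))
      dr[ok] <- d_right[cbind(rr[ok], cr[ok])]
      keep <- !is.na(dr) & abs(dr - dl) <= lr_tol
      drop <- idx[!keep]
      res$valid[drop] <- FALSE
      res$values[drop] <- NA_real_
    }
  }
  structure(list(values = res$values, valid = res$valid, search = search,
                 block = block, min_corr = min_corr,
                 cost_evals = evals),
            class = "disparity_map")
}

#' Convert disparity to plant height above the tray
#'
#' Pinhole triangulation: depth `Z = focal_px * baseline / disparity`,
#' height above the tray `= cam_height - Z`. Pixels with non-positive
#' disparity (impossible geometry, signalling an occlusion or mismatch) are
#' marked invalid rather than raising an error, as are heights outside
#' `[-height_tol_mm, cam_height_mm]`.
#'
#' @param disp a `disparity_map`.
#' @param rig a [stereo_rig()].
#' @param height_tol_mm tolerance below the tray plane before a height is
#'   declared a mismatch (mm).
#' @return an object of class `height_field` with fields `heights_mm`
#'   (numeric matrix, `NA` where invalid) and `valid`.
#' @export
disparity_to_height <- function(disp, rig, height_tol_mm = 5) {
  stopifnot(inherits(disp, "disparity_map"), inherits(rig, "stereo_rig"))
  d <- disp$values
  valid <- disp$valid & !is.na(d) & d > 0
  z <- focal_px(rig) * rig$baseline_mm / d
  h <- rig$cam_height_mm - z
  valid <- valid & !is.na(h) & h >= -height_tol_mm & h <= rig$cam_height_mm
  h[!valid] <- NA_real_
  structure(list(heights_mm = h, valid = valid), class = "height_field")
}

#' Summarize a height field into a scene-level plant height
#'
#' The scene statistic is the 95th percentile of valid plant-pixel heights:
#' a proxy for "base to highest leaf" that is robust to occasional matching
#' outliers. Mean, median, the percentile itself and the valid-pixel count
#' are returned alongside. With no valid pixels all statistics are `NA` and
#' a warning is raised.
#'
#' @param field a `height_field`.
#' @return an object of class `height_summary` with fields
#'   `plant_height_mm`, `mean_mm`, `median_mm`, `p95_mm`, `n_valid`.
#' @export
summarize_height <- function(field) {
  stopifnot(inherits(field, "height_field"))
  h <- field$heights_mm[field$valid]
  n <- length(h)
  if (n == 0L) {
    warning("summarize_height: no valid plant pixels")
    s <- list(plant_height_mm = NA_real_, mean_mm = NA_real_,
              median_mm = NA_real_, p95_mm = NA_real_, n_valid = 0L)
  } else {
    p95 <- unname(quantile(h, 0.95, type = 7))
    s <- list(plant_height_mm = p95, mean_mm = mean(h), median_mm = median(h),
              p95_mm = p95, n_valid = n)
  }
  structure(s, class = "height_summary")
}

#' @export
print.height_summary <- function(x, ...) {
  if (x$n_valid == 0L) cat("Height summary: no valid plant pixels\n")
  else cat(sprintf(paste0("Height summary: plant height %.1f mm (p95), ",
                          "mean %.1f, median %.1f, n = %d\n"),
                   x$plant_height_mm, x$mean_mm, x$median_mm, x$n_valid))
  invisible(x)
}
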