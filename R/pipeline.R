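#' Recover plant heights from a rendered or captured stereo pair
#'
#' The full measurement chain on one scene: segment both views with the
#' segment, black out the soil, run masked block matching with left-right
#' consistency, and triangulate heights with the rig. This is the same
#' chain [cmd_heightmap()] drives from the shell.
#'
#' @param left,right color rasters of the rectified pair.
#' @param rig a [stereo_rig()].
#' @param segment the [hsv_segment()] defining plant pixels.
#' @param search,block,min_corr matching parameters (see
#'   [compute_disparity()]).
#' @return a list with the left `mask`, the `disparity_map` and the
#'   `height_field`.
#' @export
recover_heights <- function(left, right, rig, segment = hsv_segment(),
                            search = c(4, 256), block = 9, min_corr = 0.5) {
  mask <- segment_plant(rgb_to_hsv_raster(left), segment)
  mask_r <- segment_plant(rgb_to_hsv_raster(right), segment)
  disp <- compute_disparity(apply_green_only(left, mask),
                            apply_green_only(right, mask_r),
                            mask, search = search, block = block,
                            min_corr = min_corr, mask_right = mask_r)
  list(mask = mask, disparity = disp,
       field = disparity_to_height(disp, rig))
}

#' RMS height error of a recovery against scene ground truth
#'
#' Root-mean-squared difference between recovered and true heights over
#' the scoreable plant pixels: valid matches that are neither occluded in
#' the right view nor inside the plant-plant discontinuity band (see
#' [render_scene()] for why those are excluded).
#'
#' @param truth a `scene_truth`.
#' @param field a `height_field` recovered from the truth's stereo pair.
#' @return a list: `rms_mm`, `n` scored pixels, `coverage` (scored
#'   fraction of plant pixels).
#' @export
height_rms_error <- function(truth, field) {
  stopifnot(inherits(truth, "scene_truth"), inherits(field, "height_field"))
  use <- field$valid & truth$mask & !truth$occluded & !truth$discontinuity
  err <- field$heights_mm[use] - truth$height_truth$heights_mm[use]
  list(rms_mm = if (length(err)) sqrt(mean(err^2)) else NA_real_,
       n = sum(use),
       coverage = sum(use) / max(1L, truth$plant_pixel_count))
}
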