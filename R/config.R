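#' Read an INI configuration file
#'
#' Parses the per-camera INI dialect: `[section]` headers, `key = value`
#' lines, `;` or `#` comments, blank lines ignored. Values that parse as
#' numbers are returned numeric, everything else as character.
#'
#' Recognized sections are `[hsv]` (segment bounds `hue_min`, `hue_max`,
#' `sat_min`, `sat_max`, `val_min`, `val_max`), `[rig]` (`baseline_mm`,
#' `focal_mm`, `sensor_w_mm`, `sensor_h_mm`, `px_w`, `px_h`,
#' `cam_height_mm`) and `[matching]` (`block`, `d_min`, `d_max`,
#' `min_corr`). A `[camera]` section (acquisition timing and gain settings)
#' is parsed but not acted upon; a notice is logged.
#'
#' @param path INI file path.
#' @return a named list of sections, each a named list of values.
#' @export
read_ini <- function(path) {
  if (!file.exists(path)) tv_usage_error(paste0("cannot read config: ", path))
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- ""
  for (i in seq_along(lines)) {
    line <- sub("[;#].*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.+\\]$", line)) {
      section <- sub("^\\[(.+)\\]$", "\\1", line)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    if (!grepl("=", line, fixed = TRUE))
      tv_usage_error(sprintf("config parse failure at line %d: '%s'", i, lines[i]))
    key <- trimws(sub("=.*$", "", line))
    val <- trimws(sub("^[^=]*=", "", line))
    if (!nzchar(key))
      tv_usage_error(sprintf("config parse failure at line %d: empty key", i))
    num <- suppressWarnings(as.numeric(val))
    out[[section]][[key]] <- if (!is.na(num)) num else val
  }
  if (!is.null(out$camera) && length(out$camera))
    message("notice: [camera] acquisition settings (",
            paste(names(out$camera), collapse = ", "),
            ") are parsed but not acted upon")
  out
}

#' Assemble a run configuration
#'
#' Merges, in increasing precedence: package defaults, an INI file, and
#' explicit overrides (named `section.key`, e.g. `"rig.cam_height_mm"`).
#' Every setting has a default except `rig.cam_height_mm`, which depends on
#' the bench and must come from the INI file or an override before any
#' height mapping is possible.
#'
#' @param ini optional INI file path (see [read_ini()]).
#' @param overrides named list of `section.key` overrides.
#' @return an object of class `run_config` with elements `segment`
#'   (an [hsv_segment()]), `rig_args`, `matching`.
#' @export
run_config <- function(ini = NULL, overrides = list()) {
  cfg <- list(
    hsv = list(hue_min = 60, hue_max = 180, sat_min = 0.15, sat_max = 1,
               val_min = 0.15, val_max = 1),
    rig = list(baseline_mm = 55, focal_mm = 5, sensor_w_mm = 6.79,
               sensor_h_mm = 5.43, px_w = 1280, px_h = 1024,
               cam_height_mm = NA_real_),
    matching = list(block = 9, d_min = 4, d_max = 256, min_corr = 0.5))
  if (!is.null(ini)) {
    parsed <- read_ini(ini)
    for (sec in intersect(names(parsed), names(cfg)))
      for (key in names(parsed[[sec]])) {
        if (!key %in% names(cfg[[sec]]))
          tv_usage_error(sprintf("unknown config key [%s] %s", sec, key))
        cfg[[sec]][[key]] <- parsed[[sec]][[key]]
      }
  }
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || is.null(cfg[[parts[1]]]) ||
        !parts[2] %in% names(cfg[[parts[1]]]))
      tv_usage_error(paste0("unknown config override: ", nm))
    cfg[[parts[1]]][[parts[2]]] <- overrides[[nm]]
  }
  structure(list(segment = do.call(hsv_segment, cfg$hsv),
                 rig_args = cfg$rig, matching = cfg$matching),
            class = "run_config")
}

# build the stereo_rig from a config, failing clearly without cam height
config_rig <- function(config) {
  if (is.na(config$rig_args$cam_height_mm))
    tv_usage_error(paste0("rig.cam_height_mm is not configured; set it in the ",
                          "INI [rig] section or as an override"))
  do.call(stereo_rig, config$rig_args)
}
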