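#' Analysis configuration
#'
#' All numeric parameters of the pipeline in one nested list, with the
#' published defaults. Every threshold used by a run is echoed into the
#' analysis report so a run can be reproduced exactly from its report.
#'
#' @param ... named overrides, either whole sections (`preprocess = list(...)`)
#'   or left at defaults.
#' @return a nested list of class `mg_config`.
#' @details Sections and defaults:
#' \describe{
#'   \item{preprocess}{`center_target = 100` (histogram centering target, gray
#'     levels; applied only when the foreground mean is darker),
#'     `center_darker_only = TRUE`, `canny_aperture = 3`, `canny_lo = 0`,
#'     `canny_hi = 255`, `saturation_floor = 250`, `dark_threshold = 50`
#'     (strictly-below pixels become black), `clahe_clip = 12`,
#'     `clahe_grid = c(20, 20)`, `closing_diameter = 5`, plus one logical
#'     toggle per stage for ablation studies.}
#'   \item{profiles}{`depths = c(0.10, 0.45, 0.55, 0.75)` (fractions of the
#'     eyelid's vertical extent, top to bottom), `n_zones = 5`.}
#'   \item{peaks}{`smooth_window = 11`, `smooth_order = 1` (Savitzky--Golay),
#'     `smooth_method = "savgol"` (`"moving_average"` with
#'     `moving_average_window = 200` is available as the exploratory
#'     alternative), `prominence = 0.1` (on the profile normalized to
#'     `[0, 1]`), `min_width = 2` (px), `fuse_distance = 10` (px, strict),
#'     `max_width = 90` (px, strict), `fused_height = "max"`.}
#'   \item{tracing}{`full_max_len = 100` (px; a shortest path longer than this
#'     ends the extraction phase), `pair_max_len = 60` (px; two-layer edges
#'     shorter than this are short glands), `accept_leq = TRUE` (accept paths
#'     with length <= `full_max_len`; the alternative reading of the stopping
#'     rule is available as `FALSE`, which accepts strictly below).}
#'   \item{metrics}{`width_summary = "mean"` (per-gland summary of its member
#'     peak widths; `"median"` available).}
#' }
#' @export
#' @examples
#' cfg <- mg_config(peaks = list(prominence = 0.15))
#' cfg$peaks$prominence
mg_config <- function(...) {
  cfg <- list(
    preprocess = list(
      center_target = 100, center_darker_only = TRUE,
      canny_aperture = 3, canny_lo = 0, canny_hi = 255,
      saturation_floor = 250,
      dark_threshold = 50,
      clahe_clip = 12, clahe_grid = c(20, 20),
      closing_diameter = 5,
      do_center = TRUE, do_reflections = TRUE, do_dark = TRUE,
      do_clahe = TRUE, do_closing = TRUE, do_equalize = TRUE
    ),
    profiles = list(depths = c(0.10, 0.45, 0.55, 0.75), n_zones = 5),
    peaks = list(
      smooth_window = 11, smooth_order = 1,
      smooth_method = "savgol", moving_average_window = 200,
      prominence = 0.1, min_width = 2,
      fuse_distance = 10, max_width = 90, fused_height = "max"
    ),
    tracing = list(full_max_len = 100, pair_max_len = 60, accept_leq = TRUE),
    metrics = list(width_summary = "mean")
  )
  over <- list(...)
  for (sec in names(over)) {
    if (!sec %in% names(cfg)) stop("unknown config section: ", sec, call. = FALSE)
    for (key in names(over[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop("unknown config key: ", sec, "$", key, call. = FALSE)
      cfg[[sec]][[key]] <- over[[sec]][[key]]
    }
  }
  structure(cfg, class = "mg_config")
}

#' Read a configuration file
#'
#' JSON file whose top-level sections/keys mirror [mg_config()]; unspecified
#' values keep their defaults.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @return `mg_config` list.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(mg_config())
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(mg_config, raw)
}
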