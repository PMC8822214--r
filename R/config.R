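#' Pipeline configuration
#'
#' Assembles and validates the full set of tunable thresholds. Values are
#' organized in sections mirroring the pipeline stages; any subset can be
#' overridden, unknown keys are rejected.
#'
#' @param calibration list: `microns_per_pixel` (default 0.1).
#' @param segmentation list: `noise_floor_um2` (0.5), `pending_ceiling_um2`
#'   (10), `a` (0.3), `b` (5), `convexity_min` (0.9), `edge_refine`
#'   (`TRUE`), `otsu_channel` (`"s"`).
#' @param classification list: `ratio_threshold` (0.8).
#' @param area list: `roundness_min` (0.85), `include_non_recall`
#'   (`FALSE`).
#' @param stats list: `alpha_normality` (0.05), `holm` (`FALSE`).
#' @return A validated `rbc_config` list.
#' @export
rbc_config <- function(calibration = list(), segmentation = list(),
                       classification = list(), area = list(),
                       stats = list()) {
  defaults <- list(
    calibration = list(microns_per_pixel = 0.1),
    segmentation = list(noise_floor_um2 = 0.5, pending_ceiling_um2 = 10,
                        a = 0.3, b = 5, convexity_min = 0.9,
                        edge_refine = TRUE, otsu_channel = "s"),
    classification = list(ratio_threshold = 0.8),
    area = list(roundness_min = 0.85, include_non_recall = FALSE),
    stats = list(alpha_normality = 0.05, holm = FALSE)
  )
  user <- list(calibration = calibration, segmentation = segmentation,
               classification = classification, area = area, stats = stats)
  cfg <- defaults
  for (sec in names(defaults)) {
    extra <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(extra))
      stop("unknown key(s) in section '", sec, "': ",
           paste(extra, collapse = ", "))
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  with(cfg$calibration,
       stopifnot(is.finite(microns_per_pixel), microns_per_pixel > 0))
  with(cfg$segmentation, {
    stopifnot(noise_floor_um2 >= 0, pending_ceiling_um2 > noise_floor_um2,
              a > 0, a < 1, b > 1, convexity_min > 0, convexity_min <= 1,
              is.logical(edge_refine), otsu_channel %in% c("s", "v", "h"))
  })
  with(cfg$classification, stopifnot(ratio_threshold > 0))
  with(cfg$area, stopifnot(roundness_min > 0, roundness_min < 1,
                           is.logical(include_non_recall)))
  with(cfg$stats, stopifnot(alpha_normality > 0, alpha_normality < 1,
                            is.logical(holm)))
  structure(cfg, class = "rbc_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may define any subset of the `rbc_config()` sections; values
#' it omits keep their defaults, keys it invents are rejected.
#'
#' @param path path to a YAML file.
#' @return A validated `rbc_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("calibration", "segmentation", "classification", "area", "stats")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config section(s): ", paste(extra, collapse = ", "))
  do.call(rbc_config, raw[intersect(names(raw), known)])
}
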