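# Run configuration: one YAML document with a block per pipeline stage.
# Unknown keys are rejected so typos cannot silently fall back to defaults.

config_schema <- list(
  seed = NULL,
  channels = c("treg", "caf"),
  detection = c("diameter_um", "quality_min", "subpixel"),
  linking = c("link_max_um", "gap_max_um", "gap_max_frames"),
  segmentation = c("sigma_px", "epsilon", "min_object_px", "fill_holes", "mode"),
  contact = c("contact_radius_um", "min_episode_frames", "bridge_max_frames"),
  spatial = c("tile_px"),
  puncta = c("diameter_um", "rel_quality")
)

#' Default run configuration
#'
#' Returns the full parameter set of the pipeline with its published
#' defaults: spot detection (8 µm diameter, quality >= 1), trajectory
#' linking (36 µm link cap, 12 µm / 5-frame gap closing), local-contrast
#' segmentation (sigma = 4 px, epsilon = 0.08), and the 2-frame (10 min at
#' 5-min sampling) minimal contact episode.
#'
#' @return A named list with blocks `channels`, `detection`, `linking`,
#'   `segmentation`, `contact`, `spatial`, `puncta`, and a `seed`.
#' @examples
#' cfg <- default_config()
#' cfg$linking$link_max_um
#' @export
default_config <- function() {
  list(
    seed = 1L,
    channels = list(treg = "treg", caf = "caf"),
    detection = as.list(default_detection_params()),
    linking = as.list(default_linking_params()),
    segmentation = list(sigma_px = 4, epsilon = 0.08, min_object_px = 64,
                        fill_holes = TRUE, mode = "per_frame"),
    contact = list(contact_radius_um = 4, min_episode_frames = 2L,
                   bridge_max_frames = 0L),
    spatial = list(tile_px = NULL),
    puncta = list(diameter_um = 0.8, rel_quality = 0.25)
  )
}

#' Validate a run configuration
#'
#' Checks block and key names against the schema and the numeric
#' constraints each stage imposes. Unknown keys are an error (naming the
#' offending key), as are non-positive distances, scales or intervals.
#'
#' @param config A config list as returned by [default_config()] or
#'   [read_config()].
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) abort("config must be a list")
  unknown <- setdiff(names(config), names(config_schema))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key: %s", unknown[1]))
  }
  for (block in intersect(names(config), names(config_schema))) {
    allowed <- config_schema[[block]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[block]]), allowed)
    if (length(bad) > 0L) {
      abort(sprintf("unknown config key: %s.%s", block, bad[1]))
    }
  }
  d <- config$detection
  if (!is.null(d$diameter_um) && d$diameter_um <= 0) {
    abort("detection.diameter_um must be > 0")
  }
  l <- config$linking
  for (k in c("link_max_um", "gap_max_um")) {
    if (!is.null(l[[k]]) && l[[k]] <= 0) abort(sprintf("linking.%s must be > 0", k))
  }
  if (!is.null(l$gap_max_frames) &&
      (l$gap_max_frames < 0 || l$gap_max_frames != round(l$gap_max_frames))) {
    abort("linking.gap_max_frames must be an integer >= 0")
  }
  s <- config$segmentation
  if (!is.null(s$sigma_px) && s$sigma_px <= 0) abort("segmentation.sigma_px must be > 0")
  if (!is.null(s$epsilon) && s$epsilon <= 0) abort("segmentation.epsilon must be > 0")
  cn <- config$contact
  if (!is.null(cn$min_episode_frames) && cn$min_episode_frames < 1) {
    abort("contact.min_episode_frames must be >= 1")
  }
  if (!is.null(cn$contact_radius_um) && cn$contact_radius_um < 0) {
    abort("contact.contact_radius_um must be >= 0")
  }
  invisible(config)
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default, so a config file only needs the parameters it changes.
#'
#' @param path YAML file path.
#' @return A validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- default_config()
  for (block in names(user)) {
    if (!block %in% names(cfg)) abort(sprintf("unknown config key: %s", block))
    if (is.list(user[[block]]) && is.list(cfg[[block]])) {
      for (k in names(user[[block]])) cfg[[block]][[k]] <- user[[block]][[k]]
    } else {
      cfg[[block]] <- user[[block]]
    }
  }
  validate_config(cfg)
  cfg
}

#' Write a run configuration to YAML
#'
#' @param config A config list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}
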