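#' Read generator configurations from YAML or JSON
#'
#' A panel config is a list of records mirroring [texture_class_spec()]
#' fields; a screen config has an `effects` list mirroring
#' [screen_effect_spec()] fields plus a `controls` map (assay -> condition).
#' Format is chosen by file extension (`.yaml`/`.yml` need the `yaml`
#' package; anything else is parsed as JSON).
#'
#' @param path config file path.
#' @return `read_texture_specs()`: list of `texture_class_spec`;
#'   `read_screen_effects()`: list with `effects` and `controls`.
#' @export
read_texture_specs <- function(path) {
  cfg <- read_config_file(path)
  lapply(cfg, function(rec) do.call(texture_class_spec, rec))
}

#' @rdname read_texture_specs
#' @export
read_screen_effects <- function(path) {
  cfg <- read_config_file(path)
  if (is.null(cfg$effects) || is.null(cfg$controls))
    stop("screen config needs 'effects' and 'controls'")
  list(effects = lapply(cfg$effects,
                        function(rec) do.call(screen_effect_spec, rec)),
       controls = cfg$controls)
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("package 'yaml' required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
}

#' Write a panel or screen configuration
#'
#' Serializes spec lists back to YAML/JSON in the same schema
#' [read_texture_specs()] reads.
#'
#' @param specs list of `texture_class_spec`, or the list returned by the
#'   `*_screen_effects()` tables.
#' @param path output path (extension selects the format).
#' @export
write_config <- function(specs, path) {
  strip <- function(x) lapply(unclass(x), identity)
  obj <- if (!is.null(specs$effects)) {
    list(effects = lapply(specs$effects, strip), controls = specs$controls)
  } else {
    lapply(specs, strip)
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("package 'yaml' required for YAML configs")
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
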