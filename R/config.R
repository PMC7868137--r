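#' Load a run configuration
#'
#' Starts from the package defaults (the published hyperparameters plus the
#' canonical architecture), overlays an optional YAML/JSON file, then named
#' overrides. Overrides use dotted paths, e.g.
#' `list("training.learning_rate" = 0.001)`. Validation errors name the
#' offending field.
#'
#' @param path Optional YAML (or JSON) configuration file.
#' @param overrides Named list of dotted-path overrides.
#' @return A `run_config` list with `generator`, `discriminator` (input size
#'   only; geometry is canonical), `training`, and `phantom` sections.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  gen_defaults <- unclass(generator_config())
  gen_defaults$depth <- NULL  # recomputed from input_size unless set by hand
  cfg <- list(
    generator = gen_defaults,
    training = unclass(training_config()),
    phantom = unclass(phantom_spec()))
  if (!is.null(path)) {
    if (!file.exists(path))
      ct_error("config_error", sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      if (!is.list(user))
        ct_error("config_error", "config file must contain a mapping")
      cfg <- utils::modifyList(cfg, user)
    }
  }
  for (nm in names(overrides)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) parts <- c("training", parts)
    if (!parts[1] %in% names(cfg) )
      ct_error("config_error", sprintf("unknown config section '%s'", parts[1]))
    cfg[[parts[1]]][[parts[2]]] <- overrides[[nm]]
  }
  # re-validate through the typed constructors so errors name the field
  cfg$generator <- tryCatch(
    do.call(generator_config, cfg$generator[names(cfg$generator) %in%
      names(formals(generator_config))]),
    ctinpaint_invalid_config = function(e)
      ct_error("config_error", paste("generator:", conditionMessage(e))))
  cfg$training <- do.call(training_config, cfg$training[names(cfg$training)
    %in% names(formals(training_config))])
  cfg$phantom <- tryCatch(
    do.call(phantom_spec, cfg$phantom[names(cfg$phantom) %in%
      names(formals(phantom_spec))]),
    ctinpaint_invalid_config = function(e)
      ct_error("config_error", paste("phantom:", conditionMessage(e))))
  structure(cfg, class = "run_config")
}

#' Write a resolved configuration snapshot
#'
#' Serializes the fully resolved configuration next to a run's outputs so the
#' run can be reproduced byte-for-byte given the same inputs.
#'
#' @param config A `run_config` (or any nested list of scalars).
#' @param path Destination YAML file.
#' @return `path`, invisibly.
#' @export
save_run_config <- function(config, path) {
  strip <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  yaml::write_yaml(strip(config), path)
  invisible(path)
}
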