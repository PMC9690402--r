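#' Default analysis configuration
#'
#' Loads the shipped configuration: HU windows, detection thresholds,
#' grading tables, reference ranges and recommendation template strings.
#' All values are plain config data so a site can adapt grading and
#' guideline wording without touching code.
#'
#' @param overrides optional named list (or path to a YAML file) merged
#'   recursively over the defaults
#' @return nested named list of configuration values
#' @examples
#' cfg <- defaultConfig()
#' cfg$cardio$threshold_hu
#' @export
defaultConfig <- function(overrides = NULL) {
  path <- system.file("extdata", "config.yaml", package = "ctscreen")
  cfg <- yaml::read_yaml(path)
  if (is.character(overrides) && length(overrides) == 1L)
    overrides <- yaml::read_yaml(overrides)
  if (!is.null(overrides))
    cfg <- utils::modifyList(cfg, overrides)
  cfg
}
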