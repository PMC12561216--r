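#' Read valve designs from a JSON or YAML document
#'
#' The document holds one design object or an array of them, with keys
#' matching the [valve_design()] arguments (`label`, `radius`,
#' `opening_degree`, `free_edge_shape`, optional `height`,
#' `commissure_height`, `commissure_span`, `n_leaflets`). The seven
#' packaged reference designs ship as
#' `system.file("extdata", "valve_designs.json", package = "leafletlab")`.
#'
#' @param path Path to a `.json` or `.yaml`/`.yml` file.
#' @return Named list of [valve_design()] objects.
#' @export
#' @examples
#' f <- system.file("extdata", "valve_designs.json", package = "leafletlab")
#' names(read_valve_designs(f))
read_valve_designs <- function(path) {
  doc <- read_config_doc(path)
  if (!is.null(doc$label)) doc <- list(doc)   # single design document
  out <- lapply(doc, function(d) do.call(valve_design, d))
  names(out) <- vapply(out, `[[`, character(1), "label")
  out
}

#' Read a pulse-duplicator preset
#'
#' A preset bundles [duplicator_settings()] arguments under `settings`
#' and an array of [group_spec()] argument sets under `groups`. The
#' packaged ISO-pulmonary preset (normotensive right-heart targets plus
#' the seven reference group summaries) ships as
#' `system.file("extdata", "preset_iso_pulmonary.json",
#' package = "leafletlab")`.
#'
#' @param path Path to a `.json` or `.yaml`/`.yml` file.
#' @return List with `settings` (a `duplicator_settings`) and `groups`
#'   (named list of `group_spec`).
#' @export
read_duplicator_preset <- function(path) {
  doc <- read_config_doc(path)
  settings <- do.call(duplicator_settings, as.list(doc$settings))
  groups <- lapply(doc$groups, function(g) do.call(group_spec, as.list(g)))
  names(groups) <- vapply(groups, `[[`, character(1), "label")
  list(settings = settings, groups = groups)
}

#' Read a crimp load case from a JSON or YAML document
#'
#' Keys match the [crimp_loadcase()] arguments (`oversizing`,
#' `pressure_mmHg`, `scale_factor`, `seed`, solver controls).
#'
#' @param path Path to a `.json` or `.yaml`/`.yml` file.
#' @return A [crimp_loadcase()].
#' @export
read_loadcase <- function(path) {
  do.call(crimp_loadcase, read_config_doc(path))
}

read_config_doc <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configuration requires the `yaml` package")
    yaml::read_yaml(path)
  } else {
    stop("unsupported configuration format: .", ext)
  }
}
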