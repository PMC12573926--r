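#' Beamline presets
#'
#' Loads the shipped configuration for the three experiments the package
#' models (one microsecond-exposure synchrotron run and two femtosecond
#' XFEL runs). Diffraction-weighted doses in the presets are authoritative
#' external inputs - they require full beam/crystal profile integration
#' and are never recomputed here.
#'
#' @param name preset name, or `NULL` for the full named list
#' @return list of preset parameters
#' @export
beamline_presets <- function(name = NULL) {
  path <- system.file("extdata", "beamline_presets.json", package = "sosdamage")
  presets <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(name)) return(presets)
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}
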