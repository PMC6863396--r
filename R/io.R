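#' Write / read a wiring diagram as JSON
#'
#' Schema: `species` (array of species records), `edges` (array of edge
#' records), `input_species`.
#'
#' @param diagram an `rm_wiring`.
#' @param path file path.
#' @return `write_wiring_json` returns `path` invisibly; `read_wiring_json`
#'   an `rm_wiring`.
#' @export
write_wiring_json <- function(diagram, path) {
  jsonlite::write_json(
    list(species = diagram$species, edges = diagram$edges,
         input_species = diagram$input_species),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_wiring_json
#' @export
read_wiring_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  wiring_diagram(as.data.frame(doc$species, stringsAsFactors = FALSE),
                 as.data.frame(doc$edges, stringsAsFactors = FALSE))
}

#' Write / read a parameter profile as JSON
#'
#' Records name, value, class, reverse pairing for every rate parameter.
#'
#' @param profile parameter `data.frame` (see [default_parameters()]).
#' @param path file path.
#' @return `write_profile_json` returns `path` invisibly;
#'   `read_profile_json` the profile `data.frame`.
#' @export
write_profile_json <- function(profile, path) {
  jsonlite::write_json(profile, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @rdname write_profile_json
#' @export
read_profile_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- as.data.frame(p, stringsAsFactors = FALSE)
  if (!"paired_forward" %in% names(p)) p$paired_forward <- NA_character_
  p$paired_forward[p$paired_forward %in% c("", "NA")] <- NA_character_
  p[, c("name", "value", "class", "is_reverse", "paired_forward")]
}
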