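# Field registry: the complete, deterministic list of annotatable attributes.
# One row per field; `kind` decides validation and serialization, `ref` is the
# vocabulary subtree backing term-kinded fields, `open` marks term-suggested
# fields that accept new candidate vocabulary.

reg_row <- function(path, kind, mult, ref = NA_character_, open = FALSE) {
  data.frame(path = path, kind = kind, multiplicity = mult,
             closed_list_ref = ref, open = open, stringsAsFactors = FALSE)
}

build_registry <- function() {
  r <- list(
    reg_row("general/title", "free_text", "one"),
    reg_row("general/abstract", "free_text", "optional"),
    reg_row("general/party", "free_text", "many"),
    reg_row("general/data_center", "free_text", "optional"),
    reg_row("general/access", "free_text", "optional"),

    reg_row("time/start", "timestamp", "optional"),
    reg_row("time/end", "timestamp", "optional"),
    reg_row("time/timezone", "closed_term", "optional", "time/timezone"),
    reg_row("time/geological/eon", "closed_term", "optional", "time/geological/eon"),
    reg_row("time/geological/era", "closed_term", "optional", "time/geological/era"),
    reg_row("time/geological/period", "closed_term", "optional", "time/geological/period"),
    reg_row("time/geological/epoch", "closed_term", "optional", "time/geological/epoch"),
    reg_row("time/geological/age", "closed_term", "optional", "time/geological/age"),
    reg_row("time/resolution", "closed_term", "optional", "time/unit"),
    reg_row("time/extent", "closed_term", "optional", "time/unit"),

    reg_row("space/location/name", "free_text", "many"),
    reg_row("space/location/type", "closed_term", "many", "space/location_type"),
    reg_row("space/location/country", "closed_term", "many", "space/country"),
    reg_row("space/location/continent", "closed_term", "many", "space/continent"),
    reg_row("space/bounding_box", "geospatial", "optional"),
    reg_row("space/point", "geospatial", "many"),
    reg_row("space/resolution", "closed_term", "optional", "space/scale"),
    reg_row("space/extent", "closed_term", "optional", "space/scale"),

    reg_row("sphere/layer", "closed_term", "many", "sphere/layer"),
    reg_row("sphere/organization", "closed_term", "optional", "sphere/organization"),

    reg_row("biome/latitudinal_zone", "closed_term", "optional", "biome/latitudinal"),
    reg_row("biome/altitudinal_zone", "closed_term", "optional", "biome/altitudinal"),
    reg_row("biome/moisture_regime", "closed_term", "optional", "biome/moisture"),
    reg_row("biome/continentality", "closed_term", "optional", "biome/continentality"),
    reg_row("biome/physiognomy", "closed_term", "optional", "biome/physiognomy"),
    reg_row("biome/special_biome", "closed_term", "optional", "biome/special"),
    reg_row("biome/condition", "closed_term", "optional", "biome/condition"),
    reg_row("biome/usage", "closed_term", "many", "biome/usage"),

    reg_row("organism/name/scientific", "free_text", "many"),
    reg_row("organism/name/code", "closed_term", "many", "organism/code"),
    reg_row("organism/taxonomy/domain", "free_text", "optional"),
    reg_row("organism/taxonomy/kingdom", "free_text", "optional"),
    reg_row("organism/taxonomy/division_or_phylum", "free_text", "optional"),
    reg_row("organism/taxonomy/class", "free_text", "optional"),
    reg_row("organism/taxonomy/order", "free_text", "optional"),
    reg_row("organism/taxonomy/family", "free_text", "optional"),
    reg_row("organism/taxonomy/genus", "free_text", "optional"),

    reg_row("process/process/name", "open_term", "many", "process/name", open = TRUE),
    reg_row("process/process/involved", "closed_term", "many", "process/involved"),
    reg_row("process/process/characterization", "closed_term", "many", "process/characterization"),
    reg_row("process/interaction/name", "open_term", "many", "process/interaction/name", open = TRUE),
    reg_row("process/interaction/partner_a", "closed_term", "many", "organism/kingdom"),
    reg_row("process/interaction/partner_b", "closed_term", "many", "organism/kingdom"),
    reg_row("process/interaction/direction", "closed_term", "many", "process/interaction/direction"),
    reg_row("process/interaction/quality", "closed_term", "many", "process/interaction/quality"),

    reg_row("chemical/element", "closed_term", "many", "chemical/element"),
    reg_row("chemical/compound", "open_term", "many", "chemical/compound", open = TRUE),
    reg_row("chemical/function", "closed_term", "many", "chemical/function"),

    reg_row("method/approach", "closed_term", "optional", "method/approach"),
    reg_row("method/context", "closed_term", "optional", "method/context"),
    reg_row("method/manipulated_variable", "open_term", "many", "method/variable", open = TRUE)
  )
  out <- do.call(rbind, r)
  stopifnot(!anyDuplicated(out$path))
  out
}

#' The annotation field registry
#'
#' The deterministic, complete registry of annotatable attributes: the
#' mandatory general-metadata block plus exactly eight orthogonal facets
#' (time, space, sphere, biome, organism, process, chemical, method). Each
#' entry states the field's value kind (\code{closed_term},
#' \code{open_term}, \code{free_text}, \code{timestamp},
#' \code{geospatial}), its multiplicity and, for term-kinded fields, the
#' vocabulary subtree its values come from.
#'
#' @return a data.frame with columns \code{path}, \code{kind},
#'   \code{multiplicity}, \code{closed_list_ref}, \code{open}.
#' @export
#' @examples
#' reg <- field_registry()
#' setdiff(unique(sub("/.*", "", reg$path)), "general")  # the eight facets
field_registry <- function() {
  if (is.null(.ecofacet$registry)) .ecofacet$registry <- build_registry()
  .ecofacet$registry
}

#' Top-level facet names, in registry order
#' @return character vector of the eight facet container names.
#' @export
facet_names <- function() {
  unique(setdiff(sub("/.*", "", field_registry()$path), "general"))
}

# is a vocabulary path open (term-suggested) rather than content-restricted?
vocab_path_open <- function(path) {
  reg <- field_registry()
  hit <- reg$closed_list_ref %in% path
  any(hit & reg$open)
}

# vocabulary subtrees referenced by closed_term fields
closed_vocab_paths <- function() {
  reg <- field_registry()
  unique(reg$closed_list_ref[reg$kind == "closed_term"])
}

# registry entry for one field path (error lists valid paths)
registry_field <- function(path) {
  reg <- field_registry()
  i <- match(path, reg$path)
  if (is.na(i)) stop("unknown field path '", path, "'; valid paths: ",
                     paste(reg$path, collapse = ", "))
  reg[i, ]
}
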