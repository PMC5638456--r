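# Annotation records: one mandatory general-metadata block plus eight
# optional facet blocks. Blocks are plain nested lists built by the
# constructors below; term references are either bare strings (id, label or
# synonym) or resolved lists with id/label/uri as produced by resolve_terms().

#' Build an annotation record
#'
#' @param record_id unique identifier of the annotated search object.
#' @param general a [general_info()] block (mandatory).
#' @param time,space,sphere,biome,organism,process,chemical,method optional
#'   facet blocks built with the corresponding constructors.
#' @return an object of class \code{eco_record}.
#' @export
annotation_record <- function(record_id, general, time = NULL, space = NULL,
                              sphere = NULL, biome = NULL, organism = NULL,
                              process = NULL, chemical = NULL, method = NULL) {
  structure(list(record_id = record_id, general = general, time = time,
                 space = space, sphere = sphere, biome = biome,
                 organism = organism, process = process, chemical = chemical,
                 method = method), class = "eco_record")
}

#' General metadata block
#' @param title dataset title (non-empty).
#' @param abstract free-text abstract.
#' @param parties list of [party()] entries; at least one for a valid record.
#' @param data_center hosting data center.
#' @param access list with \code{type} (\code{"url"}, \code{"file_path"} or
#'   \code{"database_id"}) and \code{value}.
#' @export
general_info <- function(title, abstract = "", parties = list(),
                         data_center = NULL, access = NULL) {
  list(title = title, abstract = abstract, parties = parties,
       data_center = data_center, access = access)
}

#' @rdname general_info
#' @param name,role,address,email responsible-party fields.
#' @export
party <- function(name, role = "contact", address = NULL, email = NULL) {
  list(name = name, role = role, address = address, email = email)
}

#' Time facet block
#' @param start,end ISO 8601 timestamps, reduced precision allowed
#'   (\code{"2001"}, \code{"2001-03"}, \code{"2001-03-04"},
#'   \code{"2001-03-04T12:30:00"}); comparisons use interval semantics.
#' @param timezone IANA time zone name (closed vocabulary).
#' @param geological named list of term refs at ranks \code{eon}, \code{era},
#'   \code{period}, \code{epoch}, \code{age} (each optional).
#' @param resolution,extent time-unit class terms.
#' @export
time_facet <- function(start = NULL, end = NULL, timezone = NULL,
                       geological = list(), resolution = NULL, extent = NULL) {
  list(start = start, end = end, timezone = timezone, geological = geological,
       resolution = resolution, extent = extent)
}

#' Space facet block
#' @param locations list of [location()] entries.
#' @param bounding_box named list/vector with \code{west}, \code{south},
#'   \code{east}, \code{north} in WGS84 decimal degrees; antimeridian boxes
#'   are expressed as \code{west > east}.
#' @param points list of points, each either \code{list(latitude=, longitude=)}
#'   (WGS84 decimal degrees) or \code{list(utm_zone=, easting=, northing=,
#'   datum="WGS84")}.
#' @param resolution,extent spatial scale class terms (Point...Global).
#' @export
space_facet <- function(locations = list(), bounding_box = NULL,
                        points = list(), resolution = NULL, extent = NULL) {
  if (!is.null(bounding_box)) bounding_box <- as.list(bounding_box)
  list(locations = locations, bounding_box = bounding_box, points = points,
       resolution = resolution, extent = extent)
}

#' @rdname space_facet
#' @param name free-text location name.
#' @param type location type term (City, Stream, Lake, ...).
#' @param country,continent closed vocabulary terms.
#' @export
location <- function(name, type = NULL, country = NULL, continent = NULL) {
  list(name = name, type = type, country = country, continent = continent)
}

#' Sphere facet block
#' @param layers term refs under the sphere layer subtrees (e.g. Troposphere,
#'   Abyssopelagic, A Horizon).
#' @param organization level on the ordered Atom...Biosphere scale.
#' @export
sphere_facet <- function(layers = list(), organization = NULL) {
  list(layers = as.list(layers), organization = organization)
}

#' Biome facet block
#' @param latitudinal_zone,altitudinal_zone,moisture_regime,continentality,physiognomy,special_biome,condition
#'   optional biome classification terms.
#' @param usage dominant usage terms (many allowed).
#' @export
biome_facet <- function(latitudinal_zone = NULL, altitudinal_zone = NULL,
                        moisture_regime = NULL, continentality = NULL,
                        physiognomy = NULL, special_biome = NULL,
                        condition = NULL, usage = list()) {
  list(latitudinal_zone = latitudinal_zone, altitudinal_zone = altitudinal_zone,
       moisture_regime = moisture_regime, continentality = continentality,
       physiognomy = physiognomy, special_biome = special_biome,
       condition = condition, usage = as.list(usage))
}

#' Organism facet block
#' @param names list of [organism_name()] entries.
#' @param taxonomy named list over the ranks \code{domain}, \code{kingdom},
#'   \code{division_or_phylum}, \code{class}, \code{order}, \code{family},
#'   \code{genus}.
#' @export
organism_facet <- function(names = list(), taxonomy = list()) {
  list(names = names, taxonomy = taxonomy)
}

#' @rdname organism_facet
#' @param scientific scientific name string.
#' @param code nomenclature code: botanical, zoological, fungal or viral.
#' @export
organism_name <- function(scientific, code = "botanical") {
  list(scientific = scientific, code = code)
}

#' Process facet block
#' @param processes list of [process_entry()] entries.
#' @param interactions list of [interaction()] entries.
#' @export
process_facet <- function(processes = list(), interactions = list()) {
  list(processes = processes, interactions = interactions)
}

#' @rdname process_facet
#' @param name open process-name term.
#' @param involved subset of Organisms, Chemical, Matter, Energy.
#' @param characterization Uptake, Release or Exchange.
#' @export
process_entry <- function(name, involved = list(), characterization = NULL) {
  list(name = name, involved = as.list(involved),
       characterization = characterization)
}

#' @rdname process_facet
#' @param partner_a,partner_b kingdom terms; the direction reads a to b.
#' @param direction Mutual, Affects or Is Affected By.
#' @param quality interaction quality term (e.g. Amensalism, Antagonism).
#' @export
interaction <- function(name, partner_a, partner_b, direction, quality = NULL) {
  list(name = name, partner_a = partner_a, partner_b = partner_b,
       direction = direction, quality = quality)
}

#' Chemical facet block
#' @param elements periodic-table element symbols (closed list).
#' @param compounds open compound terms (e.g. Lipids, Carbon Dioxide).
#' @param functions biological-function terms (e.g. Antibody, Attractant).
#' @export
chemical_facet <- function(elements = list(), compounds = list(),
                           functions = list()) {
  list(elements = as.list(elements), compounds = as.list(compounds),
       functions = as.list(functions))
}

#' Method facet block
#' @param approach Virtual, Manipulative or Observational.
#' @param context Microcosm, Mesocosm or Macrocosm.
#' @param manipulated_variables open terms for the manipulated gradients.
#' @export
method_facet <- function(approach = NULL, context = NULL,
                         manipulated_variables = list()) {
  list(approach = approach, context = context,
       manipulated_variables = as.list(manipulated_variables))
}

#' @export
print.eco_record <- function(x, ...) {
  present <- names(Filter(Negate(is.null), x[facet_names()]))
  cat("<eco_record> ", x$record_id, ": ", x$general$title, "\n  facets: ",
      if (length(present)) paste(present, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}
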