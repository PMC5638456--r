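# Crosswalk importers: build partial annotation records from EML, ABCD and
# Darwin Core metadata. The topic-level concept maps are shipped as data
# (inst/extdata/crosswalk/*.csv) and drive the mapping report; fields the
# source standards do not cover (interaction detail, scale classes, spheres)
# are never invented.

crosswalk_table <- function(standard) {
  f <- system.file("extdata", "crosswalk",
                   paste0(tolower(standard), ".csv"), package = "ecofacet")
  utils::read.csv(f, stringsAsFactors = FALSE)
}

# local-name lookup helpers: version-tolerant reading of source documents
ln1 <- function(node, name) {
  n <- xml2::xml_find_first(node, paste0(".//*[local-name()='", name, "']"))
  if (inherits(n, "xml_missing")) NULL else n
}
ln1_txt <- function(node, name) {
  n <- ln1(node, name)
  if (is.null(n)) NULL else trimws(xml2::xml_text(n))
}
lnN <- function(node, name)
  xml2::xml_find_all(node, paste0(".//*[local-name()='", name, "']"))

as_source_doc <- function(document) {
  if (inherits(document, "xml_document"))
    xml2::read_xml(as.character(document)) else xml2::read_xml(document)
}

# assemble the mapping report from the shipped concept table and the set of
# target annotation fields actually populated plus the source elements actually present
build_report <- function(standard, populated, present) {
  tab <- crosswalk_table(standard)
  status <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (tab$source_concept[i] == "absent") status[i] <- "missing_in_source"
    else if (tab$mode[i] == "note")
      status[i] <- if (isTRUE(present[[tab$target_field[i]]]))
        "present_unparsed" else "missing_in_source"
    else status[i] <- if (tab$target_field[i] %in% populated)
      "mapped" else "missing_in_source"
  }
  structure(data.frame(source_standard = standard,
                       target_field = tab$target_field,
                       source_concept = tab$source_concept,
                       status = status, stringsAsFactors = FALSE),
            class = c("eco_mapping_report", "data.frame"))
}

#' @export
print.eco_mapping_report <- function(x, ...) {
  cat("<mapping report> ", x$source_standard[1], ": ",
      sum(x$status == "mapped"), " mapped, ",
      sum(x$status == "missing_in_source"), " missing in source, ",
      sum(x$status == "present_unparsed"), " present but unparsed\n", sep = "")
  print.data.frame(x[x$status != "missing_in_source", ], row.names = FALSE)
  invisible(x)
}

#' Import an EML document as a partial annotation record
#'
#' Maps the Ecological Metadata Language topics covered by the concept
#' table: title/abstract/parties, temporal coverage to time start/end,
#' geographic coverage to bounding box and location name, taxonomic
#' coverage to taxonomy ranks. EML versions 2.0-2.2 are accepted by
#' local-name matching.
#'
#' @param document EML document (path, string or \code{xml_document}).
#' @inheritParams validate_record
#' @return list with \code{record} (partial \code{eco_record}) and
#'   \code{report} (the mapping report).
#' @export
import_eml <- function(document, vocab = default_vocabulary()) {
  doc <- as_source_doc(document)
  populated <- character()
  pop <- function(f) populated <<- c(populated, f)
  rid <- xml2::xml_attr(doc, "packageId")
  if (is.na(rid)) rid <- "eml-import"
  title <- ln1_txt(doc, "title"); if (!is.null(title)) pop("general/title")
  abstract <- { a <- ln1(doc, "abstract"); if (is.null(a)) NULL else trimws(xml2::xml_text(a)) }
  if (!is.null(abstract)) pop("general/abstract")
  parties <- list()
  for (role in c("creator", "contact")) {
    for (n in lnN(doc, role)) {
      nm <- ln1_txt(n, "surName") %||% ln1_txt(n, "organizationName")
      if (!is.null(nm)) parties <- c(parties, list(party(nm, role)))
    }
  }
  if (length(parties)) pop("general/party")

  start <- NULL; end <- NULL
  rng <- ln1(doc, "rangeOfDates")
  if (!is.null(rng)) {
    bd <- ln1(rng, "beginDate"); ed <- ln1(rng, "endDate")
    if (!is.null(bd)) { start <- ln1_txt(bd, "calendarDate"); if (!is.null(start)) pop("time/start") }
    if (!is.null(ed)) { end <- ln1_txt(ed, "calendarDate"); if (!is.null(end)) pop("time/end") }
  }
  time <- if (!is.null(start) || !is.null(end)) time_facet(start = start, end = end)

  locations <- list(); bbox <- NULL
  gc <- ln1(doc, "geographicCoverage")
  if (!is.null(gc)) {
    desc <- ln1_txt(gc, "geographicDescription")
    if (!is.null(desc)) { locations <- list(location(desc)); pop("space/location/name") }
    bc <- ln1(gc, "boundingCoordinates")
    if (!is.null(bc)) {
      num <- function(nm) as.numeric(ln1_txt(bc, nm))
      # EML order W/E/N/S; stored axis-ordered as west, south, east, north
      bbox <- list(west = num("westBoundingCoordinate"),
                   south = num("southBoundingCoordinate"),
                   east = num("eastBoundingCoordinate"),
                   north = num("northBoundingCoordinate"))
      pop("space/bounding_box")
    }
  }
  space <- if (length(locations) || !is.null(bbox))
    space_facet(locations = locations, bounding_box = bbox)

  taxo <- list()
  rank_map <- c(domain = "domain", kingdom = "kingdom", division = "division_or_phylum",
                phylum = "division_or_phylum", class = "class", order = "order",
                family = "family", genus = "genus")
  for (cl in lnN(doc, "taxonomicClassification")) {
    rk <- tolower(xml2::xml_text(xml2::xml_find_first(cl, "./*[local-name()='taxonRankName']")))
    vl <- xml2::xml_text(xml2::xml_find_first(cl, "./*[local-name()='taxonRankValue']"))
    if (!is.na(rk) && rk %in% names(rank_map) && !is.na(vl))
      taxo[[rank_map[[rk]]]] <- vl
  }
  organism <- if (length(taxo)) { pop("organism/taxonomy"); organism_facet(taxonomy = taxo) }

  rec <- annotation_record(rid,
                           general_info(title %||% "", abstract %||% "", parties),
                           time = time, space = space, organism = organism)
  present <- list("method/manipulated_variable" = !is.null(ln1(doc, "methodStep")))
  list(record = rec, report = build_report("EML", populated, present))
}

#' Import an ABCD 2.06 document as a partial annotation record
#'
#' Dataset metadata maps to the general block; per-unit gathering events
#' map to time, locality and coordinate points; unit-level identifications
#' map to organism name entries (one per unit).
#' @inheritParams import_eml
#' @export
import_abcd <- function(document, vocab = default_vocabulary()) {
  doc <- as_source_doc(document)
  populated <- character()
  pop <- function(f) populated <<- c(populated, f)
  rid <- ln1_txt(doc, "DatasetGUID") %||% "abcd-import"
  title <- ln1_txt(doc, "Title"); if (!is.null(title)) pop("general/title")
  abstract <- ln1_txt(doc, "Details"); if (!is.null(abstract)) pop("general/abstract")
  parties <- list()
  for (o in lnN(doc, "Owner")) {
    nm <- ln1_txt(o, "FullName")
    if (!is.null(nm)) parties <- c(parties, list(party(nm, "owner")))
  }
  if (length(parties)) pop("general/party")

  start <- NULL; end <- NULL; locations <- list(); points <- list(); names_ <- list()
  seen_loc <- character()
  for (u in lnN(doc, "Unit")) {
    if (is.null(start)) { start <- ln1_txt(u, "ISODateTimeBegin"); if (!is.null(start)) pop("time/start") }
    if (is.null(end)) { end <- ln1_txt(u, "ISODateTimeEnd"); if (!is.null(end)) pop("time/end") }
    loc <- ln1_txt(u, "LocalityText")
    if (!is.null(loc) && !loc %in% seen_loc) {
      seen_loc <- c(seen_loc, loc)
      ctry <- { cn <- ln1(u, "Country"); if (is.null(cn)) NULL else ln1_txt(cn, "Name") }
      locations <- c(locations, list(location(loc, country = ctry)))
      pop("space/location/name")
      if (!is.null(ctry)) pop("space/location/country")
    }
    cll <- ln1(u, "CoordinatesLatLong")
    if (!is.null(cll)) {
      points <- c(points, list(list(latitude = as.numeric(ln1_txt(cll, "LatitudeDecimal")),
                                    longitude = as.numeric(ln1_txt(cll, "LongitudeDecimal")))))
      pop("space/point")
    }
    sci <- ln1_txt(u, "FullScientificNameString")
    if (!is.null(sci)) {
      names_ <- c(names_, list(organism_name(sci, code = NULL)))
      pop("organism/name/scientific")
    }
  }
  time <- if (!is.null(start) || !is.null(end)) time_facet(start = start, end = end)
  space <- if (length(locations) || length(points))
    space_facet(locations = locations, points = points)
  organism <- if (length(names_)) organism_facet(names = names_)
  rec <- annotation_record(rid,
                           general_info(title %||% "", abstract %||% "", parties),
                           time = time, space = space, organism = organism)
  present <- list("time/geological" = !is.null(ln1(doc, "Stratigraphy")),
                  "sphere/layer" = !is.null(ln1(doc, "Biotope")),
                  "biome/physiognomy" = !is.null(ln1(doc, "Biotope")),
                  "organism/taxonomy" = !is.null(ln1(doc, "HigherTaxa")))
  list(record = rec, report = build_report("ABCD", populated, present))
}

#' Import Darwin Core term/value records as a partial annotation record
#'
#' Accepts a flat named record (named character vector or single-row data
#' frame, e.g. one core row of a Darwin Core Archive). Taxonomy terms map
#' to the taxonomy slots, \code{decimalLatitude}/\code{decimalLongitude} to
#' a WGS84 point, and \code{country}/\code{continent} are matched into the
#' closed vocabularies by label: values that do not match (e.g. a
#' non-English country name) are left out and surface in the report.
#'
#' @param record named character vector (or coercible) of DwC term/value pairs.
#' @inheritParams import_eml
#' @export
import_dwc <- function(record, vocab = default_vocabulary()) {
  if (is.data.frame(record)) record <- unlist(record[1, , drop = TRUE])
  record <- vapply(as.list(record), as.character, "")
  populated <- character()
  pop <- function(f) populated <<- c(populated, f)
  g <- function(term) if (term %in% names(record) && nzchar(record[[term]]))
    record[[term]] else NULL

  rid <- g("datasetID") %||% g("occurrenceID") %||% "dwc-import"
  title <- g("datasetName"); if (!is.null(title)) pop("general/title")
  parties <- list()
  if (!is.null(g("recordedBy"))) {
    parties <- list(party(g("recordedBy"), "recordedBy")); pop("general/party")
  }
  start <- NULL; end <- NULL
  if (!is.null(g("eventDate"))) {
    parts <- strsplit(g("eventDate"), "/", fixed = TRUE)[[1]]
    start <- parts[1]; pop("time/start")
    if (length(parts) > 1) { end <- parts[2]; pop("time/end") }
  }
  time <- if (!is.null(start)) time_facet(start = start, end = end)

  ctry <- g("country"); cont <- g("continent")
  ctry_ok <- !is.null(ctry) && !is.null(resolve_term(vocab, ctry, "space/country"))
  cont_ok <- !is.null(cont) && !is.null(resolve_term(vocab, cont, "space/continent"))
  if (ctry_ok) pop("space/location/country")
  if (cont_ok) pop("space/location/continent")
  locations <- if (!is.null(g("locality"))) {
    pop("space/location/name")
    list(location(g("locality"), country = if (ctry_ok) ctry,
                  continent = if (cont_ok) cont))
  } else list()
  points <- if (!is.null(g("decimalLatitude")) && !is.null(g("decimalLongitude"))) {
    pop("space/point")
    list(list(latitude = as.numeric(g("decimalLatitude")),
              longitude = as.numeric(g("decimalLongitude"))))
  } else list()
  space <- if (length(locations) || length(points))
    space_facet(locations = locations, points = points)

  taxo <- list()
  dwc_ranks <- c(kingdom = "kingdom", phylum = "division_or_phylum",
                 class = "class", order = "order", family = "family",
                 genus = "genus")
  for (term in names(dwc_ranks))
    if (!is.null(g(term))) taxo[[dwc_ranks[[term]]]] <- g(term)
  if (length(taxo)) pop("organism/taxonomy")
  names_ <- if (!is.null(g("scientificName"))) {
    pop("organism/name/scientific")
    list(organism_name(g("scientificName"), code = NULL))
  } else list()
  organism <- if (length(taxo) || length(names_))
    organism_facet(names = names_, taxonomy = taxo)

  rec <- annotation_record(rid, general_info(title %||% "", "", parties),
                           time = time, space = space, organism = organism)
  present <- list("general/data_center" = !is.null(g("institutionCode")),
                  "time/geological" = !is.null(g("earliestEpochOrLowestSeries")),
                  "biome/physiognomy" = !is.null(g("habitat")))
  rep <- build_report("DwC", populated, present)
  # unmatched closed-vocabulary labels downgrade to report entries
  if (!is.null(ctry) && !ctry_ok)
    rep$status[rep$target_field == "space/location/country"] <- "present_unparsed"
  if (!is.null(cont) && !cont_ok)
    rep$status[rep$target_field == "space/location/continent"] <- "present_unparsed"
  list(record = rec, report = rep)
}
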