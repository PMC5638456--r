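# Synthetic corpora and source-standard documents. Everything is generated
# in code under a fixed seed: structural validity is the goal, statistical
# realism of real metadata is not claimed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

WORDS_TOPIC <- c("soil", "forest", "grassland", "stream", "canopy", "litter",
                 "nutrient", "drought", "warming", "biodiversity", "root",
                 "microbial", "pollinator", "carbon", "nitrogen", "phosphorus")
WORDS_VERB <- c("dynamics", "responses", "fluxes", "turnover", "assembly",
                "stability", "limitation", "acclimation", "recovery")
SPECIES_POOL <- c("Fagus sylvatica", "Quercus robur", "Picea abies",
                  "Arrhenatherum elatius", "Lumbricus terrestris",
                  "Apis mellifera", "Amanita muscaria", "Daphnia magna")
PEOPLE_POOL <- c("A. Fischer", "B. Keller", "C. Okafor", "D. Svensson",
                 "E. Tanaka", "F. Moreau")

#' Corpus generator configuration
#'
#' @param n_records number of records to generate.
#' @param seed integer seed fixing the corpus exactly.
#' @param fill_prob named per-facet fill probabilities in [0, 1]; unnamed
#'   facets keep their defaults.
#' @param preset optional scenario preset: \code{"carbon-intro"} (the
#'   four-record keyword-ambiguity scenario: a CO2-enrichment experiment, a
#'   subsoil carbon survey, a tree-ring isotope study and observations near
#'   Carbon Village) or \code{"fungi-interaction"} (one fungus-parasitizes-
#'   plant record, one fungus-plant symbiosis record).
#' @return a \code{corpus_config} list.
#' @export
corpus_config <- function(n_records = 50, seed = 1L, fill_prob = NULL,
                          preset = NULL) {
  fp <- c(time = 0.85, space = 0.85, sphere = 0.6, biome = 0.6,
          organism = 0.7, process = 0.6, chemical = 0.5, method = 0.8)
  if (!is.null(fill_prob)) {
    bad <- setdiff(names(fill_prob), names(fp))
    if (length(bad)) stop("unknown facet in fill_prob: ", paste(bad, collapse = ", "))
    if (any(fill_prob < 0 | fill_prob > 1)) stop("fill probabilities must lie in [0, 1]")
    fp[names(fill_prob)] <- fill_prob
  }
  structure(list(n_records = n_records, seed = as.integer(seed),
                 fill_prob = fp, preset = preset), class = "corpus_config")
}

sample_label <- function(vocab, path) {
  ts <- terms_at(vocab, path)
  if (!length(ts)) stop("empty vocabulary subtree requested: ", path)
  ts[[sample.int(length(ts), 1)]]$label
}

# ordered pair (fine, coarse) of class labels from an ordered list
sample_scale_pair <- function(vocab, path) {
  ts <- terms_at(vocab, path)
  i <- sort(sample.int(length(ts), 2, replace = TRUE))
  c(ts[[i[1]]]$label, ts[[i[2]]]$label)
}

# a consistent geological chain: random leaf unit, ancestors fill the rest
sample_geological <- function(vocab) {
  leaves <- .ecofacet$geo_leaves
  if (is.null(leaves)) {
    geo <- Filter(function(t) startsWith(t$facet_path, "time/geological") &&
                    !is.na(t$num_hi), vocab$terms)
    has_kid <- unique(unlist(lapply(geo, `[[`, "parent_id")))
    leaves <- names(Filter(function(t) !t$id %in% has_kid, geo))
    .ecofacet$geo_leaves <- leaves
  }
  id <- leaves[sample.int(length(leaves), 1)]
  chain <- c(list(vocab$terms[[id]]), ancestors(vocab, id))
  out <- list()
  for (t in chain) out[[sub("time/geological/", "", t$facet_path)]] <- t$label
  out[intersect(c("eon", "era", "period", "epoch", "age"), names(out))]
}

random_record <- function(i, fp, vocab) {
  rid <- sprintf("rec%04d", i)
  title <- paste(sample(WORDS_TOPIC, 1), sample(WORDS_VERB, 1), "in",
                 sample(c("temperate", "boreal", "alpine", "riparian"), 1),
                 sample(c("forests", "grasslands", "streams", "soils"), 1))
  abstract <- paste("A study of", sample(WORDS_TOPIC, 1), "and",
                    sample(WORDS_TOPIC, 1), sample(WORDS_VERB, 1),
                    "over", sample(2:20, 1), "years.")
  dc <- sample(c("GFBio", "iDiv", NA), 1)
  general <- general_info(title, abstract,
                          parties = list(party(sample(PEOPLE_POOL, 1), "owner"),
                                         party(sample(PEOPLE_POOL, 1), "contact")),
                          data_center = if (!is.na(dc)) dc,
                          access = list(type = "url",
                                        value = paste0("http://data.example.org/", rid)))
  time <- if (runif(1) < fp[["time"]]) {
    y1 <- sample(1950:2015, 1); y2 <- y1 + sample(1:5, 1)  # end year after start
    prec <- sample(c("year", "month", "day"), 2, replace = TRUE)
    fmt <- function(y, p) switch(p, year = as.character(y),
                                 month = sprintf("%d-%02d", y, sample(1:12, 1)),
                                 day = sprintf("%d-%02d-%02d", y, sample(1:12, 1), sample(1:28, 1)))
    tu <- sample_scale_pair(vocab, "time/unit")
    time_facet(start = fmt(y1, prec[1]), end = fmt(y2, prec[2]),
               timezone = sample_label(vocab, "time/timezone"),
               geological = if (runif(1) < 0.5) sample_geological(vocab) else list(),
               resolution = tu[1], extent = tu[2])
  }
  space <- if (runif(1) < fp[["space"]]) {
    sc <- sample_scale_pair(vocab, "space/scale")
    lat <- round(runif(1, -60, 70), 3); lon <- round(runif(1, -170, 170), 3)
    space_facet(
      locations = list(location(paste(sample(LETTERS, 1), "site", i),
                                type = sample_label(vocab, "space/location_type"),
                                country = sample_label(vocab, "space/country"),
                                continent = sample_label(vocab, "space/continent"))),
      bounding_box = list(west = round(lon - runif(1, 0, 2), 3),
                          south = round(lat - 1, 3),
                          east = round(lon + runif(1, 0, 2), 3),
                          north = round(lat + 1, 3)),
      points = if (runif(1) < 0.7) list(list(latitude = lat, longitude = lon)) else
        list(list(utm_zone = paste0(sample(1:60, 1), "U"),
                  easting = round(runif(1, 2e5, 8e5)),
                  northing = round(runif(1, 1e6, 9e6)), datum = "WGS84")),
      resolution = sc[1], extent = sc[2])
  }
  sphere <- if (runif(1) < fp[["sphere"]]) {
    layer_paths <- c("sphere/layer/atmosphere", "sphere/layer/hydrosphere",
                     "sphere/layer/pedosphere", "sphere/layer/lithosphere")
    sphere_facet(layers = lapply(sample(layer_paths, sample(1:2, 1)), function(p)
      sample_label(vocab, p)),
      organization = sample_label(vocab, "sphere/organization"))
  }
  biome <- if (runif(1) < fp[["biome"]]) {
    pick <- function(p) if (runif(1) < 0.6) sample_label(vocab, p) else NULL
    biome_facet(latitudinal_zone = pick("biome/latitudinal"),
                altitudinal_zone = pick("biome/altitudinal"),
                moisture_regime = pick("biome/moisture"),
                continentality = pick("biome/continentality"),
                physiognomy = pick("biome/physiognomy"),
                special_biome = pick("biome/special"),
                condition = pick("biome/condition"),
                usage = as.list(unique(replicate(sample(0:2, 1),
                                                 sample_label(vocab, "biome/usage")))))
  }
  organism <- if (runif(1) < fp[["organism"]]) {
    organism_facet(
      names = lapply(sample(SPECIES_POOL, sample(1:2, 1)), function(s)
        organism_name(s, sample(c("botanical", "zoological", "fungal", "viral"), 1))),
      taxonomy = if (runif(1) < 0.6)
        list(kingdom = sample(c("Plantae", "Animalia", "Fungi"), 1),
             family = sample(c("Fagaceae", "Poaceae", "Apidae"), 1)) else list())
  }
  process <- if (runif(1) < fp[["process"]]) {
    procs <- lapply(seq_len(sample(1:2, 1)), function(k)
      process_entry(sample_label(vocab, "process/name"),
                    involved = as.list(sample(c("Organisms", "Chemical", "Matter", "Energy"),
                                              sample(1:2, 1))),
                    characterization = sample_label(vocab, "process/characterization")))
    ints <- if (runif(1) < 0.5) list(interaction(
      sample_label(vocab, "process/interaction/name"),
      partner_a = sample_label(vocab, "organism/kingdom"),
      partner_b = sample_label(vocab, "organism/kingdom"),
      direction = sample_label(vocab, "process/interaction/direction"),
      quality = sample_label(vocab, "process/interaction/quality"))) else list()
    process_facet(procs, ints)
  }
  chemical <- if (runif(1) < fp[["chemical"]]) {
    chemical_facet(
      elements = as.list(unique(replicate(sample(1:3, 1), sample_label(vocab, "chemical/element")))),
      compounds = as.list(unique(replicate(sample(0:2, 1), sample_label(vocab, "chemical/compound")))),
      functions = as.list(unique(replicate(sample(0:1, 1), sample_label(vocab, "chemical/function")))))
  }
  method <- if (runif(1) < fp[["method"]]) {
    method_facet(approach = sample_label(vocab, "method/approach"),
                 context = sample_label(vocab, "method/context"),
                 manipulated_variables = as.list(unique(replicate(sample(0:2, 1),
                                                                  sample_label(vocab, "method/variable")))))
  }
  annotation_record(rid, general, time = time, space = space, sphere = sphere,
                    biome = biome, organism = organism, process = process,
                    chemical = chemical, method = method)
}

preset_carbon_intro <- function() {
  list(
    annotation_record("carbon-co2",
      general_info("Elevated carbon dioxide enrichment in a temperate grassland",
                   "Global change experiment using elevated carbon dioxide concentrations as experimental treatment in grassland plots.",
                   list(party("A. Fischer", "owner"))),
      time = time_facet("1998", "2004", resolution = "Day", extent = "Year"),
      space = space_facet(list(location("Grassland FACE site", type = "Field site",
                                        country = "Germany", continent = "Europe")),
                          resolution = "Plot", extent = "Plot"),
      method = method_facet("Manipulative", "Macrocosm",
                            list("elevated carbon dioxide concentration"))),
    annotation_record("carbon-subsoil",
      general_info("Regional soil survey of subsoil carbon stocks",
                   "Soil survey reporting carbon concentrations in the subsoil across agricultural regions.",
                   list(party("B. Keller", "owner"))),
      space = space_facet(list(location("Survey region", type = "Field site",
                                        country = "Germany", continent = "Europe")),
                          resolution = "Region", extent = "Region"),
      sphere = sphere_facet(list("B Horizon")),
      chemical = chemical_facet(elements = list("C")),
      method = method_facet("Observational", "Macrocosm")),
    annotation_record("carbon-treering",
      general_info("Tree-ring carbon isotope discrimination and paleoclimate",
                   "Paleoclimate study employing carbon isotope discrimination in tree rings.",
                   list(party("C. Okafor", "owner"))),
      time = time_facet(geological = list(period = "Quaternary", epoch = "Holocene"),
                        resolution = "Year", extent = "Decade"),
      organism = organism_facet(list(organism_name("Picea abies", "botanical"))),
      chemical = chemical_facet(elements = list("C")),
      method = method_facet("Observational", "Macrocosm")),
    annotation_record("carbon-village",
      general_info("Field observations near Carbon Village, Alberta",
                   "Field observations of grassland birds near Carbon Village in Alberta, Canada.",
                   list(party("D. Svensson", "owner"))),
      space = space_facet(list(location("Carbon Village", type = "Village",
                                        country = "Canada",
                                        continent = "North America")),
                          points = list(list(latitude = 51.493, longitude = -113.141)),
                          resolution = "Point", extent = "Region"),
      organism = organism_facet(list(organism_name("Sturnella neglecta", "zoological"))),
      method = method_facet("Observational", "Macrocosm")))
}

preset_fungi_interaction <- function() {
  list(
    annotation_record("fungi-parasitism",
      general_info("Fungal parasites of beech seedlings",
                   "Antagonistic fungus plant interaction study in which fungi affect their plant hosts.",
                   list(party("E. Tanaka", "owner"))),
      organism = organism_facet(list(organism_name("Fagus sylvatica", "botanical"),
                                     organism_name("Amanita muscaria", "fungal"))),
      process = process_facet(interactions = list(
        interaction("Parasitism", partner_a = "Fungi", partner_b = "Plantae",
                    direction = "Affects", quality = "Antagonism")))),
    annotation_record("fungi-symbiosis",
      general_info("Mycorrhizal symbiosis between fungi and beech",
                   "Mutualistic fungus plant symbiosis where both partners benefit.",
                   list(party("F. Moreau", "owner"))),
      organism = organism_facet(list(organism_name("Fagus sylvatica", "botanical"))),
      process = process_facet(interactions = list(
        interaction("Symbiosis", partner_a = "Fungi", partner_b = "Plantae",
                    direction = "Mutual", quality = "Mutualism")))))
}

#' Generate a deterministic synthetic annotation corpus
#'
#' Every generated record passes [validate_record()] without errors; the
#' same configuration (including seed) reproduces the corpus exactly.
#' Scenario presets return fixed hand-built corpora (see [corpus_config()]).
#'
#' @param config a [corpus_config()].
#' @inheritParams validate_record
#' @return list of \code{eco_record}.
#' @export
generate_corpus <- function(config = corpus_config(),
                            vocab = default_vocabulary()) {
  stopifnot(inherits(config, "corpus_config"))
  if (!is.null(config$preset)) {
    return(switch(config$preset,
                  "carbon-intro" = preset_carbon_intro(),
                  "fungi-interaction" = preset_fungi_interaction(),
                  stop("unknown preset: ", config$preset)))
  }
  if (config$n_records == 0) return(list())
  with_seed(config$seed,
            lapply(seq_len(config$n_records), random_record,
                   fp = config$fill_prob, vocab = vocab))
}

xml_node_txt <- function(parent, tag, value)
  xml2::xml_add_child(parent, tag, as.character(value))

make_eml_doc <- function(s) {
  doc <- xml2::xml_new_root("eml:eml",
                            "xmlns:eml" = "eml://ecoinformatics.org/eml-2.1.1",
                            packageId = s$id, system = "synthetic")
  ds <- xml2::xml_add_child(doc, "dataset")
  xml_node_txt(ds, "title", s$title)
  cr <- xml2::xml_add_child(ds, "creator")
  inm <- xml2::xml_add_child(cr, "individualName")
  xml_node_txt(inm, "surName", s$person)
  ab <- xml2::xml_add_child(ds, "abstract")
  xml_node_txt(ab, "para", s$abstract)
  cov <- xml2::xml_add_child(ds, "coverage")
  if (!is.null(s$bbox)) {
    gc <- xml2::xml_add_child(cov, "geographicCoverage")
    xml_node_txt(gc, "geographicDescription", s$locality)
    bc <- xml2::xml_add_child(gc, "boundingCoordinates")
    xml_node_txt(bc, "westBoundingCoordinate", s$bbox["west"])
    xml_node_txt(bc, "eastBoundingCoordinate", s$bbox["east"])
    xml_node_txt(bc, "northBoundingCoordinate", s$bbox["north"])
    xml_node_txt(bc, "southBoundingCoordinate", s$bbox["south"])
  }
  tc <- xml2::xml_add_child(cov, "temporalCoverage")
  rd <- xml2::xml_add_child(tc, "rangeOfDates")
  bd <- xml2::xml_add_child(rd, "beginDate")
  xml_node_txt(bd, "calendarDate", s$start)
  ed <- xml2::xml_add_child(rd, "endDate")
  xml_node_txt(ed, "calendarDate", s$end)
  if (!is.null(s$kingdom)) {
    txc <- xml2::xml_add_child(cov, "taxonomicCoverage")
    c1 <- xml2::xml_add_child(txc, "taxonomicClassification")
    xml_node_txt(c1, "taxonRankName", "Kingdom")
    xml_node_txt(c1, "taxonRankValue", s$kingdom)
    c2 <- xml2::xml_add_child(c1, "taxonomicClassification")
    xml_node_txt(c2, "taxonRankName", "Family")
    xml_node_txt(c2, "taxonRankValue", s$family)
  }
  ct <- xml2::xml_add_child(ds, "contact")
  cnm <- xml2::xml_add_child(ct, "individualName")
  xml_node_txt(cnm, "surName", s$person)
  xml2::read_xml(as.character(doc))
}

make_abcd_doc <- function(s) {
  doc <- xml2::xml_new_root("DataSets",
                            xmlns = "http://www.tdwg.org/schemas/abcd/2.06")
  ds <- xml2::xml_add_child(doc, "DataSet")
  xml_node_txt(ds, "DatasetGUID", s$id)
  md <- xml2::xml_add_child(ds, "Metadata")
  de <- xml2::xml_add_child(md, "Description")
  rp <- xml2::xml_add_child(de, "Representation")
  xml_node_txt(rp, "Title", s$title)
  xml_node_txt(rp, "Details", s$abstract)
  oc <- xml2::xml_add_child(md, "Owners")
  ow <- xml2::xml_add_child(oc, "Owner")
  on <- xml2::xml_add_child(ow, "Person")
  xml_node_txt(on, "FullName", s$person)
  un <- xml2::xml_add_child(ds, "Units")
  for (k in seq_len(s$n_units)) {
    u <- xml2::xml_add_child(un, "Unit")
    ga <- xml2::xml_add_child(u, "Gathering")
    dt <- xml2::xml_add_child(ga, "DateTime")
    xml_node_txt(dt, "ISODateTimeBegin", s$start)
    xml_node_txt(dt, "ISODateTimeEnd", s$end)
    xml_node_txt(ga, "LocalityText", s$locality)
    co <- xml2::xml_add_child(ga, "Country")
    xml_node_txt(co, "Name", s$country)
    scs <- xml2::xml_add_child(ga, "SiteCoordinateSets")
    sc <- xml2::xml_add_child(scs, "SiteCoordinates")
    cll <- xml2::xml_add_child(sc, "CoordinatesLatLong")
    xml_node_txt(cll, "LongitudeDecimal", s$lon)
    xml_node_txt(cll, "LatitudeDecimal", s$lat)
    idn <- xml2::xml_add_child(u, "Identifications")
    idf <- xml2::xml_add_child(idn, "Identification")
    rs <- xml2::xml_add_child(idf, "Result")
    tx <- xml2::xml_add_child(rs, "TaxonIdentified")
    snm <- xml2::xml_add_child(tx, "ScientificName")
    xml_node_txt(snm, "FullScientificNameString", s$species[k])
  }
  xml2::read_xml(as.character(doc))
}

#' Generate synthetic source-standard documents with paired expectations
#'
#' Produces minimal well-formed metadata documents in one of the three
#' supported standards, each paired with the partial annotation record its
#' import is expected to yield (the oracle for crosswalk tests).
#'
#' @param standard \code{"EML"}, \code{"ABCD"} or \code{"DwC"}.
#' @param n number of documents.
#' @param seed integer seed.
#' @return list of \code{list(doc=, expected=)}; for DwC, \code{doc} is a
#'   named character vector of term/value pairs.
#' @export
generate_source_docs <- function(standard = c("EML", "ABCD", "DwC"), n = 1,
                                 seed = 1L) {
  standard <- match.arg(standard)
  with_seed(seed, lapply(seq_len(n), function(i) {
    y <- sample(1980:2018, 1)
    s <- list(id = sprintf("%s-%04d", tolower(standard), i),
              title = paste(sample(WORDS_TOPIC, 1), sample(WORDS_VERB, 1)),
              abstract = paste("Synthetic", standard, "document", i),
              person = sample(PEOPLE_POOL, 1),
              start = sprintf("%d-%02d-%02d", y, sample(1:12, 1), sample(1:28, 1)),
              end = sprintf("%d-%02d-%02d", y + 1, sample(1:12, 1), sample(1:28, 1)),
              locality = paste("Site", sample(LETTERS, 1)),
              country = sample(c("Germany", "Canada", "Japan", "Kenya"), 1),
              continent = sample(c("Europe", "North America", "Asia", "Africa"), 1),
              lat = round(runif(1, -60, 70), 4), lon = round(runif(1, -170, 170), 4),
              kingdom = sample(c("Plantae", "Animalia", NA), 1),
              family = sample(c("Fagaceae", "Poaceae", "Apidae"), 1),
              species = sample(SPECIES_POOL, 3, replace = TRUE),
              n_units = sample(1:3, 1))
    if (is.na(s$kingdom)) s$kingdom <- NULL
    s$bbox <- { lo <- round(runif(1, -170, 160), 3); la <- round(runif(1, -60, 60), 3)
                c(west = lo, south = la, east = round(lo + 5, 3),
                  north = round(la + 5, 3)) }
    switch(standard,
      EML = list(doc = make_eml_doc(s), expected = expected_eml(s)),
      ABCD = list(doc = make_abcd_doc(s), expected = expected_abcd(s)),
      DwC = {
        rec <- c(datasetID = s$id, datasetName = s$title,
                 recordedBy = s$person, locality = s$locality,
                 country = s$country, continent = s$continent,
                 decimalLatitude = as.character(s$lat),
                 decimalLongitude = as.character(s$lon),
                 eventDate = paste0(s$start, "/", s$end),
                 scientificName = s$species[1], family = s$family)
        if (!is.null(s$kingdom)) rec["kingdom"] <- s$kingdom
        list(doc = rec, expected = expected_dwc(s))
      })
  }))
}

# hand-built expected partial records mirroring the mapping tables
expected_eml <- function(s) {
  annotation_record(s$id,
    general_info(s$title, s$abstract, parties = list(party(s$person, "creator"),
                                                     party(s$person, "contact"))),
    time = time_facet(start = s$start, end = s$end),
    space = space_facet(
      locations = list(location(s$locality)),
      bounding_box = as.list(s$bbox)),
    organism = if (is.null(s$kingdom)) NULL else
      organism_facet(taxonomy = list(kingdom = s$kingdom, family = s$family)))
}

expected_abcd <- function(s) {
  annotation_record(s$id,
    general_info(s$title, s$abstract, parties = list(party(s$person, "owner"))),
    time = time_facet(start = s$start, end = s$end),
    space = space_facet(
      locations = list(location(s$locality, country = s$country)),
      points = rep(list(list(latitude = s$lat, longitude = s$lon)), s$n_units)),
    organism = organism_facet(
      names = lapply(s$species[seq_len(s$n_units)], function(x)
        organism_name(x, code = NULL))))
}

expected_dwc <- function(s) {
  annotation_record(s$id,
    general_info(s$title, "", parties = list(party(s$person, "recordedBy"))),
    time = time_facet(start = s$start, end = s$end),
    space = space_facet(
      locations = list(location(s$locality, country = s$country,
                                continent = s$continent)),
      points = list(list(latitude = s$lat, longitude = s$lon))),
    organism = organism_facet(
      names = list(organism_name(s$species[1], code = NULL)),
      taxonomy = c(if (!is.null(s$kingdom)) list(kingdom = s$kingdom),
                   list(family = s$family))))
}
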