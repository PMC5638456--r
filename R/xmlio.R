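# XML serialization: schema emission, record writing and reading. The
# instance dialect and the emitted XSD are two views of the same registry;
# the writer, the reader and the schema share the element tables below.

EF_NS <- "http://ecofacet.org/ns/annotation/1.0"
EF_SCHEMA_VERSION <- "1.0.0"

path_slug <- function(p) gsub("/", ".", p)

xsd_add <- function(.parent, .tag, ...) {
  xml2::xml_add_child(.parent, .tag, ...)
}

# ranked subtree labels for an enumeration (non-deprecated, core first)
subtree_labels <- function(vocab, ref) {
  vapply(suggest(vocab, ref, ""), `[[`, "", "label")
}

#' Emit the annotation XML schema (XSD)
#'
#' Generates an XSD 1.0 schema for annotation documents: a general metadata
#' block plus one complex type per facet, in registry order. Fields backed
#' by a closed vocabulary are constrained by label enumerations derived from
#' the supplied vocabulary; open (term-suggested) fields use an
#' unconstrained term-reference structure carrying \code{id}, \code{uri}
#' and \code{status} attributes. Output is deterministic: re-emitting from
#' the same registry and vocabulary is byte-identical.
#'
#' @param registry the field registry (defaults to [field_registry()]).
#' @param vocab vocabulary providing the closed enumerations.
#' @return an \code{xml_document} holding the schema.
#' @export
emit_xsd <- function(registry = field_registry(), vocab = default_vocabulary()) {
  doc <- xml2::xml_new_root(
    "xs:schema", "xmlns:xs" = "http://www.w3.org/2001/XMLSchema",
    "xmlns:tns" = EF_NS, targetNamespace = EF_NS,
    elementFormDefault = "qualified", attributeFormDefault = "unqualified",
    version = EF_SCHEMA_VERSION)

  term_attrs <- function(node) {
    xsd_add(node, "xs:attribute", name = "id", type = "xs:string")
    xsd_add(node, "xs:attribute", name = "uri", type = "xs:anyURI")
    xsd_add(node, "xs:attribute", name = "status", type = "xs:string")
  }
  # open term reference: any label, optional id/uri/status
  ct <- xsd_add(doc, "xs:complexType", name = "termRef")
  sc <- xsd_add(ct, "xs:simpleContent")
  ext <- xsd_add(sc, "xs:extension", base = "xs:string")
  term_attrs(ext)

  # one enumeration + one closed term type per distinct closed list
  closed_refs <- unique(registry$closed_list_ref[registry$kind == "closed_term"])
  for (ref in closed_refs) {
    st <- xsd_add(doc, "xs:simpleType", name = paste0("labels.", path_slug(ref)))
    re <- xsd_add(st, "xs:restriction", base = "xs:string")
    for (l in subtree_labels(vocab, ref))
      xsd_add(re, "xs:enumeration", value = l)
    ct <- xsd_add(doc, "xs:complexType", name = paste0("closed.", path_slug(ref)))
    sc <- xsd_add(ct, "xs:simpleContent")
    ext <- xsd_add(sc, "xs:extension", base = paste0("tns:labels.", path_slug(ref)))
    term_attrs(ext)
  }

  # helpers for element declarations
  fel <- function(seq, name, type, min = "0", max = "1")
    xsd_add(seq, "xs:element", name = name, type = type,
            minOccurs = min, maxOccurs = max)
  closed_type <- function(ref) paste0("tns:closed.", path_slug(ref))

  root <- xsd_add(doc, "xs:element", name = "annotation")
  rt <- xsd_add(root, "xs:complexType")
  seq <- xsd_add(rt, "xs:sequence")

  # general block (mandatory)
  gen <- xsd_add(seq, "xs:element", name = "general", minOccurs = "1", maxOccurs = "1")
  gt <- xsd_add(gen, "xs:complexType"); gs <- xsd_add(gt, "xs:sequence")
  fel(gs, "title", "xs:string", min = "1")
  fel(gs, "abstract", "xs:string")
  pty <- xsd_add(gs, "xs:element", name = "party", minOccurs = "1", maxOccurs = "unbounded")
  pt <- xsd_add(pty, "xs:complexType"); ps <- xsd_add(pt, "xs:sequence")
  fel(ps, "name", "xs:string", min = "1")
  fel(ps, "address", "xs:string")
  fel(ps, "email", "xs:string")
  xsd_add(pt, "xs:attribute", name = "role", type = "xs:string")
  fel(gs, "dataCenter", "xs:string")
  acc <- xsd_add(gs, "xs:element", name = "access", minOccurs = "0", maxOccurs = "1")
  at <- xsd_add(acc, "xs:complexType"); asc <- xsd_add(at, "xs:simpleContent")
  aex <- xsd_add(asc, "xs:extension", base = "xs:string")
  att <- xsd_add(aex, "xs:attribute", name = "type")
  ast <- xsd_add(att, "xs:simpleType")
  are <- xsd_add(ast, "xs:restriction", base = "xs:string")
  for (v in c("url", "file_path", "database_id"))
    xsd_add(are, "xs:enumeration", value = v)

  # time facet
  tm <- xsd_add(seq, "xs:element", name = "time", minOccurs = "0", maxOccurs = "1")
  tt <- xsd_add(tm, "xs:complexType"); tsq <- xsd_add(tt, "xs:sequence")
  fel(tsq, "start", "xs:string")
  fel(tsq, "end", "xs:string")
  fel(tsq, "timezone", closed_type("time/timezone"))
  geo <- xsd_add(tsq, "xs:element", name = "geological", minOccurs = "0", maxOccurs = "1")
  gt2 <- xsd_add(geo, "xs:complexType"); gsq <- xsd_add(gt2, "xs:sequence")
  for (rk in c("eon", "era", "period", "epoch", "age"))
    fel(gsq, rk, closed_type(paste0("time/geological/", rk)))
  fel(tsq, "resolution", closed_type("time/unit"))
  fel(tsq, "extent", closed_type("time/unit"))

  # space facet
  sp <- xsd_add(seq, "xs:element", name = "space", minOccurs = "0", maxOccurs = "1")
  st2 <- xsd_add(sp, "xs:complexType"); ssq <- xsd_add(st2, "xs:sequence")
  loc <- xsd_add(ssq, "xs:element", name = "location", minOccurs = "0", maxOccurs = "unbounded")
  lt <- xsd_add(loc, "xs:complexType"); lsq <- xsd_add(lt, "xs:sequence")
  fel(lsq, "name", "xs:string", min = "1")
  fel(lsq, "type", closed_type("space/location_type"))
  fel(lsq, "country", closed_type("space/country"))
  fel(lsq, "continent", closed_type("space/continent"))
  bb <- xsd_add(ssq, "xs:element", name = "boundingBox", minOccurs = "0", maxOccurs = "1")
  bt <- xsd_add(bb, "xs:complexType")
  for (a in c("west", "south", "east", "north"))
    xsd_add(bt, "xs:attribute", name = a, type = "xs:double", use = "required")
  pnt <- xsd_add(ssq, "xs:element", name = "point", minOccurs = "0", maxOccurs = "unbounded")
  ptt <- xsd_add(pnt, "xs:complexType")
  for (a in c("latitude", "longitude", "easting", "northing"))
    xsd_add(ptt, "xs:attribute", name = a, type = "xs:double")
  xsd_add(ptt, "xs:attribute", name = "utmZone", type = "xs:string")
  xsd_add(ptt, "xs:attribute", name = "datum", type = "xs:string")
  fel(ssq, "resolution", closed_type("space/scale"))
  fel(ssq, "extent", closed_type("space/scale"))

  # sphere facet
  sh <- xsd_add(seq, "xs:element", name = "sphere", minOccurs = "0", maxOccurs = "1")
  sht <- xsd_add(sh, "xs:complexType"); shs <- xsd_add(sht, "xs:sequence")
  fel(shs, "layer", closed_type("sphere/layer"), max = "unbounded")
  fel(shs, "organization", closed_type("sphere/organization"))

  # biome facet
  bi <- xsd_add(seq, "xs:element", name = "biome", minOccurs = "0", maxOccurs = "1")
  bit <- xsd_add(bi, "xs:complexType"); bis <- xsd_add(bit, "xs:sequence")
  fel(bis, "latitudinalZone", closed_type("biome/latitudinal"))
  fel(bis, "altitudinalZone", closed_type("biome/altitudinal"))
  fel(bis, "moistureRegime", closed_type("biome/moisture"))
  fel(bis, "continentality", closed_type("biome/continentality"))
  fel(bis, "physiognomy", closed_type("biome/physiognomy"))
  fel(bis, "specialBiome", closed_type("biome/special"))
  fel(bis, "condition", closed_type("biome/condition"))
  fel(bis, "usage", closed_type("biome/usage"), max = "unbounded")

  # organism facet
  og <- xsd_add(seq, "xs:element", name = "organism", minOccurs = "0", maxOccurs = "1")
  ogt <- xsd_add(og, "xs:complexType"); ogs <- xsd_add(ogt, "xs:sequence")
  sn <- xsd_add(ogs, "xs:element", name = "scientificName", minOccurs = "0", maxOccurs = "unbounded")
  snt <- xsd_add(sn, "xs:complexType"); snc <- xsd_add(snt, "xs:simpleContent")
  sne <- xsd_add(snc, "xs:extension", base = "xs:string")
  xsd_add(sne, "xs:attribute", name = "code",
          type = paste0("tns:labels.", path_slug("organism/code")))
  tx <- xsd_add(ogs, "xs:element", name = "taxonomy", minOccurs = "0", maxOccurs = "1")
  txt <- xsd_add(tx, "xs:complexType"); txs <- xsd_add(txt, "xs:sequence")
  for (rk in c("domain", "kingdom", "divisionOrPhylum", "class", "order",
               "family", "genus"))
    fel(txs, rk, "xs:string")

  # process facet
  pr <- xsd_add(seq, "xs:element", name = "process", minOccurs = "0", maxOccurs = "1")
  prt <- xsd_add(pr, "xs:complexType"); prs <- xsd_add(prt, "xs:sequence")
  pe <- xsd_add(prs, "xs:element", name = "processEntry", minOccurs = "0", maxOccurs = "unbounded")
  pet <- xsd_add(pe, "xs:complexType"); pes <- xsd_add(pet, "xs:sequence")
  fel(pes, "name", "tns:termRef", min = "1")
  fel(pes, "involved", closed_type("process/involved"), max = "unbounded")
  fel(pes, "characterization", closed_type("process/characterization"))
  ia <- xsd_add(prs, "xs:element", name = "interaction", minOccurs = "0", maxOccurs = "unbounded")
  iat <- xsd_add(ia, "xs:complexType"); ias <- xsd_add(iat, "xs:sequence")
  fel(ias, "name", "tns:termRef")
  fel(ias, "partnerA", closed_type("organism/kingdom"), min = "1")
  fel(ias, "partnerB", closed_type("organism/kingdom"), min = "1")
  fel(ias, "direction", closed_type("process/interaction/direction"), min = "1")
  fel(ias, "quality", closed_type("process/interaction/quality"))

  # chemical facet
  ch <- xsd_add(seq, "xs:element", name = "chemical", minOccurs = "0", maxOccurs = "1")
  cht <- xsd_add(ch, "xs:complexType"); chs <- xsd_add(cht, "xs:sequence")
  fel(chs, "element", closed_type("chemical/element"), max = "unbounded")
  fel(chs, "compound", "tns:termRef", max = "unbounded")
  fel(chs, "function", closed_type("chemical/function"), max = "unbounded")

  # method facet
  me <- xsd_add(seq, "xs:element", name = "method", minOccurs = "0", maxOccurs = "1")
  met <- xsd_add(me, "xs:complexType"); mes <- xsd_add(met, "xs:sequence")
  fel(mes, "approach", closed_type("method/approach"))
  fel(mes, "context", closed_type("method/context"))
  fel(mes, "manipulatedVariable", "tns:termRef", max = "unbounded")

  xsd_add(rt, "xs:attribute", name = "id", type = "xs:string", use = "required")
  xsd_add(rt, "xs:attribute", name = "schemaVersion", type = "xs:string",
          use = "required")
  # serialize and re-parse so the xs: prefix is bound as a real namespace
  # (nodes built before the root declaration exists are otherwise unbound)
  xml2::read_xml(as.character(doc))
}

num2chr <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)

add_txt <- function(parent, name, value) {
  if (!is.null(value) && nzchar(value))
    xml2::xml_add_child(parent, name, as.character(value))
}

# serialize a resolved term reference: attributes id/uri (when known) and
# status (when not core), label as element text
add_term <- function(parent, name, ref) {
  if (is.null(ref)) return(invisible())
  n <- xml2::xml_add_child(parent, name, ref$label)
  if (!is.null(ref$id)) xml2::xml_set_attr(n, "id", ref$id)
  if (!is.null(ref$uri)) xml2::xml_set_attr(n, "uri", ref$uri)
  if (!is.null(ref$status) && ref$status != "core")
    xml2::xml_set_attr(n, "status", ref$status)
  invisible(n)
}

#' Write an annotation record as an XML document
#'
#' The record is validated and normalized first ([resolve_terms()]); an
#' invalid record is refused with the validation issues attached to the
#' error condition. Term references are serialized with their canonical id,
#' their external URI where one is recorded, and a \code{status} attribute
#' for candidate vocabulary; timestamps are written exactly as entered.
#'
#' @inheritParams validate_record
#' @return an \code{xml_document} that validates against [emit_xsd()].
#' @export
write_record <- function(record, vocab = default_vocabulary()) {
  issues <- validate_record(record, vocab)
  if (any(issues$severity == "error")) {
    cond <- simpleError(paste0("record '", record$record_id,
                               "' does not validate; first error: ",
                               issues$message[issues$severity == "error"][1]))
    cond$issues <- issues
    stop(cond)
  }
  r <- resolve_terms(record, vocab)
  doc <- xml2::xml_new_root("annotation", xmlns = EF_NS, id = r$record_id,
                            schemaVersion = EF_SCHEMA_VERSION)
  g <- r$general
  gn <- xml2::xml_add_child(doc, "general")
  add_txt(gn, "title", g$title)
  add_txt(gn, "abstract", g$abstract)
  for (p in g$parties) {
    pn <- xml2::xml_add_child(gn, "party")
    if (!is.null(p$role)) xml2::xml_set_attr(pn, "role", p$role)
    add_txt(pn, "name", p$name)
    add_txt(pn, "address", p$address)
    add_txt(pn, "email", p$email)
  }
  add_txt(gn, "dataCenter", g$data_center)
  if (!is.null(g$access)) {
    an <- xml2::xml_add_child(gn, "access", as.character(g$access$value))
    xml2::xml_set_attr(an, "type", g$access$type)
  }
  tf <- r$time
  if (!is.null(tf)) {
    tn <- xml2::xml_add_child(doc, "time")
    add_txt(tn, "start", tf$start)
    add_txt(tn, "end", tf$end)
    add_term(tn, "timezone", tf$timezone)
    geo <- Filter(Negate(is.null), tf$geological[c("eon", "era", "period", "epoch", "age")])
    if (length(geo)) {
      gg <- xml2::xml_add_child(tn, "geological")
      for (rk in names(geo)) add_term(gg, rk, geo[[rk]])
    }
    add_term(tn, "resolution", tf$resolution)
    add_term(tn, "extent", tf$extent)
  }
  sp <- r$space
  if (!is.null(sp)) {
    snode <- xml2::xml_add_child(doc, "space")
    for (loc in sp$locations) {
      ln <- xml2::xml_add_child(snode, "location")
      add_txt(ln, "name", loc$name)
      add_term(ln, "type", loc$type)
      add_term(ln, "country", loc$country)
      add_term(ln, "continent", loc$continent)
    }
    if (!is.null(sp$bounding_box)) {
      bb <- sp$bounding_box
      xml2::xml_add_child(snode, "boundingBox", west = num2chr(bb$west),
                          south = num2chr(bb$south), east = num2chr(bb$east),
                          north = num2chr(bb$north))
    }
    for (p in sp$points) {
      if (!is.null(p$utm_zone))
        xml2::xml_add_child(snode, "point", utmZone = p$utm_zone,
                            easting = num2chr(p$easting),
                            northing = num2chr(p$northing),
                            datum = p$datum %||% "WGS84")
      else
        xml2::xml_add_child(snode, "point", latitude = num2chr(p$latitude),
                            longitude = num2chr(p$longitude))
    }
    add_term(snode, "resolution", sp$resolution)
    add_term(snode, "extent", sp$extent)
  }
  sh <- r$sphere
  if (!is.null(sh)) {
    hn <- xml2::xml_add_child(doc, "sphere")
    for (l in sh$layers) add_term(hn, "layer", l)
    add_term(hn, "organization", sh$organization)
  }
  bi <- r$biome
  if (!is.null(bi)) {
    bn <- xml2::xml_add_child(doc, "biome")
    add_term(bn, "latitudinalZone", bi$latitudinal_zone)
    add_term(bn, "altitudinalZone", bi$altitudinal_zone)
    add_term(bn, "moistureRegime", bi$moisture_regime)
    add_term(bn, "continentality", bi$continentality)
    add_term(bn, "physiognomy", bi$physiognomy)
    add_term(bn, "specialBiome", bi$special_biome)
    add_term(bn, "condition", bi$condition)
    for (u in bi$usage) add_term(bn, "usage", u)
  }
  og <- r$organism
  if (!is.null(og)) {
    on <- xml2::xml_add_child(doc, "organism")
    for (n in og$names) {
      sn <- xml2::xml_add_child(on, "scientificName", n$scientific)
      if (!is.null(n$code)) xml2::xml_set_attr(sn, "code", n$code$label)
    }
    if (length(og$taxonomy)) {
      tx <- xml2::xml_add_child(on, "taxonomy")
      rk_el <- c(domain = "domain", kingdom = "kingdom",
                 division_or_phylum = "divisionOrPhylum", class = "class",
                 order = "order", family = "family", genus = "genus")
      for (rk in names(rk_el))
        if (!is.null(og$taxonomy[[rk]])) add_txt(tx, rk_el[[rk]], og$taxonomy[[rk]])
    }
  }
  pr <- r$process
  if (!is.null(pr)) {
    pn <- xml2::xml_add_child(doc, "process")
    for (p in pr$processes) {
      en <- xml2::xml_add_child(pn, "processEntry")
      add_term(en, "name", p$name)
      for (iv in p$involved) add_term(en, "involved", iv)
      add_term(en, "characterization", p$characterization)
    }
    for (i in pr$interactions) {
      ien <- xml2::xml_add_child(pn, "interaction")
      add_term(ien, "name", i$name)
      add_term(ien, "partnerA", i$partner_a)
      add_term(ien, "partnerB", i$partner_b)
      add_term(ien, "direction", i$direction)
      add_term(ien, "quality", i$quality)
    }
  }
  ch <- r$chemical
  if (!is.null(ch)) {
    cn <- xml2::xml_add_child(doc, "chemical")
    for (e in ch$elements) add_term(cn, "element", e)
    for (cp in ch$compounds) add_term(cn, "compound", cp)
    for (fu in ch$functions) add_term(cn, "function", fu)
  }
  me <- r$method
  if (!is.null(me)) {
    mn <- xml2::xml_add_child(doc, "method")
    add_term(mn, "approach", me$approach)
    add_term(mn, "context", me$context)
    for (v in me$manipulated_variables) add_term(mn, "manipulatedVariable", v)
  }
  # re-parse so every element is bound to the declared default namespace
  xml2::read_xml(as.character(doc))
}

# parse one term element back into its resolved reference form
read_term <- function(node) {
  if (inherits(node, "xml_missing") || is.null(node)) return(NULL)
  id <- xml2::xml_attr(node, "id")
  label <- xml2::xml_text(node)
  if (is.na(id)) return(list(label = label))
  uri <- xml2::xml_attr(node, "uri")
  status <- xml2::xml_attr(node, "status")
  list(id = id, label = label, uri = if (is.na(uri)) NULL else uri,
       status = if (is.na(status)) "core" else status)
}

txt1 <- function(node, xpath, default = NULL) {
  n <- xml2::xml_find_first(node, xpath)
  if (inherits(n, "xml_missing")) default else xml2::xml_text(n)
}

term1 <- function(node, xpath) read_term(xml2::xml_find_first(node, xpath))
termN <- function(node, xpath) lapply(xml2::xml_find_all(node, xpath), read_term)

attr_num <- function(node, a) {
  v <- xml2::xml_attr(node, a)
  if (is.na(v)) NULL else as.numeric(v)
}

#' Validate an annotation document against the emitted schema
#'
#' Runs an independent XSD validation (libxml2) of the document against
#' [emit_xsd()] output and reports each violation as an issue row with the
#' XML line position.
#' @param document an \code{xml_document}.
#' @inheritParams validate_record
#' @return issue data.frame (severity, field, message, value); zero rows if
#'   the document is schema-valid.
#' @export
validate_document <- function(document, vocab = default_vocabulary()) {
  ok <- xml2::xml_validate(document, emit_xsd(vocab = vocab))
  if (isTRUE(ok))
    return(data.frame(severity = character(), field = character(),
                      message = character(), value = character(),
                      stringsAsFactors = FALSE))
  errs <- attr(ok, "errors")
  data.frame(severity = "error", field = "document", message = errs,
             value = "", stringsAsFactors = FALSE)
}

#' Read an annotation record from an XML document
#'
#' Inverse of [write_record()]: \code{read_record(write_record(r))} equals
#' the normalized form of \code{r} field for field. The document must carry
#' the annotation namespace; a different major schema version is an error,
#' an older minor version is read with a warning.
#'
#' @param document an \code{xml_document} or a path/string accepted by
#'   \code{xml2::read_xml}.
#' @inheritParams validate_record
#' @return an \code{eco_record} with all term references in resolved form.
#' @export
read_record <- function(document, vocab = default_vocabulary()) {
  # work on a private copy: xml_ns_strip mutates, callers keep their document
  doc <- if (inherits(document, "xml_document"))
    xml2::read_xml(as.character(document)) else xml2::read_xml(document)
  ns <- xml2::xml_ns(doc)[["d1"]] %||% ""
  if (!identical(ns, EF_NS))
    stop("unknown document namespace '", ns, "'; expected ", EF_NS)
  ver <- xml2::xml_attr(doc, "schemaVersion")
  if (is.na(ver)) stop("document lacks the schemaVersion attribute")
  vparts <- strsplit(c(ver, EF_SCHEMA_VERSION), ".", fixed = TRUE)
  if (vparts[[1]][1] != vparts[[2]][1])
    stop("incompatible schema major version: ", ver)
  if (!identical(ver, EF_SCHEMA_VERSION))
    warning("document written with schema version ", ver,
            "; reading as ", EF_SCHEMA_VERSION)
  doc <- xml2::xml_ns_strip(doc)
  rid <- xml2::xml_attr(doc, "id")

  gn <- xml2::xml_find_first(doc, "./general")
  acc <- xml2::xml_find_first(gn, "./access")
  general <- general_info(
    title = txt1(gn, "./title", ""),
    abstract = txt1(gn, "./abstract", ""),
    parties = lapply(xml2::xml_find_all(gn, "./party"), function(p) {
      role <- xml2::xml_attr(p, "role")
      party(name = txt1(p, "./name", ""),
            role = if (is.na(role)) "contact" else role,
            address = txt1(p, "./address"), email = txt1(p, "./email"))
    }),
    data_center = txt1(gn, "./dataCenter"),
    access = if (inherits(acc, "xml_missing")) NULL else
      list(type = xml2::xml_attr(acc, "type"), value = xml2::xml_text(acc)))

  tn <- xml2::xml_find_first(doc, "./time")
  time <- if (inherits(tn, "xml_missing")) NULL else {
    geo <- list()
    for (rk in c("eon", "era", "period", "epoch", "age")) {
      t <- term1(tn, paste0("./geological/", rk))
      if (!is.null(t)) geo[[rk]] <- t
    }
    time_facet(start = txt1(tn, "./start"), end = txt1(tn, "./end"),
               timezone = term1(tn, "./timezone"), geological = geo,
               resolution = term1(tn, "./resolution"),
               extent = term1(tn, "./extent"))
  }

  sn <- xml2::xml_find_first(doc, "./space")
  space <- if (inherits(sn, "xml_missing")) NULL else {
    bb <- xml2::xml_find_first(sn, "./boundingBox")
    space_facet(
      locations = lapply(xml2::xml_find_all(sn, "./location"), function(l)
        location(name = txt1(l, "./name", ""), type = term1(l, "./type"),
                 country = term1(l, "./country"),
                 continent = term1(l, "./continent"))),
      bounding_box = if (inherits(bb, "xml_missing")) NULL else
        list(west = attr_num(bb, "west"), south = attr_num(bb, "south"),
             east = attr_num(bb, "east"), north = attr_num(bb, "north")),
      points = lapply(xml2::xml_find_all(sn, "./point"), function(p) {
        uz <- xml2::xml_attr(p, "utmZone")
        if (!is.na(uz))
          list(utm_zone = uz, easting = attr_num(p, "easting"),
               northing = attr_num(p, "northing"),
               datum = xml2::xml_attr(p, "datum"))
        else list(latitude = attr_num(p, "latitude"),
                  longitude = attr_num(p, "longitude"))
      }),
      resolution = term1(sn, "./resolution"), extent = term1(sn, "./extent"))
  }

  hn <- xml2::xml_find_first(doc, "./sphere")
  sphere <- if (inherits(hn, "xml_missing")) NULL else
    sphere_facet(layers = termN(hn, "./layer"),
                 organization = term1(hn, "./organization"))

  bn <- xml2::xml_find_first(doc, "./biome")
  biome <- if (inherits(bn, "xml_missing")) NULL else
    biome_facet(latitudinal_zone = term1(bn, "./latitudinalZone"),
                altitudinal_zone = term1(bn, "./altitudinalZone"),
                moisture_regime = term1(bn, "./moistureRegime"),
                continentality = term1(bn, "./continentality"),
                physiognomy = term1(bn, "./physiognomy"),
                special_biome = term1(bn, "./specialBiome"),
                condition = term1(bn, "./condition"),
                usage = termN(bn, "./usage"))

  on <- xml2::xml_find_first(doc, "./organism")
  organism <- if (inherits(on, "xml_missing")) NULL else {
    tx <- xml2::xml_find_first(on, "./taxonomy")
    taxo <- list()
    if (!inherits(tx, "xml_missing")) {
      rk_el <- c(domain = "domain", kingdom = "kingdom",
                 division_or_phylum = "divisionOrPhylum", class = "class",
                 order = "order", family = "family", genus = "genus")
      for (rk in names(rk_el)) {
        v <- txt1(tx, paste0("./", rk_el[[rk]]))
        if (!is.null(v)) taxo[[rk]] <- v
      }
    }
    organism_facet(
      names = lapply(xml2::xml_find_all(on, "./scientificName"), function(s) {
        code <- xml2::xml_attr(s, "code")
        n <- organism_name(scientific = xml2::xml_text(s))
        n$code <- if (is.na(code)) NULL else {
          t <- resolve_term(vocab, code, "organism/code")
          if (is.null(t)) list(label = code)
          else list(id = t$id, label = t$label, uri = t$uri, status = t$status)
        }
        n
      }),
      taxonomy = taxo)
  }

  pn <- xml2::xml_find_first(doc, "./process")
  process <- if (inherits(pn, "xml_missing")) NULL else
    process_facet(
      processes = lapply(xml2::xml_find_all(pn, "./processEntry"), function(p)
        process_entry(name = term1(p, "./name"),
                      involved = termN(p, "./involved"),
                      characterization = term1(p, "./characterization"))),
      interactions = lapply(xml2::xml_find_all(pn, "./interaction"), function(i)
        interaction(name = term1(i, "./name"),
                    partner_a = term1(i, "./partnerA"),
                    partner_b = term1(i, "./partnerB"),
                    direction = term1(i, "./direction"),
                    quality = term1(i, "./quality"))))

  cn <- xml2::xml_find_first(doc, "./chemical")
  chemical <- if (inherits(cn, "xml_missing")) NULL else
    chemical_facet(elements = termN(cn, "./element"),
                   compounds = termN(cn, "./compound"),
                   functions = termN(cn, "./function"))

  mn <- xml2::xml_find_first(doc, "./method")
  method <- if (inherits(mn, "xml_missing")) NULL else
    method_facet(approach = term1(mn, "./approach"),
                 context = term1(mn, "./context"),
                 manipulated_variables = termN(mn, "./manipulatedVariable"))

  annotation_record(rid, general, time = time, space = space, sphere = sphere,
                    biome = biome, organism = organism, process = process,
                    chemical = chemical, method = method)
}
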