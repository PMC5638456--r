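test_that("field registry: eight facets besides general, unique paths", {
  reg <- field_registry()
  expect_identical(facet_names(),
                   c("time", "space", "sphere", "biome", "organism",
                     "process", "chemical", "method"))
  expect_length(facet_names(), 8L)
  expect_false(anyDuplicated(reg$path) > 0)
  expect_identical(reg$kind[reg$path == "space/resolution"], "closed_term")
  expect_identical(reg$closed_list_ref[reg$path == "space/resolution"], "space/scale")
  # closed_term fields all reference a non-empty vocabulary subtree
  for (ref in unique(reg$closed_list_ref[reg$kind == "closed_term"]))
    expect_gt(length(suggest(ecv, ref, "")), 0)
})

test_that("a minimal record is valid; missing essentials are errors", {
  expect_identical(nrow(validate_record(minimal_record(), ecv)), 0L)
  bad <- annotation_record("x", general_info("", parties = list()))
  iss <- validate_record(bad, ecv)
  expect_setequal(iss$field[iss$severity == "error"],
                  c("general/title", "general/party"))
  noid <- minimal_record(""); noid$record_id <- ""
  expect_true("record_id" %in% validate_record(noid, ecv)$field)
})

test_that("timestamp syntax, precision and interval-ordering checks", {
  expect_null(parse_timestamp("2001-02-30"))
  expect_null(parse_timestamp("not-a-date"))
  expect_identical(parse_timestamp("2001")$precision, "year")
  # a year covers its whole span: year-start before a mid-year date is fine
  ok <- minimal_record(time = time_facet("2001", "2001-06-15"))
  expect_identical(nrow(validate_record(ok, ecv)), 0L)
  bad <- minimal_record(time = time_facet("2001-03-04", "2000-01-01"))
  iss <- validate_record(bad, ecv)
  expect_true(any(iss$severity == "error" & iss$field == "time/start"))
  garbled <- minimal_record(time = time_facet("01.02.2003"))
  expect_true(any(validate_record(garbled, ecv)$field == "time/start"))
})

test_that("geological rank nesting is enforced against the packaged chart", {
  bad <- minimal_record(time = time_facet(
    geological = list(period = "Neogene", epoch = "Holocene")))
  iss <- validate_record(bad, ecv)
  expect_true(any(iss$severity == "error" & iss$field == "time/geological"))
  expect_match(iss$message[iss$field == "time/geological"], "not nested")
  ok <- minimal_record(time = time_facet(
    geological = list(eon = "Phanerozoic", period = "Quaternary",
                      epoch = "Holocene")))
  expect_identical(nrow(validate_record(ok, ecv)), 0L)
})

test_that("closed fields reject unknown terms, open fields warn", {
  closed <- minimal_record(method = method_facet(approach = "Imaginary"))
  iss <- validate_record(closed, ecv)
  expect_identical(iss$severity[iss$field == "method/approach"], "error")
  open <- minimal_record(method = method_facet(
    manipulated_variables = list("soil moisture manipulation")))
  iss <- validate_record(open, ecv)
  expect_identical(iss$severity[iss$field == "method/manipulated_variable"],
                   "warning")
  expect_match(iss$message[iss$field == "method/manipulated_variable"],
               "propose_term")
})

test_that("coordinate and bounding box checks; res>extent only warns", {
  bb <- function(w, s, e, n) minimal_record(
    space = space_facet(bounding_box = list(west = w, south = s, east = e, north = n)))
  expect_identical(nrow(validate_record(bb(170, -10, -170, 10), ecv)), 0L)  # wrap
  expect_true(any(validate_record(bb(0, 10, 5, -10), ecv)$severity == "error"))
  expect_true(any(validate_record(bb(-200, 0, 10, 10), ecv)$severity == "error"))
  pt <- minimal_record(space = space_facet(points = list(list(latitude = 95, longitude = 0))))
  expect_true(any(validate_record(pt, ecv)$severity == "error"))
  utm <- minimal_record(space = space_facet(points = list(
    list(utm_zone = "99Z", easting = 1, northing = 1, datum = "WGS84"))))
  expect_true(any(validate_record(utm, ecv)$severity == "error"))
  coarse <- minimal_record(space = space_facet(resolution = "Region", extent = "Point"))
  iss <- validate_record(coarse, ecv)
  expect_identical(unique(iss$severity), "warning")
})

test_that("resolve_terms normalizes synonyms and merge redirects, idempotently", {
  rec <- minimal_record(chemical = chemical_facet(compounds = list("CO2")))
  r1 <- resolve_terms(rec, ecv)
  expect_identical(r1$chemical$compounds[[1]]$label, "Carbon Dioxide")
  expect_identical(resolve_terms(r1, ecv), r1)                # idempotent
  expect_identical(nrow(validate_record(r1, ecv)), 0L)        # still valid

  # deprecated term resolves to its merge target
  v2 <- propose_term(ecv, "N-fixation", "process/name")
  id <- attr(v2, "term_id")
  tgt <- resolve_term(ecv, "Nitrogen fixation", "process/name")$id
  vm <- curate_term(v2, id, "merge", target_id = tgt)
  rec2 <- minimal_record(process = process_facet(list(process_entry("N-fixation"))))
  r2 <- resolve_terms(rec2, vm)
  expect_identical(r2$process$processes[[1]]$name$id, tgt)
})

test_that("the narrative annotations are representable and valid", {
  rec <- annotation_record("narrative",
    general_info("Elevated carbon dioxide and fungal antagonists",
                 parties = list(party("W. Orker"))),
    time = time_facet(geological = list(epoch = "Holocene")),
    sphere = sphere_facet(layers = list("Troposphere")),
    process = process_facet(interactions = list(
      interaction("Parasitism", partner_a = "Fungi", partner_b = "Plantae",
                  direction = "Affects", quality = "Antagonism"))),
    method = method_facet(approach = "Manipulative",
                          manipulated_variables = list("elevated carbon dioxide concentration")))
  expect_identical(nrow(validate_record(rec, ecv)), 0L)
  rr <- resolve_terms(rec, ecv)
  expect_identical(rr$sphere$layers[[1]]$id, "sphere-layer-atmosphere-troposphere")
})

test_that("ordered scales expose a strict total order", {
  for (p in c("space/scale", "time/unit", "sphere/organization")) {
    ords <- vapply(terms_at(ecv, p), `[[`, 0L, "ord")
    expect_identical(ords, seq_along(ords))
  }
})
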