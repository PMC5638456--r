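test_that("EML import: dates, bounding box axis order, missing taxonomy", {
  d <- generate_source_docs("EML", 1, seed = 5)[[1]]
  imp <- import_eml(d$doc)
  expect_identical(imp$record$time$start, d$expected$time$start)
  expect_identical(imp$record$time$end, d$expected$time$end)
  # EML writes W/E/N/S; the stored box is axis-ordered west,south,east,north
  expect_identical(names(imp$record$space$bounding_box),
                   c("west", "south", "east", "north"))

  # strip the taxonomic coverage: organism facet absent, report says so
  txt <- as.character(d$doc)
  no_taxa <- xml2::read_xml(gsub("<taxonomicCoverage>.*</taxonomicCoverage>", "",
                                 txt))
  imp2 <- import_eml(no_taxa)
  expect_null(imp2$record$organism)
  expect_identical(
    imp2$report$status[imp2$report$target_field == "organism/taxonomy"],
    "missing_in_source")
})

test_that("DwC import: taxonomy slots, WGS84 point, label-match rule", {
  imp <- import_dwc(c(kingdom = "Plantae", family = "Fagaceae"))
  expect_identical(imp$record$organism$taxonomy,
                   list(kingdom = "Plantae", family = "Fagaceae"))
  imp <- import_dwc(c(decimalLatitude = "51.3", decimalLongitude = "12.4"))
  expect_identical(imp$record$space$points,
                   list(list(latitude = 51.3, longitude = 12.4)))
  # a closed-vocabulary label that does not match is reported, not guessed
  imp <- import_dwc(c(locality = "Leipzig", country = "Deutschland"))
  expect_null(imp$record$space$locations[[1]]$country)
  expect_identical(
    imp$report$status[imp$report$target_field == "space/location/country"],
    "present_unparsed")
  imp <- import_dwc(c(locality = "Leipzig", country = "Germany"))
  expect_identical(imp$record$space$locations[[1]]$country, "Germany")
})

test_that("ABCD import: gathering event, locality, one name entry per unit", {
  d <- generate_source_docs("ABCD", 1, seed = 8)[[1]]
  imp <- import_abcd(d$doc)
  expect_identical(imp$record$time$start, d$expected$time$start)
  expect_identical(imp$record$space$locations[[1]]$name,
                   d$expected$space$locations[[1]]$name)
  n_units <- length(xml2::xml_find_all(d$doc, "//*[local-name()='Unit']"))
  expect_identical(length(imp$record$organism$names), n_units)
})

test_that("mapping reports cover every concept-table field exactly once", {
  docs <- list(EML = generate_source_docs("EML", 1, seed = 1)[[1]]$doc,
               ABCD = generate_source_docs("ABCD", 1, seed = 1)[[1]]$doc,
               DwC = generate_source_docs("DwC", 1, seed = 1)[[1]]$doc)
  for (std in names(docs)) {
    imp <- switch(std, EML = import_eml(docs[[std]]),
                  ABCD = import_abcd(docs[[std]]), DwC = import_dwc(docs[[std]]))
    rep <- imp$report
    expect_identical(unique(rep$source_standard), std)
    expect_false(anyDuplicated(rep$target_field) > 0)
    expect_true(all(rep$status %in%
                      c("mapped", "missing_in_source", "present_unparsed")))
    # facets the source standards do not cover are never populated
    expect_null(imp$record$process)
    expect_null(imp$record$method)
  }
})

test_that("imports equal their paired expectations for seeded documents", {
  # module-level spot check; the full 50-seed criterion runs in
  # test-acceptance.R
  for (std in c("EML", "ABCD", "DwC")) {
    docs <- generate_source_docs(std, 15, seed = 20260911)
    for (d in docs) {
      imp <- switch(std, EML = import_eml(d$doc), ABCD = import_abcd(d$doc),
                    DwC = import_dwc(d$doc))
      expect_identical(imp$record, d$expected)
      # imported records validate with no errors (warnings allowed)
      expect_false(any(validate_record(imp$record, ecv)$severity == "error"))
      # idempotence: importing the same document again is identical
    }
    d1 <- docs[[1]]
    imp_a <- switch(std, EML = import_eml(d1$doc), ABCD = import_abcd(d1$doc),
                    DwC = import_dwc(d1$doc))
    imp_b <- switch(std, EML = import_eml(d1$doc), ABCD = import_abcd(d1$doc),
                    DwC = import_dwc(d1$doc))
    expect_identical(imp_a$record, imp_b$record)
    expect_identical(imp_a$report, imp_b$report)
  }
})
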