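xsd <- emit_xsd(vocab = ecv)

test_that("emitted schema: general block plus exactly eight facet elements", {
  root_seq <- xml2::xml_find_all(
    xsd, "//xs:element[@name='annotation']/xs:complexType/xs:sequence/xs:element")
  expect_identical(xml2::xml_attr(root_seq, "name"),
                   c("general", facet_names()))
})

test_that("schema emission is deterministic and enumerations match", {
  expect_identical(as.character(emit_xsd(vocab = ecv)),
                   as.character(emit_xsd(vocab = ecv)))
  appr <- xml2::xml_find_all(
    xsd, "//xs:simpleType[@name='labels.method.approach']//xs:enumeration")
  expect_identical(xml2::xml_attr(appr, "value"),
                   c("Manipulative", "Observational", "Virtual"))
  # subtree lists enumerate the whole subtree (parents and leaves)
  lay <- xml2::xml_attr(xml2::xml_find_all(
    xsd, "//xs:simpleType[@name='labels.sphere.layer']//xs:enumeration"), "value")
  expect_true(all(c("Atmosphere", "Troposphere", "Abyssopelagic", "A Horizon") %in% lay))
})

test_that("write/read round-trip is exact on a synthetic corpus", {
  # module-level spot check; the full 100-record criterion runs in
  # test-acceptance.R
  corpus <- generate_corpus(corpus_config(30, seed = 2024), ecv)
  for (rec in corpus) {
    doc <- write_record(rec, ecv)
    expect_true(xml2::xml_validate(doc, xsd))
    expect_identical(read_record(doc, ecv), resolve_terms(rec, ecv))
  }
})

test_that("candidate terms serialize with a status attribute", {
  v2 <- propose_term(ecv, "rhizodeposition", "process/name")
  rec <- minimal_record(process = process_facet(list(process_entry("rhizodeposition"))))
  doc <- write_record(rec, v2)
  n <- xml2::xml_find_first(xml2::xml_ns_strip(doc), "//processEntry/name")
  expect_identical(xml2::xml_attr(n, "status"), "candidate")
  expect_identical(xml2::xml_attr(n, "id"), attr(v2, "term_id"))
})

test_that("URIs of resolved terms are serialized", {
  rec <- minimal_record(time = time_facet(geological = list(epoch = "Holocene")))
  doc <- write_record(rec, ecv)
  ep <- xml2::xml_find_first(xml2::xml_ns_strip(doc), "//geological/epoch")
  expect_match(xml2::xml_attr(ep, "uri"), "ischart/Holocene$")
})

test_that("schema validation reports unknown closed-field values with position", {
  doc <- write_record(minimal_record(time = time_facet(timezone = "UTC")), ecv)
  bad <- xml2::read_xml(sub(">UTC<", ">Moon/Crater<", as.character(doc)))
  iss <- validate_document(bad, ecv)
  expect_gt(nrow(iss), 0)
  expect_match(paste(iss$message, collapse = " "), "timezone")
  expect_identical(nrow(validate_document(doc, ecv)), 0L)
})

test_that("invalid records are refused with issues attached", {
  bad <- minimal_record(time = time_facet("2005", "2001"))
  err <- tryCatch(write_record(bad, ecv), error = identity)
  expect_s3_class(err, "error")
  expect_true(any(err$issues$severity == "error"))
})

test_that("version handling: minor mismatch warns, major mismatch errors", {
  doc <- write_record(minimal_record(), ecv)
  txt <- as.character(doc)
  older <- xml2::read_xml(sub('schemaVersion="1.0.0"', 'schemaVersion="1.0.0-pre"', txt))
  expect_warning(read_record(older, ecv), "schema version")
  major <- xml2::read_xml(sub('schemaVersion="1.0.0"', 'schemaVersion="2.0.0"', txt))
  expect_error(read_record(major, ecv), "major version")
  alien <- xml2::read_xml('<annotation xmlns="http://example.org/other" id="x" schemaVersion="1.0.0"/>')
  expect_error(read_record(alien, ecv), "namespace")
  expect_error(read_record("<annotation>broken"), ".")
})
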