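Package: ecofacet
Title: Faceted Annotation and Discovery for Ecological Metadata
Version: 1.0.0
Authors@R: person("ecofacet", "maintainers", email = "ecofacet@example.org",
    role = c("aut", "cre"))
Description: A typed annotation model for ecological search objects built on
    eight orthogonal facets (time, space, sphere, biome, organism, process,
    chemical, method) plus a general metadata block. Ships curated controlled
    vocabularies including the full hierarchical geological time scale with
    numeric boundaries, validates annotation records against a field
    registry, emits an XML schema and round-trips records as XML, imports
    partial annotations from EML, ABCD and Darwin Core metadata with mapping
    reports, and answers combined full-text and faceted queries with
    incremental refinement and facet value counts over an inverted index.
    Deterministic synthetic corpus generators make the whole toolkit testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
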