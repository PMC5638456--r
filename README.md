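# ecofacet

Faceted annotation and discovery for ecological metadata.

## The problem

Ecologists who want to reuse data must first find it, and full-text search
over metadata is a blunt instrument: it is blind to synonyms, homonyms and
broader/narrower terms. Searching an ecological database for *carbon* will
return CO₂-enrichment experiments, subsoil carbon surveys, tree-ring
isotope studies and field observations near Carbon Village, Alberta — four
very different things. Faceted navigation fixes this by classifying every
search object along a small set of orthogonal dimensions and letting the
searcher stack filters (`experimental treatment = elevated carbon dioxide
concentration`) on top of the text query.

`ecofacet` is a working toolkit for that workflow. It provides:

* **A typed annotation model** — one mandatory general-metadata block
  (title, abstract, responsible parties, data access) plus eight optional
  facets: **time, space, sphere, biome, organism, process, chemical,
  method**. Every annotatable attribute is described in a field registry
  with a value kind (closed term / open term / free text / numeric /
  timestamp / geospatial) and multiplicity.
* **Curated controlled vocabularies** (521 terms) shipped as plain-text
  term tables: the full hierarchical geological time scale (5 eons, 10
  eras, 22 periods, 34 epochs, 98 ages, with numeric boundaries in Ma),
  periodic-table elements, spatial scale classes, sphere layers, biome
  classifications, interaction directions and qualities, and more.
  Closed fields restrict input to the list; open fields accept new terms
  as *candidates* which a curator can accept, merge into a core term
  (leaving a synonym redirect) or reject — a controlled middle ground
  between a fixed hierarchy and an unmanaged folksonomy.
* **Deterministic classifiers** from measurements onto the categorical
  scales: area → Point/Plot/Region/Continent/Global, interval → time-unit
  class, age in Ma → chain of chart units, plus bounding-box containment
  with antimeridian wrap.
* **XML serialization**: an emitted XSD (closed lists become enumerations),
  record writing with term ids/URIs/lifecycle status, exact read-back, and
  independent libxml2 schema validation.
* **Crosswalk importers** from EML 2.x, ABCD 2.06 and Darwin Core, driven
  by shipped concept-mapping tables, each import paired with a report of
  what mapped, what the source standard lacks, and what was present but
  not parsed.
* **A faceted query engine**: inverted index with vocabulary-hierarchy
  expansion (a record annotated *Holocene* is retrievable under
  *Quaternary*), combined full-text + filter queries (AND across fields,
  OR within a field), joint interaction-pattern matching (`Mutual`
  matches either partner order), incremental refinement, and per-field
  value counts with multi-select semantics.
* **Synthetic fixtures**: seed-deterministic corpus and source-document
  generators so the whole toolkit is testable offline.

## Worked example

```r
library(ecofacet)
vocab <- default_vocabulary()

corpus <- generate_corpus(corpus_config(preset = "carbon-intro"), vocab)
idx <- build_index(corpus, vocab)

hits <- run_query(idx, facet_query(text = "carbon"))
print(hits)
#> <eco_result> 4 of 4 records matched
#>   ids: carbon-co2, carbon-subsoil, carbon-treering, carbon-village
#>   time/geological/period: Quaternary=1
#>   time/geological/epoch: Holocene=1
#>   time/resolution: Day=1, Year=1

refined <- refine(hits, filters = list(
  "method/manipulated_variable" = "elevated carbon dioxide concentration"))
print(refined)
#> <eco_result> 1 of 4 records matched
#>   ids: carbon-co2
```

The text query alone matches all four records; one facet filter isolates
the CO₂-enrichment experiment. The counts attached to a result tell the
searcher which filter values would discriminate next.

Geological and scale helpers:

```r
ctx <- geological_context(0.001)   # 1000 years before present, in Ma
paste(names(ctx), vapply(ctx, `[[`, "", "label"), sep = " = ")
#> "eon = Phanerozoic"  "era = Cenozoic"  "period = Quaternary"  "epoch = Holocene"
classify_spatial_scale(5000, "km2")
#> [1] "Region"
```

XML round trip:

```r
doc <- write_record(corpus[[1]], vocab)
#> <annotation xmlns="http://ecofacet.org/ns/annotation/1.0" id="carbon-co2"
#>             schemaVersion="1.0.0"> ...
identical(read_record(doc, vocab), resolve_terms(corpus[[1]], vocab))
#> [1] TRUE
```

## Command line

A small CLI ships in `inst/cli/ecofacet`:

```sh
ecofacet vocab list time/geological/eon
ecofacet vocab suggest process/interaction/quality A
ecofacet classify area 5000 km2
ecofacet classify age 0.001
ecofacet fixtures corpus out/ --n 20 --seed 1
ecofacet query out/ --text carbon --filter method/approach=Manipulative
ecofacet import --from eml dataset.xml
ecofacet validate out/rec0001.xml
```

See `vignettes/ecofacet-methods.Rmd` for the model, its assumptions, the
numerical choices and known limitations.
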