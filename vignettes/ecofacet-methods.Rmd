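---
title: "ecofacet: model, vocabularies and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ecofacet: model, vocabularies and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecofacet)
```

## The annotation model

An annotation record describes one *search object* (a dataset, image,
sample series) for faceted discovery. It has a mandatory general block —
title, abstract, at least one responsible party, optionally the hosting
data center and an access pointer (URL, file path or database id) — and
eight optional facet blocks: time, space, sphere, biome, organism,
process, chemical and method. The facets are orthogonal by design: each
answers one question (when, where, in which compartment, in which biome,
about which organisms, about which processes and interactions, about
which chemistry, with which methodology), and a searcher refines a result
set by intersecting selections across them.

Two principles pull against each other. *Parsimony* keeps annotation
cheap: every facet block is optional, so a record can be annotated
incrementally, and coarse statements (just an epoch, just a country) are
always legal. *Comprehensiveness* keeps discovery sharp: within a block,
fields are typed and, where a finite classification exists, closed. The
field registry (`field_registry()`) encodes this: each of its 57 fields
carries a value kind — `closed_term`, `open_term`, `free_text`,
`timestamp`, `geospatial` — a multiplicity, and for term-kinded fields
the vocabulary subtree its values come from.

### Closed versus open fields

Content-restricted (closed) fields are those where the value space is
stable or is a finite purpose-built gradient: time zones, countries,
continents, the spatial and temporal scale classes, sphere layers and
organization levels, biome classifications, study approach and context,
interaction direction. Open (term-suggested) fields are where the
vocabulary must be able to grow with the science: process names,
interaction names, chemical compounds, manipulated variables; location
names are free text. For fields with a stated example list but no
explicit open/closed ruling (location type, interaction quality, chemical
functions, involved-object classes) we chose closed, because each is
presented as a finite classification rather than a growing nomenclature;
this is a package decision and is trivially reversible in the registry.

Open fields feed a curation loop: `propose_term()` adds a `candidate`
term (closed fields refuse), and `curate_term()` lets a curator *accept*
it into the core vocabulary, *merge* it into an existing core term — the
candidate becomes `deprecated`, points at its target via `merged_into`,
and its label survives as a synonym, so old annotations keep resolving —
or *reject* it. This is the controlled middle ground between a fixed
top-down vocabulary and an unmanaged folksonomy: free growth at the edge,
curated consolidation at the core.

### Term identity

Terms have opaque slugged ids, display labels, definitions, optional URIs
linking to external vocabularies (ontologies, thesauri), a facet path and
an optional parent. Label matching everywhere is case-insensitive and
whitespace-normalized. Within one facet path, non-deprecated labels are
unique. URIs are stored, never dereferenced: no live ontology service is
consulted.

## Packaged vocabularies

The vocabulary ships as three plain-text term tables under
`inst/extdata/vocabulary/` (37 kB + 11 kB + 28 kB), loadable with
`load_vocabulary()`; `#!` header lines carry per-subtree provenance and a
version string.

**Geological time.** The table is pinned to the chart edition whose rank
counts are 5 eons, 10 eras, 22 periods, 34 epochs and 98 ages — the 2016
vintage of the international chart, before the 2018 subdivision of the
Holocene — because those printed counts are what the acceptance tests
freeze. Consequences of that pinning: the Holocene and the Pridoli are
leaf epochs without ages; the unnamed Middle/Upper Pleistocene stages
count as ages; Mississippian and Pennsylvanian are the Carboniferous'
two epoch-rank units. Two representation choices deserve a note:

* *Precambrian.* The chart's five-eon listing counts both the informal
  Precambrian grouping and its formal subdivisions (Proterozoic, Archean,
  Hadean). We model all five as eon-rank terms, but the Precambrian
  carries no numeric span and no children; the formal eons carry the
  numbers. Numeric lookups (`geological_context()`) therefore always
  resolve to exactly one unit per rank, while `terms_at()` still reports
  five eons.
* *Qualified series labels.* Ranks reuse names across periods ("Upper",
  "Series 2"), which would violate label uniqueness within a facet path;
  we use the chart's qualified forms ("Upper Jurassic", "Cambrian Series
  2", "Middle Pleistocene").

Each unit stores its younger and older bound in Ma (`num_lo`, `num_hi`),
so the chart's numbers are data, versioned with the vocabulary, not code.

**Elements.** All 118 periodic-table elements; the label is the symbol
(what appears in annotations and enumerations), the element name rides
along as a synonym so autocompletion matches both `"C"` and `"carbon"`.

**Everything else** (scale classes, time units, spheres, biomes,
kingdoms, interaction vocabulary, seed lists for countries, time zones,
location types, processes, compounds, functions, manipulated variables)
lives in the core table. Every term explicitly named in the framework
description is present; country and time-zone lists are seeds attributed
to GeoNames/IANA and are explicitly *not* claimed complete — completeness
is not an invariant, extension is a data edit.

## Numeric classifiers

* `classify_spatial_scale()` — classes partition the positive areas:
  Point < 1 m²; Plot 1 m²–0.01 km²; Region 0.01–10 000 km²; Continent
  10 000–10⁸ km²; Global above. The printed ranges do not state boundary
  ownership, so we fixed *lower-bound inclusive*: exactly 1 m² is a Plot.
  Areas are accepted in m² or km² (exact factor 10⁶).
* `classify_time_unit()` — floor rule: the largest unit whose nominal
  span does not exceed the interval. The four printed example units
  (Second, Minute, Hour, Day) are extended by Week, Month (30 days),
  Year (365 days) and Decade; the extension beyond the printed four is
  artifact-defined, as are the nominal spans of the calendar-fuzzy units.
* `geological_context()` — an age exactly on a unit boundary belongs to
  the *younger* unit (the same determinism decision as above, stated in
  the docs). Ages beyond the packaged chart span (4600 Ma) error.
* `bbox_contains()` — inclusive edges; a box with west > east wraps the
  antimeridian. No polygon geometry, no projection math: UTM coordinates
  are stored with their zone and datum as a data contract only.

## Timestamps

Reduced-precision ISO 8601 is accepted and preserved exactly as entered:
`2001`, `2001-03`, `2001-03-04`, and date-times to the minute or second.
Comparisons use interval semantics — a year denotes its full span — so
`start = "2001", end = "2001-06-15"` is consistent, and the ordering
check fails only when the start interval begins after the end interval
ends. Calendar-impossible dates (`2001-02-30`) are rejected rather than
rolled over.

## Validation and normalization

`validate_record()` returns issues as data (severity, field, message,
value), never as conditions. Errors: missing title/party, malformed or
misordered timestamps, geological ranks that are not nested (a finer rank
must descend from every coarser rank given), out-of-range coordinates,
unknown terms in closed fields, unknown taxonomy rank keys, incomplete
interactions. Warnings: unknown terms in *open* fields (the implicit
candidate-proposal hook) and a spatial resolution class coarser than the
extent class — a warning, not an error, because single-point studies
plausibly produce such records. `resolve_terms()` normalizes every term
reference to canonical id + label + URI, following synonym matches and
merge redirects; it is idempotent, and normalization never invalidates a
valid record.

## XML dialect and schema

The package defines its own namespace
(`http://ecofacet.org/ns/annotation/1.0`) and semantic version (`1.0.0`);
minor versions may only add optional elements, so a minor mismatch reads
with a warning and a major mismatch errors. Element order is fixed to
registry order and output is UTF-8, making re-emission byte-identical.
Term elements carry `id` and `uri` attributes and the label as text, plus
`status="candidate"` for uncurated vocabulary; closed fields are
enumerated in the emitted XSD (over the whole subtree, parents included),
open fields use the unconstrained term-reference type. `read_record()`
inverts `write_record()` exactly on normalized records, and
`validate_document()` runs an independent libxml2 XSD validation rather
than re-using the reader's checks. Element naming inside facets is
artifact-defined (the source framework does not print its schema).

## Crosswalk imports

The concept maps for EML, ABCD and Darwin Core ship as CSV tables
(`inst/extdata/crosswalk/`), one row per annotation field covered by the
topic mapping; the importers populate only what the tables cover —
general metadata, time, space, organism — and never invent values for
facets the source standards lack (interaction detail, scale classes,
spheres). Each import returns the partial record *and* a mapping report:
`mapped`, `missing_in_source` (the concept is absent from the standard or
from this particular document), or `present_unparsed` (e.g. EML method
descriptions, DwC geological context terms). Closed-vocabulary label
matching is strict: `country = "Deutschland"` does not silently become
Germany; it is dropped and surfaced in the report. Version tolerance is
by local-name matching (EML 2.0–2.2, ABCD 2.06). The supplementary
cell-level element choices are artifact-defined; the shipped tables
encode the topic-level mapping.

## Search semantics

`build_index()` resolves and validates every record, then builds
per-field inverted postings, *hierarchy-expanded*: a record is posted
under each annotated term and all its vocabulary ancestors, so filtering
on a period retrieves records annotated with any of its epochs or ages,
and filtering on "Hydrosphere" retrieves "Abyssopelagic" records.
Query semantics are the standard faceted-navigation contract, fixed here
because the source framework describes filters but not combination
logic: conjunction across distinct fields and the text clause,
disjunction among selected values of one field. Text search is lowercase
token matching over title + abstract with term-frequency scoring, no
stemming, no synonym expansion — deliberately so: synonym-awareness is
the facets' job, and the text engine stays a transparent baseline.
Interaction filters match *jointly* against single interaction entries
(partner A, partner B, direction read A→B, quality); "Is Affected By" is
canonicalized to the inverse "Affects", and Mutual interactions match
either partner order. Ordering is descending text score, then record id;
every tie-break in the engine is by record id.

`refine()` is definitionally equivalent to re-running the combined query
— which makes it monotone, commutative and idempotent, properties the
test suite checks against a record-by-record linear-scan oracle. Facet
counts use multi-select semantics: when counting values of field F, F's
own filter is removed, so the numbers beside unticked checkboxes remain
informative; this is a documented choice, and the joint interaction
clause is never removed. Free-text location names are both
facet-indexed (as normalized text keys) and text-searchable via the
abstract — an artifact choice, flagged as such.

## Synthetic data

`generate_corpus()` emulates only *structural* properties of annotated
corpora: per-facet presence probabilities (defaults 0.5–0.85, chosen so a
mid-sized corpus exercises every field), values drawn uniformly from the
vocabulary subtrees, internally consistent geological chains (a random
leaf unit plus its ancestors), ordered resolution/extent pairs, and
titles/abstracts from small word pools. Integer-based sampling under a
fixed seed makes corpora byte-identical across platforms. It does not
emulate real metadata's skewed term frequencies, correlated facets,
multilingual text or noisy dates — so a green property test establishes
that the machinery is correct on well-formed, uniformly random inputs,
not that retrieval quality on real archives is good. The two scenario
presets ("carbon-intro", "fungi-interaction") are fixed hand-built
corpora reproducing the worked discovery examples. The source-document
generators emit minimal well-formed EML/ABCD/DwC paired with the record
their import must yield; DwC fixtures include `recordedBy` so that
imported records satisfy the at-least-one-party invariant.

## Known limitations

* The vocabulary is a seed, not a gazetteer: country, time-zone and
  location-type lists are intentionally partial.
* No SKOS/OWL reasoning, no live terminology services; URIs are opaque.
* No geodetic conversion between UTM and geographic coordinates; both are
  stored, neither is transformed.
* No export back to EML/ABCD/DwC, and DwC import reads a flat core
  record, not archive extensions.
* Scientific names are not verified against nomenclators, and location
  names are not geocoded.
* The index is in-memory and single-machine; persistence goes through
  the XML corpus, not a binary index format.
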