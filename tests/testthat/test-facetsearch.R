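# shared mid-size corpus for the engine tests (the full 500-record oracle
# equivalence run lives in test-acceptance.R)
fs_corpus <- generate_corpus(corpus_config(150, seed = 31), ecv)
fs_idx <- build_index(fs_corpus, ecv)
fs_vals <- lapply(fs_corpus, function(r)
  ecofacet:::record_term_values(resolve_terms(r, ecv), ecv))
names(fs_vals) <- vapply(fs_corpus, `[[`, "", "record_id")

random_query <- function(vocab) {
  term_fields <- c("time/geological/period", "time/geological/epoch",
                   "space/location/country", "space/location/continent",
                   "sphere/layer", "sphere/organization", "biome/condition",
                   "biome/usage", "process/interaction/partner_a",
                   "process/process/name",
                   "chemical/element", "chemical/compound", "method/approach",
                   "method/context", "method/manipulated_variable",
                   "space/resolution", "time/resolution")
  flt <- list()
  for (p in sample(term_fields, sample(1:3, 1))) {
    f <- ecofacet:::registry_field(p)
    labs <- vapply(suggest(vocab, f$closed_list_ref, ""), `[[`, "", "label")
    flt[[p]] <- sample(labs, sample(1:2, 1))
  }
  txt <- if (runif(1) < 0.3) sample(ecofacet:::WORDS_TOPIC, 1)
  facet_query(text = txt, filters = flt)
}

test_that("empty corpus and empty query behave as identities", {
  empty <- build_index(list(), ecv)
  expect_length(run_query(empty, facet_query(text = "anything"))$ids, 0L)
  all_r <- run_query(fs_idx, facet_query())
  expect_identical(all_r$ids, sort(names(fs_vals)))
  expect_gt(length(all_r$counts), 0)
})

test_that("rebuilding on the same corpus yields identical postings", {
  expect_identical(build_index(fs_corpus, ecv)$postings, fs_idx$postings)
  dup <- c(fs_corpus[1], fs_corpus[1])
  expect_error(build_index(dup, ecv), "duplicate record id")
})

test_that("the carbon keyword scenario separates by manipulated variable", {
  idx <- build_index(generate_corpus(corpus_config(preset = "carbon-intro"), ecv), ecv)
  r_text <- run_query(idx, facet_query(text = "carbon"))
  expect_length(r_text$ids, 4L)
  r_flt <- refine(r_text, filters = list(
    "method/manipulated_variable" = "elevated carbon dioxide concentration"))
  expect_identical(r_flt$ids, "carbon-co2")
  # the counts on the unfiltered result announce the discriminating value
  expect_identical(
    unname(r_text$counts[["method/manipulated_variable"]]["elevated carbon dioxide concentration"]),
    1L)
})

test_that("the interaction filter separates parasitism from symbiosis", {
  idx <- build_index(generate_corpus(corpus_config(preset = "fungi-interaction"), ecv), ecv)
  r <- run_query(idx, facet_query(interaction = list(
    partner_a = "Fungi", partner_b = "Plantae",
    direction = "Affects", quality = "Antagonism")))
  expect_identical(r$ids, "fungi-parasitism")
  # the equivalent inverse phrasing selects the same record
  r_inv <- run_query(idx, facet_query(interaction = list(
    partner_a = "Plantae", partner_b = "Fungi",
    direction = "Is Affected By", quality = "Antagonism")))
  expect_identical(r_inv$ids, "fungi-parasitism")
  # Mutual matches either partner order
  r_mut <- run_query(idx, facet_query(interaction = list(
    partner_a = "Plantae", partner_b = "Fungi", direction = "Mutual")))
  expect_identical(r_mut$ids, "fungi-symbiosis")
})

test_that("hierarchy soundness: a filter on t matches t and descendants only", {
  for (tid in c("geo-period-quaternary", "geo-era-cenozoic",
                "sphere-layer-hydrosphere")) {
    t <- vocab_term(ecv, tid)
    path <- if (startsWith(tid, "geo")) paste0("time/geological/",
                                               sub("geo-([a-z]+)-.*", "\\1", tid))
            else "sphere/layer"
    got <- run_query(fs_idx, facet_query(filters = stats::setNames(list(t$label), path)))$ids
    want_keys <- c(tid, vapply(descendants(ecv, tid), `[[`, "", "id"))
    want <- names(Filter(function(v) any(want_keys %in% unlist(v)), fs_vals))
    expect_identical(got, sort(want))
  }
})

test_that("query() matches a record-by-record linear scan for random queries", {
  set.seed(77)
  texts <- lapply(fs_corpus, function(r)
    ecofacet:::tokenize(c(r$general$title, r$general$abstract)))
  names(texts) <- names(fs_vals)
  ints <- fs_idx$interactions
  for (k in 1:60) {
    q <- random_query(ecv)
    got <- run_query(fs_idx, q)$ids
    want <- names(Filter(function(rid) {
      if (!is.null(q$text) && !all(ecofacet:::tokenize(q$text) %in% texts[[rid]]))
        return(FALSE)
      oracle_match(fs_vals[[rid]], ints[[rid]], ecv, q)
    }, stats::setNames(as.list(names(fs_vals)), names(fs_vals))))
    # the matched sets must agree exactly; ordering is score-based for text
    expect_identical(sort(got), sort(want))
    if (is.null(q$text)) expect_identical(got, sort(want))
  }
})

test_that("refinement is equivalent, commutative, idempotent and monotone", {
  set.seed(88)
  all_r <- run_query(fs_idx, facet_query())
  for (k in 1:15) {
    qa <- random_query(ecv); qb <- random_query(ecv)
    fa <- list(path = qa$filters[[1]]$path, values = qa$filters[[1]]$values)
    fb <- list(path = qb$filters[[1]]$path, values = qb$filters[[1]]$values)
    ra <- refine(all_r, filters = list(fa))
    # refine(all-records, f) == query(f)
    expect_identical(ra$ids,
                     run_query(fs_idx, facet_query(filters = list(fa)))$ids)
    # commutative
    expect_identical(refine(ra, filters = list(fb))$ids,
                     refine(refine(all_r, filters = list(fb)),
                            filters = list(fa))$ids)
    # idempotent
    expect_identical(refine(ra, filters = list(fa))$ids, ra$ids)
    # monotone non-increasing
    expect_lte(length(refine(ra, filters = list(fb))$ids), length(ra$ids))
  }
})

test_that("facet counts equal a brute-force recount (multi-select semantics)", {
  set.seed(99)
  for (k in 1:10) {
    q <- random_query(ecv)
    res <- run_query(fs_idx, q)
    for (path in names(res$counts)) {
      q_rest <- q; q_rest$filters <- Filter(function(cl) cl$path != path, q$filters)
      base <- run_query(fs_idx, q_rest)$ids
      recount <- integer()
      for (rid in base)
        for (k2 in unique(fs_vals[[rid]][[path]])) {
          lab <- if (startsWith(k2, "txt:")) sub("^txt:", "", k2)
                 else ecv$terms[[k2]]$label
          recount[lab] <- (if (lab %in% names(recount)) recount[[lab]] else 0L) + 1L
        }
      expect_identical(sort(res$counts[[path]][order(names(res$counts[[path]]))]),
                       sort(recount[order(names(recount))]))
    }
  }
})

test_that("scale-range filters respect the ordered class tables", {
  r <- run_query(fs_idx, facet_query(scale_range = list(
    field = "time/resolution", min = "Hour", max = "Day")))
  want <- names(Filter(function(v) {
    k <- v[["time/resolution"]]
    !is.null(k) && ecv$terms[[k[1]]]$label %in% c("Hour", "Day")
  }, fs_vals))
  expect_identical(r$ids, sort(want))
  expect_error(run_query(fs_idx, facet_query(scale_range = list(
    field = "time/resolution", min = "Nanosecond"))), "ordered scale")
})

test_that("unknown fields and unknown closed values are rejected", {
  expect_error(facet_query(filters = list("no/such" = "x")), "unknown field")
  expect_error(run_query(fs_idx, facet_query(filters = list(
    "method/approach" = "Telepathic"))), "unknown value")
})
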