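test_that("packaged geological subtree matches the chart rank counts", {
  for (rk in names(GEO_RANKS))
    expect_length(terms_at(ecv, paste0("time/geological/", rk)), GEO_RANKS[[rk]])
  expect_setequal(
    vapply(terms_at(ecv, "time/geological/eon"), `[[`, "", "label"),
    c("Phanerozoic", "Precambrian", "Proterozoic", "Archean", "Hadean"))
})

test_that("terms_at returns canonical order and rejects unknown paths", {
  expect_identical(vapply(terms_at(ecv, "space/scale"), `[[`, "", "label"),
                   c("Point", "Plot", "Region", "Continent", "Global"))
  err <- expect_error(terms_at(ecv, "no/such/path"), "valid paths")
  expect_match(conditionMessage(err), "space/scale")
  # registered path that simply has no terms yet -> empty list, no error
  empty <- load_tsv(character())
  expect_length(empty$terms, 0L)
  expect_identical(terms_at(empty, "space/scale"), list())
})

test_that("term-table load errors name the offending term", {
  expect_error(load_tsv(c(
    "a\tA\tprocess/name\t\td\t\tcore\t\t\t\t",
    "a\tB\tprocess/name\t\td\t\tcore\t\t\t\t")), "duplicate term id a")
  expect_error(load_tsv(
    "a\tA\tprocess/name\tnope\td\t\tcore\t\t\t\t"), "unknown id nope")
  expect_error(load_tsv(
    "a\tA\tprocess/name\ta\td\t\tcore\t\t\t\t"), "cycle.*\\ba\\b")
  expect_error(load_tsv(c(
    "a\tA\tprocess/name\tb\td\t\tcore\t\t\t\t",
    "b\tB\tprocess/name\ta\td\t\tcore\t\t\t\t")), "cycle")
})

test_that("ancestors follows the packaged hierarchy (independent table oracle)", {
  # oracle: follow parent_id pointers straight from the shipped TSV
  tsv <- utils::read.delim(
    system.file("extdata", "vocabulary", "geological.tsv", package = "ecofacet"),
    comment.char = "#", stringsAsFactors = FALSE)
  chain_from_table <- function(id) {
    out <- character()
    repeat {
      p <- tsv$parent_id[tsv$id == id]
      if (!nzchar(p)) break
      out <- c(out, p); id <- p
    }
    out
  }
  hol <- resolve_term(ecv, "Holocene", "time/geological")
  expect_identical(vapply(ancestors(ecv, hol$id), `[[`, "", "id"),
                   chain_from_table(hol$id))
  expect_identical(vapply(ancestors(ecv, hol$id), `[[`, "", "label"),
                   c("Quaternary", "Cenozoic", "Phanerozoic"))
  # a root eon has no ancestors
  expect_length(ancestors(ecv, "geo-eon-hadean"), 0L)
  expect_error(ancestors(ecv, "no-such-id"), "unknown term id")
})

test_that("descendants matches forced counts and the rank arithmetic", {
  syn <- load_tsv(c(
    "e1\tEra One\ttime/geological/era\t\td\t\tcore\t\t\t\t",
    sprintf("p%d\tPeriod %d\ttime/geological/period\te1\td\t\tcore\t\t\t\t", 1:3, 1:3),
    sprintf("ep%d\tEpoch %d\ttime/geological/epoch\tp%d\td\t\tcore\t\t\t\t",
            1:6, 1:6, rep(1:3, each = 2))))
  expect_length(descendants(syn, "e1"), 9L)
  expect_length(descendants(syn, "ep1"), 0L)
  # all eon roots together dominate every finer-rank term exactly once
  eons <- vapply(terms_at(ecv, "time/geological/eon"), `[[`, "", "id")
  expect_identical(sum(vapply(eons, function(e) length(descendants(ecv, e)), 0L)),
                   sum(GEO_RANKS[c("era", "period", "epoch", "age")]))
})

test_that("descendants and ancestors are mutually consistent (exhaustive)", {
  geo <- Filter(function(t) startsWith(t$facet_path, "time/geological"),
                ecv$terms)
  for (t in geo) {
    for (d in descendants(ecv, t$id))
      expect_true(t$id %in% vapply(ancestors(ecv, d$id), `[[`, "", "id"))
    for (a in ancestors(ecv, t$id))
      expect_true(t$id %in% vapply(descendants(ecv, a$id), `[[`, "", "id"))
  }
})

test_that("suggest ranks prefix matches on labels and synonyms", {
  qual <- vapply(suggest(ecv, "process/interaction/quality", "A"), `[[`, "", "label")
  expect_true(all(c("Amensalism", "Antagonism") %in% qual))
  # synonym hit: element symbols carry full names as synonyms
  expect_true("C" %in% vapply(suggest(ecv, "chemical/element", "carb"), `[[`, "", "label"))
  # empty prefix returns the whole field, ranked; nonsense returns nothing
  expect_length(suggest(ecv, "method/approach", ""), 3L)
  expect_length(suggest(ecv, "method/approach", "zzz"), 0L)
  # candidates rank after core terms
  v2 <- propose_term(ecv, "Ablation", "process/name")
  s <- suggest(v2, "process/name", "a")
  expect_false(is.unsorted(match(vapply(s, `[[`, "", "status"),
                                 c("core", "candidate"))))
  expect_true("Ablation" %in% vapply(s, `[[`, "", "label"))
})

test_that("propose_term respects the open/closed field contract", {
  v2 <- propose_term(ecv, "mycorrhization", "process/name")
  t <- vocab_term(v2, attr(v2, "term_id"))
  expect_identical(t$status, "candidate")
  expect_identical(t$label, "mycorrhization")
  expect_error(propose_term(ecv, "Mars", "space/continent"), "closed")
  expect_error(propose_term(ecv, "Troposphere", "sphere/layer/atmosphere"), "closed")
  err <- expect_error(propose_term(ecv, "Speciation", "process/name"),
                      "already exists")
  expect_match(conditionMessage(err), "process-name-speciation")
  expect_error(propose_term(ecv, "  ", "process/name"), "non-empty")
})

test_that("curation: accept, merge redirect, reject", {
  v2 <- propose_term(ecv, "N-fixation", "process/name")
  id <- attr(v2, "term_id")
  va <- curate_term(v2, id, "accept")
  expect_identical(vocab_term(va, id)$status, "core")

  tgt <- resolve_term(ecv, "Nitrogen fixation", "process/name")$id
  vm <- curate_term(v2, id, "merge", target_id = tgt)
  expect_identical(vocab_term(vm, id)$id, tgt)            # id lookup redirects
  expect_identical(resolve_term(vm, "N-fixation", "process/name")$id, tgt)
  expect_true("N-fixation" %in% vocab_term(vm, tgt)$synonyms)
  # ancestors of a deprecated term are computed on its merge target
  expect_identical(ancestors(vm, id), ancestors(vm, tgt))

  vr <- curate_term(v2, id, "reject")
  expect_error(vocab_term(vr, id), "unknown term id")

  expect_error(curate_term(ecv, "process-name-speciation", "accept"),
               "only candidate")
  expect_error(curate_term(v2, id, "merge", target_id = id), "core term")
})

test_that("randomized propose/curate sequences preserve all invariants", {
  set.seed(404)
  v <- ecv
  pool <- character()
  open_paths <- c("process/name", "chemical/compound", "method/variable")
  for (i in 1:40) {
    act <- sample(c("propose", "accept", "merge", "reject"), 1)
    if (act == "propose" || !length(pool)) {
      v2 <- try(propose_term(v, paste0("term-", i), sample(open_paths, 1)),
                silent = TRUE)
      if (!inherits(v2, "try-error")) { v <- v2; pool <- c(pool, attr(v2, "term_id")) }
    } else {
      id <- sample(pool, 1); pool <- setdiff(pool, id)
      v <- switch(act,
        accept = curate_term(v, id, "accept"),
        reject = curate_term(v, id, "reject"),
        merge = curate_term(v, id, "merge",
                            target_id = resolve_term(v, "Speciation", "process/name")$id))
    }
    expect_no_error(ecofacet:::validate_vocabulary(v))
  }
})
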