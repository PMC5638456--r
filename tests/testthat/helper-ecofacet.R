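# shared fixtures: the packaged vocabulary is loaded once per test run
ecv <- default_vocabulary()

GEO_RANKS <- c(eon = 5L, era = 10L, period = 22L, epoch = 34L, age = 98L)

# write a term table to a temp file and load it
load_tsv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("id\tlabel\tfacet_path\tparent_id\tdefinition\turi\tstatus\tsynonyms\tord\tnum_lo\tnum_hi",
               lines), f)
  load_vocabulary(f)
}

# minimal valid record
minimal_record <- function(id = "m1", ...) {
  annotation_record(id, general_info("A title", parties = list(party("P. Erson"))),
                    ...)
}

# independent per-record query oracle: documented semantics, no index
oracle_match <- function(rec_vals, rec_ints, vocab, q) {
  # text clause handled by caller (needs title/abstract)
  for (cl in q$filters) {
    keys <- vapply(cl$values, function(v)
      ecofacet:::filter_key(vocab, cl$path, v), "")
    vals <- rec_vals[[cl$path]]
    if (is.null(vals)) return(FALSE)
    expanded <- unlist(lapply(vals, function(k) {
      if (startsWith(k, "txt:")) k
      else c(k, vapply(ancestors(vocab, k), `[[`, "", "id"))
    }))
    if (!any(keys %in% expanded)) return(FALSE)
  }
  if (!is.null(q$interaction)) {
    spec <- ecofacet:::canon_int_spec(vocab, q$interaction)
    if (is.null(rec_ints) ||
        !any(vapply(rec_ints, ecofacet:::int_match, NA, spec = spec)))
      return(FALSE)
  }
  TRUE
}
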