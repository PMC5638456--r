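# Faceted search: inverted index with hierarchy expansion, combined
# full-text + filter queries, incremental refinement and facet value counts.
# Semantics: AND across distinct fields and the text clause, OR among the
# selected values of one field; Mutual interactions match either partner
# order; deterministic tie-break by record id.

tokenize <- function(x) {
  t <- strsplit(tolower(paste(x, collapse = " ")), "[^a-z0-9]+")[[1]]
  t[nzchar(t)]
}

# canonical posting key for a resolved term reference
term_key <- function(ref) {
  if (is.null(ref)) return(NULL)
  if (!is.null(ref$id)) ref$id else paste0("txt:", norm_label(ref$label))
}

ORDERED_SCALE_FIELDS <- c("time/resolution", "time/extent", "space/resolution",
                          "space/extent", "sphere/organization", "method/context")

# direction read a -> b; "Is Affected By" is stored as the inverse "Affects",
# Mutual keeps an unordered partner pair
canon_interaction <- function(i) {
  dir <- if (is.null(i$direction)) NA_character_ else i$direction$label
  a <- term_key(i$partner_a); b <- term_key(i$partner_b)
  if (identical(dir, "Is Affected By")) { tmp <- a; a <- b; b <- tmp; dir <- "Affects" }
  list(name = term_key(i$name), a = a, b = b, dir = dir,
       quality = term_key(i$quality))
}

#' Build a faceted-search index over a record corpus
#'
#' Postings are hierarchy-expanded: a record annotated with a term is
#' indexed under that term and all its vocabulary ancestors, so filtering on
#' e.g. a geological period retrieves records annotated with any of its
#' epochs or ages. Title and abstract feed a token text index; ordered
#' scales (time/space resolution and extent, organization level, method
#' context) additionally get rank side-tables for range filters.
#'
#' @param records list of valid \code{eco_record}s (unique ids).
#' @inheritParams validate_record
#' @return an object of class \code{eco_index}.
#' @export
build_index <- function(records, vocab = default_vocabulary()) {
  ids <- vapply(records, `[[`, "", "record_id")
  if (anyDuplicated(ids))
    stop("duplicate record id in corpus: ", ids[duplicated(ids)][1])
  postings <- list(); direct <- list(); text <- list()
  interactions <- list(); scale_ord <- list()
  anc_cache <- new.env(parent = emptyenv())
  expand <- function(key) {
    if (startsWith(key, "txt:")) return(key)
    hit <- anc_cache[[key]]
    if (is.null(hit)) {
      hit <- c(key, vapply(ancestors(vocab, key), `[[`, "", "id"))
      anc_cache[[key]] <- hit
    }
    hit
  }
  for (rec in records) {
    rid <- rec$record_id
    rr <- resolve_terms(rec, vocab)  # validates; stops on invalid records
    vals <- record_term_values(rr, vocab)
    direct[[rid]] <- vals
    for (path in names(vals)) {
      for (key in unique(vals[[path]])) {
        for (k in expand(key)) {
          postings[[path]][[k]] <- c(postings[[path]][[k]], rid)
        }
      }
      if (path %in% ORDERED_SCALE_FIELDS) {
        t <- vocab$terms[[vals[[path]][1]]]
        if (!is.null(t) && !is.na(t$ord)) scale_ord[[path]][[rid]] <- t$ord
      }
    }
    for (tok in tokenize(c(rr$general$title, rr$general$abstract))) {
      cur <- text[[tok]]
      if (is.null(cur)) cur <- integer()
      cur[rid] <- (if (rid %in% names(cur)) cur[[rid]] else 0L) + 1L
      text[[tok]] <- cur
    }
    if (!is.null(rr$process) && length(rr$process$interactions))
      interactions[[rid]] <- lapply(rr$process$interactions, canon_interaction)
  }
  structure(list(ids = sort(ids), postings = postings, direct = direct,
                 text = text, interactions = interactions,
                 scale_ord = scale_ord, vocab = vocab,
                 n = length(records)), class = "eco_index")
}

#' Construct a query
#'
#' @param text optional full-text clause over title and abstract; all tokens
#'   must occur (conjunction with the filters).
#' @param filters filter clauses: a named list mapping field paths to one or
#'   more selected values (OR within a field), or a list of
#'   \code{list(path=, values=)} clauses.
#' @param interaction optional interaction pattern, any subset of
#'   \code{list(name=, partner_a=, partner_b=, direction=, quality=)},
#'   matched jointly against single interaction entries.
#' @param scale_range optional \code{list(field=, min=, max=)} over an
#'   ordered scale field, bounds inclusive by class label.
#' @return an object of class \code{eco_query}.
#' @export
facet_query <- function(text = NULL, filters = list(), interaction = NULL,
                        scale_range = NULL) {
  cl <- list()
  if (length(filters)) {
    if (!is.null(names(filters)) && any(nzchar(names(filters)))) {
      for (p in names(filters))
        cl[[length(cl) + 1L]] <- list(path = p,
                                      values = as.character(unlist(filters[[p]])))
    } else cl <- filters
  }
  for (c0 in cl) registry_field(c0$path)  # errors on unknown field
  structure(list(text = text, filters = cl, interaction = interaction,
                 scale_range = scale_range), class = "eco_query")
}

# map one user-facing filter value to its posting key; closed fields reject
# unknown values
filter_key <- function(vocab, path, value) {
  f <- registry_field(path)
  t <- resolve_term(vocab, value, f$closed_list_ref)
  if (!is.null(t)) return(t$id)
  if (f$kind == "closed_term")
    stop("unknown value '", value, "' for closed field ", path)
  paste0("txt:", norm_label(value))
}

scale_bound <- function(vocab, field, label) {
  f <- registry_field(field)
  t <- resolve_term(vocab, label, f$closed_list_ref)
  if (is.null(t) || is.na(t$ord))
    stop("'", label, "' is not a class of the ordered scale ", f$closed_list_ref)
  t$ord
}

# interaction spec in canonical key form
canon_int_spec <- function(vocab, spec) {
  g <- function(slot, path) {
    if (is.null(spec[[slot]])) return(NULL)
    t <- resolve_term(vocab, spec[[slot]], path)
    if (is.null(t)) paste0("txt:", norm_label(ref_label(spec[[slot]]))) else t$id
  }
  dir <- if (is.null(spec$direction)) NULL else {
    t <- resolve_term(vocab, spec$direction, "process/interaction/direction")
    if (is.null(t)) stop("unknown interaction direction: ", spec$direction)
    t$label
  }
  out <- list(name = g("name", "process/interaction/name"),
              a = g("partner_a", "organism/kingdom"),
              b = g("partner_b", "organism/kingdom"),
              dir = dir, quality = g("quality", "process/interaction/quality"))
  if (identical(out$dir, "Is Affected By")) {
    tmp <- out$a; out$a <- out$b; out$b <- tmp; out$dir <- "Affects"
  }
  out
}

# does one stored (canonical) interaction tuple satisfy the spec?
int_match <- function(tuple, spec) {
  eqk <- function(x, y) is.null(y) || (!is.null(x) && identical(x, y))
  if (!eqk(tuple$name, spec$name)) return(FALSE)
  if (!eqk(tuple$quality, spec$quality)) return(FALSE)
  mutual <- identical(tuple$dir, "Mutual")
  if (!is.null(spec$dir) && !identical(tuple$dir, spec$dir)) return(FALSE)
  if (mutual) {
    # either partner order
    want <- c(spec$a, spec$b); have <- c(tuple$a, tuple$b)
    return(all(want %in% have))
  }
  eqk(tuple$a, spec$a) && eqk(tuple$b, spec$b)
}

# core matcher; exclude_path implements multi-select facet counting
match_ids <- function(index, q, exclude_path = NULL) {
  ids <- index$ids
  if (!is.null(q$text) && nzchar(q$text)) {
    for (tok in tokenize(q$text)) {
      hit <- names(index$text[[tok]])
      ids <- intersect(ids, hit %||% character())
    }
  }
  for (cl in q$filters) {
    if (identical(cl$path, exclude_path)) next
    keys <- vapply(cl$values, function(v) filter_key(index$vocab, cl$path, v), "")
    hit <- unique(unlist(index$postings[[cl$path]][keys], use.names = FALSE))
    ids <- intersect(ids, hit %||% character())
  }
  if (!is.null(q$interaction)) {
    spec <- canon_int_spec(index$vocab, q$interaction)
    hit <- names(Filter(function(tuples) any(vapply(tuples, int_match, NA, spec = spec)),
                        index$interactions))
    ids <- intersect(ids, hit %||% character())
  }
  sr <- q$scale_range
  if (!is.null(sr)) {
    lo <- if (is.null(sr$min)) -Inf else scale_bound(index$vocab, sr$field, sr$min)
    hi <- if (is.null(sr$max)) Inf else scale_bound(index$vocab, sr$field, sr$max)
    tab <- index$scale_ord[[sr$field]]
    hit <- names(Filter(function(o) o >= lo && o <= hi, tab %||% list()))
    ids <- intersect(ids, hit %||% character())
  }
  sort(ids)
}

text_scores <- function(index, text, ids) {
  score <- stats::setNames(numeric(length(ids)), ids)
  for (tok in tokenize(text)) {
    tf <- index$text[[tok]]
    common <- intersect(ids, names(tf))
    score[common] <- score[common] + tf[common]
  }
  score
}

#' Run a faceted query
#'
#' Conjunction across the text clause and distinct filter fields,
#' disjunction among the selected values of one field. Results are ordered
#' by descending text score (term frequency over title + abstract) where a
#' text clause is present, then by record id.
#'
#' @param index an \code{eco_index}.
#' @param q an [facet_query()] object.
#' @return an \code{eco_result} with fields \code{ids}, \code{counts}
#'   (per-field value counts over the matched set, own-filter removed) and
#'   \code{query}.
#' @export
run_query <- function(index, q = facet_query()) {
  stopifnot(inherits(index, "eco_index"))
  if (!inherits(q, "eco_query")) stop("q must be built with facet_query()")
  ids <- match_ids(index, q)
  if (!is.null(q$text) && nzchar(q$text) && length(ids)) {
    sc <- text_scores(index, q$text, ids)
    ids <- ids[order(-sc[ids], ids)]
  }
  res <- structure(list(ids = ids, counts = NULL, query = q, index = index),
                   class = "eco_result")
  res$counts <- facet_counts(index, res)
  res
}

#' Per-field facet value counts for a result
#'
#' For every term-kinded field, counts of matched records per direct
#' annotation value. Counts use multi-select semantics: the field's own
#' filter clauses are removed before counting, so the numbers beside
#' unticked checkboxes stay informative.
#'
#' @inheritParams run_query
#' @param result an \code{eco_result} from this index.
#' @return named list: field path to named count vector (labels to counts).
#' @export
facet_counts <- function(index, result) {
  out <- list()
  reg <- field_registry()
  term_fields <- reg$path[reg$kind %in% c("closed_term", "open_term")]
  for (path in term_fields) {
    ids <- match_ids(index, result$query, exclude_path = path)
    cnt <- integer()
    for (rid in ids) {
      keys <- unique(index$direct[[rid]][[path]])
      for (k in keys) cnt[k] <- (if (k %in% names(cnt)) cnt[[k]] else 0L) + 1L
    }
    if (length(cnt)) {
      labs <- vapply(names(cnt), function(k) {
        if (startsWith(k, "txt:")) sub("^txt:", "", k)
        else index$vocab$terms[[k]]$label
      }, "")
      names(cnt) <- labs
      out[[path]] <- cnt[order(-cnt, names(cnt))]
    }
  }
  out
}

#' Refine a previous result with additional clauses
#'
#' Equivalent to re-running the combined query: refinement never changes
#' semantics, only accumulates filters. Monotone (the matched set shrinks or
#' stays equal), commutative and idempotent.
#'
#' @param result an \code{eco_result}.
#' @param filters,text,interaction,scale_range additional clauses, as in
#'   [facet_query()]; \code{NULL} leaves the previous clause untouched.
#' @return a new \code{eco_result}.
#' @export
refine <- function(result, filters = list(), text = NULL, interaction = NULL,
                   scale_range = NULL) {
  stopifnot(inherits(result, "eco_result"))
  q <- result$query
  extra <- facet_query(text = text, filters = filters,
                       interaction = interaction, scale_range = scale_range)
  for (cl in extra$filters) {
    dup <- any(vapply(q$filters, function(c0)
      identical(c0$path, cl$path) && setequal(c0$values, cl$values), NA))
    if (!isTRUE(dup)) q$filters[[length(q$filters) + 1L]] <- cl
  }
  if (!is.null(text)) q$text <- paste(c(q$text, text), collapse = " ")
  if (!is.null(interaction)) q$interaction <- interaction
  if (!is.null(scale_range)) q$scale_range <- scale_range
  run_query(result$index, q)
}

#' @export
print.eco_result <- function(x, ...) {
  cat("<eco_result> ", length(x$ids), " of ", x$index$n, " records matched\n",
      sep = "")
  if (length(x$ids)) cat("  ids: ", paste(utils::head(x$ids, 8), collapse = ", "),
                         if (length(x$ids) > 8) ", ..." else "", "\n", sep = "")
  shown <- utils::head(Filter(length, x$counts), 3)
  for (p in names(shown)) {
    v <- utils::head(shown[[p]], 4)
    cat("  ", p, ": ", paste(names(v), v, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.eco_index <- function(x, ...) {
  cat("<eco_index> ", x$n, " records, ", length(x$postings),
      " indexed fields, ", length(x$text), " text tokens\n", sep = "")
  invisible(x)
}
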