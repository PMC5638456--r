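#' @title Controlled vocabularies
#' @description Load, query, extend and curate the packaged controlled
#'   vocabularies, including the hierarchical geological time scale.
#' @name vocabulary
NULL

.ecofacet <- new.env(parent = emptyenv())

#' Normalize a label for matching
#'
#' Case-insensitive, whitespace-normalized label key. Used everywhere labels
#' are compared so that "Nitrogen  Fixation" and "nitrogen fixation" match.
#' @param x character vector of labels.
#' @return normalized character vector.
#' @keywords internal
norm_label <- function(x) tolower(gsub("[[:space:]]+", " ", trimws(x)))

slugify <- function(x) gsub("^-|-$", "", gsub("-+", "-", gsub("[^a-z0-9]+", "-", tolower(x))))

#' Load a vocabulary from term tables
#'
#' Reads one or more UTF-8 tab-separated term tables (columns \code{id},
#' \code{label}, \code{facet_path}, \code{parent_id}, \code{definition},
#' \code{uri}, \code{status}, \code{synonyms} (pipe-separated), \code{ord},
#' \code{num_lo}, \code{num_hi}; lines starting with \code{#!} carry
#' per-subtree provenance and version metadata). With no argument the
#' packaged default vocabulary is loaded.
#'
#' All structural invariants are enforced on load: unique ids, referential
#' integrity and acyclicity of \code{parent_id}, parents within the same
#' facet subtree, \code{deprecated} status if and only if \code{merged_into}
#' is present, unique label/facet-path pairs among non-deprecated terms, and
#' non-empty definitions for core terms of closed fields.
#'
#' @param source \code{NULL} for the packaged vocabulary, or a directory or
#'   character vector of term-table files.
#' @return an object of class \code{eco_vocabulary}.
#' @export
#' @examples
#' v <- load_vocabulary()
#' length(terms_at(v, "time/geological/eon"))
load_vocabulary <- function(source = NULL) {
  if (is.null(source))
    source <- system.file("extdata", "vocabulary", package = "ecofacet")
  files <- if (length(source) == 1L && dir.exists(source))
    list.files(source, pattern = "\\.tsv$", full.names = TRUE) else source
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("term table not found: ", paste(missing, collapse = ", "))
  prov <- character(); vers <- character(); tabs <- list()
  for (f in sort(files)) {
    lines <- readLines(f, encoding = "UTF-8")
    meta <- lines[startsWith(lines, "#!")]
    for (m in meta) {
      p <- strsplit(sub("^#!\\s*", "", m), "\t", fixed = TRUE)[[1]]
      if (p[1] == "provenance" && length(p) >= 3) prov[p[2]] <- p[3]
      if (p[1] == "version" && length(p) >= 3) vers[p[2]] <- p[3]
    }
    body <- lines[!startsWith(lines, "#!")]
    tab <- utils::read.delim(text = body, stringsAsFactors = FALSE,
                             quote = "", na.strings = NULL,
                             colClasses = "character")
    tabs[[f]] <- tab
  }
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL
  for (col in c("parent_id", "definition", "uri", "synonyms", "merged_into"))
    if (is.null(tab[[col]])) tab[[col]] <- rep("", nrow(tab))
  terms <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    structure(list(
      id = r$id, label = r$label, facet_path = r$facet_path,
      parent_id = if (nzchar(r$parent_id)) r$parent_id else NULL,
      definition = r$definition,
      uri = if (nzchar(r$uri)) r$uri else NULL,
      status = if (nzchar(r$status)) r$status else "core",
      synonyms = if (nzchar(r$synonyms)) strsplit(r$synonyms, "|", fixed = TRUE)[[1]] else character(),
      merged_into = if (nzchar(r$merged_into)) r$merged_into else NULL,
      ord = suppressWarnings(as.integer(r$ord)),
      num_lo = suppressWarnings(as.numeric(r$num_lo)),
      num_hi = suppressWarnings(as.numeric(r$num_hi))
    ), class = "eco_term")
  })
  if (length(terms)) names(terms) <- vapply(terms, `[[`, "", "id")
  vocab <- structure(list(
    terms = terms,
    version = paste0("ecofacet-vocab ",
                     paste(names(vers), unname(vers), sep = "=", collapse = "; ")),
    provenance = prov
  ), class = "eco_vocabulary")
  vocab <- vocab_reindex(vocab)
  validate_vocabulary(vocab)
  vocab
}

# rebuild derived lookup tables (children map, label index)
vocab_reindex <- function(vocab) {
  terms <- vocab$terms
  kids <- list()
  labkey <- character()
  for (t in terms) {
    if (!is.null(t$parent_id)) kids[[t$parent_id]] <- c(kids[[t$parent_id]], t$id)
    if (t$status != "deprecated") {
      for (l in c(t$label, t$synonyms)) {
        key <- paste0(t$facet_path, "|", norm_label(l))
        labkey[key] <- t$id
      }
    }
  }
  vocab$children <- kids
  vocab$label_index <- labkey
  vocab$term_paths <- sort(unique(vapply(terms, `[[`, "", "facet_path")))
  vocab
}

validate_vocabulary <- function(vocab) {
  terms <- vocab$terms
  ids <- vapply(terms, `[[`, "", "id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("vocabulary load error: duplicate term id ", dup[1])
  for (t in terms) {
    for (ref in c(t$parent_id, t$merged_into))
      if (!is.null(ref) && !ref %in% ids)
        stop("vocabulary load error: term ", t$id, " references unknown id ", ref)
    if (!t$status %in% c("core", "candidate", "deprecated"))
      stop("vocabulary load error: term ", t$id, " has unknown status ", t$status)
    if ((t$status == "deprecated") != !is.null(t$merged_into))
      stop("vocabulary load error: term ", t$id,
           ": status 'deprecated' and 'merged_into' must occur together")
    if (!is.null(t$parent_id)) {
      pp <- strsplit(terms[[t$parent_id]]$facet_path, "/")[[1]]
      cp <- strsplit(t$facet_path, "/")[[1]]
      k <- min(2L, length(pp), length(cp))
      if (!identical(pp[seq_len(k)], cp[seq_len(k)]))
        stop("vocabulary load error: term ", t$id,
             " has parent outside its facet subtree (", terms[[t$parent_id]]$facet_path, ")")
    }
  }
  # acyclicity of the parent graph
  for (t in terms) {
    seen <- character(); cur <- t$id
    while (!is.null(cur)) {
      if (cur %in% seen)
        stop("vocabulary load error: cycle in parent chain at term ", cur)
      seen <- c(seen, cur)
      cur <- terms[[cur]]$parent_id
    }
  }
  # label+path uniqueness among non-deprecated terms
  live <- Filter(function(t) t$status != "deprecated", terms)
  key <- vapply(live, function(t) paste0(t$facet_path, "|", norm_label(t$label)), "")
  if (anyDuplicated(key))
    stop("vocabulary load error: duplicate label in field ", key[duplicated(key)][1])
  # closed-field core terms need a definition
  closed <- closed_vocab_paths()
  for (t in live)
    if (t$status == "core" && !nzchar(t$definition) &&
        any(t$facet_path == closed | startsWith(t$facet_path, paste0(closed, "/"))))
      stop("vocabulary load error: core term ", t$id,
           " of closed field ", t$facet_path, " lacks a definition")
  invisible(vocab)
}

#' Packaged default vocabulary (cached)
#' @return the packaged \code{eco_vocabulary}, loaded once per session.
#' @export
default_vocabulary <- function() {
  if (is.null(.ecofacet$vocab)) .ecofacet$vocab <- load_vocabulary()
  .ecofacet$vocab
}

#' @export
print.eco_vocabulary <- function(x, ...) {
  st <- table(vapply(x$terms, `[[`, "", "status"))
  cat("<eco_vocabulary> ", length(x$terms), " terms (",
      paste(names(st), unname(st), sep = ": ", collapse = ", "), ")\n",
      "  version: ", x$version, "\n", sep = "")
  invisible(x)
}

#' @export
print.eco_term <- function(x, ...) {
  cat("<term> ", x$label, " [", x$id, "] @ ", x$facet_path,
      " (", x$status, ")\n", sep = "")
  if (nzchar(x$definition)) cat("  ", x$definition, "\n", sep = "")
  invisible(x)
}

# all facet paths known to the vocabulary or the field registry
vocab_paths <- function(vocab) {
  sort(unique(c(vapply(vocab$terms, `[[`, "", "facet_path"),
                stats::na.omit(field_registry()$closed_list_ref))))
}

#' Look up a term by id
#' @param vocab an \code{eco_vocabulary}.
#' @param term_id term id.
#' @param follow_merge follow \code{merged_into} redirects of deprecated terms.
#' @return an \code{eco_term}.
#' @export
vocab_term <- function(vocab, term_id, follow_merge = TRUE) {
  t <- vocab$terms[[term_id]]
  if (is.null(t)) stop("unknown term id: ", term_id)
  while (follow_merge && !is.null(t$merged_into)) t <- vocab$terms[[t$merged_into]]
  t
}

#' Terms registered at a facet path
#'
#' Non-deprecated terms whose \code{facet_path} equals \code{facet_path},
#' in canonical order (explicit \code{ord} where the list is ordered, then
#' label).
#' @inheritParams vocab_term
#' @param facet_path slash-separated vocabulary path, e.g.
#'   \code{"time/geological/period"}.
#' @return list of \code{eco_term}.
#' @export
terms_at <- function(vocab, facet_path) {
  paths <- vocab_paths(vocab)
  if (!facet_path %in% paths)
    stop("unknown facet path '", facet_path, "'; valid paths: ",
         paste(paths, collapse = ", "))
  hit <- Filter(function(t) t$facet_path == facet_path && t$status != "deprecated",
                vocab$terms)
  ord <- vapply(hit, function(t) if (is.na(t$ord)) .Machine$integer.max else t$ord, 0L)
  lab <- vapply(hit, `[[`, "", "label")
  unname(hit[order(ord, lab)])
}

#' Ancestors of a term, nearest first
#'
#' Follows \code{parent_id} to the subtree root. For a deprecated term the
#' chain is computed on its \code{merged_into} target.
#' @inheritParams vocab_term
#' @return list of \code{eco_term}, nearest ancestor first.
#' @export
ancestors <- function(vocab, term_id) {
  t <- vocab_term(vocab, term_id)
  out <- list()
  while (!is.null(t$parent_id)) {
    t <- vocab$terms[[t$parent_id]]
    out[[length(out) + 1L]] <- t
  }
  out
}

#' Descendants of a term (transitive closure of child links)
#' @inheritParams vocab_term
#' @return list of \code{eco_term}; excludes the term itself.
#' @export
descendants <- function(vocab, term_id) {
  t <- vocab_term(vocab, term_id)
  out <- character(); queue <- t$id
  while (length(queue)) {
    kids <- unlist(vocab$children[queue], use.names = FALSE)
    out <- c(out, kids)
    queue <- kids
  }
  unname(vocab$terms[sort(out)])
}

#' Autocompletion suggestions for a facet path
#'
#' Case-insensitive prefix match on labels and synonyms over the subtree
#' rooted at \code{facet_path}; core terms rank before candidates, ties are
#' alphabetical. An empty prefix returns all terms of the field, ranked.
#' @inheritParams terms_at
#' @param prefix string prefix (may be empty).
#' @return list of \code{eco_term}, ranked.
#' @export
suggest <- function(vocab, facet_path, prefix = "") {
  p <- norm_label(prefix)
  hit <- Filter(function(t) {
    t$status != "deprecated" &&
      (t$facet_path == facet_path || startsWith(t$facet_path, paste0(facet_path, "/"))) &&
      (p == "" || any(startsWith(norm_label(c(t$label, t$synonyms)), p)))
  }, vocab$terms)
  st <- vapply(hit, function(t) match(t$status, c("core", "candidate")), 0L)
  lab <- vapply(hit, `[[`, "", "label")
  unname(hit[order(st, lab)])
}

#' Propose a new candidate term for an open field
#'
#' Open (term-suggested) fields accept new vocabulary, which enters with
#' status \code{candidate} and awaits curation; content-restricted (closed)
#' fields reject proposals.
#' @inheritParams terms_at
#' @param label display label of the new term (non-empty).
#' @param definition optional free-text definition.
#' @param uri optional identifier linking the concept to an external
#'   vocabulary (ontology or thesaurus).
#' @return the updated vocabulary; the id of the new term is attached as
#'   attribute \code{"term_id"}.
#' @export
propose_term <- function(vocab, label, facet_path, definition = "", uri = NULL) {
  if (!nzchar(trimws(label))) stop("term label must be non-empty")
  if (!facet_path %in% vocab_paths(vocab))
    stop("unknown facet path '", facet_path, "'")
  if (!vocab_path_open(facet_path))
    stop("field '", facet_path, "' is content-restricted (closed); ",
         "new terms cannot be proposed for it")
  existing <- unname(vocab$label_index[paste0(facet_path, "|", norm_label(label))])
  if (!is.na(existing))
    stop("a non-deprecated term with label '", label, "' already exists in '",
         facet_path, "': ", existing)
  id <- paste0(gsub("/", "-", facet_path), "-", slugify(label))
  while (id %in% names(vocab$terms)) id <- paste0(id, "-x")
  term <- structure(list(
    id = id, label = trimws(label), facet_path = facet_path, parent_id = NULL,
    definition = definition, uri = uri, status = "candidate",
    synonyms = character(), merged_into = NULL,
    ord = NA_integer_, num_lo = NA_real_, num_hi = NA_real_), class = "eco_term")
  vocab$terms[[id]] <- term
  vocab <- vocab_reindex(vocab)
  structure(vocab, term_id = id)
}

#' Curate a candidate term
#'
#' \code{accept} promotes the candidate to a core term; \code{merge}
#' deprecates it, redirects it to a core target and adds its label to the
#' target's synonyms; \code{reject} removes it.
#' @inheritParams vocab_term
#' @param action one of \code{"accept"}, \code{"merge"}, \code{"reject"}.
#' @param target_id core term to merge into (for \code{action = "merge"}).
#' @return the updated vocabulary.
#' @export
curate_term <- function(vocab, term_id, action = c("accept", "merge", "reject"),
                        target_id = NULL) {
  action <- match.arg(action)
  t <- vocab_term(vocab, term_id, follow_merge = FALSE)
  if (t$status != "candidate")
    stop("only candidate terms can be curated; '", term_id, "' is ", t$status)
  if (action == "accept") {
    vocab$terms[[term_id]]$status <- "core"
  } else if (action == "merge") {
    if (is.null(target_id)) stop("merge requires a target_id")
    tgt <- vocab_term(vocab, target_id, follow_merge = FALSE)
    if (tgt$status != "core")
      stop("merge target must be a core term; '", target_id, "' is ", tgt$status)
    vocab$terms[[term_id]]$status <- "deprecated"
    vocab$terms[[term_id]]$merged_into <- target_id
    vocab$terms[[target_id]]$synonyms <-
      unique(c(tgt$synonyms, t$label))
  } else {
    vocab$terms[[term_id]] <- NULL
  }
  vocab <- vocab_reindex(vocab)
  validate_vocabulary(vocab)
  vocab
}

#' Resolve a term reference within a vocabulary subtree
#'
#' A reference may be a term id, a label or a synonym (case-insensitive,
#' whitespace-normalized). Merge redirects of deprecated terms are followed.
#' @inheritParams terms_at
#' @param ref term id or label.
#' @return an \code{eco_term}, or \code{NULL} if nothing matches.
#' @export
resolve_term <- function(vocab, ref, facet_path = NULL) {
  if (is.list(ref)) ref <- ref$id %||% ref$label
  t <- vocab$terms[[ref]]
  if (!is.null(t) &&
      (is.null(facet_path) || t$facet_path == facet_path ||
       startsWith(t$facet_path, paste0(facet_path, "/")))) {
    while (!is.null(t$merged_into)) t <- vocab$terms[[t$merged_into]]
    return(t)
  }
  all_paths <- vocab$term_paths
  paths <- if (is.null(facet_path)) all_paths else
    grep(paste0("^", facet_path, "(/|$)"), all_paths, value = TRUE)
  for (p in paths) {
    id <- unname(vocab$label_index[paste0(p, "|", norm_label(ref))])
    if (!is.na(id)) {
      t <- vocab$terms[[id]]
      while (!is.null(t$merged_into)) t <- vocab$terms[[t$merged_into]]
      return(t)
    }
  }
  NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a
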