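# Record validation and term normalization. Issues are data, not conditions:
# validate_record() returns a data.frame and never throws on bad content.

# Apply fn(ref, field_path) to every term reference in a record, replacing
# each reference with the return value. One walker backs validation,
# normalization and index extraction so the three can never disagree on
# where terms live.
map_term_refs <- function(record, fn) {
  # in-place slot update that never removes a NULL slot (assigning NULL into
  # a list would drop it and break structural round-trip identity)
  ms <- function(lst, slot, path) {
    if (!is.null(lst[[slot]])) lst[[slot]] <- fn(lst[[slot]], path)
    lst
  }
  ml <- function(lst, path) lapply(lst, function(r) fn(r, path))
  tf <- record$time
  if (!is.null(tf)) {
    tf <- ms(tf, "timezone", "time/timezone")
    for (rk in c("eon", "era", "period", "epoch", "age"))
      tf$geological <- ms(tf$geological, rk, paste0("time/geological/", rk))
    tf <- ms(tf, "resolution", "time/resolution")
    tf <- ms(tf, "extent", "time/extent")
    record$time <- tf
  }
  sp <- record$space
  if (!is.null(sp)) {
    sp$locations <- lapply(sp$locations, function(loc) {
      loc <- ms(loc, "type", "space/location/type")
      loc <- ms(loc, "country", "space/location/country")
      ms(loc, "continent", "space/location/continent")
    })
    sp <- ms(sp, "resolution", "space/resolution")
    sp <- ms(sp, "extent", "space/extent")
    record$space <- sp
  }
  sh <- record$sphere
  if (!is.null(sh)) {
    sh$layers <- ml(sh$layers, "sphere/layer")
    sh <- ms(sh, "organization", "sphere/organization")
    record$sphere <- sh
  }
  bi <- record$biome
  if (!is.null(bi)) {
    for (slot in c("latitudinal_zone", "altitudinal_zone", "moisture_regime",
                   "continentality", "physiognomy", "special_biome", "condition"))
      bi <- ms(bi, slot, paste0("biome/", slot))
    bi$usage <- ml(bi$usage, "biome/usage")
    record$biome <- bi
  }
  og <- record$organism
  if (!is.null(og)) {
    og$names <- lapply(og$names, function(n) ms(n, "code", "organism/name/code"))
    record$organism <- og
  }
  pr <- record$process
  if (!is.null(pr)) {
    pr$processes <- lapply(pr$processes, function(p) {
      p <- ms(p, "name", "process/process/name")
      p$involved <- ml(p$involved, "process/process/involved")
      ms(p, "characterization", "process/process/characterization")
    })
    pr$interactions <- lapply(pr$interactions, function(i) {
      i <- ms(i, "name", "process/interaction/name")
      i <- ms(i, "partner_a", "process/interaction/partner_a")
      i <- ms(i, "partner_b", "process/interaction/partner_b")
      i <- ms(i, "direction", "process/interaction/direction")
      ms(i, "quality", "process/interaction/quality")
    })
    record$process <- pr
  }
  ch <- record$chemical
  if (!is.null(ch)) {
    ch$elements <- ml(ch$elements, "chemical/element")
    ch$compounds <- ml(ch$compounds, "chemical/compound")
    ch$functions <- ml(ch$functions, "chemical/function")
    record$chemical <- ch
  }
  me <- record$method
  if (!is.null(me)) {
    me <- ms(me, "approach", "method/approach")
    me <- ms(me, "context", "method/context")
    me$manipulated_variables <- ml(me$manipulated_variables, "method/manipulated_variable")
    record$method <- me
  }
  record
}

ref_label <- function(ref) {
  if (is.list(ref)) as.character(ref$label %||% ref$id) else as.character(ref)
}

#' Parse a reduced-precision ISO 8601 timestamp
#'
#' Accepted forms: year, year-month, date, and date-time (minutes or
#' seconds). The stated precision is preserved; the value denotes the full
#' interval it covers (a bare year means that whole year), which is what the
#' ordering check and range queries use.
#' @param x timestamp string.
#' @return list with \code{lo}, \code{hi} (POSIXct, UTC) and
#'   \code{precision}, or \code{NULL} if the string does not parse.
#' @export
parse_timestamp <- function(x) {
  if (is.null(x) || !is.character(x) || length(x) != 1L) return(NULL)
  pats <- c(year = "^\\d{4}$", month = "^\\d{4}-\\d{2}$",
            day = "^\\d{4}-\\d{2}-\\d{2}$",
            minute = "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}$",
            second = "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}$")
  prec <- names(pats)[vapply(pats, grepl, NA, x = x)]
  if (!length(prec)) return(NULL)
  prec <- prec[1]
  lo_str <- switch(prec, year = paste0(x, "-01-01 00:00:00"),
                   month = paste0(x, "-01 00:00:00"),
                   day = paste0(x, " 00:00:00"),
                   minute = paste0(sub("T", " ", x), ":00"),
                   second = sub("T", " ", x))
  lo <- tryCatch(as.POSIXct(lo_str, tz = "UTC"), error = function(e) NA)
  if (is.na(lo)) return(NULL)
  hi <- switch(prec,
    year = as.POSIXct(paste0(as.integer(x) + 1L, "-01-01"), tz = "UTC"),
    month = {
      y <- as.integer(substr(x, 1, 4)); m <- as.integer(substr(x, 6, 7))
      if (is.na(m) || m < 1 || m > 12) return(NULL)
      if (m == 12) as.POSIXct(paste0(y + 1, "-01-01"), tz = "UTC")
      else as.POSIXct(sprintf("%d-%02d-01", y, m + 1), tz = "UTC")
    },
    day = lo + 86400, minute = lo + 60, second = lo + 1)
  # reject e.g. 2001-02-30, which POSIXct would silently roll over
  if (prec %in% c("day", "minute", "second") &&
      format(lo, "%Y-%m-%d") != substr(x, 1, 10)) return(NULL)
  list(lo = lo, hi = hi - 1, precision = prec)
}

#' Validate an annotation record
#'
#' Checks every structural invariant of the record against the field
#' registry and the vocabulary: mandatory general metadata, timestamp syntax
#' and ordering (interval semantics), geological rank consistency (each
#' finer rank must be nested in each coarser one), coordinate and bounding
#' box ranges, taxonomy rank keys, and term resolution. Unknown terms in
#' closed fields are errors; unknown terms in open fields are warnings (the
#' hook for an implicit candidate proposal). The spatial
#' resolution-not-above-extent rule is a warning, so single-point edge cases
#' do not hard-fail.
#'
#' @param record an \code{eco_record}.
#' @param vocab an \code{eco_vocabulary}.
#' @return data.frame with columns \code{severity} (\code{error} or
#'   \code{warning}), \code{field}, \code{message}, \code{value}; zero rows
#'   for a fully valid record.
#' @export
validate_record <- function(record, vocab = default_vocabulary()) {
  iss <- list()
  add <- function(severity, field, message, value = "") {
    iss[[length(iss) + 1L]] <<- data.frame(severity = severity, field = field,
                                           message = message,
                                           value = as.character(value),
                                           stringsAsFactors = FALSE)
  }
  if (is.null(record$record_id) || !nzchar(record$record_id))
    add("error", "record_id", "record_id must be non-empty")
  g <- record$general
  if (is.null(g)) add("error", "general", "general block is mandatory")
  else {
    if (is.null(g$title) || !nzchar(trimws(g$title)))
      add("error", "general/title", "title must be non-empty")
    if (!length(g$parties))
      add("error", "general/party", "at least one responsible party is required")
    if (!is.null(g$access) && !isTRUE(g$access$type %in% c("url", "file_path", "database_id")))
      add("error", "general/access", "access type must be url, file_path or database_id",
          g$access$type %||% "")
  }
  # term resolution via the shared walker
  map_term_refs(record, function(ref, path) {
    f <- registry_field(path)
    t <- resolve_term(vocab, ref, f$closed_list_ref)
    if (is.null(t)) {
      if (f$kind == "closed_term")
        add("error", path, "unknown term in closed field", ref_label(ref))
      else
        add("warning", path, "term not in vocabulary; consider propose_term()",
            ref_label(ref))
    }
    ref
  })
  tf <- record$time
  if (!is.null(tf)) {
    ts <- list()
    for (slot in c("start", "end")) {
      if (!is.null(tf[[slot]])) {
        ts[[slot]] <- parse_timestamp(tf[[slot]])
        if (is.null(ts[[slot]]))
          add("error", paste0("time/", slot), "not a valid ISO 8601 timestamp",
              tf[[slot]])
      }
    }
    if (!is.null(ts$start) && !is.null(ts$end) && ts$start$lo > ts$end$hi)
      add("error", "time/start", "start must not be after end",
          paste(tf$start, ">", tf$end))
    # nested geological ranks: every finer term must descend from each coarser
    ranks <- c("eon", "era", "period", "epoch", "age")
    given <- Filter(Negate(is.null), lapply(ranks, function(rk) {
      r <- tf$geological[[rk]]
      if (is.null(r)) NULL
      else resolve_term(vocab, r, paste0("time/geological/", rk))
    }))
    if (length(given) > 1) {
      for (i in seq_along(given)[-1]) {
        anc <- vapply(ancestors(vocab, given[[i]]$id), `[[`, "", "id")
        for (j in seq_len(i - 1))
          if (!given[[j]]$id %in% anc)
            add("error", "time/geological",
                paste0("'", given[[i]]$label, "' is not nested in '",
                       given[[j]]$label, "'"), given[[i]]$label)
      }
    }
  }
  sp <- record$space
  if (!is.null(sp)) {
    bb <- sp$bounding_box
    if (!is.null(bb)) {
      num <- vapply(c("west", "south", "east", "north"),
                    function(k) is.numeric(bb[[k]]) && is.finite(bb[[k]]), NA)
      if (!all(num))
        add("error", "space/bounding_box", "west/south/east/north must be finite numbers")
      else {
        if (bb$south > bb$north || abs(bb$south) > 90 || abs(bb$north) > 90)
          add("error", "space/bounding_box", "latitudes must satisfy -90 <= south <= north <= 90",
              paste(bb$south, bb$north))
        if (abs(bb$west) > 180 || abs(bb$east) > 180)
          add("error", "space/bounding_box", "longitudes must lie in [-180, 180]",
              paste(bb$west, bb$east))
      }
    }
    for (p in sp$points) {
      if (!is.null(p$utm_zone)) {
        if (!grepl("^[0-9]{1,2}[C-HJ-NP-X]$", p$utm_zone))
          add("error", "space/point", "malformed UTM zone", p$utm_zone)
        if (!identical(p$datum %||% "WGS84", "WGS84"))
          add("error", "space/point", "UTM points must use the WGS84 datum",
              p$datum)
      } else {
        if (is.null(p$latitude) || is.null(p$longitude) ||
            abs(p$latitude) > 90 || abs(p$longitude) > 180)
          add("error", "space/point", "WGS84 point out of range",
              paste(p$latitude %||% NA, p$longitude %||% NA))
      }
    }
    res <- resolve_term(vocab, sp$resolution %||% "", "space/scale")
    ext <- resolve_term(vocab, sp$extent %||% "", "space/scale")
    if (!is.null(res) && !is.null(ext) && res$ord > ext$ord)
      add("warning", "space/resolution",
          "spatial resolution class is coarser than the extent class",
          paste(res$label, ">", ext$label))
  }
  og <- record$organism
  if (!is.null(og) && length(og$taxonomy)) {
    bad <- setdiff(names(og$taxonomy),
                   c("domain", "kingdom", "division_or_phylum", "class",
                     "order", "family", "genus"))
    if (length(bad))
      add("error", "organism/taxonomy", "unknown taxonomy rank key",
          paste(bad, collapse = ", "))
  }
  pr <- record$process
  if (!is.null(pr)) for (i in pr$interactions)
    if (is.null(i$partner_a) || is.null(i$partner_b) || is.null(i$direction))
      add("error", "process/interaction",
          "an interaction needs both partners and a direction")
  if (!length(iss))
    return(data.frame(severity = character(), field = character(),
                      message = character(), value = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, iss)
}

#' Is a record valid (no error-severity issues)?
#' @inheritParams validate_record
#' @return logical.
#' @export
is_valid_record <- function(record, vocab = default_vocabulary()) {
  !any(validate_record(record, vocab)$severity == "error")
}

#' Normalize all term references of a record
#'
#' Every term reference is replaced by its canonical form
#' \code{list(id, label, uri, status)}: synonyms are replaced by the
#' canonical term, deprecated terms by their \code{merged_into} target.
#' Open-field values not in the vocabulary stay as label-only references.
#' Idempotent.
#'
#' @inheritParams validate_record
#' @return the normalized \code{eco_record}.
#' @export
resolve_terms <- function(record, vocab = default_vocabulary()) {
  issues <- validate_record(record, vocab)
  if (any(issues$severity == "error"))
    stop("record does not validate; first error: ",
         issues$message[issues$severity == "error"][1], " [",
         issues$field[issues$severity == "error"][1], "]")
  out <- map_term_refs(record, function(ref, path) {
    f <- registry_field(path)
    t <- resolve_term(vocab, ref, f$closed_list_ref)
    if (is.null(t)) list(label = ref_label(ref))
    else list(id = t$id, label = t$label, uri = t$uri, status = t$status)
  })
  # canonical rank order so serialization round-trips are exact
  if (!is.null(out$time))
    out$time$geological <- out$time$geological[
      intersect(c("eon", "era", "period", "epoch", "age"),
                names(out$time$geological))]
  out
}

# canonical index keys for every term-kinded value of a record:
# term id when resolvable, otherwise "txt:<normalized label>" for open text
record_term_values <- function(record, vocab) {
  vals <- list()
  map_term_refs(record, function(ref, path) {
    f <- registry_field(path)
    t <- resolve_term(vocab, ref, f$closed_list_ref)
    key <- if (is.null(t)) paste0("txt:", norm_label(ref_label(ref))) else t$id
    vals[[path]] <<- c(vals[[path]], key)
    ref
  })
  vals
}
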