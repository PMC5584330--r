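#' @title Triple-pattern matching and endpoint replication
#' @description A minimal triple-pattern store with LIMIT/OFFSET paging
#'   (the `?s ?p ?o` query reduced to its algorithmic core) and a
#'   replication driver that mirrors a source store into a wiki in
#'   auto-advancing batches, restartable from a recorded offset.
#' @name replicator_store
NULL

#' Match a triple pattern against a store with stable paging
#'
#' Bound positions must match exactly; `NULL` positions are wildcards.
#' Results come in canonical order, so disjoint `[offset,
#' offset + limit)` windows partition the full result set -- the
#' property that makes batched replication sound. (Paging over an
#' endpoint without a total order is unsound; this store always
#' orders.)
#'
#' @param store an [rdf_triples] object.
#' @param s,p subject/predicate IRI, or `NULL` for a wildcard.
#' @param o object value (IRI or literal lexical form), or `NULL`.
#' @param limit maximum rows returned (`NULL` = no limit, else >= 1).
#' @param offset rows to skip from the start of the result (>= 0).
#' @return An [rdf_triples] object (window of the result).
#' @export
match_triples <- function(store, s = NULL, p = NULL, o = NULL,
                          limit = NULL, offset = 0L) {
  stopifnot(is.null(limit) || limit >= 1L, offset >= 0L)
  tbl <- canonicalize_triples(tibble::as_tibble(store)[triple_cols()])
  keep <- rep(TRUE, nrow(tbl))
  if (!is.null(s)) keep <- keep & tbl$subject == s
  if (!is.null(p)) keep <- keep & tbl$predicate == p
  if (!is.null(o)) keep <- keep & tbl$object == o
  tbl <- tbl[keep, , drop = FALSE]
  n <- nrow(tbl)
  if (offset >= n) {
    tbl <- tbl[0L, , drop = FALSE]
  } else {
    last <- if (is.null(limit)) n else min(n, offset + limit)
    tbl <- tbl[(offset + 1L):last, , drop = FALSE]
  }
  new_rdf_triples(tbl, prefixes = prefixes(store))
}

#' An in-memory triple-pattern source
#'
#' Wraps a triple set behind the fetch interface the replicator
#' consumes: `fetch(limit, offset)` returning one canonical-order page
#' of all triples.
#'
#' @param ts an [rdf_triples] object.
#' @return A `triple_source` object.
#' @export
memory_source <- function(ts) {
  # canonicalize once at construction; each fetch is then a plain slice
  tbl <- canonicalize_triples(tibble::as_tibble(ts)[triple_cols()])
  pfx <- prefixes(ts)
  structure(list(
    fetch = function(limit, offset) {
      n <- nrow(tbl)
      win <- if (offset >= n) tbl[0L, , drop = FALSE] else
        tbl[(offset + 1L):min(n, offset + limit), , drop = FALSE]
      new_rdf_triples(win, prefixes = pfx)
    },
    description = sprintf("in-memory source (%d triples)", nrow(ts))
  ), class = "triple_source")
}

#' A SPARQL-protocol triple-pattern source
#'
#' Adapter speaking the SPARQL protocol over HTTP: each fetch issues
#' `SELECT ?s ?p ?o WHERE { ?s ?p ?o } ORDER BY ?s ?p ?o LIMIT ...
#' OFFSET ...` and maps the JSON result bindings to triples. The
#' explicit ORDER BY imposes the stable total order that paging
#' requires; endpoints that page without one may return overlapping or
#' incomplete windows. Requires network access; intended for live
#' replication only.
#'
#' @param endpoint SPARQL endpoint URL.
#' @return A `triple_source` object.
#' @export
sparql_source <- function(endpoint) {
  structure(list(
    fetch = function(limit, offset) {
      q <- sprintf(
        "SELECT ?s ?p ?o WHERE { ?s ?p ?o } ORDER BY ?s ?p ?o LIMIT %d OFFSET %d",
        limit, offset)
      url <- paste0(endpoint, "?query=", utils::URLencode(q, reserved = TRUE),
                    "&format=json")
      res <- jsonlite::fromJSON(url, simplifyVector = FALSE)
      bindings <- res$results$bindings
      if (length(bindings) == 0L) return(rdf_triples())
      row <- function(b) {
        o <- b$o
        tibble::tibble(
          subject = b$s$value, predicate = b$p$value, object = o$value,
          object_type = if (identical(o$type, "literal") ||
                            identical(o$type, "typed-literal")) "literal" else "iri",
          datatype = o$datatype %||% NA_character_,
          language = o$`xml:lang` %||% NA_character_)
      }
      new_rdf_triples(canonicalize_triples(
        dplyr::bind_rows(lapply(bindings, row))))
    },
    description = paste("SPARQL endpoint", endpoint)
  ), class = "triple_source")
}

#' @export
print.triple_source <- function(x, ...) {
  cat("<triple_source:", x$description, ">\n")
  invisible(x)
}

#' An importing wiki session (replication sink)
#'
#' A mutable wiki a replicator can feed batches into: it accumulates a
#' site, a shared title index and the resolver configuration.
#'
#' @param cfg a [resolver_config()].
#' @return A `wiki_session` environment.
#' @export
wiki_session <- function(cfg = resolver_config()) {
  sess <- new.env(parent = emptyenv())
  sess$cfg <- cfg
  sess$site <- new_wiki_site(cfg = cfg)
  class(sess) <- "wiki_session"
  sess
}

#' Import a batch of triples into a session
#' @param sess a [wiki_session()].
#' @param ts an [rdf_triples] batch.
#' @param finalize run datatype inference and template synthesis after
#'   this batch; batch drivers pass `FALSE` and call
#'   [session_finalize()] once at the end.
#' @return The session, invisibly.
#' @export
session_import <- function(sess, ts, finalize = TRUE) {
  sess$site <- import_rdf(ts, cfg = sess$cfg, site = sess$site,
                          finalize = finalize)
  invisible(sess)
}

#' Finalize a session's site (datatype inference, template synthesis)
#' @param sess a [wiki_session()].
#' @return The session, invisibly.
#' @export
session_finalize <- function(sess) {
  sess$site <- synthesize_templates(infer_site_types(sess$site))
  invisible(sess)
}

#' @export
print.wiki_session <- function(x, ...) {
  cat("<wiki_session>\n")
  print(x$site)
  invisible(x)
}

#' Replicate a triple source into a wiki session in batches
#'
#' Repeatedly fetches all-wildcard pages of `batch_limit` triples from
#' the source, runs each batch through the import pipeline into the
#' sink, and advances the offset by the page size -- the batch-wise
#' mirror of an external store. A page shorter than the limit
#' (including an empty one) ends the run. A source failure mid-run
#' returns the state with `done = FALSE` and the last safe offset, so
#' the run can resume; passing a `max_batches` budget likewise leaves a
#' resumable state.
#'
#' @param source a `triple_source` (e.g. [memory_source()]).
#' @param sink a [wiki_session()], filled in place.
#' @param batch_limit triples per batch (>= 1).
#' @param state a `replication_state` from an earlier interrupted run,
#'   to resume from its recorded offset.
#' @param max_batches stop (resumably) after this many batches.
#' @return A `replication_state`: list with `offset`, `batch_limit`,
#'   `done`, and `batches` (fetches performed in this call).
#' @export
replicate_triples <- function(source, sink, batch_limit = 100L,
                              state = NULL, max_batches = Inf) {
  stopifnot(batch_limit >= 1L)
  offset <- if (is.null(state)) 0L else state$offset
  batches <- 0L
  done <- FALSE
  repeat {
    if (batches >= max_batches) break
    page <- tryCatch(source$fetch(limit = batch_limit, offset = offset),
                     error = function(e) e)
    if (inherits(page, "error")) {
      warning(sprintf("source failed at offset %d: %s; returning resumable state",
                      offset, conditionMessage(page)), call. = FALSE)
      break
    }
    batches <- batches + 1L
    if (nrow(page) > 0L) {
      session_import(sink, page, finalize = FALSE)
      offset <- offset + nrow(page)
    }
    if (nrow(page) < batch_limit) {
      done <- TRUE
      break
    }
  }
  session_finalize(sink)  # cheap one-shot recomputation; keeps the
                          # sink renderable even after an interrupt
  structure(list(offset = offset, batch_limit = batch_limit, done = done,
                 batches = batches), class = "replication_state")
}
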