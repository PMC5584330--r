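#' @title Wiki page model and import pipeline
#' @description Turns per-subject triple groups into wiki pages carrying
#'   property-value facts, infers SMW datatypes for properties from the
#'   XSD types observed in the data, synthesizes one template per
#'   rdf:type, and supports chunked imports and in-place merging.
#' @name page_builder
NULL

page_cols <- function() {
  c("title", "ns", "name", "equivalent_uri", "smw_type", "free_text",
    "template")
}

fact_cols <- function() {
  c("page", "property", "value_kind", "value", "datatype", "language")
}

spec_cols <- function() c("template", "param", "property")

empty_pages <- function() {
  tibble::tibble(title = character(), ns = character(), name = character(),
                 equivalent_uri = character(), smw_type = character(),
                 free_text = character(), template = character())
}

empty_facts <- function() {
  tibble::tibble(page = character(), property = character(),
                 value_kind = character(), value = character(),
                 datatype = character(), language = character())
}

empty_specs <- function() {
  tibble::tibble(template = character(), param = character(),
                 property = character())
}

new_wiki_site <- function(pages = empty_pages(), facts = empty_facts(),
                          specs = empty_specs(), index = title_index(),
                          prefixes = character(), cfg = resolver_config()) {
  structure(list(pages = sort_pages(pages), facts = sort_facts(facts),
                 specs = specs, index = index,
                 prefixes = normalize_prefixes(prefixes), cfg = cfg),
            class = "wiki_site")
}

sort_pages <- function(pages) {
  if (nrow(pages) == 0L) return(pages)
  ns_rank <- match(pages$ns, c("Main", "Property", "Template"))
  pages[radix_order(ns_rank, pages$name), , drop = FALSE]
}

sort_facts <- function(facts) {
  facts <- dplyr::distinct(facts)
  if (nrow(facts) == 0L) return(facts)
  facts[radix_order(facts$page, facts$property, facts$value,
                    facts$value_kind), , drop = FALSE]
}

#' @export
print.wiki_site <- function(x, ...) {
  cat(sprintf(
    "<wiki_site: %d pages (%d main, %d property, %d template), %d facts, %d template specs>\n",
    nrow(x$pages), sum(x$pages$ns == "Main"), sum(x$pages$ns == "Property"),
    sum(x$pages$ns == "Template"), nrow(x$facts),
    length(unique(x$specs$template))))
  invisible(x)
}

#' Build wiki pages from per-subject triple groups
#'
#' One page per subject resource. Predicates become Property-namespace
#' titles, IRI objects become page links (creating stub pages with full
#' equivalent URIs for referenced-but-subjectless resources, so links
#' never dangle), and literal objects are kept verbatim. rdf:type
#' statements are kept as ordinary facts under the configured type
#' property so export can reconstruct them. Every imported page carries
#' its subject IRI as its equivalent URI.
#'
#' @param groups a named list from [aggregate_by_subject()], or an
#'   [rdf_triples] object (aggregated internally).
#' @param cfg a [resolver_config()].
#' @param index a [title_index()], updated in place.
#' @param labels optional precomputed label table (named vector,
#'   uri -> label text). Defaults to the label table of `groups` itself;
#'   the chunked import pipeline passes the full-graph table so titles
#'   do not depend on the chunk partition.
#' @return A `wiki_site` object (property types not yet inferred; see
#'   [infer_site_types()]).
#' @export
build_pages <- function(groups, cfg = resolver_config(),
                        index = title_index(), labels = NULL) {
  ts <- if (inherits(groups, "rdf_triples") || is.data.frame(groups)) {
    groups
  } else {
    dplyr::bind_rows(lapply(groups, tibble::as_tibble))
  }
  tbl <- canonicalize_triples(tibble::as_tibble(ts)[triple_cols()])
  pfx <- if (inherits(groups, "rdf_triples")) prefixes(groups) else {
    do.call(c, c(list(character()), lapply(unname(groups), prefixes)))
  }
  if (is.null(labels)) labels <- label_table(tbl, cfg$label_properties)
  build_pages_tbl(tbl, pfx, cfg, index, labels)
}

# Worker over an already canonical triple table; the chunked import
# pipeline slices one canonical table and calls this per chunk.
build_pages_tbl <- function(tbl, pfx, cfg, index, labels) {
  if (nrow(tbl) == 0L) {
    return(new_wiki_site(index = index, prefixes = pfx, cfg = cfg))
  }

  subjects <- unique(tbl$subject)
  iri_obj <- tbl$object_type == "iri"
  objects <- setdiff(unique(tbl$object[iri_obj]), subjects)
  predicates <- unique(tbl$predicate)

  # rdf:type maps to the configured type property name; register it so
  # export can restore the original predicate URI.
  if (RDF_TYPE %in% predicates &&
      is.na(index_title_of(index, RDF_TYPE))) {
    disambiguate(cfg$type_property_name, RDF_TYPE, index, ns = "Property")
  }

  subj_titles <- resolve_uris(subjects, "Main", labels, cfg, index)
  obj_titles <- resolve_uris(objects, "Main", labels, cfg, index)
  pred_titles <- resolve_uris(predicates, "Property", labels, cfg, index)

  title_of <- stats::setNames(c(subj_titles, obj_titles, pred_titles),
                              c(subjects, objects, predicates))

  facts <- fast_tibble(list(
    page = unname(title_of[tbl$subject]),
    property = split_title(unname(title_of[tbl$predicate]))$name,
    value_kind = ifelse(iri_obj, "page", "literal"),
    value = ifelse(iri_obj, unname(title_of[tbl$object]), tbl$object),
    datatype = tbl$datatype,
    language = tbl$language
  ))

  counts <- table(facts$page)
  heavy <- counts[counts > cfg$fact_warn_threshold]
  if (length(heavy) > 0L) {
    warning(sprintf("%d page(s) hold more than %d facts (largest: '%s' with %d)",
                    length(heavy), cfg$fact_warn_threshold,
                    names(which.max(heavy)), max(heavy)), call. = FALSE)
  }

  main_uris <- c(subjects, objects)
  main_titles <- c(subj_titles, obj_titles)
  ord <- radix_order(main_titles)
  nm <- length(main_titles)
  np <- length(pred_titles)
  pages <- fast_tibble(list(
    title = c(main_titles[ord], pred_titles),
    ns = rep(c("Main", "Property"), c(nm, np)),
    name = c(main_titles[ord], split_title(pred_titles)$name),
    equivalent_uri = c(main_uris[ord], predicates),
    smw_type = rep(NA_character_, nm + np),
    free_text = rep("", nm + np),
    template = rep(NA_character_, nm + np)
  ))

  new_wiki_site(pages = pages, facts = facts, index = index,
                prefixes = pfx, cfg = cfg)
}

#' Infer the SMW datatype of a property from its observed values
#'
#' Decision table: all-IRI values give `"Page"`; literals typed
#' xsd:integer/decimal/double/float give `"Number"`, xsd:date/dateTime
#' give `"Date"`, xsd:boolean gives `"Boolean"`, xsd:anyURI gives
#' `"URL"`; anything else (plain, language-tagged, or a mix of literal
#' types) gives `"Text"`. A mix of IRIs and literals gives `"Page"`
#' with a warning.
#'
#' @param object_type character vector (`"iri"`/`"literal"`), one entry
#'   per observed value of the property.
#' @param datatype datatype IRIs aligned with `object_type` (`NA` for
#'   IRIs and plain literals).
#' @return A single SMW datatype label.
#' @export
#' @examples
#' infer_property_type("literal", "http://www.w3.org/2001/XMLSchema#decimal")
infer_property_type <- function(object_type, datatype = NA_character_) {
  n <- length(object_type)
  if (n == 0L) stop("cannot infer a property type from zero values",
                    call. = FALSE)
  datatype <- rep_len(datatype, n)
  is_iri <- object_type == "iri"
  if (all(is_iri)) return("Page")
  if (any(is_iri)) {
    warning("property holds both page and literal values; using type Page",
            call. = FALSE)
    return("Page")
  }
  labels <- unique(smw_literal_type(datatype))
  if (length(labels) == 1L) labels else "Text"
}

smw_literal_type <- function(datatype) {
  local <- stringr::str_replace(datatype, stringr::fixed(XSD), "")
  dplyr::case_when(
    is.na(datatype) ~ "Text",
    local %in% c("integer", "decimal", "double", "float") ~ "Number",
    local %in% c("date", "dateTime") ~ "Date",
    local == "boolean" ~ "Boolean",
    local == "anyURI" ~ "URL",
    .default = "Text"
  )
}

#' Annotate property pages with inferred SMW datatypes
#'
#' Re-derives every property page's `smw_type` from the full fact table
#' (facts keep value kind and XSD datatype, so typing is independent of
#' how the import was chunked or merged).
#'
#' @param site a `wiki_site`.
#' @return The site with `smw_type` filled on property pages.
#' @export
infer_site_types <- function(site) {
  prop <- site$pages$ns == "Property"
  if (!any(prop) || nrow(site$facts) == 0L) return(site)
  f <- site$facts
  ot <- ifelse(f$value_kind == "page", "iri", "literal")
  types <- vapply(split(seq_len(nrow(f)), f$property),
                  function(idx) infer_property_type(ot[idx], f$datatype[idx]),
                  character(1))
  site$pages$smw_type[prop] <- unname(types[site$pages$name[prop]])
  site
}

#' Synthesize one template per rdf:type and pack typed pages
#'
#' For each distinct type value among the imported subjects, one
#' template specification is generated, named after the type's page
#' title, with one parameter per property used by subjects of that type
#' (union across subjects, sorted). Each typed page is marked to render
#' its facts as a call to its template; untyped pages keep inline
#' facts. Pages with several type facts are assigned the
#' lexicographically first type. Template specs and assignments are
#' recomputed from the fact table, so the result is independent of
#' chunking or merge history.
#'
#' @param site a `wiki_site`.
#' @return The site with `specs` filled, `template` assigned on typed
#'   pages, and one Template-namespace page per spec.
#' @export
synthesize_templates <- function(site) {
  tp <- site$cfg$type_property_name
  site$pages$template <- NA_character_
  site$pages <- site$pages[site$pages$ns != "Template", , drop = FALSE]
  site$specs <- empty_specs()
  tf <- site$facts[site$facts$property == tp &
                     site$facts$value_kind == "page", , drop = FALSE]
  if (nrow(tf) == 0L) return(site)
  tf <- tf[radix_order(tf$page, tf$value), , drop = FALSE]
  first_type <- tf[!duplicated(tf$page), , drop = FALSE]
  assigned <- stats::setNames(first_type$value, first_type$page)

  f <- site$facts
  tmpl <- unname(assigned[f$page])
  pf <- tibble::tibble(template = tmpl, property = f$property)[!is.na(tmpl), ]
  pf <- dplyr::distinct(pf)
  pf <- pf[radix_order(pf$template, pf$property), , drop = FALSE]
  site$specs <- tibble::tibble(template = pf$template, param = pf$property,
                               property = pf$property)

  hit <- match(site$pages$title, names(assigned))
  site$pages$template <- ifelse(is.na(hit), NA_character_,
                                unname(assigned)[hit])

  tnames <- unique(site$specs$template)
  template_pages <- tibble::tibble(
    title = paste0("Template:", tnames), ns = "Template", name = tnames,
    equivalent_uri = NA_character_, smw_type = NA_character_,
    free_text = "", template = NA_character_)
  site$pages <- sort_pages(dplyr::bind_rows(site$pages, template_pages))
  site
}

#' Split a triple set into consecutive import chunks
#'
#' The first `offset` triples (in canonical order) are skipped --
#' useful when restarting an interrupted import -- and the remainder is
#' emitted in chunks of at most `chunksize` statements whose
#' concatenation equals the non-skipped remainder.
#'
#' @param ts an [rdf_triples] object.
#' @param chunksize maximum triples per chunk (>= 1).
#' @param offset number of leading triples to skip (>= 0).
#' @return A list of [rdf_triples] chunks (possibly empty).
#' @export
chunk_stream <- function(ts, chunksize = Inf, offset = 0L) {
  stopifnot(chunksize >= 1L, offset >= 0L)
  tbl <- canonicalize_triples(tibble::as_tibble(ts)[triple_cols()])
  pfx <- prefixes(ts)
  n <- nrow(tbl)
  if (offset >= n) return(list())
  tbl <- tbl[(offset + 1L):n, , drop = FALSE]
  n <- nrow(tbl)
  starts <- seq(1L, n, by = min(chunksize, n))
  lapply(starts, function(s) {
    new_rdf_triples(tbl[s:min(s + chunksize - 1L, n), , drop = FALSE],
                    prefixes = pfx)
  })
}

# Structural union of two sites sharing one title index. Existing free
# text and facts win; incoming fills gaps on matched pages.
merge_sites_raw <- function(existing, incoming) {
  check_equri_conflicts(existing$pages, incoming$pages)
  pe <- existing$pages
  pi <- incoming$pages
  m <- match(pi$title, pe$title)
  hit <- which(!is.na(m))
  if (length(hit) > 0L) {
    rows <- m[hit]
    for (col in c("equivalent_uri", "smw_type", "template")) {
      fill <- is.na(pe[[col]][rows]) & !is.na(pi[[col]][hit])
      pe[[col]][rows[fill]] <- pi[[col]][hit][fill]
    }
    fill <- pe$free_text[rows] == "" & pi$free_text[hit] != ""
    pe$free_text[rows[fill]] <- pi$free_text[hit][fill]
  }
  pages <- bind_rows2(pe, pi[is.na(m), , drop = FALSE])
  facts <- bind_rows2(existing$facts, incoming$facts)
  new_wiki_site(pages = pages, facts = facts,
                specs = existing$specs, index = existing$index,
                prefixes = c(existing$prefixes, incoming$prefixes),
                cfg = existing$cfg)
}

check_equri_conflicts <- function(a, b) {
  ja <- a[!is.na(a$equivalent_uri), c("title", "equivalent_uri")]
  jb <- b[!is.na(b$equivalent_uri), c("title", "equivalent_uri")]
  m <- dplyr::inner_join(ja, jb, by = "equivalent_uri",
                         suffix = c("", ".in"),
                         relationship = "many-to-many")
  bad <- m$title != m$title.in
  if (any(bad)) {
    stop(sprintf("equivalent URI <%s> is bound to two titles: '%s' and '%s'",
                 m$equivalent_uri[bad][1L], m$title[bad][1L],
                 m$title.in[bad][1L]), call. = FALSE)
  }
  invisible(NULL)
}

#' Merge an incoming import into an existing wiki site
#'
#' Pages are matched by equivalent URI / title; incoming facts are
#' appended only when absent (set union, so re-imports never duplicate
#' facts and merging never deletes anything); existing free text and
#' manually added facts are preserved untouched. Property datatypes and
#' template specs are recomputed from the merged fact table. Binding
#' one equivalent URI to two different titles is an error.
#'
#' @param existing,incoming `wiki_site` objects built against one
#'   shared [title_index()].
#' @return The merged `wiki_site`.
#' @export
merge_pages <- function(existing, incoming) {
  out <- merge_sites_raw(existing, incoming)
  out <- infer_site_types(out)
  if (nrow(existing$specs) > 0L || nrow(incoming$specs) > 0L) {
    out <- synthesize_templates(out)
  }
  out
}

# Resolve every URI of the graph up front, in canonical order
# (subjects, then object-only URIs, then predicates). Title assignment
# -- including collision suffixes -- thereby depends only on the graph
# and the pre-existing index, never on how the import is chunked.
resolve_graph_titles <- function(ts, cfg, index, labels = NULL) {
  tbl <- canonicalize_triples(tibble::as_tibble(ts)[triple_cols()])
  resolve_graph_titles_tbl(tbl, cfg, index, labels)
}

resolve_graph_titles_tbl <- function(tbl, cfg, index, labels = NULL) {
  if (nrow(tbl) == 0L) return(invisible(index))
  if (is.null(labels)) labels <- label_table(tbl, cfg$label_properties)
  subjects <- unique(tbl$subject)
  objects <- setdiff(unique(tbl$object[tbl$object_type == "iri"]), subjects)
  predicates <- unique(tbl$predicate)
  if (RDF_TYPE %in% predicates && is.na(index_title_of(index, RDF_TYPE))) {
    disambiguate(cfg$type_property_name, RDF_TYPE, index, ns = "Property")
  }
  resolve_uris(subjects, "Main", labels, cfg, index)
  resolve_uris(objects, "Main", labels, cfg, index)
  resolve_uris(predicates, "Property", labels, cfg, index)
  invisible(index)
}

#' Import an RDF graph into a wiki site
#'
#' The end-to-end import pipeline: canonicalize, aggregate per subject,
#' resolve titles, build pages and facts (optionally in chunks of
#' `chunksize` triples, skipping `offset` leading triples), merge the
#' chunks, infer property datatypes, and synthesize templates from
#' rdf:type. Titles are resolved against the full graph's label table,
#' so the resulting page set does not depend on the chunk partition.
#'
#' @param ts an [rdf_triples] object.
#' @param cfg a [resolver_config()].
#' @param index a [title_index()] (updated in place); pass a shared
#'   index to import several datasets into one site.
#' @param chunksize,offset import batching, as in [chunk_stream()].
#' @param templates synthesize templates per rdf:type (default `TRUE`).
#' @param finalize run datatype inference and template synthesis after
#'   the chunks are merged (default `TRUE`). Batch drivers that import
#'   many consecutive slices (e.g. the endpoint replicator) set this to
#'   `FALSE` and finalize once at the end -- both steps are pure
#'   recomputations from the merged fact table, so deferring them does
#'   not change the result.
#' @param site an existing `wiki_site` to update in place (re-import /
#'   incremental import); defaults to an empty site.
#' @return A `wiki_site`.
#' @export
#' @examples
#' ts <- rdf_triples("http://ex.org/a", "http://ex.org/p", "v",
#'                   object_type = "literal")
#' site <- import_rdf(ts)
#' site$facts
import_rdf <- function(ts, cfg = resolver_config(), index = NULL,
                       chunksize = Inf, offset = 0L, templates = TRUE,
                       finalize = TRUE, site = NULL) {
  if (is.null(index)) {
    index <- if (is.null(site)) title_index() else site$index
  }
  if (is.null(site)) {
    site <- new_wiki_site(index = index, prefixes = prefixes(ts), cfg = cfg)
  }
  ctbl <- canonicalize_triples(tibble::as_tibble(ts)[triple_cols()])
  labels <- label_table(ctbl, cfg$label_properties)
  had_specs <- nrow(site$specs) > 0L
  resolve_graph_titles_tbl(ctbl, cfg, index, labels)
  n <- nrow(ctbl)
  if (offset < n) {
    for (start in seq(offset + 1L, n, by = min(chunksize, n))) {
      chunk_tbl <- ctbl[start:min(start + chunksize - 1L, n), , drop = FALSE]
      built <- build_pages_tbl(chunk_tbl, prefixes(ts), cfg, index, labels)
      site <- merge_sites_raw(site, built)
    }
  }
  if (finalize) {
    site <- infer_site_types(site)
    if (templates || had_specs) site <- synthesize_templates(site)
  }
  site
}
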