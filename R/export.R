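#' @title RDF export
#' @description Reconstructs RDF from the wiki page model, restoring
#'   the originally imported URIs through the stored Equivalent-URI
#'   links, and filters the wiki-added metadata so that an
#'   import/export round trip reproduces the input graph exactly.
#' @name exporter
NULL

OWL_SAMEAS <- "http://www.w3.org/2002/07/owl#sameAs"
SWIVT <- "http://semantic-mediawiki.org/swivt/1.0#"

#' Wiki metadata predicates removed by [filter_metadata()]
#'
#' The wiki stores bookkeeping facts about every page it creates --
#' the Equivalent URI link itself, the inferred property datatype, and
#' (on a live wiki) modification/creation dates and display titles.
#' These predicates carry wiki metadata, not imported data, and are
#' excluded when checking round-trip consistency.
#'
#' @return Named character vector: wiki property name to predicate IRI.
#' @export
metadata_predicates <- function() {
  c("Equivalent URI" = OWL_SAMEAS,
    "Has type" = paste0(SWIVT, "type"),
    "Modification date" = paste0(SWIVT, "wikiPageModificationDate"),
    "Creation date" = paste0(SWIVT, "wikiPageCreationDate"),
    "Display title of" = paste0(SWIVT, "wikiPageDisplayTitle"))
}

#' Mint a wiki-internal resolver URI for a page title
#' @noRd
wiki_minted_uri <- function(base_url, title) {
  enc <- vapply(stringr::str_replace_all(title, stringr::fixed(" "), "_"),
                utils::URLencode, character(1),
                reserved = TRUE, USE.NAMES = FALSE)
  paste0(base_url, "/Special:URIResolver/", enc)
}

#' Export a wiki site back to RDF triples
#'
#' Every fact becomes one triple. With `origuris = TRUE` (the default)
#' subjects, predicates and page-valued objects are translated back to
#' the URIs stored as Equivalent URI at import time, so the export is
#' expressed in the original ontology; pages lacking an equivalent URI
#' (legitimately, for manually created pages) fall back to a
#' wiki-minted `<base>/Special:URIResolver/<title>` URI with a
#' warning. With `origuris = FALSE` all resource URIs are wiki-minted.
#' Literal datatypes and language tags are restored from the preserved
#' value markers. Equivalent-URI facts themselves and other wiki
#' metadata are consumed, not emitted, unless `include_metadata` asks
#' for them (as owl:sameAs and datatype annotation triples).
#'
#' @param site a `wiki_site` (from [import_rdf()] or
#'   [site_from_dump()]).
#' @param origuris restore originally imported URIs (default `TRUE`).
#' @param include_metadata also emit the wiki's bookkeeping triples
#'   (default `FALSE`).
#' @param base_url base for wiki-minted URIs; defaults to the site
#'   configuration.
#' @return An [rdf_triples] object carrying the site's prefix map.
#' @export
export_rdf <- function(site, origuris = TRUE, include_metadata = FALSE,
                       base_url = NULL) {
  if (is.null(base_url)) base_url <- site$cfg$base_url
  pages <- site$pages
  facts <- site$facts

  minted <- wiki_minted_uri(base_url, pages$title)
  uri_of_page <- if (origuris) {
    as.character(ifelse(is.na(pages$equivalent_uri), minted,
                        pages$equivalent_uri))
  } else {
    minted
  }
  names(uri_of_page) <- pages$title

  if (origuris && nrow(facts) > 0L) {
    referenced <- unique(c(facts$page,
                           facts$value[facts$value_kind == "page"]))
    missing <- referenced[referenced %in%
                            pages$title[is.na(pages$equivalent_uri) &
                                          pages$ns != "Template"]]
    if (length(missing) > 0L) {
      warning(sprintf(
        "%d page(s) involved in facts have no equivalent URI; using wiki-minted URIs (first: '%s')",
        length(missing), missing[1L]), call. = FALSE)
    }
  }

  prop_titles <- paste0("Property:", facts$property)
  known_prop <- prop_titles %in% pages$title
  prop_uri <- ifelse(known_prop, unname(uri_of_page[prop_titles]),
                     wiki_minted_uri(base_url, prop_titles))

  is_page_val <- facts$value_kind == "page"
  obj <- facts$value
  known_obj <- is_page_val & obj %in% pages$title
  obj[known_obj] <- unname(uri_of_page[facts$value[known_obj]])
  obj[is_page_val & !known_obj] <-
    wiki_minted_uri(base_url, facts$value[is_page_val & !known_obj])

  out <- tibble::tibble(
    subject = as.character(uri_of_page[facts$page]),
    predicate = as.character(prop_uri),
    object = as.character(obj),
    object_type = as.character(ifelse(is_page_val, "iri", "literal")),
    datatype = facts$datatype,
    language = facts$language
  )

  if (include_metadata) {
    meta <- metadata_predicates()
    with_uri <- !is.na(pages$equivalent_uri)
    equri <- tibble::tibble(
      subject = unname(uri_of_page[pages$title[with_uri]]),
      predicate = meta[["Equivalent URI"]],
      object = pages$equivalent_uri[with_uri],
      object_type = "iri", datatype = NA_character_,
      language = NA_character_)
    typed <- pages$ns == "Property" & !is.na(pages$smw_type)
    hastype <- tibble::tibble(
      subject = unname(uri_of_page[pages$title[typed]]),
      predicate = meta[["Has type"]],
      object = pages$smw_type[typed],
      object_type = "literal", datatype = NA_character_,
      language = NA_character_)
    out <- dplyr::bind_rows(out, equri, hastype)
  }

  new_rdf_triples(canonicalize_triples(out), prefixes = site$prefixes)
}

#' Remove wiki metadata triples from an exported set
#'
#' Drops every triple whose predicate is in the wiki-metadata predicate
#' set (Equivalent URI links, datatype annotations, page dates, display
#' titles); all other triples pass through untouched. This is the
#' filter applied before checking that an import/export round trip
#' reproduced the imported data.
#'
#' @param ts an [rdf_triples] object.
#' @param predicates character vector of metadata predicate IRIs
#'   (default [metadata_predicates()]).
#' @return The filtered [rdf_triples].
#' @export
filter_metadata <- function(ts, predicates = metadata_predicates()) {
  tbl <- tibble::as_tibble(ts)[triple_cols()]
  new_rdf_triples(canonicalize_triples(tbl[!tbl$predicate %in% predicates, ,
                                           drop = FALSE]),
                  prefixes = prefixes(ts))
}
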