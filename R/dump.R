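#' @title MediaWiki XML dumps
#' @description Writes and reads the MediaWiki XML export format
#'   (export-0.10 schema) that carries rendered pages between the
#'   converter and a wiki. Page text is stored as plain, XML-escaped
#'   text so dumps stay inspectable in a text editor, and output is
#'   byte-stable across runs when the timestamp is fixed.
#' @name dump_xml
NULL

WIKI_NS_NUMBERS <- c(Main = 0L, Template = 10L, Property = 102L)

DEFAULT_DUMP_TIMESTAMP <- "1970-01-01T00:00:00Z"

#' Construct a dump document
#'
#' @param pages tibble with columns `title`, `ns` (`"Main"`,
#'   `"Template"` or `"Property"`) and `text`; page titles must be
#'   unique.
#' @param site_name wiki site name written into the dump header.
#' @param timestamp ISO-8601 revision timestamp. A fixed epoch by
#'   default so repeated conversions are byte-identical; pass
#'   `format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")` for wall
#'   clock stamps.
#' @return A `wiki_dump` object.
#' @export
wiki_dump <- function(pages, site_name = "rdfwikiforge",
                      timestamp = DEFAULT_DUMP_TIMESTAMP) {
  stopifnot(all(c("title", "ns", "text") %in% names(pages)))
  pages <- tibble::as_tibble(pages)[c("title", "ns", "text")]
  dup <- duplicated(pages$title)
  if (any(dup)) {
    stop(sprintf("duplicate page title in dump: '%s'",
                 pages$title[dup][1L]), call. = FALSE)
  }
  structure(list(pages = pages, site_name = site_name,
                 timestamp = timestamp), class = "wiki_dump")
}

#' @export
print.wiki_dump <- function(x, ...) {
  cat(sprintf("<wiki_dump: %d pages, site '%s', timestamp %s>\n",
              nrow(x$pages), x$site_name, x$timestamp))
  invisible(x)
}

xml_escape_text <- function(x) {
  x <- stringr::str_replace_all(x, stringr::fixed("&"), "&amp;")
  x <- stringr::str_replace_all(x, stringr::fixed("<"), "&lt;")
  stringr::str_replace_all(x, stringr::fixed(">"), "&gt;")
}

#' Serialize a dump document as MediaWiki export XML
#'
#' Emits the export-0.10 element names (`mediawiki/page/title`, `ns`,
#' `revision/timestamp`, `text`), one revision per page, with numeric
#' namespaces Main=0, Template=10, Property=102. Deterministic given a
#' fixed timestamp; [read_dump()] inverts it exactly.
#'
#' @param d a [wiki_dump()] (or a `wiki_site`, rendered on the fly, or
#'   a rendered-pages tibble).
#' @param site_name,timestamp used when `d` is not already a
#'   `wiki_dump`.
#' @return A single XML string.
#' @export
write_dump <- function(d, site_name = "rdfwikiforge",
                       timestamp = DEFAULT_DUMP_TIMESTAMP) {
  if (inherits(d, "wiki_site")) {
    d <- wiki_dump(render_pages(d), site_name = site_name,
                   timestamp = timestamp)
  } else if (!inherits(d, "wiki_dump")) {
    d <- wiki_dump(d, site_name = site_name, timestamp = timestamp)
  }
  p <- d$pages
  nsnum <- WIKI_NS_NUMBERS[p$ns]
  if (any(is.na(nsnum))) {
    stop(sprintf("unknown namespace '%s'", p$ns[is.na(nsnum)][1L]),
         call. = FALSE)
  }
  full_titles <- p$title
  page_xml <- if (nrow(p) == 0L) character() else sprintf(
    paste0("  <page>\n",
           "    <title>%s</title>\n",
           "    <ns>%d</ns>\n",
           "    <id>%d</id>\n",
           "    <revision>\n",
           "      <id>%d</id>\n",
           "      <timestamp>%s</timestamp>\n",
           "      <contributor><username>Rdfwikiforge</username></contributor>\n",
           "      <model>wikitext</model>\n",
           "      <format>text/x-wiki</format>\n",
           "      <text xml:space=\"preserve\">%s</text>\n",
           "    </revision>\n",
           "  </page>"),
    xml_escape_text(full_titles), nsnum, seq_len(nrow(p)),
    seq_len(nrow(p)), d$timestamp, xml_escape_text(p$text))
  paste0(
    "<mediawiki xmlns=\"http://www.mediawiki.org/xml/export-0.10/\" version=\"0.10\" xml:lang=\"en\">\n",
    "  <siteinfo>\n",
    "    <sitename>", xml_escape_text(d$site_name), "</sitename>\n",
    "    <namespaces>\n",
    "      <namespace key=\"0\"/>\n",
    "      <namespace key=\"10\">Template</namespace>\n",
    "      <namespace key=\"102\">Property</namespace>\n",
    "    </namespaces>\n",
    "  </siteinfo>\n",
    paste(page_xml, collapse = "\n"),
    if (nrow(p) > 0L) "\n" else "",
    "</mediawiki>\n")
}

#' Read a MediaWiki export XML dump
#'
#' Tolerant inverse of [write_dump()]: unknown elements are ignored,
#' and when a page carries several revisions the text of the latest
#' timestamp (ties: last in document order) is taken. Namespaces are
#' taken from the numeric `ns` element when it is one of the known
#' values, falling back to the title prefix.
#'
#' @param xml an XML string, or a path to an XML file.
#' @return A [wiki_dump()].
#' @export
read_dump <- function(xml) {
  doc <- xml2::read_xml(xml)
  xml2::xml_ns_strip(doc)
  site_name <- xml2::xml_text(xml2::xml_find_first(doc, "./siteinfo/sitename"))
  if (is.na(site_name)) site_name <- ""
  page_nodes <- xml2::xml_find_all(doc, "./page")
  ns_names <- stats::setNames(names(WIKI_NS_NUMBERS),
                              as.character(WIKI_NS_NUMBERS))
  rows <- vector("list", length(page_nodes))
  stamp <- NA_character_
  for (i in seq_along(page_nodes)) {
    node <- page_nodes[[i]]
    title <- xml2::xml_text(xml2::xml_find_first(node, "./title"))
    if (is.na(title)) {
      stop(sprintf("dump page %d has no <title> element", i), call. = FALSE)
    }
    revs <- xml2::xml_find_all(node, "./revision")
    if (length(revs) == 0L) {
      stop(sprintf("dump page %d ('%s') has no <revision> element", i, title),
           call. = FALSE)
    }
    times <- xml2::xml_text(xml2::xml_find_first(revs, "./timestamp"))
    times[is.na(times)] <- ""
    best <- which(times == max(times))
    best <- best[length(best)]
    text_node <- xml2::xml_find_first(revs[[best]], "./text")
    if (inherits(text_node, "xml_missing")) {
      stop(sprintf("dump page %d ('%s') has no <text> element", i, title),
           call. = FALSE)
    }
    text <- xml2::xml_text(text_node)
    nsn <- xml2::xml_text(xml2::xml_find_first(node, "./ns"))
    ns <- if (!is.na(nsn) && nsn %in% names(ns_names)) {
      ns_names[[nsn]]
    } else {
      split_title(title)$ns
    }
    if (is.na(stamp) && times[best] != "") stamp <- times[best]
    rows[[i]] <- tibble::tibble(title = title, ns = ns, text = text)
  }
  pages <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(title = character(), ns = character(), text = character())
  wiki_dump(pages, site_name = site_name,
            timestamp = if (is.na(stamp)) DEFAULT_DUMP_TIMESTAMP else stamp)
}

#' Rebuild a wiki site from a dump document
#'
#' Parses every page's wikitext back into the page model: template
#' specs are recovered from Template-namespace pages first, facts and
#' special properties from the rest, and the URI/title index is rebuilt
#' from the stored Equivalent URI facts.
#'
#' @param d a [wiki_dump()] (or XML string/path, read on the fly).
#' @param cfg a [resolver_config()].
#' @return A `wiki_site`.
#' @export
site_from_dump <- function(d, cfg = resolver_config()) {
  if (!inherits(d, "wiki_dump")) d <- read_dump(d)
  p <- d$pages
  is_tmpl <- p$ns == "Template"
  specs <- empty_specs()
  parsed_tmpl <- lapply(which(is_tmpl), function(i) {
    parse_page(p$title[i], p$text[i], ns = "Template")
  })
  if (length(parsed_tmpl)) {
    specs <- dplyr::bind_rows(lapply(parsed_tmpl, function(x) x$spec))
  }
  index <- title_index()
  pages <- vector("list", nrow(p))
  facts <- vector("list", nrow(p))
  k <- 0L
  for (i in seq_len(nrow(p))) {
    if (is_tmpl[i]) {
      pages[[i]] <- tibble::tibble(
        title = p$title[i], ns = "Template",
        name = split_title(p$title[i])$name,
        equivalent_uri = NA_character_, smw_type = NA_character_,
        free_text = "", template = NA_character_)
      next
    }
    pg <- parse_page(p$title[i], p$text[i], specs = specs, ns = p$ns[i])
    if (!is.na(pg$equivalent_uri)) {
      index_register(index, pg$equivalent_uri, pg$title)
    }
    pages[[i]] <- tibble::tibble(
      title = pg$title, ns = pg$ns, name = pg$name,
      equivalent_uri = pg$equivalent_uri, smw_type = pg$smw_type,
      free_text = pg$free_text, template = pg$template)
    facts[[i]] <- pg$facts
  }
  new_wiki_site(
    pages = dplyr::bind_rows(pages),
    facts = dplyr::bind_rows(facts[!vapply(facts, is.null, logical(1))]),
    specs = specs, index = index, cfg = cfg)
}
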