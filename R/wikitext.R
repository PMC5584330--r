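#' @title Semantic wikitext rendering and parsing
#' @description The syntax layer shared by import and export: renders
#'   wiki pages to SMW-style wikitext (inline `[[Property::value]]`
#'   facts, the Equivalent URI special property, template calls,
#'   `[[Has type::...]]` annotations on property pages) and parses such
#'   wikitext back into the page model.
#'
#' @details Literal fact values always end in an HTML-comment marker --
#'   `<!--plain-->`, `<!--^^datatypeIRI-->` or `<!--@lang-->` -- which
#'   MediaWiki renders invisibly. The marker keeps a literal that
#'   happens to equal some page title distinguishable from a page link
#'   and preserves exact XSD datatypes and language tags through the
#'   wiki, which plain SMW syntax has no lexical slot for.
#' @name wikitext
NULL

EQUIV_URI_PROP <- "Equivalent URI"
HAS_TYPE_PROP <- "Has type"

literal_escapes <- c(
  "&" = "&amp;", "<" = "&lt;", ">" = "&gt;",
  "[" = "&#91;", "]" = "&#93;", "{" = "&#123;", "}" = "&#125;",
  "|" = "&#124;", "=" = "&#61;", ";" = "&#59;",
  "\n" = "&#10;", "\r" = "&#13;"
)

#' Reversibly escape a literal for embedding in fact syntax
#'
#' Characters that would break the inline fact syntax, template-call
#' argument lists or the XML layer (`| [ ] { } = ; < > &` and
#' newlines) are encoded as HTML entities; [unescape_literal()] is the
#' exact inverse on arbitrary strings.
#'
#' @param x character vector.
#' @return Escaped character vector.
#' @export
#' @examples
#' escape_literal("a|b")  # "a&#124;b"
escape_literal <- function(x) {
  # single pass: entities introduced for one character are never
  # re-scanned, so escaping is injective and exactly invertible
  stringr::str_replace_all(x, "[&<>\\[\\]{}|=;\n\r]",
                           function(m) unname(literal_escapes[m]))
}

literal_unescapes <- stats::setNames(names(literal_escapes),
                                     unname(literal_escapes))
literal_entity_re <- paste(unname(literal_escapes), collapse = "|")

#' @rdname escape_literal
#' @export
unescape_literal <- function(x) {
  stringr::str_replace_all(x, literal_entity_re,
                           function(m) unname(literal_unescapes[m]))
}

# Split a ";"-joined list of escaped values. Raw ";" in escaped text is
# either a separator or the terminator of an entity such as "&#124;";
# only the former are split points.
split_escaped_values <- function(x) {
  semis <- stringr::str_locate_all(x, stringr::fixed(";"))[[1L]][, 1L]
  if (length(semis) == 0L) return(x)
  ents <- stringr::str_locate_all(x, "&(?:amp|lt|gt|#[0-9]{1,3});")[[1L]]
  seps <- setdiff(semis, ents[, 2L])
  if (length(seps) == 0L) return(x)
  starts <- c(1L, seps + 1L)
  ends <- c(seps - 1L, nchar(x))
  substring(x, starts, ends)
}

# A fact value as embedded in wikitext: page values are bare titles
# (titles cannot contain delimiter characters); literal values are
# escaped and suffixed with their type marker.
fact_value_text <- function(value_kind, value, datatype, language) {
  marker <- ifelse(!is.na(datatype),
                   paste0("<!--^^", escape_literal(datatype), "-->"),
                   ifelse(!is.na(language),
                          paste0("<!--@", language, "-->"),
                          "<!--plain-->"))
  ifelse(value_kind == "page", value,
         paste0(escape_literal(value), marker))
}

value_marker_re <- "^(.*)<!--(?:\\^\\^(.+)|@([A-Za-z][A-Za-z0-9-]*)|(plain))-->$"

parse_value_text <- function(s) {
  m <- stringr::str_match(s, value_marker_re)
  lit <- !is.na(m[, 1L])
  tibble::tibble(
    value_kind = ifelse(lit, "literal", "page"),
    value = ifelse(lit, unescape_literal(m[, 2L]), s),
    datatype = ifelse(lit & !is.na(m[, 3L]), unescape_literal(m[, 3L]),
                      NA_character_),
    language = m[, 4L]
  )
}

fact_line_re <- "^\\[\\[([^:\\]\\[|{}]+)::(.*)\\]\\]$"
template_line_re <- "^\\{\\{([^|{}]+)((?:\\|[^|{}]*)*)\\}\\}$"
template_body_re <- "^\\[\\[([^:\\]\\[|{}]+)::\\{\\{\\{([^|{}]+)\\|\\}\\}\\}\\]\\]$"

render_fact_lines <- function(facts) {
  if (nrow(facts) == 0L) return(character())
  paste0("[[", facts$property, "::",
         fact_value_text(facts$value_kind, facts$value,
                         facts$datatype, facts$language), "]]")
}

render_template_call <- function(name, facts, spec) {
  args <- character()
  for (i in seq_len(nrow(spec))) {
    f <- facts[facts$property == spec$property[i], , drop = FALSE]
    if (nrow(f) == 0L) next
    vals <- fact_value_text(f$value_kind, f$value, f$datatype, f$language)
    args <- c(args, paste0(spec$param[i], "=",
                           paste(vals[radix_order(vals)], collapse = ";")))
  }
  paste0("{{", name, if (length(args)) "|" else "",
         paste(args, collapse = "|"), "}}")
}

render_template_body <- function(spec) {
  paste0("[[", spec$property, "::{{{", spec$param, "|}}}]]")
}

#' Render wiki pages to wikitext
#'
#' Facts appear as sorted `[[Property::value]]` lines, or as a single
#' template call when the page is assigned one; every imported page
#' carries exactly one `[[Equivalent URI::...]]` fact; property pages
#' additionally carry `[[Has type::...]]`; free text follows after a
#' blank line. Output is deterministic.
#'
#' @param site a `wiki_site` (from [import_rdf()] or [site_from_dump()]).
#' @return A tibble with columns `title`, `ns`, `text`, one row per
#'   page, in deterministic order.
#' @export
render_pages <- function(site) {
  pages <- site$pages
  facts <- site$facts
  specs <- site$specs
  np <- nrow(pages)
  spec_by_tmpl <- split(specs, specs$template)

  # a fact is packed into its page's template call when the page is
  # typed and the property is one of the template's parameters
  fact_tmpl <- pages$template[match(facts$page, pages$title)]
  packed <- !is.na(fact_tmpl) &
    paste0(fact_tmpl, "\r", facts$property) %in%
      paste0(specs$template, "\r", specs$property)

  page_levels <- factor(facts$page, levels = pages$title)
  inline_txt <- vapply(
    split(render_fact_lines(facts[!packed, , drop = FALSE]),
          page_levels[!packed]),
    paste, character(1), collapse = "\n")

  call_txt <- stats::setNames(rep("", np), pages$title)
  typed <- which(!is.na(pages$template))
  if (length(typed) > 0L) {
    pf <- facts[packed, , drop = FALSE]
    val_txt <- fact_value_text(pf$value_kind, pf$value, pf$datatype,
                               pf$language)
    by_page <- split(seq_len(nrow(pf)), factor(pf$page, levels = pages$title))
    for (i in typed) {
      idx <- by_page[[i]]
      sp <- spec_by_tmpl[[pages$template[i]]]
      vals_by_prop <- split(val_txt[idx], pf$property[idx])
      present <- sp$property %in% names(vals_by_prop)
      args <- vapply(sp$property[present], function(prop) {
        v <- vals_by_prop[[prop]]
        paste(v[radix_order(v)], collapse = ";")
      }, character(1))
      call_txt[i] <- paste0("{{", pages$template[i],
                            if (any(present)) "|" else "",
                            paste(sp$param[present], "=", args, sep = "",
                                  collapse = "|"), "}}")
    }
  }

  equri_txt <- ifelse(is.na(pages$equivalent_uri), "",
                      paste0("[[", EQUIV_URI_PROP, "::",
                             escape_literal(pages$equivalent_uri), "]]"))
  type_txt <- ifelse(is.na(pages$smw_type), "",
                     paste0("[[", HAS_TYPE_PROP, "::", pages$smw_type, "]]"))
  free_txt <- ifelse(is.na(pages$free_text) | pages$free_text == "", "",
                     paste0("\n", pages$free_text))

  tmpl_body <- vapply(pages$name, function(nm) {
    sp <- spec_by_tmpl[[nm]]
    if (is.null(sp)) "" else paste(render_template_body(sp), collapse = "\n")
  }, character(1), USE.NAMES = FALSE)

  join_lines <- function(...) {
    parts <- cbind(...)
    apply(parts, 1L, function(r) paste(r[r != ""], collapse = "\n"))
  }
  texts <- ifelse(pages$ns == "Template", tmpl_body,
                  join_lines(unname(call_txt), unname(inline_txt),
                             equri_txt, type_txt, free_txt))
  tibble::tibble(title = pages$title, ns = pages$ns, text = texts)
}

#' Render a single wiki page
#'
#' @param site a `wiki_site`.
#' @param title full page title (e.g. `"Aspirin"`, `"Property:PKa"`).
#' @return A list with elements `title`, `ns` and `text`.
#' @export
render_page <- function(site, title) {
  hit <- which(site$pages$title == title)
  if (length(hit) == 0L) {
    stop(sprintf("no page with title '%s' in this site", title),
         call. = FALSE)
  }
  sub <- site
  sub$pages <- site$pages[hit, , drop = FALSE]
  r <- render_pages(sub)
  list(title = r$title[[1L]], ns = r$ns[[1L]], text = r$text[[1L]])
}

#' Parse wikitext back into page fields
#'
#' The inverse of [render_pages()] for the dialect it emits, tolerant
#' of arbitrary other text: facts are recovered from inline syntax,
#' from `{{#set:...}}` calls and from calls to known templates
#' (expanded through their specs); the Equivalent URI and Has type
#' facts are lifted into their dedicated fields; everything else is
#' preserved as free text. Malformed fact-like lines produce a warning
#' and fall back to free text; parsing never fails on arbitrary input.
#'
#' @param title full page title.
#' @param text page wikitext (LF or CRLF line endings).
#' @param specs template specification tibble (columns `template`,
#'   `param`, `property`); calls to templates not listed are treated as
#'   free text.
#' @param ns page namespace (`"Main"`, `"Property"`, `"Template"`);
#'   defaults to the namespace encoded in the title prefix.
#' @return A list with fields `title`, `ns`, `name`, `equivalent_uri`,
#'   `smw_type`, `free_text`, `template` and a `facts` tibble.
#' @export
parse_page <- function(title, text, specs = empty_specs(), ns = NULL) {
  st <- split_title(title)
  if (is.null(ns)) ns <- st$ns
  out <- list(title = title, ns = ns, name = st$name,
              equivalent_uri = NA_character_, smw_type = NA_character_,
              free_text = "", template = NA_character_,
              facts = empty_facts())
  lines <- stringr::str_split_1(text %||% "", "\r?\n")
  free <- character()
  fact_rows <- list()

  if (ns == "Template") {
    # template bodies are one generated fact pattern per parameter;
    # anything else is kept as free text of the template page
    m <- stringr::str_match(lines, template_body_re)
    hit <- !is.na(m[, 1L])
    out$spec <- tibble::tibble(template = st$name, param = m[hit, 3L],
                               property = m[hit, 2L])
    out$free_text <- paste(lines[!hit], collapse = "\n")
    return(out)
  }

  spec_by_tmpl <- if (nrow(specs) > 0L) split(specs, specs$template) else list()

  for (line in lines) {
    fm <- stringr::str_match(line, fact_line_re)
    if (!is.na(fm[1L])) {
      prop <- stringr::str_squish(fm[2L])
      val <- fm[3L]
      if (prop == EQUIV_URI_PROP) {
        out$equivalent_uri <- unescape_literal(val)
      } else if (prop == HAS_TYPE_PROP) {
        out$smw_type <- val
      } else {
        v <- parse_value_text(val)
        fact_rows[[length(fact_rows) + 1L]] <-
          tibble::tibble(page = title, property = prop,
                         value_kind = v$value_kind, value = v$value,
                         datatype = v$datatype, language = v$language)
      }
      next
    }
    tm <- stringr::str_match(line, template_line_re)
    if (!is.na(tm[1L])) {
      name <- stringr::str_squish(tm[2L])
      argstr <- tm[3L]
      if (stringr::str_starts(name, stringr::fixed("#set:"))) {
        argstr <- paste0("|", stringr::str_sub(name, 6L), argstr)
        fact_rows[[length(fact_rows) + 1L]] <-
          parse_set_args(title, argstr)
        next
      }
      if (!is.null(spec_by_tmpl[[name]])) {
        out$template <- name
        fact_rows[[length(fact_rows) + 1L]] <-
          expand_template_call(title, argstr, spec_by_tmpl[[name]])
        next
      }
      free <- c(free, line)
      next
    }
    if (stringr::str_detect(line, "^\\[\\[[^\\]]*::") ||
        stringr::str_detect(line, "^\\{\\{#set:")) {
      warning(sprintf("malformed fact syntax kept as free text on page '%s': %s",
                      title, line), call. = FALSE)
    }
    free <- c(free, line)
  }

  out$facts <- if (length(fact_rows)) dplyr::bind_rows(fact_rows) else empty_facts()
  # drop the single blank separator line render_pages() places before
  # free text
  while (length(free) > 0L && free[1L] == "") free <- free[-1L]
  out$free_text <- paste(free, collapse = "\n")
  out
}

parse_template_args <- function(argstr) {
  if (is.na(argstr) || argstr == "") return(character())
  parts <- stringr::str_split_1(stringr::str_sub(argstr, 2L), stringr::fixed("|"))
  m <- stringr::str_match(parts, "^([^=]*)=(.*)$")
  vals <- ifelse(is.na(m[, 1L]), parts, m[, 3L])
  names(vals) <- ifelse(is.na(m[, 1L]), "", stringr::str_squish(m[, 2L]))
  vals
}

expand_template_call <- function(title, argstr, spec) {
  args <- parse_template_args(argstr)
  rows <- list()
  for (param in names(args)) {
    prop <- spec$property[match(param, spec$param)]
    if (is.na(prop)) next
    vals <- split_escaped_values(args[[param]])
    vals <- vals[vals != ""]
    if (length(vals) == 0L) next
    v <- parse_value_text(vals)
    rows[[length(rows) + 1L]] <-
      tibble::tibble(page = title, property = prop,
                     value_kind = v$value_kind, value = v$value,
                     datatype = v$datatype, language = v$language)
  }
  if (length(rows)) dplyr::bind_rows(rows) else empty_facts()
}

parse_set_args <- function(title, argstr) {
  args <- parse_template_args(argstr)
  rows <- list()
  for (prop in names(args)) {
    if (prop == "") next
    v <- parse_value_text(args[[prop]])
    rows[[length(rows) + 1L]] <-
      tibble::tibble(page = title, property = prop,
                     value_kind = v$value_kind, value = v$value,
                     datatype = v$datatype, language = v$language)
  }
  if (length(rows)) dplyr::bind_rows(rows) else empty_facts()
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
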