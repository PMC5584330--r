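#' @title URI-to-title resolution
#' @description Resolves every IRI in a graph to a unique, human
#'   friendly, MediaWiki-legal page title by an ordered strategy chain,
#'   and maintains the bidirectional URI/title registry that later makes
#'   lossless export possible.
#' @name title_forge
NULL

DC_TITLE <- "http://purl.org/dc/elements/1.1/title"
RDFS_LABEL <- "http://www.w3.org/2000/01/rdf-schema#label"
SKOS_PREFLABEL <- "http://www.w3.org/2004/02/skos/core#prefLabel"
FOAF_NAME <- "http://xmlns.com/foaf/0.1/name"

#' Resolver configuration
#'
#' Settings that drive title resolution and the import pipeline.
#'
#' @param label_properties ordered character vector of predicate IRIs
#'   whose literal values may serve as page titles (priority order).
#' @param prefixes extra prefix declarations (named character vector)
#'   merged with those found in the dataset; drives the
#'   namespace-abbreviation strategy.
#' @param namespace_separator string placed between a prefix label and
#'   the local remainder in abbreviated titles. A space by default:
#'   a colon would collide with MediaWiki namespace syntax.
#' @param type_property_name wiki property name under which rdf:type
#'   statements are kept as ordinary facts.
#' @param base_url base URL used to mint wiki-internal resolver URIs on
#'   export when a page has no stored equivalent URI (or `origuris` is
#'   off).
#' @param fact_warn_threshold emit a warning when a single subject holds
#'   more than this many facts (such pages are legal but unwieldy to
#'   edit by hand).
#' @return A list with class `resolver_config`.
#' @export
resolver_config <- function(label_properties = c(DC_TITLE, RDFS_LABEL,
                                                 SKOS_PREFLABEL, FOAF_NAME),
                            prefixes = character(),
                            namespace_separator = " ",
                            type_property_name = "Rdf type",
                            base_url = "http://localhost/wiki",
                            fact_warn_threshold = 1000L) {
  structure(list(
    label_properties = as.character(label_properties),
    prefixes = normalize_prefixes(prefixes),
    namespace_separator = namespace_separator,
    type_property_name = type_property_name,
    base_url = sub("/+$", "", base_url),
    fact_warn_threshold = as.integer(fact_warn_threshold)
  ), class = "resolver_config")
}

#' Load a resolver configuration from a YAML file
#'
#' Recognized keys: `label_properties` (list), `prefixes` (map),
#' `namespace_separator`, `type_property_name`, `base_url`,
#' `fact_warn_threshold`. Missing keys fall back to the defaults of
#' [resolver_config()].
#'
#' @param path path to a YAML file.
#' @return A `resolver_config`.
#' @export
read_resolver_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- resolver_config()
  args <- list()
  for (key in names(defaults)) {
    args[[key]] <- if (!is.null(y[[key]])) y[[key]] else defaults[[key]]
  }
  args$prefixes <- unlist(args$prefixes)
  if (is.null(args$prefixes)) args$prefixes <- character()
  do.call(resolver_config, args)
}

#' Create an empty URI/title index
#'
#' The index is a mutable registry holding the bijection between
#' resource URIs and resolved wiki titles (the in-memory form of the
#' Equivalent-URI linkage). Both directions are kept exact inverses;
#' registration is atomic with resolution.
#'
#' @return A `title_index` object.
#' @export
title_index <- function() {
  structure(list(u2t = new.env(parent = emptyenv()),
                 t2u = new.env(parent = emptyenv())),
            class = "title_index")
}

#' Look up the title registered for a URI (or `NA`)
#' @param index a [title_index()].
#' @param uri resource IRI.
#' @return Full page title (with namespace prefix) or `NA`.
#' @export
index_title_of <- function(index, uri) {
  t <- index$u2t[[uri]]
  if (is.null(t)) NA_character_ else t
}

#' Look up the URI registered for a full title (or `NA`)
#' @param index a [title_index()].
#' @param title full page title, e.g. `"Aspirin"` or `"Property:PKa"`.
#' @return Resource IRI or `NA`.
#' @export
index_uri_of <- function(index, title) {
  u <- index$t2u[[title]]
  if (is.null(u)) NA_character_ else u
}

index_register <- function(index, uri, title) {
  index$u2t[[uri]] <- title
  index$t2u[[title]] <- uri
  invisible(index)
}

#' Number of registered URI/title pairs
#' @param index a [title_index()].
#' @return Integer count.
#' @export
index_size <- function(index) length(ls(index$u2t))

#' Tidy a title index into a two-column tibble
#' @param x a [title_index()].
#' @param ... unused.
#' @return A tibble with columns `uri` and `title`, sorted by `uri`.
#' @method tidy title_index
#' @export
tidy.title_index <- function(x, ...) {
  uris <- ls(x$u2t, sorted = FALSE)
  titles <- vapply(uris, function(u) x$u2t[[u]], character(1),
                   USE.NAMES = FALSE)
  ord <- radix_order(uris)
  tibble::tibble(uri = uris[ord], title = titles[ord])
}

#' @export
print.title_index <- function(x, ...) {
  cat(sprintf("<title_index: %d entries>\n", index_size(x)))
  invisible(x)
}

#' Dump a title index as a two-column TSV file (for audit)
#' @param index a [title_index()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_index_tsv <- function(index, path) {
  tbl <- tidy.title_index(index)
  utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

title_forbidden_re <- "[#<>\\[\\]|{}:;=&\\x00-\\x1f\\x7f]"

#' Sanitize a raw name into a MediaWiki-legal page title
#'
#' Forbidden characters (`# < > [ ] | { }` plus colon, semicolon,
#' equals sign, ampersand and control characters -- slightly stricter
#' than MediaWiki itself, so a page title can never collide with the
#' delimiters of the embedded fact syntax)
#' become `-`; underscores become spaces; whitespace is collapsed and
#' trimmed; the first character is uppercased; the result is truncated
#' to 255 bytes on a character boundary. Idempotent. An empty result
#' signals to the caller that the strategy producing `raw` failed.
#'
#' @param raw character vector of candidate names.
#' @return Sanitized character vector (possibly containing `""`).
#' @export
#' @examples
#' sanitize_title("gene_x [1]")  # "Gene x -1-"
sanitize_title <- function(raw) {
  x <- stringr::str_replace_all(raw, stringr::fixed("_"), " ")
  # collapse whitespace (incl. tab/newline) before the control-char
  # rule, so whitespace controls collapse instead of becoming "-"
  x <- stringr::str_squish(x)
  x <- stringr::str_replace_all(x, title_forbidden_re, "-")
  nz <- !is.na(x) & x != ""
  stringr::str_sub(x[nz], 1L, 1L) <- toupper(stringr::str_sub(x[nz], 1L, 1L))
  long <- nz & nchar(x, type = "bytes") > 255L
  if (any(long)) {
    x[long] <- vapply(x[long], function(s) {
      chars <- strsplit(s, "", fixed = TRUE)[[1L]]
      keep <- cumsum(nchar(chars, type = "bytes")) <= 255L
      stringr::str_trim(paste(chars[keep], collapse = ""))
    }, character(1), USE.NAMES = FALSE)
  }
  x
}

#' Local part of a URI
#'
#' The substring after the last `/` or `#` (whichever occurs later);
#' empty when the URI ends with the separator; the whole URI when it
#' contains neither.
#'
#' @param uri character vector of IRIs.
#' @return Character vector.
#' @export
#' @examples
#' local_part("http://ex.org/a/b#C9")  # "C9"
local_part <- function(uri) {
  ifelse(stringr::str_detect(uri, "[/#]"),
         stringr::str_replace(uri, "^.*[/#]", ""),
         uri)
}

#' Abbreviate a URI using a namespace prefix map
#'
#' The longest declared namespace IRI that is a prefix of `uri` is
#' replaced by its label followed by `sep`. `NA` when no namespace
#' matches or when the remainder would be empty.
#'
#' @param uri character vector of IRIs.
#' @param prefixes named character vector (label to namespace IRI).
#' @param sep separator between label and remainder (default space).
#' @return Character vector with `NA` where no abbreviation applies.
#' @export
#' @examples
#' abbreviate_uri("http://ex.org/vocab/pKa",
#'                c(v = "http://ex.org/vocab/"))  # "v pKa"
abbreviate_uri <- function(uri, prefixes, sep = " ") {
  prefixes <- normalize_prefixes(prefixes)
  out <- rep(NA_character_, length(uri))
  if (length(prefixes) == 0L) return(out)
  for (k in radix_order(-nchar(prefixes))) {
    ns <- unname(prefixes[k])
    hit <- is.na(out) & stringr::str_starts(uri, stringr::fixed(ns)) &
      nchar(uri) > nchar(ns)
    out[hit] <- paste0(names(prefixes)[k], sep,
                       stringr::str_sub(uri[hit], nchar(ns) + 1L))
  }
  out
}

full_title <- function(ns, name) {
  ifelse(ns == "Main", name, paste0(ns, ":", name))
}

split_title <- function(title) {
  m <- stringr::str_match(title, "^(Property|Template):(.*)$")
  ns <- ifelse(is.na(m[, 1L]), "Main", m[, 2L])
  name <- ifelse(is.na(m[, 1L]), title, m[, 3L])
  list(ns = ns, name = name)
}

#' Disambiguate a sanitized candidate title and register it
#'
#' If the candidate (within its namespace) is unbound, or already bound
#' to the same URI, it is used as-is. Otherwise the smallest integer
#' k >= 2 such that `"candidate (k)"` is free is appended. The winning
#' title is registered in the index atomically with resolution, keeping
#' the URI/title maps exact inverses.
#'
#' @param candidate sanitized non-empty name (no namespace prefix).
#' @param uri the resource IRI the title will stand for.
#' @param index a [title_index()], updated in place.
#' @param ns namespace: `"Main"`, `"Property"` or `"Template"`.
#' @return The full registered title.
#' @export
disambiguate <- function(candidate, uri, index, ns = "Main") {
  stopifnot(is.character(candidate), nzchar(candidate))
  base <- full_title(ns, candidate)
  bound <- index_uri_of(index, base)
  if (is.na(bound)) {
    index_register(index, uri, base)
    return(base)
  }
  if (identical(bound, uri)) return(base)
  k <- 2L
  repeat {
    cand <- full_title(ns, sprintf("%s (%d)", candidate, k))
    bound <- index_uri_of(index, cand)
    if (is.na(bound)) {
      index_register(index, uri, cand)
      return(cand)
    }
    if (identical(bound, uri)) return(cand)
    k <- k + 1L
  }
}

#' Resolve a URI to a wiki page title
#'
#' Strategies are applied strictly in order, stopping at the first that
#' yields a non-empty sanitized name:
#' \enumerate{
#'   \item an existing index entry for the URI is reused unchanged;
#'   \item the value of the first configured label property present
#'     among `subject_triples` (lexicographically smallest value on
#'     ties);
#'   \item abbreviation of the URI's namespace via the prefix map;
#'   \item the local part of the URI (after the last `/` or `#`).
#' }
#' The result is sanitized, disambiguated against collisions and
#' registered in the index before it is returned.
#'
#' @param uri resource IRI.
#' @param subject_triples an [rdf_triples] object (or tibble) holding
#'   the triples whose subject is `uri`; may be `NULL`/empty for
#'   object-only URIs.
#' @param cfg a [resolver_config()].
#' @param index a [title_index()], updated in place.
#' @param ns target namespace for a newly minted title.
#' @return The full page title.
#' @export
resolve_title <- function(uri, subject_triples = NULL,
                          cfg = resolver_config(), index = title_index(),
                          ns = "Main") {
  existing <- index_title_of(index, uri)
  if (!is.na(existing)) return(existing)
  label <- best_label(subject_triples, cfg$label_properties)
  candidate <- first_nonempty(c(
    sanitize_title(label),
    sanitize_title(abbreviate_uri(uri, cfg$prefixes, cfg$namespace_separator)),
    sanitize_title(local_part(uri))
  ))
  if (is.na(candidate)) {
    stop(sprintf("no title could be determined for URI <%s>", uri),
         call. = FALSE)
  }
  disambiguate(candidate, uri, index, ns = ns)
}

first_nonempty <- function(x) {
  x <- x[!is.na(x) & x != ""]
  if (length(x) == 0L) NA_character_ else x[[1L]]
}

best_label <- function(subject_triples, label_properties) {
  if (is.null(subject_triples) || nrow(subject_triples) == 0L) {
    return(NA_character_)
  }
  tbl <- tibble::as_tibble(subject_triples)
  hit <- tbl$object_type == "literal" & tbl$predicate %in% label_properties
  if (!any(hit)) return(NA_character_)
  tbl <- tbl[hit, , drop = FALSE]
  prio <- match(tbl$predicate, label_properties)
  tbl$object[radix_order(prio, tbl$object)][1L]
}

# Vectorized strategy chain over many URIs sharing one graph-wide label
# table; registration stays sequential (disambiguation is inherently
# order-dependent). `labels` is a named character vector uri -> label.
resolve_uris <- function(uris, ns, labels, cfg, index) {
  if (length(uris) == 0L) return(character())
  out <- vapply(uris, function(u) index_title_of(index, u), character(1),
                USE.NAMES = FALSE)
  todo <- is.na(out)
  if (!any(todo)) return(out)
  u <- uris[todo]
  lab <- unname(labels[u])
  cand <- sanitize_title(lab)
  need <- is.na(cand) | cand == ""
  cand[need] <- sanitize_title(
    abbreviate_uri(u[need], cfg$prefixes, cfg$namespace_separator))
  need <- is.na(cand) | cand == ""
  cand[need] <- sanitize_title(local_part(u[need]))
  bad <- is.na(cand) | cand == ""
  if (any(bad)) {
    stop(sprintf("no title could be determined for URI <%s>",
                 u[which(bad)[1L]]), call. = FALSE)
  }
  res <- character(length(u))
  for (i in seq_along(u)) {
    res[i] <- disambiguate(cand[i], u[i], index, ns = ns)
  }
  out[todo] <- res
  out
}

# Graph-wide label table: the winning label candidate per subject,
# honoring label-property priority then lexicographic tie-break.
label_table <- function(ts, label_properties) {
  tbl <- tibble::as_tibble(ts)
  hit <- tbl$object_type == "literal" & tbl$predicate %in% label_properties
  if (!any(hit)) return(stats::setNames(character(), character()))
  tbl <- tbl[hit, , drop = FALSE]
  prio <- match(tbl$predicate, label_properties)
  tbl <- tbl[radix_order(tbl$subject, prio, tbl$object), , drop = FALSE]
  keep <- !duplicated(tbl$subject)
  stats::setNames(tbl$object[keep], tbl$subject[keep])
}
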