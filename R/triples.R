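#' Construct a set of RDF triples
#'
#' The central data container of the package: a tibble with one row per
#' RDF statement and columns `subject`, `predicate`, `object`,
#' `object_type` (`"iri"` or `"literal"`), `datatype` and `language`
#' (both `NA` unless the object is a typed or language-tagged literal).
#' An optional prefix map (named character vector, prefix label to
#' namespace IRI) travels with the set as the `"prefixes"` attribute.
#'
#' RDF graphs are sets: duplicate statements are collapsed and rows are
#' kept in a canonical codepoint-lexicographic order (subject, predicate,
#' serialized object term), so identical graphs always produce identical
#' tibbles and identical serializations.
#'
#' @param subject,predicate character vectors of absolute IRIs.
#' @param object character vector of IRIs or literal lexical forms.
#' @param object_type `"iri"` or `"literal"`, recycled.
#' @param datatype datatype IRI per literal, `NA` for plain literals.
#' @param language BCP-47 language tag per literal, `NA` if untagged.
#'   A literal may carry a datatype or a language, never both.
#' @param prefixes named character vector mapping prefix labels (no
#'   colon) to namespace IRIs.
#' @return A `rdf_triples` tibble (also `tbl_df`).
#' @export
#' @examples
#' rdf_triples("http://ex.org/a", "http://ex.org/p", "v",
#'             object_type = "literal")
rdf_triples <- function(subject = character(), predicate = character(),
                        object = character(),
                        object_type = rep("iri", length(object)),
                        datatype = NA_character_, language = NA_character_,
                        prefixes = character()) {
  n <- length(object)
  tbl <- tibble::tibble(
    subject = as.character(subject),
    predicate = as.character(predicate),
    object = as.character(object),
    object_type = rep_len(as.character(object_type), n),
    datatype = rep_len(as.character(datatype), n),
    language = rep_len(as.character(language), n)
  )
  validate_triples(tbl)
  new_rdf_triples(canonicalize_triples(tbl), prefixes = prefixes)
}

new_rdf_triples <- function(tbl, prefixes = character()) {
  stopifnot(is.data.frame(tbl))
  out <- tibble::as_tibble(tbl)
  class(out) <- c("rdf_triples", class(tibble::tibble()))
  attr(out, "prefixes") <- normalize_prefixes(prefixes)
  out
}

validate_triples <- function(tbl) {
  if (nrow(tbl) == 0L) return(invisible(tbl))
  bad <- !tbl$object_type %in% c("iri", "literal")
  if (any(bad)) stop("object_type must be 'iri' or 'literal'", call. = FALSE)
  check_absolute_iri(tbl$subject, "subject")
  check_absolute_iri(tbl$predicate, "predicate")
  check_absolute_iri(tbl$object[tbl$object_type == "iri"], "IRI object")
  both <- !is.na(tbl$datatype) & !is.na(tbl$language)
  if (any(both)) {
    stop("a literal cannot carry both a datatype and a language tag",
         call. = FALSE)
  }
  lit <- tbl$object_type == "literal"
  if (any((!is.na(tbl$datatype) | !is.na(tbl$language)) & !lit)) {
    stop("datatype/language are only valid on literal objects", call. = FALSE)
  }
  invisible(tbl)
}

check_absolute_iri <- function(x, what) {
  if (length(x) == 0L) return(invisible(x))
  bad <- !stringr::str_detect(x, "^[A-Za-z][A-Za-z0-9+.-]*:") |
    stringr::str_detect(x, "[ \t\r\n<>\"]")
  if (any(bad)) {
    stop(sprintf("%s is not an absolute IRI: %s", what, x[which(bad)[1L]]),
         call. = FALSE)
  }
  invisible(x)
}

normalize_prefixes <- function(prefixes) {
  prefixes <- unlist(prefixes)
  if (length(prefixes) == 0L) {
    return(stats::setNames(character(), character()))
  }
  if (is.null(names(prefixes))) {
    stop("prefixes must be a named character vector", call. = FALSE)
  }
  prefixes <- prefixes[!duplicated(names(prefixes))]
  prefixes[radix_order(names(prefixes))]
}

# Codepoint (byte-wise UTF-8) ordering -- locale-independent, so every
# pipeline stage is deterministic across machines.
radix_order <- function(...) order(..., method = "radix")

# Validation-free tibble constructor and two-table row bind for the hot
# paths (batched imports construct many small tables).
fast_tibble <- function(cols) {
  tibble::new_tibble(cols, nrow = if (length(cols)) length(cols[[1L]]) else 0L)
}

bind_rows2 <- function(a, b) {
  if (nrow(a) == 0L) return(b)
  if (nrow(b) == 0L) return(a)
  fast_tibble(stats::setNames(
    lapply(names(a), function(cl) c(a[[cl]], b[[cl]])), names(a)))
}

#' Serialized N-Triples object term for each row
#' @noRd
nt_object_term <- function(object, object_type, datatype, language) {
  out <- ifelse(object_type == "iri",
                paste0("<", object, ">"),
                paste0("\"", escape_nt_string(object), "\""))
  lit <- object_type == "literal"
  dt <- lit & !is.na(datatype)
  lg <- lit & !is.na(language)
  out[dt] <- paste0(out[dt], "^^<", datatype[dt], ">")
  out[lg] <- paste0(out[lg], "@", language[lg])
  out
}

canonicalize_triples <- function(tbl) {
  tbl <- dplyr::distinct(tbl)
  if (nrow(tbl) > 0L) {
    term <- nt_object_term(tbl$object, tbl$object_type,
                           tbl$datatype, tbl$language)
    tbl <- tbl[radix_order(tbl$subject, tbl$predicate, term), , drop = FALSE]
  }
  tbl
}

#' Get or set the prefix map of a triple set
#'
#' @param ts an [rdf_triples] object.
#' @param value named character vector of prefix label to namespace IRI.
#' @return Named character vector (possibly empty).
#' @export
prefixes <- function(ts) {
  p <- attr(ts, "prefixes")
  if (is.null(p)) stats::setNames(character(), character()) else p
}

#' @rdname prefixes
#' @export
`prefixes<-` <- function(ts, value) {
  attr(ts, "prefixes") <- normalize_prefixes(value)
  ts
}

#' Set equality of two triple sets
#'
#' Triple sets are compared as sets of statements; prefix maps are
#' carried metadata and do not participate in equality.
#'
#' @param a,b [rdf_triples] objects.
#' @return `TRUE` or `FALSE`.
#' @export
triples_equal <- function(a, b) {
  ca <- canonicalize_triples(tibble::as_tibble(a)[triple_cols()])
  cb <- canonicalize_triples(tibble::as_tibble(b)[triple_cols()])
  isTRUE(all.equal(as.data.frame(ca), as.data.frame(cb),
                   check.attributes = FALSE))
}

triple_cols <- function() {
  c("subject", "predicate", "object", "object_type", "datatype", "language")
}

#' Set difference of triple sets (statements in `a` not in `b`)
#' @param a,b [rdf_triples] objects.
#' @return An [rdf_triples] object keeping `a`'s prefixes.
#' @export
triples_setdiff <- function(a, b) {
  d <- dplyr::anti_join(tibble::as_tibble(a)[triple_cols()],
                        tibble::as_tibble(b)[triple_cols()],
                        by = triple_cols())
  new_rdf_triples(canonicalize_triples(d), prefixes = prefixes(a))
}

#' Union of triple sets (duplicates collapsed, prefix maps merged)
#' @param a,b [rdf_triples] objects.
#' @return An [rdf_triples] object.
#' @export
triples_union <- function(a, b) {
  u <- dplyr::bind_rows(tibble::as_tibble(a)[triple_cols()],
                        tibble::as_tibble(b)[triple_cols()])
  pfx <- c(prefixes(a), prefixes(b))
  new_rdf_triples(canonicalize_triples(u), prefixes = pfx)
}

#' Aggregate a triple set per subject resource
#'
#' Groups statements by their subject IRI, the first step of the
#' RDF-to-wiki conversion: each group becomes one wiki page. Keys are the
#' distinct subjects in canonical (codepoint-lexicographic) order and
#' within a group triples are sorted by (predicate, object), so the
#' concatenation of all groups reproduces the input set exactly.
#'
#' @param ts an [rdf_triples] object.
#' @return A named list of `rdf_triples`, one element per subject.
#' @export
#' @examples
#' ts <- rdf_triples(c("http://e/s", "http://e/s"),
#'                   c("http://e/p", "http://e/q"),
#'                   c("x", "y"), object_type = "literal")
#' names(aggregate_by_subject(ts))
aggregate_by_subject <- function(ts) {
  tbl <- canonicalize_triples(tibble::as_tibble(ts)[triple_cols()])
  if (nrow(tbl) == 0L) return(stats::setNames(list(), character()))
  subjects <- unique(tbl$subject)  # already canonically ordered
  groups <- split(tbl, factor(tbl$subject, levels = subjects))
  pfx <- prefixes(ts)
  lapply(groups, function(g) new_rdf_triples(g, prefixes = pfx))
}

#' @export
print.rdf_triples <- function(x, ...) {
  cat(sprintf("<rdf_triples: %d statement%s, %d prefix%s>\n", nrow(x),
              if (nrow(x) == 1L) "" else "s", length(prefixes(x)),
              if (length(prefixes(x)) == 1L) "" else "es"))
  NextMethod()
}

#' Tidy a triple set into a plain tibble
#' @param x an [rdf_triples] object.
#' @param ... unused.
#' @return A tibble with the six statement columns.
#' @method tidy rdf_triples
#' @export
tidy.rdf_triples <- function(x, ...) {
  tibble::as_tibble(x)[triple_cols()]
}
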