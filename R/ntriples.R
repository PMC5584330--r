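#' @title N-Triples reading and writing
#' @description Line-oriented parser and canonical serializer for the
#'   W3C N-Triples format, the package's canonical RDF serialization.
#' @name ntriples
NULL

# Escape a literal lexical form for N-Triples output. Only the five
# mandatory escapes; all other characters are written as raw UTF-8.
escape_nt_string <- function(x) {
  x <- stringr::str_replace_all(x, stringr::fixed("\\"), "\\\\")
  x <- stringr::str_replace_all(x, stringr::fixed("\""), "\\\"")
  x <- stringr::str_replace_all(x, stringr::fixed("\n"), "\\n")
  x <- stringr::str_replace_all(x, stringr::fixed("\r"), "\\r")
  stringr::str_replace_all(x, stringr::fixed("\t"), "\\t")
}

# Decode N-Triples/Turtle string escapes (\n \t \r \b \f \" \' \\,
# \uXXXX, \UXXXXXXXX) in a single left-to-right pass.
unescape_nt_string <- function(x) {
  has <- stringr::str_detect(x, stringr::fixed("\\"))
  if (!any(has)) return(x)
  x[has] <- stringr::str_replace_all(
    x[has],
    "\\\\(u[0-9a-fA-F]{4}|U[0-9a-fA-F]{8}|.)",
    function(m) {
      esc <- substr(m, 2L, nchar(m))
      first <- substr(esc, 1L, 1L)
      if (first == "u" || first == "U") {
        intToUtf8(strtoi(substr(esc, 2L, nchar(esc)), 16L))
      } else {
        switch(esc, n = "\n", t = "\t", r = "\r", b = "\b", f = "\f", esc)
      }
    }
  )
  x
}

nt_line_re <- paste0(
  "^\\s*",
  "(<[^<>\\s]*>|_:\\S+)\\s+",                          # subject
  "(<[^<>\\s]*>)\\s+",                                 # predicate
  "(<[^<>\\s]*>|_:\\S+|\"(?:[^\"\\\\]|\\\\.)*\"",      # object: iri/bnode/lit
  "(?:\\^\\^<[^<>\\s]*>|@[A-Za-z][A-Za-z0-9-]*)?)",    # datatype or lang
  "\\s*\\.\\s*$"
)

#' Parse N-Triples text into a triple set
#'
#' Full N-Triples support: comments (`#` lines) and blank lines are
#' skipped, literal escapes (`\n`, `\t`, `\"`, `\uXXXX`, `\UXXXXXXXX`)
#' are decoded, duplicate statements are collapsed. Blank-node labels
#' are skolemized to IRIs of the form `urn:bnode:<scope>:<label>` (with
#' a warning carrying the count), so every anonymous resource can still
#' become an addressable wiki page.
#'
#' @param text a length-1 string or character vector of lines.
#' @param bnode_scope string distinguishing skolem IRIs of independent
#'   imports; the default gives stable, reproducible IRIs for a file.
#' @return An [rdf_triples] object (empty prefix map; N-Triples carries
#'   no prefix declarations).
#' @export
#' @examples
#' parse_ntriples('<http://ex.org/a> <http://ex.org/p> "v" .')
parse_ntriples <- function(text, bnode_scope = "import") {
  lines <- if (length(text) == 1L) {
    stringr::str_split_1(text, "\r?\n")
  } else {
    as.character(text)
  }
  keep <- !stringr::str_detect(lines, "^\\s*(#|$)")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(rdf_triples())

  m <- stringr::str_match(lines, nt_line_re)
  bad <- which(is.na(m[, 1L]))
  if (length(bad) > 0L) {
    stop(sprintf("malformed N-Triples statement at line %d: %s",
                 lineno[bad[1L]], lines[bad[1L]]), call. = FALSE)
  }

  subj <- decode_nt_resource(m[, 2L], bnode_scope)
  pred <- decode_nt_resource(m[, 3L], bnode_scope)

  obj_raw <- m[, 4L]
  is_lit <- stringr::str_starts(obj_raw, "\"")
  object <- character(length(obj_raw))
  datatype <- rep(NA_character_, length(obj_raw))
  language <- rep(NA_character_, length(obj_raw))
  if (any(!is_lit)) {
    object[!is_lit] <- decode_nt_resource(obj_raw[!is_lit], bnode_scope)
  }
  if (any(is_lit)) {
    lm <- stringr::str_match(
      obj_raw[is_lit],
      "^\"((?:[^\"\\\\]|\\\\.)*)\"(?:\\^\\^<([^>]*)>|@([A-Za-z][A-Za-z0-9-]*))?$"
    )
    object[is_lit] <- unescape_nt_string(lm[, 2L])
    datatype[is_lit] <- lm[, 3L]
    language[is_lit] <- lm[, 4L]
  }

  n_bnodes <- sum(stringr::str_starts(c(m[, 2L], obj_raw[!is_lit]), "_:"))
  if (n_bnodes > 0L) {
    warning(sprintf("skolemized %d blank node reference(s) into urn:bnode:%s:* IRIs",
                    n_bnodes, bnode_scope), call. = FALSE)
  }
  rdf_triples(subject = subj, predicate = pred, object = object,
              object_type = ifelse(is_lit, "literal", "iri"),
              datatype = datatype, language = language)
}

decode_nt_resource <- function(term, bnode_scope) {
  iri <- stringr::str_starts(term, "<")
  out <- character(length(term))
  out[iri] <- unescape_nt_string(stringr::str_sub(term[iri], 2L, -2L))
  out[!iri] <- paste0("urn:bnode:", bnode_scope, ":",
                      stringr::str_sub(term[!iri], 3L))
  rel <- iri & !stringr::str_detect(out, "^[A-Za-z][A-Za-z0-9+.-]*:")
  if (any(rel)) {
    stop(sprintf("relative IRI not allowed: <%s>", out[which(rel)[1L]]),
         call. = FALSE)
  }
  out
}

#' Serialize a triple set as canonical N-Triples
#'
#' One statement per line, lines sorted codepoint-lexicographically by
#' (subject, predicate, object term), so equal graphs produce
#' byte-identical output and `parse_ntriples(write_ntriples(ts))`
#' returns `ts`.
#'
#' @param ts an [rdf_triples] object.
#' @return A single string; `""` for the empty set.
#' @export
write_ntriples <- function(ts) {
  tbl <- canonicalize_triples(tibble::as_tibble(ts)[triple_cols()])
  if (nrow(tbl) == 0L) return("")
  lines <- paste0("<", tbl$subject, "> <", tbl$predicate, "> ",
                  nt_object_term(tbl$object, tbl$object_type,
                                 tbl$datatype, tbl$language), " .")
  paste0(paste(lines, collapse = "\n"), "\n")
}
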