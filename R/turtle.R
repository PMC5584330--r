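#' @title Turtle subset reading and writing
#' @description A pragmatic Turtle subset: `@prefix`/`@base` directives,
#'   prefixed names, the `;` and `,` abbreviations, the `a` keyword,
#'   typed and language-tagged literals, and bare numeric/boolean
#'   shorthand. Collections, anonymous blank-node property lists and
#'   triple-quoted strings are rejected with an error naming the
#'   construct and its line, never silently dropped.
#' @name turtle
NULL

RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
XSD <- "http://www.w3.org/2001/XMLSchema#"

turtle_token_re <- paste(
  c("#[^\n]*",                                   # comment
    "\"{3}",                                     # long string (unsupported)
    "'{3}",
    "<[^<>\\s]*>",                               # IRIREF
    "\"(?:[^\"\\\\\n]|\\\\.)*\"",                # STRING
    "'(?:[^'\\\\\n]|\\\\.)*'",
    "\\^\\^",
    "@[A-Za-z][A-Za-z0-9-]*",                    # langtag / directive
    "[+-]?(?:[0-9]+\\.[0-9]*|\\.[0-9]+|[0-9]+)(?:[eE][+-]?[0-9]+)?",
    "_:[A-Za-z0-9][A-Za-z0-9._-]*",              # blank node label
    "(?:[A-Za-z][A-Za-z0-9_.-]*)?:(?:(?:[A-Za-z0-9_%]|\\\\.)(?:[A-Za-z0-9_.%-]|\\\\.)*)?",
    "[A-Za-z][A-Za-z0-9_-]*",                    # bare word (a, true, ...)
    "[.;,\\[\\]()]"),
  collapse = "|"
)

tokenize_turtle <- function(text) {
  mm <- gregexpr(turtle_token_re, text, perl = TRUE)[[1L]]
  starts <- as.integer(mm)
  if (starts[1L] == -1L) starts <- integer()
  lens <- attr(mm, "match.length")
  toks <- substring(text, starts, starts + lens - 1L)
  # coverage check: everything outside tokens must be whitespace
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(starts)) {
    covered[starts[i]:(starts[i] + lens[i] - 1L)] <- TRUE
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  stray <- which(!covered & !chars %in% c(" ", "\t", "\r", "\n"))
  if (length(stray) > 0L) {
    stop(sprintf("unrecognized Turtle syntax '%s' at line %d",
                 chars[stray[1L]], line_of(text, stray[1L])), call. = FALSE)
  }
  keep <- !stringr::str_starts(toks, "#")
  list(tokens = toks[keep], lines = line_of(text, starts)[keep])
}

line_of <- function(text, pos) {
  nl <- c(0L, which(strsplit(text, "", fixed = TRUE)[[1L]] == "\n"))
  findInterval(pos, nl + 1L)
}

#' Parse a Turtle document (supported subset) into a triple set
#'
#' All `@prefix` directives are collected into the result's prefix map,
#' which later drives the namespace-abbreviation title strategy.
#' Unsupported Turtle constructs (collections, `[...]` property lists,
#' triple-quoted strings) raise an error naming the construct and line.
#'
#' @param text a length-1 Turtle string.
#' @param bnode_scope skolemization scope for labelled blank nodes, as
#'   in [parse_ntriples()].
#' @return An [rdf_triples] object with populated prefixes.
#' @export
#' @examples
#' parse_turtle("@prefix ex: <http://ex.org/> . ex:a ex:p ex:b .")
parse_turtle <- function(text, bnode_scope = "import") {
  text <- paste(text, collapse = "\n")
  tk <- tokenize_turtle(text)
  toks <- tk$tokens
  tlines <- tk$lines
  n <- length(toks)
  pfx <- character()
  base <- ""
  n_bnodes <- 0L

  subj <- character(); pred <- character(); obj <- character()
  otype <- character(); dt <- character(); lang <- character()

  i <- 1L
  fail <- function(msg, at = min(i, n)) {
    stop(sprintf("%s at line %d", msg,
                 if (n == 0L) 1L else tlines[at]), call. = FALSE)
  }
  peek <- function() if (i <= n) toks[i] else NA_character_
  advance <- function() {
    t <- peek()
    if (is.na(t)) fail("unexpected end of input", n)
    i <<- i + 1L
    t
  }

  expand_term <- function(t, at) {
    if (stringr::str_starts(t, "<")) {
      iri <- unescape_nt_string(stringr::str_sub(t, 2L, -2L))
      if (!stringr::str_detect(iri, "^[A-Za-z][A-Za-z0-9+.-]*:")) {
        if (base == "") {
          stop(sprintf("relative IRI <%s> without @base at line %d",
                       iri, tlines[at]), call. = FALSE)
        }
        iri <- paste0(base, iri)
      }
      return(iri)
    }
    if (stringr::str_starts(t, "_:")) {
      n_bnodes <<- n_bnodes + 1L
      return(paste0("urn:bnode:", bnode_scope, ":",
                    stringr::str_sub(t, 3L)))
    }
    parts <- stringr::str_match(t, "^([^:]*):(.*)$")
    label <- parts[2L]
    local <- stringr::str_replace_all(parts[3L], "\\\\(.)", "\\1")
    hit <- match(label, names(pfx))  # match(), not pfx[label]: the empty
    if (is.na(hit)) {                # default prefix ':' has name ""
      stop(sprintf("undeclared prefix '%s:' at line %d", label, tlines[at]),
           call. = FALSE)
    }
    paste0(unname(pfx[hit]), local)
  }

  read_resource <- function(role) {
    at <- i
    t <- advance()
    if (t %in% c("[", "(")) {
      fail(sprintf("unsupported Turtle construct '%s' (%s)", t,
                   if (t == "[") "anonymous blank-node property list"
                   else "collection"), at)
    }
    if (!grepl("^[<_]|:", t)) {
      fail(sprintf("expected %s, found '%s'", role, t), at)
    }
    expand_term(t, at)
  }

  emit <- function(s, p, o, ot, d, l) {
    subj[length(subj) + 1L] <<- s; pred[length(pred) + 1L] <<- p
    obj[length(obj) + 1L] <<- o; otype[length(otype) + 1L] <<- ot
    dt[length(dt) + 1L] <<- d; lang[length(lang) + 1L] <<- l
  }

  read_object <- function(s, p) {
    at <- i
    t <- advance()
    if (t %in% c("\"\"\"", "'''")) {
      fail("unsupported Turtle construct: triple-quoted string", at)
    }
    if (t %in% c("[", "(")) {
      fail(sprintf("unsupported Turtle construct '%s' (%s)", t,
                   if (t == "[") "anonymous blank-node property list"
                   else "collection"), at)
    }
    if (stringr::str_starts(t, "\"") || stringr::str_starts(t, "'")) {
      lex <- unescape_nt_string(stringr::str_sub(t, 2L, -2L))
      d <- NA_character_; l <- NA_character_
      if (identical(peek(), "^^")) {
        advance()
        d <- expand_term(advance(), i - 1L)
      } else if (!is.na(peek()) && stringr::str_starts(peek(), "@")) {
        l <- stringr::str_sub(advance(), 2L)
      }
      emit(s, p, lex, "literal", d, l)
    } else if (t %in% c("true", "false")) {
      emit(s, p, t, "literal", paste0(XSD, "boolean"), NA_character_)
    } else if (grepl("^[+-]?[.0-9]", t)) {
      d <- if (grepl("[eE]", t)) "double" else if (grepl("\\.", t)) "decimal" else "integer"
      emit(s, p, t, "literal", paste0(XSD, d), NA_character_)
    } else {
      emit(s, p, expand_term(t, at), "iri", NA_character_, NA_character_)
    }
  }

  while (i <= n) {
    t <- peek()
    if (t %in% c("@prefix", "@base")) {
      advance()
      if (t == "@prefix") {
        at <- i
        nst <- advance()
        if (!stringr::str_detect(nst, "^(?:[A-Za-z][A-Za-z0-9_.-]*)?:$")) {
          fail(sprintf("expected prefix label before IRI, found '%s'", nst), at)
        }
        label <- stringr::str_sub(nst, 1L, -2L)
        irit <- advance()
        if (!stringr::str_starts(irit, "<")) fail("expected namespace IRI", i - 1L)
        pfx[label] <- unescape_nt_string(stringr::str_sub(irit, 2L, -2L))
      } else {
        irit <- advance()
        if (!stringr::str_starts(irit, "<")) fail("expected base IRI", i - 1L)
        base <- unescape_nt_string(stringr::str_sub(irit, 2L, -2L))
      }
      if (!identical(advance(), ".")) fail("expected '.' after directive", i - 1L)
      next
    }
    s <- read_resource("subject")
    repeat {
      at <- i
      pt <- advance()
      p <- if (pt == "a") RDF_TYPE else {
        if (!grepl("^<|:", pt)) fail(sprintf("expected predicate, found '%s'", pt), at)
        expand_term(pt, at)
      }
      repeat {
        read_object(s, p)
        if (identical(peek(), ",")) { advance(); next }
        break
      }
      sep <- advance()
      if (sep == ";") {
        if (identical(peek(), ".")) { advance(); break }
        next
      }
      if (sep == ".") break
      fail(sprintf("expected '.', ';' or ',', found '%s'", sep), i - 1L)
    }
  }

  if (n_bnodes > 0L) {
    warning(sprintf("skolemized %d blank node reference(s) into urn:bnode:%s:* IRIs",
                    n_bnodes, bnode_scope), call. = FALSE)
  }
  rdf_triples(subject = subj, predicate = pred, object = obj,
              object_type = otype, datatype = dt, language = lang,
              prefixes = pfx)
}

# Abbreviate an IRI to prefix:local for Turtle output when the local
# part is syntactically safe; otherwise NA (caller falls back to <iri>).
turtle_pname <- function(iris, pfx) {
  out <- rep(NA_character_, length(iris))
  if (length(pfx) == 0L) return(out)
  ord <- radix_order(-nchar(pfx))
  for (k in ord) {
    ns <- unname(pfx[k])
    hit <- is.na(out) & stringr::str_starts(iris, stringr::fixed(ns))
    if (!any(hit)) next
    local <- stringr::str_sub(iris[hit], nchar(ns) + 1L)
    ok <- stringr::str_detect(local, "^[A-Za-z0-9_][A-Za-z0-9_.-]*$") &
      !stringr::str_ends(local, stringr::fixed("."))
    idx <- which(hit)[ok]
    out[idx] <- paste0(names(pfx)[k], ":",
                       stringr::str_sub(iris[idx], nchar(ns) + 1L))
  }
  out
}

#' Serialize a triple set as Turtle
#'
#' Emits the set's prefix map as `@prefix` directives and one statement
#' per line in canonical order, abbreviating IRIs to prefixed names
#' where the local part is syntactically safe and writing `a` for
#' rdf:type. Output is accepted by [parse_turtle()] and by standard
#' Turtle parsers.
#'
#' @param ts an [rdf_triples] object.
#' @return A single Turtle string.
#' @export
write_turtle <- function(ts) {
  tbl <- canonicalize_triples(tibble::as_tibble(ts)[triple_cols()])
  pfx <- prefixes(ts)
  header <- if (length(pfx) > 0L) {
    paste0("@prefix ", names(pfx), ": <", unname(pfx), "> .")
  } else {
    character()
  }
  if (nrow(tbl) == 0L) {
    return(if (length(header) == 0L) "" else paste0(paste(header, collapse = "\n"), "\n"))
  }
  term_iri <- function(x) {
    ab <- turtle_pname(x, pfx)
    ifelse(is.na(ab), paste0("<", x, ">"), ab)
  }
  s <- term_iri(tbl$subject)
  p <- ifelse(tbl$predicate == RDF_TYPE, "a", term_iri(tbl$predicate))
  o <- character(nrow(tbl))
  iri <- tbl$object_type == "iri"
  o[iri] <- term_iri(tbl$object[iri])
  lit <- !iri
  o[lit] <- paste0("\"", escape_nt_string(tbl$object[lit]), "\"")
  hasdt <- lit & !is.na(tbl$datatype)
  o[hasdt] <- paste0(o[hasdt], "^^", term_iri(tbl$datatype[hasdt]))
  haslg <- lit & !is.na(tbl$language)
  o[haslg] <- paste0(o[haslg], "@", tbl$language[haslg])
  body <- paste0(s, " ", p, " ", o, " .")
  paste0(paste(c(header, if (length(header)) "" else NULL, body),
               collapse = "\n"), "\n")
}
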