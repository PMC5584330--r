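#' @title Synthetic RDF fixture generator
#' @description Deterministic generators for three families of
#'   synthetic graphs shaped like the biomedical datasets the pipeline
#'   is meant for: rare-disease gene association graphs whose genes and
#'   disorders are linked only through intermediate association nodes
#'   (`orphanet_like`), compound/pKa/publication graphs with rdf:type
#'   information driving template synthesis (`drugmet_like`), and
#'   uniform random graphs with controllable label and type coverage
#'   that exercise every title strategy and datatype-inference row
#'   (`random`). All fixtures are blank-node free; the same recipe and
#'   seed always produce byte-identical N-Triples.
#' @name cli_fixtures
NULL

FIX <- "http://fixture.example.org/"

#' Generate a synthetic RDF fixture graph
#'
#' @param kind `"orphanet_like"`, `"drugmet_like"` or `"random"`.
#' @param n_entities number of primary entities (gene/disorder pairs,
#'   compounds, or generic resources).
#' @param seed RNG seed; the same recipe is byte-reproducible.
#' @param label_fraction fraction of entities carrying a label-property
#'   literal (drives title strategy 1 coverage).
#' @param typed_fraction fraction of entities carrying rdf:type
#'   (`random` kind only; the other recipes fix their own typing).
#' @return An [rdf_triples] object with a populated prefix map.
#' @export
#' @examples
#' generate_fixture("drugmet_like", n_entities = 3, seed = 1)
generate_fixture <- function(kind = c("orphanet_like", "drugmet_like",
                                      "random"),
                             n_entities = 10L, seed = 1L,
                             label_fraction = 0.5, typed_fraction = 0.5) {
  kind <- match.arg(kind)
  stopifnot(n_entities >= 1L, label_fraction >= 0, label_fraction <= 1,
            typed_fraction >= 0, typed_fraction <= 1)
  withr::with_seed(seed, switch(
    kind,
    orphanet_like = fixture_orphanet(n_entities, label_fraction),
    drugmet_like = fixture_drugmet(n_entities, label_fraction),
    random = fixture_random(n_entities, label_fraction, typed_fraction)
  ))
}

# Disorder-gene association graphs: genes and disorders are never
# linked directly; an intermediate association node points at both.
fixture_orphanet <- function(n, label_fraction) {
  vocab <- paste0(FIX, "orphanet-vocab#")
  genes <- sprintf("%sorphanet/gene/G%04d", FIX, seq_len(n))
  disorders <- sprintf("%sorphanet/disorder/D%04d", FIX, seq_len(n))
  extra <- max(0L, floor(n / 2))
  pair_gene <- c(seq_len(n), sample.int(n, extra, replace = TRUE))
  pair_dis <- c(seq_len(n), sample.int(n, extra, replace = TRUE))
  assocs <- sprintf("%sorphanet/assoc/A%04d", FIX, seq_along(pair_gene))

  s <- character(); p <- character(); o <- character()
  ot <- character(); dt <- character(); lg <- character()
  add <- function(su, pr, ob, kind = "iri", d = NA_character_,
                  l = NA_character_) {
    n <- length(su)
    s <<- c(s, su); p <<- c(p, rep_len(pr, n)); o <<- c(o, rep_len(ob, n))
    ot <<- c(ot, rep_len(kind, n))
    dt <<- c(dt, rep_len(d, n))
    lg <<- c(lg, rep_len(l, n))
  }

  add(assocs, paste0(vocab, "gene"), genes[pair_gene])
  add(assocs, paste0(vocab, "disorder"), disorders[pair_dis])
  add(assocs, RDF_TYPE, rep(paste0(vocab, "GeneDisorderAssociation"),
                            length(assocs)))
  add(assocs, paste0(vocab, "status"),
      sample(c("validated", "not validated"), length(assocs), replace = TRUE),
      kind = "literal")
  add(genes, paste0(vocab, "symbol"),
      sprintf("GN%04d", seq_len(n)), kind = "literal")

  lab_g <- runif(n) < label_fraction
  lab_d <- runif(n) < label_fraction
  if (any(lab_g)) {
    add(genes[lab_g], RDFS_LABEL, sprintf("Gene %04d", which(lab_g)),
        kind = "literal")
  }
  if (any(lab_d)) {
    add(disorders[lab_d], RDFS_LABEL,
        sprintf("Disorder %04d", which(lab_d)), kind = "literal")
  }

  rdf_triples(s, p, o, object_type = ot, datatype = dt, language = lg,
              prefixes = c(orph = paste0(FIX, "orphanet/"),
                           orphv = vocab))
}

# Compound/pKa/publication graphs with rdf:type on every compound, so
# template synthesis is exercised; pKa values are xsd:decimal literals.
fixture_drugmet <- function(n, label_fraction) {
  vocab <- paste0(FIX, "drugmet-vocab#")
  compounds <- sprintf("%sdrugmet/compound/C%04d", FIX, seq_len(n))
  npub <- max(1L, ceiling(n / 3))
  pubs <- sprintf("%sdrugmet/publication/P%04d", FIX, seq_len(npub))

  s <- character(); p <- character(); o <- character()
  ot <- character(); dt <- character(); lg <- character()
  add <- function(su, pr, ob, kind = "iri", d = NA_character_,
                  l = NA_character_) {
    n <- length(su)
    s <<- c(s, su); p <<- c(p, rep_len(pr, n)); o <<- c(o, rep_len(ob, n))
    ot <<- c(ot, rep_len(kind, n))
    dt <<- c(dt, rep_len(d, n))
    lg <<- c(lg, rep_len(l, n))
  }

  add(compounds, RDF_TYPE, rep(paste0(vocab, "Compound"), n))
  add(compounds, paste0(vocab, "pKa"),
      sprintf("%.2f", round(runif(n, 0, 14), 2)),
      kind = "literal", d = paste0(XSD, "decimal"))
  add(compounds, paste0(vocab, "citedIn"),
      pubs[sample.int(npub, n, replace = TRUE)])

  lab <- runif(n) < label_fraction
  if (any(lab)) {
    add(compounds[lab], DC_TITLE, sprintf("Compound %04d", which(lab)),
        kind = "literal")
  }
  add(pubs, DC_TITLE, sprintf("Publication %04d", seq_len(npub)),
      kind = "literal")

  rdf_triples(s, p, o, object_type = ot, datatype = dt, language = lg,
              prefixes = c(dm = paste0(FIX, "drugmet/"), dmv = vocab))
}

fixture_words <- c("alpha", "beta", "gamma", "delta", "kappa", "sigma",
                   "omega", "zeta")

fixture_gnarly <- c("pipe | pipe", "bracket ]] bracket", "brace {{ brace",
                    "line\nbreak", "tab\tand \"quotes\"",
                    "back\\slash", "semi;colon=eq", "unicode \u00e5\u00e4\u00f6",
                    "amp & lt < gt >")

# Uniform random graphs over two namespaces (one with a declared
# prefix, one without, plus a nested sub-namespace to exercise
# longest-match abbreviation); one fixed value kind per predicate so
# datatype inference is deterministic.
fixture_random <- function(n, label_fraction, typed_fraction) {
  ns_pref <- paste0(FIX, "r/a/")
  ns_nested <- paste0(FIX, "r/a/b/")
  ns_bare <- "http://random.example.net/x#"
  vocab <- paste0(FIX, "r-vocab#")
  pool <- c(ns_pref, ns_nested, ns_bare)
  entities <- paste0(pool[sample.int(3L, n, replace = TRUE)],
                     sprintf("n%05d", seq_len(n)))

  preds <- list(
    list(p = paste0(vocab, "linksTo"), kind = "iri"),
    list(p = paste0(vocab, "count"), kind = "literal",
         d = paste0(XSD, "integer")),
    list(p = paste0(vocab, "score"), kind = "literal",
         d = paste0(XSD, "decimal")),
    list(p = paste0(vocab, "weight"), kind = "literal",
         d = paste0(XSD, "double")),
    list(p = paste0(vocab, "measured"), kind = "literal",
         d = paste0(XSD, "date")),
    list(p = paste0(vocab, "updated"), kind = "literal",
         d = paste0(XSD, "dateTime")),
    list(p = paste0(vocab, "active"), kind = "literal",
         d = paste0(XSD, "boolean")),
    list(p = paste0(vocab, "homepage"), kind = "literal",
         d = paste0(XSD, "anyURI")),
    list(p = paste0(vocab, "note"), kind = "literal", d = NA_character_),
    list(p = paste0(vocab, "comment"), kind = "literal",
         d = NA_character_, lang = "en"),
    list(p = paste0(vocab, "oddText"), kind = "literal", d = NA_character_)
  )

  m <- 3L * n
  pick <- sample.int(length(preds), m, replace = TRUE)
  s <- entities[sample.int(n, m, replace = TRUE)]
  p <- vapply(preds, function(x) x$p, character(1))[pick]
  o <- character(m); ot <- character(m)
  dt <- rep(NA_character_, m); lg <- rep(NA_character_, m)
  for (i in seq_len(m)) {
    def <- preds[[pick[i]]]
    ot[i] <- def$kind
    if (def$kind == "iri") {
      o[i] <- entities[sample.int(n, 1L)]
      next
    }
    dt[i] <- def$d
    if (!is.null(def$lang)) lg[i] <- def$lang
    local <- sub(paste0(vocab, collapse = ""), "", def$p, fixed = TRUE)
    o[i] <- switch(
      local,
      count = as.character(sample.int(10000L, 1L)),
      score = sprintf("%.3f", runif(1, -10, 10)),
      weight = sprintf("%.6e", runif(1, 0, 1)),
      measured = sprintf("20%02d-%02d-%02d", sample.int(25, 1),
                         sample.int(12, 1), sample.int(28, 1)),
      updated = sprintf("20%02d-%02d-%02dT%02d:%02d:%02dZ",
                        sample.int(25, 1), sample.int(12, 1),
                        sample.int(28, 1), sample.int(24, 1) - 1L,
                        sample.int(60, 1) - 1L, sample.int(60, 1) - 1L),
      active = sample(c("true", "false"), 1L),
      homepage = sprintf("http://example.org/site/%d", sample.int(1000L, 1L)),
      note = paste(sample(fixture_words, 3L, replace = TRUE), collapse = " "),
      comment = paste(sample(fixture_words, 2L, replace = TRUE),
                      collapse = " "),
      oddText = sample(fixture_gnarly, 1L)
    )
  }

  lab <- runif(n) < label_fraction
  if (any(lab)) {
    s <- c(s, entities[lab])
    p <- c(p, rep(RDFS_LABEL, sum(lab)))
    o <- c(o, vapply(seq_len(sum(lab)), function(i) {
      paste(sample(fixture_words, 2L, replace = TRUE), collapse = " ")
    }, character(1)))
    ot <- c(ot, rep("literal", sum(lab)))
    dt <- c(dt, rep(NA_character_, sum(lab)))
    lg <- c(lg, rep(NA_character_, sum(lab)))
  }
  typed <- runif(n) < typed_fraction
  if (any(typed)) {
    s <- c(s, entities[typed])
    p <- c(p, rep(RDF_TYPE, sum(typed)))
    o <- c(o, paste0(vocab, sample(c("ClassA", "ClassB", "ClassC"),
                                   sum(typed), replace = TRUE)))
    ot <- c(ot, rep("iri", sum(typed)))
    dt <- c(dt, rep(NA_character_, sum(typed)))
    lg <- c(lg, rep(NA_character_, sum(typed)))
  }

  rdf_triples(s, p, o, object_type = ot, datatype = dt, language = lg,
              prefixes = c(ra = ns_pref, rab = ns_nested, rv = vocab))
}
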