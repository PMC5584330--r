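test_that("a single literal triple yields one main page plus its property page", {
  ts <- rdf_triples("http://e/s", "http://e/pKa", "3.5",
                    object_type = "literal",
                    datatype = "http://www.w3.org/2001/XMLSchema#decimal")
  site <- import_rdf(ts)
  expect_equal(sum(site$pages$ns == "Main"), 1L)
  expect_equal(sum(site$pages$ns == "Property"), 1L)
  expect_equal(nrow(site$facts), 1L)
  expect_equal(site$facts$value_kind, "literal")
  expect_equal(site$pages$equivalent_uri[site$pages$ns == "Main"],
               "http://e/s")
  expect_equal(site$pages$smw_type[site$pages$ns == "Property"], "Number")
})

test_that("IRI objects become page links and object-only URIs get stub pages", {
  ts <- rdf_triples("http://e/s", "http://e/p", "http://e/o")
  site <- import_rdf(ts)
  opage <- site$pages[site$pages$equivalent_uri %in% "http://e/o", ]
  expect_equal(nrow(opage), 1L)
  expect_equal(opage$ns, "Main")
  f <- site$facts
  expect_equal(f$value_kind, "page")
  expect_equal(f$value, opage$title)
  # the stub has no facts of its own but a full equivalent URI
  expect_equal(sum(f$page == opage$title), 0L)
})

test_that("association-style graphs keep genes and disorders linked only indirectly", {
  g <- generate_fixture("orphanet_like", 6, seed = 1)
  site <- import_rdf(g)
  by_uri <- function(pat) {
    u <- site$pages$equivalent_uri
    site$pages$title[!is.na(u) & grepl(pat, u)]
  }
  gene_titles <- by_uri("/gene/")
  dis_titles <- by_uri("/disorder/")
  # graph-walk oracle: no fact on a gene page points at a disorder page
  gene_facts <- site$facts[site$facts$page %in% gene_titles, ]
  expect_false(any(gene_facts$value %in% dis_titles))
  # every association page links one gene and one disorder
  assoc_titles <- by_uri("/assoc/")
  for (at in assoc_titles) {
    vals <- site$facts$value[site$facts$page == at &
                               site$facts$value_kind == "page"]
    expect_true(any(vals %in% gene_titles))
    expect_true(any(vals %in% dis_titles))
  }
})

test_that("datatype inference follows the decision table exhaustively", {
  xsd <- "http://www.w3.org/2001/XMLSchema#"
  # single observations
  expect_equal(infer_property_type("literal", paste0(xsd, "decimal")),
               "Number")
  expect_equal(infer_property_type("iri", NA), "Page")
  expect_equal(infer_property_type("literal", paste0(xsd, "date")), "Date")
  expect_equal(infer_property_type("literal", paste0(xsd, "boolean")),
               "Boolean")
  expect_equal(infer_property_type("literal", paste0(xsd, "anyURI")), "URL")
  expect_equal(infer_property_type("literal", NA), "Text")
  expect_error(infer_property_type(character(0)), "zero values")

  # exhaustive 1- and 2-element combinations against an oracle that
  # recomputes the documented decision rule independently
  kinds <- list(
    iri = list(ot = "iri", dt = NA_character_, smw = "Page"),
    int = list(ot = "literal", dt = paste0(xsd, "integer"), smw = "Number"),
    dec = list(ot = "literal", dt = paste0(xsd, "decimal"), smw = "Number"),
    dbl = list(ot = "literal", dt = paste0(xsd, "double"), smw = "Number"),
    flt = list(ot = "literal", dt = paste0(xsd, "float"), smw = "Number"),
    date = list(ot = "literal", dt = paste0(xsd, "date"), smw = "Date"),
    dttm = list(ot = "literal", dt = paste0(xsd, "dateTime"), smw = "Date"),
    bool = list(ot = "literal", dt = paste0(xsd, "boolean"), smw = "Boolean"),
    uri = list(ot = "literal", dt = paste0(xsd, "anyURI"), smw = "URL"),
    plain = list(ot = "literal", dt = NA_character_, smw = "Text"),
    custom = list(ot = "literal", dt = "http://e/myType", smw = "Text")
  )
  oracle <- function(sel) {
    ot <- vapply(sel, function(k) k$ot, character(1))
    if (all(ot == "iri")) return("Page")
    if (any(ot == "iri")) return("Page")  # mixed -> Page (with warning)
    labs <- unique(vapply(sel, function(k) k$smw, character(1)))
    if (length(labs) == 1L) labs else "Text"
  }
  for (i in seq_along(kinds)) {
    for (j in seq_along(kinds)) {
      sel <- kinds[c(i, j)]
      ot <- vapply(sel, function(k) k$ot, character(1))
      dt <- vapply(sel, function(k) k$dt, character(1))
      mixed <- length(unique(ot)) > 1L
      got <- if (mixed) {
        expect_warning(infer_property_type(ot, dt), "both page and literal")
        suppressWarnings(infer_property_type(ot, dt))
      } else {
        infer_property_type(ot, dt)
      }
      expect_identical(got, oracle(sel))
    }
  }
})

test_that("template synthesis groups typed pages and leaves untyped graphs alone", {
  g <- generate_fixture("drugmet_like", 2, seed = 3, label_fraction = 1)
  site <- import_rdf(g)
  expect_equal(length(unique(site$specs$template)), 1L)
  spec <- site$specs
  # one parameter per property used by compounds (pKa, citedIn, title
  # label, and the type fact itself)
  compound_pages <- site$pages$title[!is.na(site$pages$template)]
  expect_equal(length(compound_pages), 2L)
  used <- sort(unique(site$facts$property[site$facts$page %in%
                                            compound_pages]))
  expect_equal(sort(spec$param), used)
  # Template page exists
  expect_true(any(site$pages$ns == "Template"))

  untyped <- rdf_triples("http://e/s", "http://e/p", "v",
                         object_type = "literal")
  site2 <- import_rdf(untyped)
  expect_equal(nrow(site2$specs), 0L)
  expect_false(any(site2$pages$ns == "Template"))
})

test_that("chunk_stream skips, bounds and conserves", {
  g <- generate_fixture("random", 4, seed = 1)
  ts <- rdf_triples(g$subject[1:10], g$predicate[1:10], paste0("v", 1:10),
                    object_type = "literal")
  chunks <- chunk_stream(ts, chunksize = 4)
  expect_equal(vapply(chunks, nrow, integer(1)), c(4L, 4L, 2L))
  expect_length(chunk_stream(ts, chunksize = 4, offset = 10), 0L)
  expect_length(chunk_stream(ts, chunksize = 4, offset = 99), 0L)
  got <- do.call(rbind, lapply(chunks, as.data.frame))
  expect_equal(got, as.data.frame(ts), ignore_attr = TRUE)
  off <- chunk_stream(ts, chunksize = 3, offset = 4)
  expect_equal(sum(vapply(off, nrow, integer(1))), 6L)
})

test_that("chunked import equals single-pass import for random partitions", {
  withr::with_seed(21, {
    for (rep in 1:6) {
      g <- generate_fixture(sample(c("random", "drugmet_like"), 1),
                            n_entities = sample(10:60, 1), seed = rep)
      one <- import_rdf(g)
      cs <- sample(c(1L, 3L, 17L, 1000L), 1)
      many <- import_rdf(g, index = title_index(), chunksize = cs)
      expect_identical(many$pages, one$pages)
      expect_identical(many$facts, one$facts)
      expect_identical(many$specs, one$specs)
    }
  })
})

test_that("merging is idempotent, additive-only, and preserves manual content", {
  g <- generate_fixture("drugmet_like", 8, seed = 4)
  x <- import_rdf(g)
  m <- merge_pages(x, x)
  expect_identical(m$pages, x$pages)
  expect_identical(m$facts, x$facts)
  expect_identical(m$specs, x$specs)

  # manual free text and a manually added fact survive a re-import
  y <- x
  i <- which(y$pages$ns == "Main")[1]
  y$pages$free_text[i] <- "Hand-written curation note."
  manual <- y$facts[1, ]
  manual$property <- "Curator note"
  manual$value <- "checked"
  manual$value_kind <- "literal"
  manual$datatype <- NA_character_
  y$facts <- dplyr::bind_rows(y$facts, manual)
  z <- merge_pages(y, import_rdf(g, index = y$index))
  expect_true("Hand-written curation note." %in% z$pages$free_text)
  expect_true(any(z$facts$property == "Curator note"))
  # no fact was removed and no fact duplicated
  expect_equal(nrow(z$facts), nrow(y$facts))
  expect_equal(anyDuplicated(z$facts), 0L)
})

test_that("an incoming page with one new fact appends exactly that fact", {
  a <- import_rdf(rdf_triples("http://e/s", "http://e/p", "v1",
                              object_type = "literal"))
  b <- import_rdf(rdf_triples("http://e/s", "http://e/p", "v2",
                              object_type = "literal"), index = a$index)
  m <- merge_pages(a, b)
  expect_equal(nrow(m$facts), 2L)
  expect_setequal(m$facts$value, c("v1", "v2"))
})

test_that("binding one equivalent URI to two titles is a merge conflict", {
  a <- import_rdf(rdf_triples("http://e/s", "http://e/p", "v",
                              object_type = "literal"))
  idx2 <- title_index()
  disambiguate("Other name", "http://e/s", idx2)
  b <- import_rdf(rdf_triples("http://e/s", "http://e/q", "w",
                              object_type = "literal"), index = idx2)
  expect_error(merge_pages(a, b), "two titles")
})

test_that("sequentially importing two halves matches one-shot import semantically", {
  withr::with_seed(31, {
    for (rep in 1:4) {
      g <- generate_fixture("random", 40, seed = 100 + rep)
      rows <- sample(nrow(g))
      half1 <- g[sort(rows[1:(nrow(g) %/% 2)]), ]
      half2 <- g[sort(rows[(nrow(g) %/% 2 + 1):nrow(g)]), ]
      idx <- title_index()
      s1 <- import_rdf(new_rdf_triples(half1), index = idx)
      s2 <- import_rdf(new_rdf_triples(half2), index = idx)
      seq_site <- merge_pages(s1, s2)
      back <- filter_metadata(export_rdf(seq_site, include_metadata = TRUE))
      expect_identical(write_ntriples(back), write_ntriples(g))
    }
  })
})

test_that("total imported triples equal total facts (fact conservation)", {
  for (g in fixture_grid(n = 15, seeds = 1)) {
    site <- import_rdf(g)
    expect_equal(nrow(site$facts), nrow(g))
  }
})

test_that("overloaded subjects trigger the configurable fact-count warning", {
  n <- 30
  ts <- rdf_triples(rep("http://e/huge", n), rep("http://e/p", n),
                    paste0("v", seq_len(n)), object_type = "literal")
  cfg <- resolver_config(fact_warn_threshold = 10)
  expect_warning(import_rdf(ts, cfg = cfg), "more than 10 facts")
  expect_silent(import_rdf(ts))
})
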