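test_that("sanitize_title applies the documented rewrite rules", {
  expect_equal(sanitize_title("gene_x [1]"), "Gene x -1-")
  expect_equal(sanitize_title("Aspirin"), "Aspirin")
  expect_equal(sanitize_title("  many   spaces\tand_under  "),
               "Many spaces and under")
  expect_equal(sanitize_title("a#b<c>d|e"), "A-b-c-d-e")
  expect_equal(sanitize_title(""), "")
})

test_that("sanitize_title is idempotent on random strings and respects the byte cap", {
  withr::with_seed(11, {
    for (i in 1:200) {
      s <- rawToChar(as.raw(sample(c(1:126), sample(1:40, 1),
                                   replace = TRUE)))
      out <- sanitize_title(s)
      expect_identical(sanitize_title(out), out)
    }
  })
  long <- paste(rep("å", 200), collapse = "")  # 2 bytes per char
  out <- sanitize_title(long)
  expect_lte(nchar(out, type = "bytes"), 255L)
  expect_identical(sanitize_title(out), out)
})

test_that("local_part takes the segment after the last slash or hash", {
  expect_equal(local_part("http://ex.org/a/b#C9"), "C9")
  expect_equal(local_part("http://ex.org/a/b"), "b")
  expect_equal(local_part("http://ex.org/a/"), "")
  expect_equal(local_part("urn:x:y"), "urn:x:y")
})

test_that("abbreviate_uri substitutes the longest matching namespace", {
  expect_equal(abbreviate_uri("http://ex.org/vocab/pKa",
                              c(v = "http://ex.org/vocab/")), "v pKa")
  expect_true(is.na(abbreviate_uri("http://other.org/x",
                                   c(v = "http://ex.org/vocab/"))))
  expect_true(is.na(abbreviate_uri("http://ex.org/vocab/",
                                   c(v = "http://ex.org/vocab/"))))
  # nested namespaces: longest wins, checked against a brute-force
  # oracle over all declared entries
  pfx <- c(a = "http://e/x/", b = "http://e/x/y/", c = "http://e/")
  uris <- c("http://e/x/y/z", "http://e/x/q", "http://e/top", "http://f/n")
  brute <- vapply(uris, function(u) {
    hits <- pfx[startsWith(u, pfx) & nchar(u) > nchar(pfx)]
    if (length(hits) == 0L) return(NA_character_)
    best <- hits[which.max(nchar(hits))]
    paste0(names(best), " ", substring(u, nchar(best) + 1L))
  }, character(1), USE.NAMES = FALSE)
  expect_equal(abbreviate_uri(uris, pfx), brute)
})

test_that("title strategies apply strictly in priority order", {
  cfg <- resolver_config(prefixes = c(on = "http://ex.org/onto#"))
  # strategy 1 (label) beats strategy 2 (prefix) beats strategy 3
  lab <- rdf_triples("http://ex.org/onto#d1",
                     "http://purl.org/dc/elements/1.1/title", "Aspirin",
                     object_type = "literal")
  idx <- title_index()
  expect_equal(resolve_title("http://ex.org/onto#d1", lab, cfg, idx),
               "Aspirin")
  expect_equal(resolve_title("http://ex.org/onto#d2", NULL, cfg, idx),
               "On d2")
  cfg0 <- resolver_config()
  expect_equal(resolve_title("http://ex.org/onto#GeneX42", NULL, cfg0, idx),
               "GeneX42")
})

test_that("an already-indexed URI short-circuits resolution (strategy 0)", {
  cfg <- resolver_config()
  idx <- title_index()
  first <- resolve_title("http://e/x", NULL, cfg, idx)
  n <- index_size(idx)
  lab <- rdf_triples("http://e/x",
                     "http://www.w3.org/2000/01/rdf-schema#label",
                     "Better name", object_type = "literal")
  expect_identical(resolve_title("http://e/x", lab, cfg, idx), first)
  expect_equal(index_size(idx), n)
})

test_that("label-property priority and value tie-breaks are deterministic", {
  cfg <- resolver_config()
  st <- rdf_triples(
    rep("http://e/x", 3),
    c("http://www.w3.org/2000/01/rdf-schema#label",
      "http://purl.org/dc/elements/1.1/title",
      "http://purl.org/dc/elements/1.1/title"),
    c("Rdfs label", "B title", "A title"), object_type = "literal")
  # dc:title outranks rdfs:label; smallest dc:title value wins the tie
  expect_equal(resolve_title("http://e/x", st, cfg, title_index()),
               "A title")
})

test_that("resolution fails with the URI when every strategy sanitizes to empty", {
  expect_error(resolve_title("http://ex.org/a/", NULL, resolver_config(),
                             title_index()),
               "http://ex.org/a/")
})

test_that("disambiguation appends the smallest free numeric suffix and keeps a bijection", {
  idx <- title_index()
  expect_equal(disambiguate("X", "http://e/1", idx), "X")
  expect_equal(disambiguate("X", "http://e/1", idx), "X")  # same URI reuses
  expect_equal(disambiguate("X", "http://e/2", idx), "X (2)")
  uris <- paste0("http://e/n", 1:20)
  titles <- vapply(uris, function(u) disambiguate("Collide", u, idx),
                   character(1))
  expect_equal(length(unique(titles)), 20L)
  expect_setequal(titles, c("Collide", paste0("Collide (", 2:20, ")")))
  # brute-force inverse check
  for (i in seq_along(uris)) {
    expect_equal(index_uri_of(idx, titles[[i]]), uris[[i]])
    expect_equal(index_title_of(idx, uris[[i]]), titles[[i]])
  }
})

test_that("the URI/title index is an exact bijection on every fixture", {
  for (g in fixture_grid(n = 20, seeds = 1:2)) {
    site <- import_rdf(g)
    tbl <- tidy(site$index)
    expect_equal(anyDuplicated(tbl$uri), 0L)
    expect_equal(anyDuplicated(tbl$title), 0L)
    expect_equal(vapply(tbl$title, function(t) index_uri_of(site$index, t),
                        character(1), USE.NAMES = FALSE), tbl$uri)
  }
})

test_that("resolution is deterministic across fresh runs on identical input", {
  g <- generate_fixture("random", 40, seed = 2, label_fraction = 1)
  t1 <- tidy(import_rdf(g)$index)
  t2 <- tidy(import_rdf(g)$index)
  expect_identical(t1, t2)
})

test_that("resolver configuration loads from YAML with defaults filled in", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "label_properties:",
    "  - http://www.w3.org/2004/02/skos/core#prefLabel",
    "prefixes:",
    "  chebi: http://purl.obolibrary.org/obo/CHEBI_",
    "namespace_separator: ' '",
    "base_url: http://wiki.example.org/w"), path)
  cfg <- read_resolver_config(path)
  expect_equal(cfg$label_properties,
               "http://www.w3.org/2004/02/skos/core#prefLabel")
  expect_equal(cfg$prefixes,
               c(chebi = "http://purl.obolibrary.org/obo/CHEBI_"))
  expect_equal(cfg$base_url, "http://wiki.example.org/w")
  expect_equal(cfg$type_property_name, resolver_config()$type_property_name)
})

test_that("the index dumps to a two-column TSV", {
  idx <- title_index()
  disambiguate("A", "http://e/1", idx)
  disambiguate("B", "http://e/2", idx, ns = "Property")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_index_tsv(idx, path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$title, c("A", "Property:B"))
})
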