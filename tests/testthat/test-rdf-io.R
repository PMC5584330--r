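test_that("a minimal N-Triples statement parses to one plain-literal triple", {
  ts <- parse_ntriples('<http://ex.org/a> <http://ex.org/p> "v" .')
  expect_s3_class(ts, "rdf_triples")
  expect_equal(nrow(ts), 1L)
  expect_equal(ts$subject, "http://ex.org/a")
  expect_equal(ts$object_type, "literal")
  expect_equal(ts$object, "v")
  expect_true(is.na(ts$datatype) && is.na(ts$language))
})

test_that("empty input, comments and blank lines give an empty triple set", {
  expect_equal(nrow(parse_ntriples("")), 0L)
  expect_equal(nrow(parse_ntriples("# only a comment\n\n   \n")), 0L)
})

test_that("byte-identical statements collapse, matching a line-dedup oracle", {
  lines <- c('<http://ex.org/a> <http://ex.org/p> "v" .',
             '<http://ex.org/a> <http://ex.org/q> <http://ex.org/b> .',
             '<http://ex.org/a> <http://ex.org/p> "v" .')
  ts <- parse_ntriples(paste(lines, collapse = "\n"))
  expect_equal(nrow(ts), length(unique(lines)))
})

test_that("literal escapes decode and round-trip through the writer", {
  text <- '<http://ex.org/a> <http://ex.org/p> "line\\nbreak\\ttab \\"q\\" back\\\\slash \\u00E5" .'
  ts <- parse_ntriples(text)
  expect_equal(ts$object, "line\nbreak\ttab \"q\" back\\slash å")
  expect_equal(parse_ntriples(write_ntriples(ts)), ts, ignore_attr = TRUE)
})

test_that("typed and language-tagged literals parse correctly", {
  ts <- parse_ntriples(paste0(
    '<http://e/s> <http://e/p> "3.5"^^<http://www.w3.org/2001/XMLSchema#decimal> .\n',
    '<http://e/s> <http://e/q> "hi"@en-GB .'))
  expect_equal(sort(ts$datatype, na.last = TRUE),
               c("http://www.w3.org/2001/XMLSchema#decimal", NA))
  expect_equal(sort(ts$language, na.last = TRUE), c("en-GB", NA))
})

test_that("malformed statements fail with the offending line number", {
  expect_error(parse_ntriples("# ok\n<http://e/s> <http://e/p> .\n"),
               "line 2")
  expect_error(parse_ntriples('<http://e/s> "notapredicate" <http://e/o> .'),
               "malformed")
})

test_that("relative IRIs are rejected", {
  expect_error(parse_ntriples('</rel> <http://e/p> "v" .'), "relative IRI")
})

test_that("blank nodes are skolemized into stable urn:bnode IRIs with a warning", {
  text <- '_:b1 <http://e/p> _:b2 .'
  expect_warning(ts <- parse_ntriples(text, bnode_scope = "t1"),
                 "skolemized 2 blank node")
  expect_equal(ts$subject, "urn:bnode:t1:b1")
  expect_equal(ts$object, "urn:bnode:t1:b2")
  suppressWarnings({
    again <- parse_ntriples(text, bnode_scope = "t1")
  })
  expect_identical(write_ntriples(ts), write_ntriples(again))
})

test_that("the writer emits canonical sorted output and inverts the parser", {
  expect_identical(write_ntriples(rdf_triples()), "")
  one <- rdf_triples("http://e/s", "http://e/p", "v", object_type = "literal")
  out <- write_ntriples(one)
  expect_match(out, " \\.\n$")
  expect_equal(length(strsplit(out, "\n")[[1]]), 1L)
  for (g in fixture_grid(n = 12, seeds = 1:2)) {
    txt <- write_ntriples(g)
    lines <- strsplit(txt, "\n")[[1]]
    expect_identical(lines, lines[order(lines, method = "radix")])
    expect_equal(parse_ntriples(txt), g, ignore_attr = TRUE)
  }
})

test_that("aggregation per subject conserves the input set", {
  ts <- rdf_triples(c("http://e/s", "http://e/s", "http://e/t"),
                    c("http://e/p", "http://e/q", "http://e/p"),
                    c("x", "y", "z"), object_type = "literal")
  groups <- aggregate_by_subject(ts)
  expect_named(groups, c("http://e/s", "http://e/t"))
  expect_equal(nrow(groups[["http://e/s"]]), 2L)
  expect_length(aggregate_by_subject(rdf_triples()), 0L)

  g <- generate_fixture("random", 125, seed = 7)  # ~500 triples
  groups <- aggregate_by_subject(g)
  sizes <- vapply(groups, nrow, integer(1))
  expect_equal(sum(sizes), nrow(g))
  # independent grouping oracle: per-subject counts via tapply
  oracle <- tapply(seq_len(nrow(g)), g$subject, length)
  expect_equal(sizes[names(oracle)], oracle[names(oracle)],
               ignore_attr = TRUE)
  # no triple in two groups; union reproduces the set
  rebuilt <- do.call(rbind, lapply(groups, as.data.frame))
  expect_true(triples_equal(rdf_triples(rebuilt$subject, rebuilt$predicate,
                                        rebuilt$object, rebuilt$object_type,
                                        rebuilt$datatype, rebuilt$language),
                            g))
})

test_that("duplicate triples collapse and equality is order-insensitive", {
  a <- rdf_triples(c("http://e/s", "http://e/s"), c("http://e/p", "http://e/p"),
                   c("v", "v"), object_type = "literal")
  expect_equal(nrow(a), 1L)
  b <- tiny_graph()
  shuffled <- b[rev(seq_len(nrow(b))), ]
  expect_true(triples_equal(b, rdf_triples(
    shuffled$subject, shuffled$predicate, shuffled$object,
    shuffled$object_type, shuffled$datatype, shuffled$language)))
})
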