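test_that("literal escaping matches the documented entities and inverts exactly", {
  expect_equal(escape_literal("a|b"), "a&#124;b")
  expect_equal(escape_literal("plain text"), "plain text")
  expect_equal(unescape_literal(escape_literal("x ]] y {{ z | w")),
               "x ]] y {{ z | w")
  withr::with_seed(5, {
    pool <- c(letters, " ", "|", "[", "]", "{", "}", "=", ";", "&", "<",
              ">", "\n", "\r", "#", "1", "\"", "\\", "å", "::")
    for (i in 1:400) {
      s <- paste(sample(pool, sample(0:25, 1), replace = TRUE),
                 collapse = "")
      expect_identical(unescape_literal(escape_literal(s)), s)
    }
  })
})

test_that("rendered pages carry fact syntax, one Equivalent URI, and type annotations", {
  ts <- rdf_triples("http://e/aspirin", "http://e/pKa", "3.5",
                    object_type = "literal",
                    datatype = "http://www.w3.org/2001/XMLSchema#decimal")
  site <- import_rdf(ts)
  r <- render_pages(site)
  main <- r$text[r$ns == "Main"]
  expect_match(main, "\\[\\[PKa::3\\.5", fixed = FALSE)
  expect_equal(
    lengths(regmatches(main, gregexpr("Equivalent URI::", main))), 1L)
  prop <- r$text[r$ns == "Property"]
  expect_match(prop, "[[Has type::Number]]", fixed = TRUE)
  # single-page renderer agrees
  one <- render_page(site, r$title[r$ns == "Property"])
  expect_identical(one$text, prop)
  expect_error(render_page(site, "No such page"), "no page")
})

test_that("every rendered imported page contains its Equivalent URI exactly once", {
  g <- generate_fixture("random", 20, seed = 8)
  r <- render_pages(import_rdf(g))
  imported <- r$ns != "Template"
  counts <- lengths(regmatches(r$text[imported],
                               gregexpr("\\[\\[Equivalent URI::",
                                        r$text[imported])))
  expect_true(all(counts == 1L))
})

test_that("render and parse are inverse on the page model, with and without templates", {
  for (kind in c("random", "drugmet_like")) {
    g <- generate_fixture(kind, 12, seed = 6)
    for (templates in c(TRUE, FALSE)) {
      site <- import_rdf(g, templates = templates)
      r <- render_pages(site)
      for (i in seq_len(nrow(r))) {
        if (r$ns[i] == "Template") next
        pg <- parse_page(r$title[i], r$text[i], specs = site$specs,
                         ns = r$ns[i])
        want_facts <- sort_facts(site$facts[site$facts$page == r$title[i], ])
        expect_identical(sort_facts(pg$facts), want_facts)
        row <- site$pages[site$pages$title == r$title[i], ]
        expect_identical(pg$equivalent_uri, row$equivalent_uri)
        expect_identical(pg$smw_type, row$smw_type)
        expect_identical(pg$template, row$template)
        expect_identical(pg$free_text, row$free_text)
      }
    }
  }
})

test_that("template bodies regenerate their specification on parse", {
  g <- generate_fixture("drugmet_like", 5, seed = 2)
  site <- import_rdf(g)
  r <- render_pages(site)
  tmpl <- which(r$ns == "Template")[1]
  pg <- parse_page(r$title[tmpl], r$text[tmpl], ns = "Template")
  got <- pg$spec[order(pg$spec$param), ]
  want <- site$specs[order(site$specs$param), ]
  expect_equal(as.data.frame(got), as.data.frame(want), ignore_attr = TRUE)
})

test_that("inline facts, prose and mixed pages parse as expected", {
  p <- parse_page("X", "[[Prop a::Val A]]\n[[Prop b::3<!--plain-->]]")
  expect_equal(nrow(p$facts), 2L)
  expect_equal(p$facts$value_kind, c("page", "literal"))
  expect_equal(p$free_text, "")

  prose <- "Just some notes.\nSecond line."
  p2 <- parse_page("Y", prose)
  expect_equal(nrow(p2$facts), 0L)
  expect_identical(p2$free_text, prose)
})

test_that("set-parser-function calls are accepted on parse", {
  p <- parse_page("X", "{{#set:Height=1.88<!--plain-->|Friend=Bob}}")
  expect_equal(nrow(p$facts), 2L)
  expect_setequal(p$facts$property, c("Height", "Friend"))
  expect_equal(p$facts$value_kind[p$facts$property == "Friend"], "page")
})

test_that("unknown templates and malformed facts degrade to free text without failing", {
  txt <- "{{Mystery|a=1}}\n[[broken::no close\nplain tail"
  expect_warning(p <- parse_page("X", txt), "malformed fact")
  expect_equal(nrow(p$facts), 0L)
  expect_match(p$free_text, "Mystery", fixed = TRUE)
  expect_match(p$free_text, "plain tail", fixed = TRUE)
})

test_that("parsing is total on arbitrary text", {
  withr::with_seed(13, {
    pool <- c(letters, "[", "]", "{", "}", ":", "|", "=", "\n", "#", "<",
              "!", "-", ">", "&", ";")
    for (i in 1:100) {
      s <- paste(sample(pool, sample(0:60, 1), replace = TRUE),
                 collapse = "")
      expect_no_error(suppressWarnings(parse_page("Z", s)))
    }
  })
})
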