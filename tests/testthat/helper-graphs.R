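# Shared fixture builders for the test suite. Everything is generated
# in code; no data files.

EX <- "http://ex.org/"

# A tiny mixed graph: IRI links, typed/plain/lang literals, a label.
tiny_graph <- function() {
  rdf_triples(
    subject = c(paste0(EX, "a"), paste0(EX, "a"), paste0(EX, "a"),
                paste0(EX, "b"), paste0(EX, "b")),
    predicate = c(paste0(EX, "p"), paste0(EX, "knows"),
                  "http://www.w3.org/2000/01/rdf-schema#label",
                  paste0(EX, "pKa"), paste0(EX, "note")),
    object = c("v", paste0(EX, "b"), "Alpha",
               "3.5", "hello"),
    object_type = c("literal", "iri", "literal", "literal", "literal"),
    datatype = c(NA, NA, NA,
                 "http://www.w3.org/2001/XMLSchema#decimal", NA),
    language = c(NA, NA, NA, NA, "en"),
    prefixes = c(ex = EX)
  )
}

# All fixture kinds at a given entity count, fixed seeds.
fixture_grid <- function(n = 15, seeds = 1:3) {
  out <- list()
  for (kind in c("orphanet_like", "drugmet_like", "random")) {
    for (seed in seeds) {
      out[[paste(kind, seed, sep = "_")]] <-
        generate_fixture(kind, n_entities = n, seed = seed)
    }
  }
  out
}

canonical_nt <- function(ts) write_ntriples(ts)

# Full import -> dump -> parse -> export -> filter pipeline.
roundtrip_via_dump <- function(g, cfg = resolver_config()) {
  site <- import_rdf(g, cfg = cfg)
  site2 <- site_from_dump(read_dump(write_dump(site)), cfg = cfg)
  filter_metadata(export_rdf(site2, origuris = TRUE,
                             include_metadata = TRUE))
}
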