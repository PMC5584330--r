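---
title: "Round-tripping RDF through a semantic wiki page model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Round-tripping RDF through a semantic wiki page model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdfwikiforge)
```

## The problem

Semantic wikis such as Semantic MediaWiki (SMW) store machine-readable
*facts* — property–value pairs embedded in page text — alongside
ordinary prose, which makes them attractive platforms for collaborative
curation of biomedical linked data: rare-disease gene associations,
compound property measurements, and similar moderately sized but
structurally rich datasets. What SMW historically lacked is a general,
*lossless* batch import of RDF: a way to turn a triple set into a page
structure, let people edit around it, and later export exactly the
triples that went in.

`rdfwikiforge` implements that conversion pipeline and its inverse in
R. One triple set goes in; one wiki page per subject resource comes
out, each page carrying its facts, a stored **Equivalent URI** link to
the original resource, auto-generated templates per `rdf:type`, and a
MediaWiki XML dump for bulk import. The export direction walks the page
model back to triples using the Equivalent-URI links, and a metadata
filter removes what the wiki itself added, so that

```
filter_metadata(export(import(G))) == G
```

holds as a set of triples, byte-exactly after canonical N-Triples
serialization. That identity is the package's defining property and the
core of its test suite.

## The pipeline

1. **Parse.** N-Triples is the canonical input format and is supported
   in full; a documented Turtle subset (`@prefix`/`@base`, prefixed
   names, `;`/`,` abbreviations, the `a` keyword, typed and
   language-tagged literals, bare numeric/boolean shorthand) is also
   accepted. Unsupported Turtle constructs — collections, anonymous
   blank-node property lists, triple-quoted strings — fail loudly with
   the construct name and line, never silently dropping statements.
   RDF graphs are sets, so duplicate statements collapse on parse.
2. **Aggregate per subject.** Each distinct subject becomes one wiki
   page; its triples become the page's facts.
3. **Resolve titles.** Every URI is mapped to a human-friendly,
   MediaWiki-legal title by an ordered strategy chain (below), and the
   URI↔title pairs are registered in a bidirectional index.
4. **Build facts and infer datatypes.** Predicates become
   Property-namespace pages annotated with an SMW datatype inferred
   from the XSD types observed in the data; IRI objects become page
   links (stub pages with full Equivalent URIs are created for
   referenced-but-subjectless resources so links never dangle);
   literal objects are kept verbatim.
5. **Synthesize templates.** For each distinct `rdf:type` value among
   the subjects, one template is generated, named after the type's
   page, with one parameter per property used by subjects of that type;
   typed pages render their facts as a call to that template.
6. **Render and dump.** Pages are rendered to SMW-style wikitext and
   wrapped in a MediaWiki XML export file (schema export-0.10,
   namespaces Main=0, Template=10, Property=102), with a fixed default
   timestamp so dumps are byte-reproducible.

The export direction (`site_from_dump()` + `export_rdf()`) inverts
steps 6→2 and finally filters wiki metadata.

## Title resolution

Strategies are tried strictly in order, stopping at the first that
yields a non-empty sanitized name:

0. an existing index entry for the URI (an existing page) is reused;
1. the value of the first configured label property present among the
   subject's triples — default priority `dc:title` > `rdfs:label` >
   `skos:prefLabel` > `foaf:name`, configurable; among multiple values
   of one property the lexicographically smallest wins, so resolution
   is deterministic;
2. namespace abbreviation via the prefix map (longest declared
   namespace wins); the separator between prefix label and local
   remainder is a space, because a colon would collide with MediaWiki
   namespace syntax;
3. the URI's local part (after the last `/` or `#`).

Sanitization replaces characters MediaWiki forbids, and additionally
`: ; = &`, with `-`. The extra four are stricter than MediaWiki
itself: they are the delimiters of the embedded fact syntax and of
template argument lists, and banning them from titles is what makes
the wikitext dialect unambiguous to parse. Underscores become spaces,
whitespace is collapsed, the first character is uppercased, and the
result is truncated to 255 bytes on a character boundary; the function
is idempotent.

Collisions get the smallest free numeric suffix, `"Name (2)"`,
`"Name (3)"`, … — the common wiki disambiguation style. Registration is
atomic with resolution, so the URI→title and title→URI maps are exact
inverses at all times. Whether a *label* collision should instead fall
back to abbreviation is genuinely open; the suffix policy was chosen
because it preserves the label's readability and keeps resolution a
pure function of the graph.

Within one import, titles are resolved for the whole graph up front
(subjects, then object-only URIs, then predicates, each in canonical
order). This makes title assignment — including collision suffixes —
independent of how the import is chunked, which in turn makes the
chunk-partition invariance below exact rather than approximate.

Blank nodes have no URI to link back to; they are skolemized on input
to `urn:bnode:<scope>:<label>` IRIs (with a warning count) so every
anonymous resource can still become an addressable page. The original
tools' blank-node behavior is undocumented; skolemization is this
package's choice and is flagged here.

## The wikitext dialect

Facts render as inline `[[Property::value]]` lines (the `{{#set:...}}`
parser-function form is accepted on parse but never emitted — one
canonical dialect keeps the round trip testable). Three details make
the dialect lossless:

* **Literal markers.** Every literal value ends in an invisible HTML
  comment: `<!--^^datatypeIRI-->` for typed literals, `<!--@lang-->`
  for language-tagged ones, `<!--plain-->` otherwise. SMW wikitext has
  no lexical slot for datatypes, and without a marker on *plain*
  literals, `[[P::Aspirin]]` would be ambiguous between a page link
  and a literal equal to a page title. Markers render invisibly in
  MediaWiki.
* **Escaping.** Characters that would break fact syntax, template
  argument lists or the XML layer (`& < > [ ] { } | = ;` and newlines)
  are HTML-entity encoded in a single pass, so escaping is injective
  and `unescape(escape(s)) == s` for arbitrary strings. Multi-valued
  template parameters are joined with `;`; the splitter distinguishes
  separator semicolons from entity terminators, so escaped values may
  contain any character.
* **Invertible templates.** A generated template body is one inline
  fact pattern per parameter (`[[Prop::{{{param|}}}]]`), so expanding a
  call through its spec yields exactly the facts that were packed, and
  the spec itself can be re-read from the template page in a dump.

Parsing wikitext is total: unknown templates and malformed fact-like
lines degrade to free text (with a warning), because real wikis are
messy and an exporter must never die on a page of prose. One
asymmetry is accepted: the renderer separates facts from free text
with one blank line, which the parser strips, so free text beginning
with blank lines does not round-trip those leading blanks.

## Datatype inference

A property's SMW type is decided from all values observed for it:
all-IRI → `Page`; literals whose XSD types all map to one label →
that label (`integer`/`decimal`/`double`/`float` → `Number`,
`date`/`dateTime` → `Date`, `boolean` → `Boolean`, `anyURI` → `URL`);
anything else — plain, language-tagged, or mixed literal types —
→ `Text`. A property holding both pages and literals gets `Page` plus
a warning; its literal facts still round-trip because of the value
markers. Inference runs over the *merged* fact table (facts retain
their value kind and datatype), so the result is independent of chunk
partitioning and merge history.

`rdf:type` statements are kept as ordinary facts under the
configurable property name `"Rdf type"` *in addition to* driving
template synthesis — also when a template call already encodes the
type — because export must reconstruct them; the type property is
registered in the index so the original predicate URI is restored.

## Chunking, merging, replication

`--chunksize`/`--offset` batch an import restartably: the first
`offset` triples (canonical order) are skipped and the remainder is
processed in chunks. Merging is set-union on facts — re-imports never
duplicate and never delete a fact (deletion detection is out of scope
by design), and existing free text and manually added facts are
untouched. Binding one Equivalent URI to two titles is an error.
Property types and templates are recomputed from the merged fact
table after every public merge, which makes `merge(x, x) == x` exact.

The replicator reduces a SPARQL-endpoint mirror to its algorithmic
core: repeatedly fetch all-wildcard triple pages of `batch_limit`
from a source, import each batch, and advance the offset by the page
size; a short (or empty) page ends the run. Paging is only sound
against a source with a stable total order — the in-memory store
orders canonically and the (never network-tested) SPARQL adapter adds
an explicit `ORDER BY`, a requirement real endpoints do not always
honor and which is therefore documented rather than assumed. A source
failure or batch budget leaves a resumable state with the last safe
offset; type inference and template synthesis are deferred to a single
finalize step after the last batch, a pure recomputation that does not
change the result. Interrupt-and-resume therefore reproduces the
uninterrupted sink exactly.

## The synthetic-data generators

Tests and the acceptance script run entirely on generated graphs, in
three families:

* `orphanet_like` — genes and disorders linked *only* through
  intermediate association nodes (n genes, n disorders, ~1.5n typed
  association nodes with a status literal and a gene symbol literal;
  `rdfs:label` on a configurable fraction of entities). This exercises
  the indirect-linking structure typical of rare-disease association
  data.
* `drugmet_like` — compounds typed `Compound` carrying
  `xsd:decimal` pKa literals and links to publications, with
  `dc:title` labels; this drives template synthesis and `Number`
  inference, like curated compound-property collections.
* `random` — uniform graphs over three namespaces (one with a declared
  prefix, one nested inside it to exercise longest-match abbreviation,
  one with no prefix), eleven predicates with one fixed value kind
  each covering every row of the datatype table, plus deliberately
  hostile literals (pipes, brackets, braces, newlines, quotes,
  backslashes, non-ASCII). Label and type coverage are dials
  (default 0.5 each), and the small label vocabulary forces title
  collisions, so disambiguation is exercised constantly.

The same recipe and seed give byte-identical N-Triples. What the
generators deliberately do **not** emulate: blank nodes (skolemization
is tested separately on hand-written input), named graphs, mixed
page/literal predicates (the inference table's warning row is tested
directly instead), and real-world scale beyond ~10^5 triples. Passing
tests on these fixtures therefore demonstrate structural and
serialization correctness, not robustness to arbitrary third-party
RDF in the wild.

Problem sizes used by the checked-in system tests: 201 graphs of
10–2000 triples for the round-trip identity; replication sources of
~1,200 triples (batch limits 1 and 7) and ~5,000 triples (limits 7 and
100); one ~100,000-triple graph for the conversion completion check.
These sizes keep the whole suite in the minutes range on one CPU while
still crossing every power-of-ten below the demonstrator scale.

## Numerical and formatting choices

* All orderings are codepoint-lexicographic (byte order of UTF-8),
  locale-independent; every serialization is therefore deterministic
  and diffable.
* Canonical N-Triples output escapes only `\" \\ \n \r \t` and keeps
  other characters as raw UTF-8.
* Dumps default to the fixed timestamp `1970-01-01T00:00:00Z`;
  `--timestamp now` opts into wall-clock stamps.
* Wiki-minted URIs (used when a page has no stored Equivalent URI, or
  when `origuris` is off) have the form
  `<base>/Special:URIResolver/<percent-encoded title>` with spaces as
  underscores. The exact encoding SMW uses internally varies across
  releases; this package documents its own and applies it
  consistently.
* The wiki-metadata predicate set removed by `filter_metadata()` is an
  explicit, configurable list (`owl:sameAs` for Equivalent URI, a
  swivt-style type predicate for Has type, page date and display-title
  predicates).
* Pages holding more than 1000 facts (configurable) trigger a warning:
  technically fine, practically unwieldy to edit.

## An example

```{r example}
g <- generate_fixture("drugmet_like", n_entities = 3, seed = 1)
site <- import_rdf(g)
glance(site)
cat(render_page(site, site$pages$title[!is.na(site$pages$template)][1])$text)
back <- filter_metadata(export_rdf(site, origuris = TRUE,
                                   include_metadata = TRUE))
identical(write_ntriples(back), write_ntriples(g))
```

## Known limitations

* Input formats are N-Triples and the Turtle subset only; no RDF/XML,
  JSON-LD, TriG or N-Quads, and no named-graph support.
* Deletion is never detected on re-import: facts removed upstream
  survive in the wiki.
* Plain literals and `xsd:string`-typed literals are kept distinct;
  the generators avoid `xsd:string`, and datasets using it will
  round-trip it faithfully but as a typed literal.
* Free text starting with blank lines loses those leading blanks
  through render/parse.
* The SPARQL HTTP adapter is provided but exercised only against
  in-memory sources; endpoint quirks (ordering, encodings) are
  untested by design.
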