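---
title: "Indexing and searching biological databanks with seqindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indexing and searching biological databanks with seqindex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqindex)
```

## The problem

Labs accumulate flat-file databanks — GenBank and EMBL divisions, GFF3
annotation, FASTA sequence sets, PDB structures — and need to answer
questions like *"all CDS features between positions A and B on chromosome
C"*, or *"every record mentioning a kinase"*, against **their own** copies
of the data, without shipping it to a remote service. `seqindex` is an
embeddable indexing platform for exactly that: it parses bank files into
key/value documents, indexes them in an inverted index with a Lucene-style
query language, stores bulk payloads (sequences, structure bodies) in a
chunked key/value store, and answers genome-browser-style region queries.
Every indexed document remembers its provenance — file path, byte offset
and byte length of the original record — so any search hit can be traced
back to, and reproduced from, the untouched bank file.

## The data model

A **document** is one record's metadata: a mapping from field names to
*ordered, multi-valued* lists of values (GenBank qualifiers repeat, GFF3
`Dbxref` attributes hold several accessions), a **content-type** of the
form `biosequence/<format>` recorded at indexing time, and an optional
**source location** `(path, offset, length)`. The content-type routes a
result to the right consumer: `biosequence/gff` documents (GFF3 features
*and* exploded GenBank/EMBL feature tables) are region-queryable;
`biosequence/pdb` documents carry the whole structure file as a payload
for a viewer.

A **field schema** declares, per field, a kind (`text`, `keyword` or
`numeric`) and whether the field is *indexed* (usable as a query filter),
*stored* (returned with results), or both. The schema is **open**: an
undeclared field defaults to `{text, indexed, stored}`. Bank formats
carry unpredictable qualifiers, and silently dropping them — or refusing
to index them — would be worse than the modest index overhead. The
shipped `default_schema()` types `start`, `end`, `length` and `score` as
numeric (so ranged queries compare numbers) and identifier-like fields
(`seqid`, `type`, `id`, `accession`, `strand`) as keywords.

## Parsing and provenance

The five built-in readers (FASTA, GFF3, GenBank, EMBL, PDB) are written
against byte-level line scanning rather than a third-party parser because
the byte-accurate source span *is* the contract: for every emitted
document, re-reading `[offset, offset + length)` from the bank file and
re-parsing that slice must reproduce the document exactly. Tests verify
this property for every record of generated thousand-record banks, and
cross-check FASTA content against `Biostrings`.

Conventions worth knowing:

* Coordinates in GFF3/GenBank/EMBL feature documents stay **1-based,
  end-inclusive**, exactly as in the source format. The only 1-based to
  0-based conversion in the package happens in `sequence_of_region()`.
* GenBank/EMBL **feature explosion** is on by default: each feature-table
  entry becomes its own searchable document typed `biosequence/gff`, with
  `seqid` set to the record accession — so a GenBank division and a GFF3
  annotation file answer the same region queries. `explode = FALSE`
  gives header-only indexing.
* Compound and fuzzy locations (`join(...)`, `<`/`>`) are reduced to
  their outermost `min..max` span and flagged `location_exact: false`;
  region queries need a single interval, and the original location text
  is always recoverable from the source bytes.
* Sequences are uppercased and stripped of whitespace/position digits
  before storage: ORIGIN-block formatting is presentation, not data.
* A malformed GFF3 line (wrong column count) is a *recoverable* error:
  skipped, logged, reported in the indexing job report. Structural errors
  (a GenBank record without its `//` terminator) abort that record with a
  `truncated_record` condition. Banks are large and dirty; one bad line
  should not cost a million-record ingest.
* `/translation` qualifiers become chunk-store payloads keyed
  `<doc_id>:translation`, not searchable fields — they are bulk data.

New formats plug in through `register_format_plugin()`: a reader function
with the same contract as the built-ins, bound to a `-t <name>` token.
Field recoding rules (`recoder_rule()`) rewrite fields at indexing time —
e.g. splitting `db_xref` values `taxon:9606` into separately searchable
database and accession parts.

## The index and its scoring model

The embedded index keeps, per `(field, term)`, a posting list of
document ids with within-value token positions; per numeric field, a
sorted `(value, doc_id)` table; and a stored-fields store. Mutations
(add, partial update, delete) queue as pending operations and become
visible **atomically at commit**; the on-disk segment (a self-describing
JSON file) is replaced via temp-file-and-rename, so a crash between add
and commit leaves the previous committed state intact.

Text fields pass through a simple analyzer: lowercase, split on anything
that is not a letter or digit, keeping `.`, `_`, `-` inside alphanumeric
runs. Keyword fields match as whole lowercased values; numeric fields
match by value. Multi-valued fields are indexed with a large position gap
between values, so phrases never match across value boundaries.

Matching a score is:

$$\mathrm{score}(d, q) \;=\; \sum_{t \in \text{leaves}(q)} \bigl(1 + \ln \mathrm{tf}(t, f, d)\bigr)\,\Bigl(1 + \ln \tfrac{N+1}{\mathrm{df}(t,f)+1}\Bigr)$$

summed over the positive term/phrase/prefix/fuzzy leaves matching in
field $f$; range and negated leaves contribute nothing, and a query with
no scoring leaf at all (a pure filter) scores every match 1.0. This is a
deliberately simple TF-IDF without document-length normalization: the
production search engines this design follows treat scoring as an
internal, version-dependent detail, so the package fixes a small,
closed-form, shard-stable model instead of emulating any of them. Ties
are broken by ascending document id, which makes paging deterministic and
testable. Fuzzy terms expand against the index vocabulary within
Damerau–Levenshtein distance 1 or 2 (adjacent transposition counts as one
edit).

## Shards and global statistics

An index can be split into independent shards behind one entry point
(`shardset()`, `distributed_search()`). Document routing is
`hash(doc_id) mod n_shards` by default — any shard count suits any input
mix — with an option to pin whole banks to shards. Queries run in two
phases: shards first report corpus sizes, per-term document frequencies
and fuzzy/prefix vocabulary expansions; these are summed/unioned into
*global* statistics; then every shard matches and scores with the global
numbers and the entry point merges by `(score desc, doc_id asc)`.

The two-phase exchange is the load-bearing design decision: with
per-shard IDF, a document's score would depend on which shard it landed
on, and the defining property — *any* partition of a corpus returns
hit-for-hit, score-identical results to one big index — would fail. The
test suite checks exactly that, over random 2-, 3- and 4-shard partitions
and 200 random queries, at a 1e-9 score tolerance (observed agreement is
bitwise, since the merge fixes one summation order). An unreachable shard
fails the whole query: returning partial results as if complete would be
silent data loss. High availability belongs to replicated infrastructure,
not to this library.

## The query language

`parse_query()` accepts a Lucene-style subset: `field:term`,
`field:"a phrase"`, inclusive ranges `field:[a TO b]` with `*` as open
bound, fuzzy `term~1`/`term~2` (bare `~` means 2), `prefix*`, uppercase
`AND`/`OR`/`NOT`, parentheses. Two adjacent clauses combine with `AND`
(filter-like semantics suit the typical use: *feature type X on
chromosome Y between A and B*), unfielded clauses search all indexed
full-text fields, and precedence is `NOT > AND > OR`. Boosts, regexes and
proximity operators are deliberately out of scope. `normalize_query()`
resolves the tree against a schema: terms are analyzed, a multi-token
term on a text field becomes an `AND` of its tokens, range bounds are
cast to the field's type, and a pure-`NOT` query is rewritten as
*match-all minus X*.

## Chunked payload storage

`store_put()` splits a datum into fixed-size chunks (64 KiB by default;
the original systems this mirrors do not document a size, and 64 KiB
keeps whole small sequences in one chunk while bounding the cost of
subrange reads on chromosomes). `store_get(key, start, stop)` uses
**0-based, stop-exclusive byte** coordinates — pure storage semantics —
and reads *only* the chunks overlapping the range, observable through a
chunk-read counter. The backend is a minimal put/get/delete/list
interface with embedded file-based and in-memory implementations, so a
remote key/value service could be slotted in without touching callers.

## Region queries

`features_in_region()` answers "which features overlap `seqid:start-end`"
as an index query (`content_type:biosequence/gff AND seqid:<id> AND
start:[* TO end] AND end:[start TO *]`) — closed-interval intersection on
1-based coordinates. Features are returned whole, not clipped; clipping
is a renderer's concern. Strand is reported but never filters.
`sequence_of_region()` slices the reference payload stored under the
seqid, and `export_region_gff()` serializes results as GFF3 that
round-trips through the parser (attributes ordered ID, Name, Parent, then
alphabetical).

## Service surface and CLI

The query surface mirrors a Solr-flavoured REST dialect — `/search` with
`q`/`start`/`rows` (JSON or CSV export with `;`-joined multi-values),
`/document/<id>` (all stored fields, provenance, storage links),
`/storage/<key>?start=&stop=`, `/region` — implemented as in-process
request/response functions returning `{status, body}` pairs. The package
is an embeddable library: the handlers contain all routing and error
semantics (400 with a column for query syntax errors, 404, 416) and can
sit behind any HTTP layer, while R scripts and the bundled `seqindex`
command-line tool (`inst/cli/seqindex`: `index`, `search`, `fetch`,
`region`, `gen` subcommands) use them directly. Offline bulk indexing is
the supported ingest path; the CLI exits 0 exactly when no record was
skipped.

## The synthetic-bank generator

`generate_bank()` writes format-valid FASTA/GFF3/GenBank/EMBL/PDB files
*and* their ground truth (expected fields, payloads, byte offsets) from
the same writer in one pass, fully determined by a seed. It emulates the
structural features that matter to an indexer — wrapped sequences,
60-column ORIGIN blocks with position numbers, qualifier continuation
lines, `complement()` locations, multi-valued `Dbxref` attributes,
embedded `##FASTA` sections, optional injected malformed lines with a
known skip count — and deliberately nothing biological beyond format
validity: no codon structure, no realistic gene models, uniform
ACGT sequences. Passing tests therefore demonstrate *format and
contract* correctness on clean-but-dirty-able inputs, not robustness to
every pathology of real public banks (multi-line GFF3 features sharing an
ID, exotic location operators, mixed encodings).

Default generator conditions used throughout the tests: 1,000-record
FASTA banks (50–400 bp), 1,000-feature GFF3 banks over four 5 kb
reference sequences, 100-record GenBank banks with 3–5 features each —
sizes chosen so every property suite (including the 200-query
brute-force oracle comparison and the shard-partition sweeps) runs in a
few minutes on one CPU while still exercising multi-chunk payloads,
multi-shard routing and paging depth.

## Numerical and degenerate-input choices

* Range bounds are inclusive on both ends, matching the `[a TO b]`
  bracket syntax.
* Offsets are always bytes; text is decoded as UTF-8 with a Latin-1
  fallback.
* Empty payloads are storable (`n_chunks = 0`); zero-record banks parse
  to empty results.
* Deleting an unknown id or storage key warns and does nothing;
  re-registering an identical content-type is a no-op, a conflicting one
  an error.
* The optional query-result cache is invalidated at commit and never
  load-bearing for correctness.

## Limitations

No replication, leader election or load balancing; single writer, many
readers; no Lucene file-format compatibility or score emulation; no
phrase-proximity scoring or relevance boosts; no DAS interface or
ontology layer. Query latency contracts are out of scope — the index is
an embedded structure sized for lab-scale metadata, not a 600 GB
deployment.
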