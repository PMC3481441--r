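Package: seqindex
Title: Indexing, Searching and Browsing of Biological Databank Flat Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained indexing platform for biological databanks
    distributed as flat files. Streams FASTA, GFF3, GenBank, EMBL and PDB
    records into key/value documents that remember their origin (file path
    and byte offsets), indexes them in an embedded inverted index with
    TF-IDF scoring, numeric range filters, fuzzy and prefix matching, and a
    Lucene-style query language; supports index shards with a single query
    entry point that exchanges global statistics and merges ranked results;
    stores raw sequence payloads in a chunked key/value store with subrange
    retrieval; and answers genome-browser-style region queries (features
    overlapping an interval, sequence of an interval) exported as GFF3. A
    deterministic synthetic-bank generator produces test corpora with
    machine-readable ground truth, and a command-line tool exposes
    indexing, searching, record fetching and region extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
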