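# seqindex

Indexing, searching and browsing of biological databank flat files, as an
embeddable R package.

Labs hold their data as flat-file banks — GenBank/EMBL divisions, GFF3
annotation, FASTA sequence sets, PDB structures — and the question "which
records match these criteria?" usually means either grep or uploading data
to someone else's server. `seqindex` is a self-contained alternative: a
databank indexing platform that

* **parses** FASTA, GFF3, GenBank, EMBL and PDB (plus user plugins) into
  key/value documents that remember exactly where they came from (file,
  byte offset, byte length — any hit can be reproduced from the original
  bank file);
* **indexes** them in an embedded inverted index with a Lucene-style query
  language: full-text and fielded terms, phrases, inclusive ranges
  (`start:[100 TO 200]`), fuzzy (`kinsae~1`, Damerau–Levenshtein) and
  prefix (`kin*`) matching, `AND`/`OR`/`NOT`;
* **scores and pages** results with a fixed TF-IDF model,
  score(d,q) = Σ over matching query terms of (1 + ln tf) · (1 + ln((N+1)/(df+1))),
  with deterministic tie-breaking by document id;
* **shards**: a corpus split across index shards answers every query
  hit-for-hit identically to one big index, because the entry point
  exchanges global (N, df) statistics before scoring and merges ranked
  results;
* **stores** bulk payloads (sequences, translations, PDB bodies) in a
  chunked key/value store with subrange retrieval — extracting a gene
  from the middle of a stored chromosome reads only the chunks it
  overlaps;
* **answers region queries** genome-browser style: features overlapping
  `seqid:start-end` (exported as round-trippable GFF3) and the sequence
  of any interval;
* **generates its own test data**: a deterministic synthetic-bank
  generator emits format-valid banks together with machine-readable
  ground truth, so the whole property suite runs offline.

## Worked example

Generate a small annotated bank, index it across two shards, and query it:

```r
library(seqindex)
td <- tempfile(); dir.create(td)
bank <- file.path(td, "annotations.gff")
generate_bank("gff3", 200, 42, bank, list(fasta_section = TRUE))

cli_index(bank, "gff3", file.path(td, "ix"), shards = 2)
#> indexed 204 of 204 record(s) from 1 file(s); 0 skipped; 4 payload(s) stored [1.353s]
```

204 documents: 200 feature lines plus the four reference sequences of the
embedded `##FASTA` section, whose residues went to the chunk store. Now
search — genes starting between positions 1000 and 2000:

```r
svc <- open_bank(file.path(td, "ix"))
res <- http_search(svc, 'type:gene AND start:[1000 TO 2000]', rows = 3)
res$body$total
#> [1] 11
# id, score, location, Name of the first page:
#> f00013  score=2.316  chr1:1744-2031  Name=membrane
#> f00043  score=2.316  chr2:1240-1384  Name=binding
#> f00057  score=2.316  chr3:1525-1540  Name=terminase
```

Eleven genes match; the range clause filters (contributing no score) while
the `type:gene` term scores each hit identically, so ties break by id.
Region queries return GFF3:

```r
cat(http_region(svc, "chr2", 1500, 1700)$body)
#> ##gff-version 3
#> chr2	annotator	exon	1154	1538	.	+	.	ID=f00049;Name=chaperone;Dbxref=GO:0450685,taxon:9463
#> chr2	est2genome	gene	1242	1530	.	-	.	ID=f00109;Name=regulator;note=polymerase ribosomal hypothetical
#> ...   (7 overlapping features in total, whole, sorted by start)

sequence_of_region(svc$store, region("chr2", 1601, 1640))
#> [1] "GTCACGTTAACTGGTGCTCAACATCGCAGCACAGGTGCAC"
```

And every hit links back to its original bytes:

```r
doc <- http_document(svc, "f00013")$body
doc$source
#> $path  ".../annotations.gff"   $offset 1093   $length 94
cat(fetch_original(source_location(doc$source$path, doc$source$offset, doc$source$length)))
#> chr1	curated	gene	1744	2031	.	+	.	ID=f00013;Name=membrane;note=transporter regulator chaperone
```

The same operations are available from the shell via the bundled script
(`inst/cli/seqindex`): `seqindex gen`, `seqindex index -t gff3 ...`,
`seqindex search -q ...`, `seqindex fetch --id ... --original`,
`seqindex region --seqid ...`.

## Documentation

The methods vignette (`vignettes/databank-indexing.Rmd`) describes the
data model, the analyzer and scoring model, the global-statistics shard
merge, coordinate conventions, the chunk-store access contract, and what
the synthetic banks do and do not emulate. Function-level documentation
lives in the roxygen comments under `R/`.
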