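# Shared fixtures: generated corpora (cached per test run), an independent
# recursive edit-distance oracle, and document-level comparison helpers.

.fixtures <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture_dir <- function() {
  if (is.null(.fixtures$dir)) {
    .fixtures$dir <- tempfile("seqindex-fixtures-")
    dir.create(.fixtures$dir)
  }
  .fixtures$dir
}

# a generated bank plus its parse, cached by key
bank_fixture <- function(key, format, n, seed, params = list()) {
  if (is.null(.fixtures[[key]])) {
    path <- file.path(fixture_dir(), paste0(key, ".", format))
    truth <- generate_bank(format, n, seed, path, params)
    recs <- parse_bank(format, path)
    .fixtures[[key]] <- list(path = path, truth = truth, recs = recs,
                             docs = lapply(recs, `[[`, "document"))
  }
  .fixtures[[key]]
}

# the 1,000-feature GFF3 corpus (with reference sequences) most query and
# region checks run against, indexed once
gff_corpus <- function() {
  if (is.null(.fixtures$gff_ix)) {
    fx <- bank_fixture("corpus1000", "gff3", 1000L, 42L,
                       list(fasta_section = TRUE))
    ix <- index_create(NULL)
    for (d in fx$docs) index_add(ix, d)
    index_commit(ix)
    st <- store_open(NULL)
    for (s in names(fx$truth$reference_sequences)) {
      store_put(st, s, fx$truth$reference_sequences[[s]])
    }
    fx$ix <- ix
    fx$store <- st
    fx$feature_docs <- Filter(function(d) identical(d$content_type, "biosequence/gff"),
                              fx$docs)
    .fixtures$gff_ix <- fx
  }
  .fixtures$gff_ix
}

# independent Damerau-Levenshtein oracle: plain recursion with memoisation,
# no DP table shared with the implementation
dl_reference <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    cost <- if (sa[i] == sb[j]) 0L else 1L
    v <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L, rec(i - 1L, j - 1L) + cost)
    if (i > 1L && j > 1L && sa[i] == sb[j - 1L] && sa[i - 1L] == sb[j]) {
      v <- min(v, rec(i - 2L, j - 2L) + 1L)
    }
    memo[[key]] <- v
    v
  }
  rec(length(sa), length(sb))
}

# truth record -> document (for field-for-field comparison with a parse)
truth_doc <- function(tr, content_type, path) {
  make_document(tr$fields, content_type,
                source_location(path, tr$offset, tr$length),
                doc_id = tr$doc_id)
}

# content-type a truth record's document should carry
truth_content_type <- function(tr, format) {
  if (format %in% c("genbank", "embl")) {
    if (!is.null(tr$fields$type)) "biosequence/gff" else paste0("biosequence/", format)
  } else if (format == "gff3") {
    if (!is.null(tr$fields$type)) "biosequence/gff" else "biosequence/fasta"
  } else paste0("biosequence/", format)
}

read_bytes <- function(path, offset, length) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  seek(con, where = offset)
  rawToChar(readBin(con, "raw", n = length))
}

# re-parse the byte slice a truth record points at, with offsets anchored
# at the slice's true position
reparse_slice <- function(path, tr, format) {
  txt <- read_bytes(path, tr$offset, tr$length)
  fmt <- if (format == "gff3" && is.null(tr$fields$type)) "fasta"
         else format
  parse_bank(fmt, path, text = txt, offset0 = tr$offset)
}

# brute-force interval overlap used against features_in_region
overlap_scan <- function(docs, seqid, start, end, type = NULL) {
  hit <- Filter(function(d) {
    identical(d$fields$seqid[[1]], seqid) &&
      as.numeric(d$fields$start[[1]]) <= end &&
      as.numeric(d$fields$end[[1]]) >= start &&
      (is.null(type) || identical(d$fields$type[[1]], type))
  }, docs)
  s <- vapply(hit, function(d) as.numeric(d$fields$start[[1]]), 0)
  e <- vapply(hit, function(d) as.numeric(d$fields$end[[1]]), 0)
  i <- vapply(hit, `[[`, "", "doc_id")
  hit[order(s, e, i, method = "radix")]
}

# split documents into shards by the package router, build committed indexes
build_shards <- function(docs, n_shards) {
  groups <- split(docs, vapply(docs, route_document, 0, n_shards = n_shards))
  shards <- lapply(unname(groups), function(g) {
    ix <- index_create(NULL)
    for (d in g) index_add(ix, d)
    index_commit(ix)
    ix
  })
  shardset(shards)
}
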