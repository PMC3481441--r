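# Deterministic synthetic-bank generator. Produces FASTA / GFF3 / GenBank
# / EMBL / PDB files together with machine-readable ground truth (expected
# document fields, payloads and byte offsets), emitted by the same writer
# in the same pass — so parser fidelity can be checked without any
# downloaded data. All randomness flows from the seed; the same
# (format, n, seed, params) always produces byte-identical files.
#
# Content is format-valid but biologically arbitrary: uniform ACGT (or
# amino-acid) sequences, gene-like vocabulary words, random intervals.

BANK_WORDS <- c("kinase", "transporter", "polymerase", "ribosomal", "hypothetical",
                "membrane", "binding", "regulator", "synthase", "transferase",
                "receptor", "helicase", "protease", "oxidase", "reductase",
                "chaperone", "permease", "integrase", "terminase", "ligase")

rand_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

rand_words <- function(k) paste(sample(BANK_WORDS, k, replace = TRUE), collapse = " ")

wrap_seq <- function(s, width = 60L) {
  if (!nzchar(s)) return(character(0))
  starts <- seq(1L, nchar(s), by = width)
  vapply(starts, function(i) substr(s, i, min(i + width - 1L, nchar(s))), "")
}

#' Generate a synthetic bank file with ground truth
#'
#' @param format one of `"fasta"`, `"gff3"`, `"genbank"`, `"embl"`,
#'   `"pdb"`.
#' @param n_records number of records (FASTA sequences, GFF3 feature
#'   lines, GenBank/EMBL entries; PDB supports exactly 1 structure per
#'   file).
#' @param seed integer seed fixing all randomness.
#' @param out path the bank file is written to.
#' @param params format-specific knobs:
#'   * fasta: `len_range` (default 50..400), `wrap` (60)
#'   * gff3: `n_seqs` (4), `seq_len` (5000), `fasta_section` (FALSE),
#'     `dirty_lines` (0: malformed lines injected for skip testing)
#'   * genbank/embl: `len_range` (150..600), `n_features_range` (3..5)
#' @return invisibly, the ground truth: list with `format`, `path`,
#'   `n_records`, `total_residues`, `skipped_expected` and `records` —
#'   one entry per expected document with `doc_id`, `fields`, `payload`,
#'   `payload_id`, `offset`, `length`.
#' @export
generate_bank <- function(format, n_records, seed, out, params = list()) {
  if (!format %in% c("fasta", "gff3", "genbank", "embl", "pdb")) {
    seqindex_error("unknown_format", sprintf("unknown generator format '%s'", format))
  }
  if (n_records < 0) seqindex_error("bad_n", "n_records must be >= 0")
  truth <- withr::with_seed(seed, switch(format,
    fasta = gen_fasta(n_records, out, params),
    gff3 = gen_gff3(n_records, out, params),
    genbank = gen_flatfile(n_records, out, params, "genbank"),
    embl = gen_flatfile(n_records, out, params, "embl"),
    pdb = gen_pdb(n_records, out, params)))
  truth$format <- format
  truth$path <- out
  invisible(truth)
}

truth_record <- function(doc_id, fields, payload, payload_id, offset, length) {
  list(doc_id = doc_id, fields = fields, payload = payload,
       payload_id = payload_id, offset = offset, length = length)
}

write_bank <- function(out, text) {
  con <- file(out, open = "wb")
  on.exit(close(con))
  if (nzchar(text)) writeChar(text, con, eos = NULL)
}

gen_fasta <- function(n, out, params) {
  len_range <- params$len_range %||% c(50L, 400L)
  wrap <- params$wrap %||% 60L
  pieces <- character(n)
  records <- vector("list", n)
  pos <- 0
  for (i in seq_len(n)) {
    id <- sprintf("seq%05d", i)
    desc <- rand_words(sample(2:4, 1))
    len <- sample(len_range[1]:len_range[2], 1)
    s <- rand_seq(len)
    lines <- c(sprintf(">%s %s", id, desc), wrap_seq(s, wrap))
    rec_text <- paste(lines, collapse = "\n")
    records[[i]] <- truth_record(
      id, list(id = id, description = desc, length = len),
      s, id, pos, nchar(rec_text, type = "bytes"))
    pieces[i] <- rec_text
    pos <- pos + nchar(rec_text, type = "bytes") + 1
  }
  write_bank(out, if (n) paste0(paste(pieces, collapse = "\n"), "\n") else "")
  list(n_records = n, records = records, skipped_expected = 0L,
       total_residues = sum(vapply(records, function(r) nchar(r$payload), 0)))
}

gen_gff3 <- function(n, out, params) {
  n_seqs <- params$n_seqs %||% 4L
  slen <- params$seq_len %||% 5000L
  fasta_section <- isTRUE(params$fasta_section)
  dirty <- params$dirty_lines %||% 0L
  seqids <- sprintf("chr%d", seq_len(n_seqs))
  refseqs <- setNames(vapply(seqids, function(s) rand_seq(slen), ""), seqids)
  types <- c("gene", "mRNA", "exon", "CDS", "repeat_region")
  sources <- c("annotator", "est2genome", "curated")
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", seqids, slen))
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    seqid <- sample(seqids, 1)
    type <- sample(types, 1)
    src <- sample(sources, 1)
    start <- sample.int(slen - 50L, 1)
    end <- min(start + sample.int(500L, 1), slen)
    score_txt <- if (runif(1) < 0.5) "." else as.character(sample.int(1000L, 1))
    strand_txt <- sample(c("+", "-", "."), 1, prob = c(0.45, 0.45, 0.1))
    phase_txt <- if (type == "CDS") as.character(sample(0:2, 1)) else "."
    fid <- sprintf("f%05d", i)
    name <- sample(BANK_WORDS, 1)
    attrs <- sprintf("ID=%s;Name=%s", fid, name)
    fields <- list(seqid = seqid, source_tag = src, type = type,
                   start = start, end = end)
    if (score_txt != ".") fields$score <- as.numeric(score_txt)
    if (strand_txt != ".") fields$strand <- strand_txt
    if (phase_txt != ".") fields$phase <- phase_txt
    fields$ID <- fid
    fields$Name <- name
    if (runif(1) < 0.3) {
      dbx <- c(sprintf("GO:%07d", sample.int(999999L, 1)),
               sprintf("taxon:%d", sample.int(99999L, 1)))
      attrs <- paste0(attrs, ";Dbxref=", paste(dbx, collapse = ","))
      fields$Dbxref <- dbx
    }
    if (runif(1) < 0.4) {
      note <- rand_words(3)
      attrs <- paste0(attrs, ";note=", note)
      fields$note <- note
    }
    feats[[i]] <- list(fields = fields,
                       line = paste(c(seqid, src, type, start, end, score_txt,
                                      strand_txt, phase_txt, attrs),
                                    collapse = "\t"))
  }
  # dirty mode: known-bad lines (wrong column count) the indexer must skip
  body <- vapply(feats, `[[`, "", "line")
  is_bad <- logical(length(body))
  if (dirty > 0L && n > 0L) {
    bad <- vapply(seq_len(dirty), function(k) {
      paste(c(sample(seqids, 1), "corrupt", "gene", sample.int(slen, 1),
              sample.int(slen, 1), ".", "+"), collapse = "\t")
    }, "")
    at <- sort(sample.int(length(body) + dirty, dirty))
    merged <- character(length(body) + dirty)
    merged[at] <- bad
    merged[-at] <- body
    is_bad <- seq_along(merged) %in% at
    body <- merged
  }
  feat_meta <- vector("list", length(body))
  feat_meta[!is_bad] <- feats
  lines <- c(lines, body)
  if (fasta_section) {
    lines <- c(lines, "##FASTA",
               unlist(lapply(seqids, function(s) c(paste0(">", s), wrap_seq(refseqs[[s]])))))
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  write_bank(out, text)
  sl <- scan_lines(text)
  records <- list()
  li <- length(lines) - length(body) - (if (fasta_section) {
    sum(vapply(seqids, function(s) 1L + length(wrap_seq(refseqs[[s]])), 0L)) + 1L
  } else 0L)
  # li = number of header pragma lines before the feature body
  for (k in seq_along(body)) {
    if (is_bad[k]) next
    i <- li + k
    ft <- feat_meta[[k]]
    records[[length(records) + 1L]] <- truth_record(
      ft$fields$ID, ft$fields, NULL, NULL, sl$offset[i], sl$nbytes[i])
  }
  if (fasta_section) {
    fa_first <- li + length(body) + 2L       # line after "##FASTA"
    i <- fa_first
    for (s in seqids) {
      nlines <- 1L + length(wrap_seq(refseqs[[s]]))
      last <- i + nlines - 1L
      rec_len <- sl$offset[last] + sl$nbytes[last] - sl$offset[i]
      records[[length(records) + 1L]] <- truth_record(
        s, list(id = s, length = nchar(refseqs[[s]])),
        refseqs[[s]], s, sl$offset[i], rec_len)
      i <- i + nlines
    }
  }
  list(n_records = n, records = records, skipped_expected = as.integer(dirty),
       total_residues = if (fasta_section) sum(nchar(refseqs)) else 0,
       reference_sequences = if (fasta_section) as.list(refseqs))
}

gen_flatfile <- function(n, out, params, flavor) {
  len_range <- params$len_range %||% c(150L, 600L)
  nf_range <- params$n_features_range %||% c(3L, 5L)
  pieces <- character(n)
  records <- list()
  pos <- 0
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in seq_len(n)) {
    locus <- sprintf("LOC%05d", i)
    acc <- sprintf("%s%05d", if (flavor == "genbank") "GB" else "EM", i)
    len <- sample(len_range[1]:len_range[2], 1)
    s <- rand_seq(len)
    definition <- rand_words(sample(3:5, 1))
    organism <- paste0(toupper(substr(sample(BANK_WORDS, 1), 1, 1)),
                       substr(sample(BANK_WORDS, 1), 2, 8), " ",
                       sample(BANK_WORDS, 1))
    nf <- sample(nf_range[1]:nf_range[2], 1)
    feats <- list(list(key = "source", start = 1L, end = len, strand = "+",
                       quals = list(organism = organism)))
    for (k in seq_len(nf - 1L)) {
      fs <- sample.int(max(len - 30L, 1L), 1)
      fe <- min(fs + sample.int(100L, 1), len)
      gene <- sample(BANK_WORDS, 1)
      quals <- list(gene = gene)
      key <- sample(c("gene", "CDS"), 1)
      if (key == "CDS") {
        quals$db_xref <- sprintf("taxon:%d", sample.int(99999L, 1))
        if (runif(1) < 0.6) {
          quals$translation <- rand_seq(sample(20:80, 1), aa)
        }
      }
      feats[[length(feats) + 1L]] <-
        list(key = key, start = fs, end = fe,
             strand = sample(c("+", "-"), 1), quals = quals)
    }
    rec_lines <- if (flavor == "genbank") {
      genbank_record_lines(locus, acc, len, definition, organism, feats, s)
    } else {
      embl_record_lines(locus, acc, len, definition, organism, feats, s)
    }
    rec_text <- paste(rec_lines, collapse = "\n")
    rec_len <- nchar(rec_text, type = "bytes")
    hdr_fields <- list(locus = locus, length = len, definition = definition,
                       accession = acc, organism = organism)
    if (flavor == "genbank") hdr_fields$version <- paste0(acc, ".1")
    ct <- paste0("biosequence/", flavor)
    records[[length(records) + 1L]] <- truth_record(
      acc, hdr_fields, s, acc, pos, rec_len)
    for (k in seq_along(feats)) {
      ft <- feats[[k]]
      fid <- paste0(acc, ":f", k)
      ffields <- list(seqid = acc, type = ft$key, start = ft$start,
                      end = ft$end, strand = ft$strand)
      for (qn in names(ft$quals)) {
        if (qn != "translation") ffields[[qn]] <- ft$quals[[qn]]
      }
      tr <- ft$quals$translation
      records[[length(records) + 1L]] <- truth_record(
        fid, ffields, tr, if (!is.null(tr)) paste0(fid, ":translation"),
        pos, rec_len)
    }
    pieces[i] <- rec_text
    pos <- pos + rec_len + 1
  }
  write_bank(out, if (n) paste0(paste(pieces, collapse = "\n"), "\n") else "")
  list(n_records = n, records = records, skipped_expected = 0L,
       total_residues = sum(vapply(records, function(r) {
         if (is.null(r$payload)) 0 else nchar(r$payload)
       }, 0)))
}

format_location <- function(ft) {
  loc <- sprintf("%d..%d", ft$start, ft$end)
  if (ft$strand == "-") paste0("complement(", loc, ")") else loc
}

qualifier_lines <- function(quals, lead) {
  unlist(lapply(names(quals), function(qn) {
    v <- quals[[qn]]
    if (qn == "translation") {
      body <- paste0('/translation="', v, '"')
      chunks <- wrap_seq(body, 58L)
      paste0(lead, chunks)
    } else {
      paste0(lead, sprintf('/%s="%s"', qn, v))
    }
  }))
}

genbank_record_lines <- function(locus, acc, len, definition, organism, feats, s) {
  origin <- {
    starts <- seq(1L, len, by = 60L)
    vapply(starts, function(p) {
      blocks <- vapply(seq(p, min(p + 59L, len), by = 10L), function(b) {
        tolower(substr(s, b, min(b + 9L, len)))
      }, "")
      sprintf("%9d %s", p, paste(blocks, collapse = " "))
    }, "")
  }
  c(sprintf("LOCUS       %-16s %d bp    DNA     linear   SYN 01-JAN-2000", locus, len),
    sprintf("DEFINITION  %s", definition),
    sprintf("ACCESSION   %s", acc),
    sprintf("VERSION     %s.1", acc),
    "SOURCE      synthetic construct",
    sprintf("  ORGANISM  %s", organism),
    "FEATURES             Location/Qualifiers",
    unlist(lapply(feats, function(ft) {
      c(sprintf("     %-16s%s", ft$key, format_location(ft)),
        qualifier_lines(ft$quals, strrep(" ", 21L)))
    })),
    "ORIGIN",
    origin,
    "//")
}

embl_record_lines <- function(locus, acc, len, definition, organism, feats, s) {
  def_words <- strsplit(definition, " ", fixed = TRUE)[[1]]
  half <- ceiling(length(def_words) / 2)
  seq_block <- {
    starts <- seq(1L, len, by = 60L)
    vapply(starts, function(p) {
      blocks <- vapply(seq(p, min(p + 59L, len), by = 10L), function(b) {
        tolower(substr(s, b, min(b + 9L, len)))
      }, "")
      sprintf("     %-66s%d", paste(blocks, collapse = " "), min(p + 59L, len))
    }, "")
  }
  c(sprintf("ID   %s; SV 1; linear; DNA; STD; UNC; %d BP.", locus, len),
    "XX",
    sprintf("AC   %s;", acc),
    "XX",
    sprintf("DE   %s", paste(def_words[seq_len(half)], collapse = " ")),
    sprintf("DE   %s", paste(def_words[-seq_len(half)], collapse = " ")),
    "XX",
    sprintf("OS   %s", organism),
    "XX",
    "FH   Key             Location/Qualifiers",
    "FH",
    unlist(lapply(feats, function(ft) {
      c(sprintf("FT   %-16s%s", ft$key, format_location(ft)),
        qualifier_lines(ft$quals, paste0("FT", strrep(" ", 19L))))
    })),
    "XX",
    sprintf("SQ   Sequence %d BP;", len),
    seq_block,
    "//")
}

gen_pdb <- function(n, out, params) {
  if (n != 1L) seqindex_error("bad_n", "the PDB generator writes one structure per file")
  pdb_id <- params$pdb_id %||% sprintf("%d%s%s%s", sample(1:9, 1),
                                       sample(LETTERS, 1), sample(LETTERS, 1),
                                       sample(LETTERS, 1))
  cls <- toupper(sample(BANK_WORDS, 1))
  title1 <- toupper(rand_words(3))
  title2 <- toupper(rand_words(2))
  mol <- toupper(paste(sample(BANK_WORDS, 2), collapse = " "))
  org <- toupper(paste(sample(BANK_WORDS, 2), collapse = " "))
  pad80 <- function(x) sprintf("%-80s", x)
  lines <- c(
    pad80(sprintf("HEADER    %-40s%-9s   %4s", cls, "12-JAN-98", pdb_id)),
    pad80(sprintf("TITLE     %s", title1)),
    pad80(sprintf("TITLE    2 %s", title2)),
    pad80("COMPND    MOL_ID: 1;"),
    pad80(sprintf("COMPND   2 MOLECULE: %s;", mol)),
    pad80("SOURCE    MOL_ID: 1;"),
    pad80(sprintf("SOURCE   2 ORGANISM_SCIENTIFIC: %s;", org)),
    pad80("ATOM      1  N   MET A   1      11.104  13.207   2.100  1.00 20.00           N"),
    pad80("END"))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  write_bank(out, text)
  fields <- list(pdb_id = pdb_id, classification = cls,
                 deposition_date = "12-JAN-98",
                 title = paste(title1, title2),
                 compound = mol, organism = org)
  list(n_records = 1L,
       records = list(truth_record(pdb_id, fields, text, pdb_id, 0,
                                   nchar(text, type = "bytes"))),
       skipped_expected = 0L, total_residues = 0)
}

# ---- random query generator --------------------------------------------

#' Generate random queries over a synthetic GFF3 corpus
#'
#' Draws a mix of fielded terms, full-text terms, numeric ranges (with
#' open bounds), fuzzy terms, prefixes and boolean combinations with
#' parentheses and NOT — the query shapes the engine supports — phrased
#' against the fields and vocabulary the GFF3 generator emits.
#'
#' @param n number of queries.
#' @param seed integer seed.
#' @param seq_len coordinate upper bound used for ranges.
#' @return character vector of query strings.
#' @export
generate_queries <- function(n, seed, seq_len = 5000L) {
  withr::with_seed(seed, {
    types <- c("gene", "mRNA", "exon", "CDS", "repeat_region")
    mutate_word <- function(w) {
      i <- sample.int(nchar(w), 1)
      op <- sample(c("sub", "del", "swap"), 1)
      chars <- strsplit(w, "")[[1]]
      if (op == "sub") chars[i] <- sample(letters, 1)
      else if (op == "del" && nchar(w) > 2) chars <- chars[-i]
      else if (i > 1) chars[c(i - 1, i)] <- chars[c(i, i - 1)]
      paste(chars, collapse = "")
    }
    clause <- function() {
      kind <- sample(c("fterm", "term", "range", "fuzzy", "prefix", "phrase"), 1,
                     prob = c(0.25, 0.2, 0.2, 0.12, 0.13, 0.1))
      switch(kind,
        fterm = sample(c(
          sprintf("type:%s", sample(types, 1)),
          sprintf("seqid:chr%d", sample.int(4L, 1)),
          sprintf("Name:%s", sample(BANK_WORDS, 1)),
          sprintf("source_tag:%s", sample(c("annotator", "est2genome", "curated"), 1))), 1),
        term = sample(BANK_WORDS, 1),
        range = {
          a <- sample.int(seq_len, 1)
          b <- min(a + sample.int(seq_len, 1), seq_len)
          fld <- sample(c("start", "end", "score"), 1, prob = c(0.45, 0.45, 0.1))
          if (fld == "score") { a <- sample.int(1000L, 1); b <- min(a + 400L, 1000L) }
          style <- sample(1:3, 1)
          if (style == 1) sprintf("%s:[%d TO %d]", fld, a, b)
          else if (style == 2) sprintf("%s:[* TO %d]", fld, b)
          else sprintf("%s:[%d TO *]", fld, a)
        },
        fuzzy = sprintf("%s~%d", mutate_word(sample(BANK_WORDS, 1)), sample(1:2, 1)),
        prefix = {
          w <- sample(BANK_WORDS, 1)
          paste0(substr(w, 1, sample(3:4, 1)), "*")
        },
        phrase = sprintf("note:\"%s\"", rand_words(2)))
    }
    vapply(seq_len_int(n), function(i) {
      shape <- sample(1:4, 1, prob = c(0.35, 0.3, 0.2, 0.15))
      if (shape == 1) clause()
      else if (shape == 2) paste(clause(), sample(c("AND", "OR"), 1), clause())
      else if (shape == 3) sprintf("%s AND NOT %s", clause(), clause())
      else sprintf("(%s OR %s) AND %s", clause(), clause(), clause())
    }, "")
  })
}

seq_len_int <- function(n) seq_len(as.integer(n))
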