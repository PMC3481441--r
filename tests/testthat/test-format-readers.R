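write_tmp <- function(text, ext = ".txt") {
  f <- tempfile(fileext = ext)
  con <- file(f, "wb")
  if (nzchar(text)) writeChar(text, con, eos = NULL)
  close(con)
  f
}

test_that("FASTA records map to id/description/length with the sequence as payload", {
  f <- write_tmp(">s1 my desc\nACGT\nAC\n")
  recs <- parse_fasta(f)
  expect_length(recs, 1)
  d <- recs[[1]]$document
  expect_identical(d$fields$id, "s1")
  expect_identical(d$fields$description, "my desc")
  expect_equal(d$fields$length, 6)
  expect_identical(recs[[1]]$payload, "ACGTAC")
  expect_identical(d$content_type, "biosequence/fasta")
  # source covers header through last sequence byte
  expect_equal(d$source$offset, 0)
  expect_equal(d$source$length, nchar(">s1 my desc\nACGT\nAC"))
})

test_that("FASTA offsets equal a byte scan for '>' and edge records parse", {
  fx <- bank_fixture("fa50", "fasta", 50L, 7L)
  raw <- readBin(fx$path, "raw", n = file.size(fx$path))
  gt_pos <- which(raw == charToRaw(">")) - 1L     # 0-based '>' offsets
  offs <- vapply(fx$recs, function(r) r$document$source$offset, 0)
  expect_equal(offs, as.numeric(gt_pos))

  f <- write_tmp(">s1\n\n>s2\nA\n")
  recs <- parse_fasta(f)
  expect_equal(vapply(recs, function(r) r$document$fields$length, 0), c(0, 1))

  expect_error(parse_fasta(write_tmp("ACGT\n>s1\nA\n")), class = "malformed_input")
  expect_length(parse_fasta(write_tmp("")), 0)
})

test_that("GFF3 feature lines become typed documents; pragmas don't; bad lines skip", {
  f <- write_tmp(paste0("##gff-version 3\n",
                        "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=g1;Name=abc\n",
                        "chr1\tsrc\tbroken\t1\t2\n",
                        "chr1\tsrc\texon\t5\t9\t.\t-\t.\tDbxref=GO:1,GO:2\n"))
  recs <- parse_gff3(f)
  expect_length(recs, 2)
  d <- recs[[1]]$document
  expect_identical(d$doc_id, "g1")
  expect_equal(d$fields$start, 100)
  expect_equal(d$fields$end, 200)
  expect_identical(d$fields$strand, "+")
  expect_identical(d$fields$Name, "abc")
  expect_identical(recs[[2]]$document$fields$Dbxref, c("GO:1", "GO:2"))
  sk <- skipped_lines(recs)
  expect_equal(sk$line, 3L)
  expect_match(sk$reason, "9 tab-separated")
})

test_that("GenBank records yield a header document plus exploded features", {
  txt <- paste0(
    "LOCUS       X                4 bp    DNA     linear   SYN 01-JAN-2000\n",
    "ACCESSION   X1\n",
    "FEATURES             Location/Qualifiers\n",
    "     gene            10..50\n",
    "                     /gene=\"abc\"\n",
    "     CDS             complement(10..50)\n",
    "     misc_feature    join(1..2,3..4)\n",
    "ORIGIN\n",
    "        1 acgt\n",
    "//\n")
  recs <- parse_genbank(write_tmp(txt))
  expect_length(recs, 4)
  hd <- recs[[1]]$document
  expect_identical(hd$fields$locus, "X")
  expect_identical(hd$fields$accession, "X1")
  expect_equal(hd$fields$length, 4)
  expect_identical(recs[[1]]$payload, "ACGT")          # uppercased, digits stripped
  ft <- recs[[2]]$document
  expect_identical(ft$content_type, "biosequence/gff")
  expect_equal(ft$fields$start, 10); expect_equal(ft$fields$end, 50)
  expect_identical(ft$fields$strand, "+")
  expect_identical(ft$fields$gene, "abc")
  expect_identical(recs[[3]]$document$fields$strand, "-")   # complement()
  join_ft <- recs[[4]]$document
  expect_equal(join_ft$fields$start, 1); expect_equal(join_ft$fields$end, 4)
  expect_identical(join_ft$fields$location_exact, "false")  # compound span

  expect_error(parse_genbank(write_tmp("LOCUS       Y  4 bp\nORIGIN\n        1 acgt\n")),
               class = "truncated_record")
})

test_that("translations become separate payloads keyed <id>:translation", {
  txt <- paste0(
    "LOCUS       X                4 bp    DNA     linear   SYN 01-JAN-2000\n",
    "ACCESSION   X1\n",
    "FEATURES             Location/Qualifiers\n",
    "     CDS             1..4\n",
    "                     /translation=\"MKVN\n",
    "                     PQRS\"\n",
    "ORIGIN\n        1 acgt\n//\n")
  recs <- parse_genbank(write_tmp(txt))
  cds <- recs[[2]]
  expect_identical(cds$payload, "MKVNPQRS")             # continuation joined seamlessly
  expect_identical(cds$payload_id, "X1:f1:translation")
  expect_null(cds$document$fields$translation)          # payload, not a field
  # explosion off: translation hangs off the header record
  recs2 <- parse_genbank(write_tmp(txt), explode = FALSE)
  expect_length(recs2, 1)
  expect_identical(recs2[[1]]$extra_payloads[["X1:translation"]], "MKVNPQRS")
})

test_that("EMBL mirrors the GenBank mapping (ID/AC/DE/OS/FT/SQ)", {
  txt <- paste0(
    "ID   X1; SV 1; linear; DNA; STD; UNC; 4 BP.\n",
    "AC   AC1;\n",
    "DE   line one\n",
    "DE   line two\n",
    "OS   Genus species\n",
    "FT   gene            10..50\n",
    "FT                   /gene=\"abc\"\n",
    "SQ   Sequence 4 BP;\n",
    "     acgt                                                                  4\n",
    "//\n")
  recs <- parse_embl(write_tmp(txt))
  hd <- recs[[1]]$document
  expect_identical(hd$content_type, "biosequence/embl")
  expect_identical(hd$fields$locus, "X1")
  expect_identical(hd$fields$accession, "AC1")
  expect_equal(hd$fields$length, 4)
  expect_identical(hd$fields$definition, "line one line two")
  expect_identical(hd$fields$organism, "Genus species")
  expect_identical(recs[[1]]$payload, "ACGT")
  ft <- recs[[2]]$document
  expect_equal(ft$fields$start, 10)
  expect_identical(ft$fields$gene, "abc")
})

test_that("PDB header columns map to fields and the whole file is the payload", {
  fx <- bank_fixture("pdb1", "pdb", 1L, 5L)
  d <- fx$recs[[1]]$document
  tr <- fx$truth$records[[1]]
  expect_identical(d$fields$pdb_id, tr$fields$pdb_id)
  expect_identical(d$fields$title, tr$fields$title)       # TITLE continuations joined
  expect_identical(d$fields$organism, tr$fields$organism)
  expect_identical(fx$recs[[1]]$payload, tr$payload)

  no_src <- write_tmp("HEADER    HYDROLASE                               12-JAN-98   1ABC\nEND\n")
  d2 <- parse_pdb(no_src)[[1]]$document
  expect_identical(d2$fields$pdb_id, "1ABC")
  expect_null(d2$fields$organism)                          # optional record absent
  expect_error(parse_pdb(write_tmp("TITLE     X\n")), class = "malformed_input")
})

test_that("recoders split/rename/map/drop as declared and no-op on absent fields", {
  loc <- source_location("/b", 0, 10)
  d <- make_document(list(db_xref = "taxon:9606", definition = "a kinase"),
                     "biosequence/genbank", loc, doc_id = "x")
  r <- apply_recoders(d, list(
    recoder_rule("db_xref", "split", sep = ":", outputs = c("db_xref_db", "db_xref_id"))))
  expect_identical(r$fields$db_xref_db, "taxon")
  expect_identical(r$fields$db_xref_id, "9606")
  expect_identical(r$fields$db_xref, "taxon:9606")        # original kept

  r2 <- apply_recoders(d, list(recoder_rule("definition", "rename", new = "description")))
  expect_null(r2$fields$definition)
  expect_identical(r2$fields$description, "a kinase")

  r3 <- apply_recoders(d, list(recoder_rule("nope", "drop")))
  expect_true(doc_equal(d, r3))                            # absent field: no-op

  r4 <- apply_recoders(d, list(
    recoder_rule("db_xref", "map", pattern = "^taxon:", template = "", outputs = "taxon_id")))
  expect_identical(r4$fields$taxon_id, "9606")

  # separator missing from the value: passes through unsplit, with a message
  d2 <- make_document(list(db_xref = "plain"), "biosequence/genbank", loc, doc_id = "y")
  expect_message(
    r5 <- apply_recoders(d2, list(
      recoder_rule("db_xref", "split", sep = ":", outputs = c("a", "b")))),
    "passed through")
  expect_null(r5$fields$a)
})

test_that("format plugins register, parse through -t dispatch, and collide loudly", {
  reg <- seqindex:::new_reader_registry()
  twoline_reader <- function(path, text = NULL, offset0 = 0, ...) {
    if (is.null(text)) text <- seqindex:::read_file_text(path)
    sl <- seqindex:::scan_lines(text, offset0)
    out <- list()
    for (i in seq(1, length(sl$line), by = 2)) {
      src <- source_location(path, sl$offset[i],
                             sl$offset[i + 1] + sl$nbytes[i + 1] - sl$offset[i])
      doc <- make_document(list(id = sl$line[i], length = sl$nbytes[i + 1]),
                           "biosequence/fasta", src)
      out[[length(out) + 1L]] <- parsed_record(doc, payload = sl$line[i + 1])
    }
    out
  }
  register_format_plugin("twoline", twoline_reader, "biosequence/fasta", registry = reg)
  expect_true("twoline" %in% available_formats(reg))
  f <- write_tmp("a1\nACGT\na2\nGG\na3\nTTTT\n")
  recs <- parse_bank("twoline", f, registry = reg)
  expect_length(recs, 3)
  expect_identical(vapply(recs, function(r) r$document$doc_id, ""), c("a1", "a2", "a3"))
  expect_identical(recs[[2]]$payload, "GG")
  # plugin records honor the source-fidelity contract
  b <- read_bytes(f, recs[[3]]$document$source$offset, recs[[3]]$document$source$length)
  expect_identical(b, "a3\nTTTT")

  expect_error(register_format_plugin("fasta", twoline_reader, "biosequence/fasta",
                                      registry = reg),
               class = "plugin_collision")
  expect_error(register_format_plugin("x2", twoline_reader, "biosequence/nope",
                                      registry = reg),
               class = "unknown_content_type")
  expect_error(parse_bank("nosuch", f, registry = reg), class = "unknown_format")
})

test_that("concatenating two valid single-record files yields the union of records", {
  t1 <- generate_bank("fasta", 1, 1, tempfile())
  t2 <- generate_bank("fasta", 1, 2, tempfile())
  both <- write_tmp(paste0(read_bytes(t1$path, 0, file.size(t1$path)),
                           read_bytes(t2$path, 0, file.size(t2$path))), ".fa")
  recs <- parse_fasta(both)
  expect_length(recs, 2)
  expect_identical(recs[[1]]$payload, t1$records[[1]]$payload)
  expect_identical(recs[[2]]$payload, t2$records[[1]]$payload)

  g1 <- generate_bank("genbank", 1, 3, tempfile())
  g2 <- generate_bank("genbank", 1, 4, tempfile())
  gboth <- write_tmp(paste0(read_bytes(g1$path, 0, file.size(g1$path)),
                            read_bytes(g2$path, 0, file.size(g2$path))), ".gbk")
  ids <- vapply(parse_genbank(gboth), function(r) r$document$doc_id, "")
  want <- c(vapply(g1$records, `[[`, "", "doc_id"), vapply(g2$records, `[[`, "", "doc_id"))
  expect_identical(ids, want)
})

test_that("FASTA payloads agree with an independent reader", {
  skip_if_not_installed("Biostrings")
  fx <- bank_fixture("fa50", "fasta", 50L, 7L)
  ref <- Biostrings::readDNAStringSet(fx$path)
  expect_identical(vapply(fx$recs, `[[`, "", "payload"),
                   unname(as.character(ref)))
  expect_identical(vapply(fx$recs, function(r) r$document$fields$id, ""),
                   unname(vapply(strsplit(names(ref), " "), `[[`, "", 1)))
})

test_that("payload totals match the generator's ground truth", {
  for (key in list(c("fa50", "fasta"), c("gb10", "genbank"))) {
    fx <- if (key[1] == "fa50") bank_fixture("fa50", "fasta", 50L, 7L)
          else bank_fixture("gb10", "genbank", 10L, 8L)
    got <- sum(vapply(fx$recs, function(r) if (is.null(r$payload)) 0 else nchar(r$payload), 0))
    expect_equal(got, fx$truth$total_residues)
  }
})
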