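feature_doc <- function(id, seqid, start, end, type = "gene", strand = "+") {
  make_document(list(seqid = seqid, source_tag = "t", type = type,
                     start = start, end = end, strand = strand, ID = id),
                "biosequence/gff", doc_id = id)
}

index_of <- function(docs) {
  ix <- index_create(NULL)
  for (d in docs) index_add(ix, d)
  index_commit(ix)
  ix
}

test_that("region overlap is closed-interval intersection on 1-based coordinates", {
  docs <- list(feature_doc("a", "chr1", 100, 200),
               feature_doc("b", "chr1", 150, 250),
               feature_doc("c", "chr1", 300, 400),
               feature_doc("d", "chr2", 160, 310))
  ix <- index_of(docs)
  got <- features_in_region(ix, region("chr1", 160, 310))
  expect_identical(vapply(got, `[[`, "", "doc_id"), c("a", "b", "c"))
  got2 <- features_in_region(ix, region("chr1", 201, 299))
  expect_identical(vapply(got2, `[[`, "", "doc_id"), "b")
  # type filter and invalid regions
  expect_length(features_in_region(ix, region("chr1", 160, 310), type = "mRNA"), 0)
  expect_error(region("chr1", 10, 5), class = "bad_region")
})

test_that("random regions agree with the brute-force overlap scan", {
  fx <- gff_corpus()
  feats <- fx$feature_docs
  withr::with_seed(77, {
    for (k in 1:30) {
      seqid <- sprintf("chr%d", sample.int(4, 1))
      a <- sample.int(4900, 1)
      b <- min(a + sample.int(800, 1), 5000)
      type <- if (runif(1) < 0.3) sample(c("gene", "exon", "CDS"), 1)
      got <- features_in_region(fx$ix, region(seqid, a, b), type = type)
      want <- overlap_scan(feats, seqid, a, b, type = type)
      expect_identical(vapply(got, `[[`, "", "doc_id"),
                       vapply(want, `[[`, "", "doc_id"))
    }
  })
})

test_that("region sequences come from the stored payload at the right offset", {
  st <- store_open(NULL)
  store_put(st, "chr9", "ACGTACGTAC")
  expect_identical(sequence_of_region(st, region("chr9", 3, 6)), "GTAC")
  expect_identical(sequence_of_region(st, region("chr9", 1, 10)), "ACGTACGTAC")
  expect_error(sequence_of_region(st, region("chr9", 1, 11)), class = "bad_range")
  expect_error(sequence_of_region(st, region("nochr", 1, 5)), class = "unknown_key")
  # length contract on the shared corpus
  fx <- gff_corpus()
  refs <- fx$truth$reference_sequences
  withr::with_seed(5, {
    for (k in 1:20) {
      s <- sample(names(refs), 1)
      a <- sample.int(4000, 1); b <- a + sample.int(500, 1)
      seqtxt <- sequence_of_region(fx$store, region(s, a, b))
      expect_equal(nchar(seqtxt), b - a + 1)
      expect_identical(seqtxt, substr(refs[[s]], a, b))
    }
  })
})

test_that("GFF3 export round-trips through the parser", {
  one <- feature_doc("g1", "chr1", 10, 99)
  out <- export_region_gff(list(one))
  expect_identical(strsplit(out, "\n")[[1]][1], "##gff-version 3")
  expect_length(strsplit(out, "\n")[[1]], 2)
  expect_identical(export_region_gff(list()), "##gff-version 3\n")
  # mandatory fields enforced
  bad <- make_document(list(seqid = "c", type = "gene", start = 5), "biosequence/gff",
                       doc_id = "frag")
  expect_error(export_region_gff(list(bad)), class = "serialization_error")

  fx <- gff_corpus()
  feats <- fx$feature_docs
  withr::with_seed(21, picks <- sample(seq_along(feats), 100))
  for (i in picks) {
    d <- feats[[i]]
    back <- parse_gff3("x.gff", text = export_region_gff(list(d)))[[1]]$document
    expect_true(doc_equal(d, back, ignore_source = TRUE))
  }
})
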