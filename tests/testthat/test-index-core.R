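mini_doc <- function(id, ...) {
  make_document(list(...), "biosequence/gff", doc_id = id)
}

test_that("the analyzer lowercases and splits, keeping joiners inside runs", {
  expect_identical(tokenize("ABC kinase, gene"), c("abc", "kinase", "gene"))
  expect_identical(tokenize("GO:0005634"), c("go", "0005634"))
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize("gene_id-1.2"), "gene_id-1.2")
  expect_identical(tokenize("trailing. dot"), c("trailing", "dot"))
})

test_that("documents are searchable only after commit; re-add replaces", {
  ix <- index_create(NULL)
  index_add(ix, mini_doc("d1", note = "unique kinase"))
  expect_equal(index_search(ix, "kinase")$total, 0)     # commit gate
  index_commit(ix)
  expect_equal(index_search(ix, "kinase")$total, 1)
  got <- index_get(ix, "d1")
  expect_identical(got$fields$note, "unique kinase")

  index_add(ix, mini_doc("d1", note = "now a ligase"))  # same id, new fields
  index_commit(ix)
  expect_equal(index_ndocs(ix), 1)
  expect_equal(index_search(ix, "kinase")$total, 0)     # last write wins
  expect_equal(index_search(ix, "ligase")$total, 1)
})

test_that("partial update changes only the named fields", {
  ix <- index_create(NULL)
  index_add(ix, mini_doc("d1", organism = "Mus musculus", note = "kinase"))
  index_commit(ix)
  index_update(ix, "d1", list(organism = "Homo sapiens"))
  index_commit(ix)
  d <- index_get(ix, "d1")
  expect_identical(d$fields$organism, "Homo sapiens")
  expect_identical(d$fields$note, "kinase")             # untouched field kept
  expect_equal(index_search(ix, "organism:sapiens")$total, 1)
  expect_error(index_update(ix, "ghost", list(a = 1)), class = "unknown_doc")
})

test_that("partial update refuses documents with indexed-only fields, naming them", {
  sch <- schema(field_schema("hidden", "text", indexed = TRUE, stored = FALSE))
  ix <- index_create(NULL, sch)
  index_add(ix, mini_doc("d1", hidden = "xyz", note = "ok"))
  index_commit(ix)
  err <- tryCatch(index_update(ix, "d1", list(note = "new")),
                  partial_update_unsupported = function(e) e)
  expect_match(conditionMessage(err), "hidden")
})

test_that("delete removes findability; unknown delete warns; re-add restores", {
  ix <- index_create(NULL)
  index_add(ix, mini_doc("d1", note = "singular oxidase"))
  index_commit(ix)
  index_delete(ix, "d1"); index_commit(ix)
  expect_equal(index_search(ix, "oxidase")$total, 0)
  expect_equal(index_ndocs(ix), 0)
  index_delete(ix, "nope")
  expect_warning(index_commit(ix), class = "unknown_doc")
  index_add(ix, mini_doc("d1", note = "singular oxidase")); index_commit(ix)
  expect_equal(index_search(ix, "oxidase")$total, 1)
})

test_that("search matches, pages and filters ranges inclusively", {
  ix <- index_create(NULL)
  index_add(ix, mini_doc("d1", note = "gene kinase"))
  index_add(ix, mini_doc("d2", note = "gene"))
  index_add(ix, mini_doc("d3", start = 100))
  index_add(ix, mini_doc("d4", start = 200))
  index_add(ix, mini_doc("d5", start = 300))
  index_commit(ix)

  r <- index_search(ix, "kinase")
  expect_equal(r$total, 1)
  expect_identical(r$hits$doc_id, "d1")

  r2 <- index_search(ix, "gene", offset = 1, limit = 1)
  expect_equal(r2$total, 2)                   # total independent of paging
  expect_equal(nrow(r2$hits), 1)
  full <- index_search(ix, "gene", limit = 10)
  expect_identical(r2$hits$doc_id, full$hits$doc_id[2])

  r3 <- index_search(ix, "start:[150 TO 350]", limit = 10)
  expect_setequal(r3$hits$doc_id, c("d4", "d5"))
  # bounds are inclusive on both ends
  expect_setequal(index_search(ix, "start:[100 TO 300]", limit = 10)$hits$doc_id,
                  c("d3", "d4", "d5"))
  expect_equal(index_search(ix, "nofield:x")$total, 0)     # unknown field: open schema, no match
  sch <- schema(field_schema("priv", "text", indexed = FALSE, stored = TRUE))
  ix2 <- index_create(NULL, sch)
  index_add(ix2, mini_doc("a", priv = "x", note = "y")); index_commit(ix2)
  expect_error(index_search(ix2, "priv:x"), class = "field_not_searchable")
})

test_that("scores follow the closed-form TF-IDF model", {
  ix <- index_create(NULL)
  index_add(ix, mini_doc("d1", note = "kinase gene"))
  index_commit(ix)
  # single doc, term present once: (1 + ln 1) * (1 + ln(2/2)) = 1
  expect_equal(index_search(ix, "note:kinase")$hits$score, 1.0, tolerance = 1e-12)

  index_add(ix, mini_doc("d2", note = "gene"))
  index_commit(ix)
  # N=2, df=1, tf=1: 1 + ln(3/2)
  expect_equal(index_search(ix, "note:kinase")$hits$score, 1 + log(3 / 2),
               tolerance = 1e-12)
  # range-only queries are pure filters: every match scores 1.0
  ix2 <- index_create(NULL)
  index_add(ix2, mini_doc("a", start = 5)); index_add(ix2, mini_doc("b", start = 7))
  index_commit(ix2)
  expect_equal(index_search(ix2, "start:[1 TO 10]")$hits$score, c(1.0, 1.0),
               tolerance = 1e-12)
  # score_document exposes the same numbers
  expect_equal(score_document(ix, "d1", "note:kinase"), 1 + log(3 / 2),
               tolerance = 1e-12)
})

test_that("fuzzy expansion follows Damerau-Levenshtein distance", {
  vocab <- c("gene", "gone", "kinase")
  expect_setequal(evaluate_fuzzy("gane", vocab, 1), c("gene", "gone"))
  expect_true("gene" %in% evaluate_fuzzy("gene", vocab, 1))   # distance 0 included
  expect_setequal(evaluate_fuzzy("kinsae", vocab, 1), "kinase")  # transposition = 1 edit
  expect_error(evaluate_fuzzy("x", vocab, 3), class = "bad_fuzzy")
})

test_that("the edit distance agrees with an independent recursive oracle", {
  withr::with_seed(17, {
    alphabet <- letters[1:6]
    for (k in 1:150) {
      a <- paste(sample(alphabet, sample(0:8, 1), replace = TRUE), collapse = "")
      b <- paste(sample(alphabet, sample(0:8, 1), replace = TRUE), collapse = "")
      expect_identical(dl_distance(a, b), as.integer(dl_reference(a, b)))
    }
  })
})

test_that("paging concatenation reproduces the full ranked list exactly once", {
  fx <- gff_corpus()
  for (q in c("kinase", "type:gene OR membrane", "start:[1000 TO 3000]")) {
    full <- index_search(fx$ix, q, offset = 0, limit = 100000)
    pages <- character(0)
    k <- 17
    off <- 0
    repeat {
      p <- index_search(fx$ix, q, offset = off, limit = k)
      if (!nrow(p$hits)) break
      pages <- c(pages, p$hits$doc_id)
      off <- off + k
    }
    expect_identical(pages, full$hits$doc_id)
  }
})

test_that("adding term occurrences raises own score, never raises others'", {
  ix <- index_create(NULL)
  index_add(ix, mini_doc("d1", note = "kinase alpha"))
  index_add(ix, mini_doc("d2", note = "kinase beta"))
  index_commit(ix)
  s_before <- index_search(ix, "note:kinase", limit = 10)
  sc <- function(res, id) res$hits$score[res$hits$doc_id == id]
  index_add(ix, mini_doc("d1", note = "kinase kinase alpha"))   # one more occurrence
  index_commit(ix)
  s_after <- index_search(ix, "note:kinase", limit = 10)
  expect_gte(sc(s_after, "d1"), sc(s_before, "d1"))
  # adding the term to a *different* (new) document must not raise d2's score
  index_add(ix, mini_doc("d3", note = "kinase gamma"))
  index_commit(ix)
  s_more <- index_search(ix, "note:kinase", limit = 10)
  expect_lte(sc(s_more, "d2"), sc(s_after, "d2"))
})

test_that("a committed index survives restart; uncommitted work does not", {
  dir <- tempfile("ix-")
  ix <- index_create(dir)
  index_add(ix, mini_doc("d1", note = "persistent protease"))
  index_commit(ix)
  index_add(ix, mini_doc("d2", note = "volatile helicase"))
  # simulated crash before commit: just reopen from disk
  ix2 <- index_open(dir)
  expect_equal(index_ndocs(ix2), 1)
  expect_equal(index_search(ix2, "protease")$total, 1)
  expect_equal(index_search(ix2, "helicase")$total, 0)
  d <- index_get(ix2, "d1")
  expect_identical(d$fields$note, "persistent protease")
})
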