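test_that("doc_id comes from the id field, else a deterministic source hash", {
  loc <- source_location("/bank/x.gff", 120, 44)
  d1 <- make_document(list(id = "g1", type = "gene"), "biosequence/gff", loc)
  expect_identical(d1$doc_id, "g1")

  d2 <- make_document(list(type = "gene"), "biosequence/gff", loc)
  d3 <- make_document(list(type = "mRNA"), "biosequence/gff", loc)
  expect_identical(d2$doc_id, d3$doc_id)   # same (path, offset) -> same id
  d4 <- make_document(list(type = "gene"),
                      "biosequence/gff", source_location("/bank/x.gff", 121, 44))
  expect_false(identical(d2$doc_id, d4$doc_id))
  expect_match(d2$doc_id, "^[0-9a-f]{8}$")
})

test_that("documents require registered content types and non-empty fields", {
  expect_error(make_document(list(seq = "ACGT"), "biosequence/unknown"),
               class = "unknown_content_type")
  expect_error(make_document(list(), "biosequence/gff"),
               class = "empty_fields")
  expect_error(make_document(list(x = 1), "biosequence/gff"),
               class = "no_doc_id")   # no id field, no source to hash
})

test_that("content-type registration validates names and is idempotent", {
  reg <- seqindex:::new_content_type_registry()
  register_content_type("biosequence/gff", list(region = TRUE), registry = reg)
  expect_true(content_type_info("biosequence/gff", registry = reg)$region)
  # identical re-registration is a no-op
  expect_silent(register_content_type("biosequence/gff", list(region = TRUE),
                                      registry = reg))
  expect_error(register_content_type("biosequence/gff", list(region = FALSE),
                                     registry = reg),
               class = "content_type_conflict")
  expect_error(register_content_type("text/plain", registry = reg),
               class = "bad_content_type")
  expect_error(content_type_info("biosequence/nope", registry = reg),
               class = "unknown_content_type")
})

test_that("serialization round-trips field-for-field with value order preserved", {
  loc <- source_location("/b/f.gbk", 0, 999)
  d <- make_document(list(accession = "GB1", db_xref = c("taxon:9606", "GO:1", "GO:2"),
                          start = c(10, 5), note = "kinase like"),
                     "biosequence/genbank", loc, doc_id = "GB1")
  d2 <- doc_from_list(jsonlite::fromJSON(jsonlite::toJSON(doc_to_list(d), auto_unbox = TRUE, digits = NA),
                                         simplifyVector = FALSE))
  expect_true(doc_equal(d, d2))
  expect_identical(d2$fields$db_xref, c("taxon:9606", "GO:1", "GO:2"))
  expect_identical(d2$fields$start, c(10, 5))   # numeric kind and order kept
})

test_that("schema declarations enforce the indexed-or-stored invariant", {
  expect_silent(field_schema("start", "numeric", indexed = TRUE, stored = TRUE))
  expect_error(field_schema("x", "text", indexed = FALSE, stored = FALSE),
               class = "bad_schema")
  expect_error(schema(field_schema("a", "text"), field_schema("a", "keyword")),
               class = "bad_schema")   # duplicates
})

test_that("schema files load, and the open-schema default applies to the rest", {
  f <- tempfile(fileext = ".yml")
  writeLines(c("- name: start", "  kind: numeric",
               "- name: secret", "  kind: text", "  indexed: true", "  stored: false"), f)
  sch <- load_schema(f)
  expect_identical(seqindex:::schema_kind(sch, "start"), "numeric")
  expect_false(seqindex:::schema_is_stored(sch, "secret"))
  # undeclared field: {text, indexed, stored}
  und <- seqindex:::schema_field(sch, "whatever")
  expect_identical(und$kind, "text")
  expect_true(und$indexed && und$stored)

  bad <- tempfile(fileext = ".yml")
  writeLines(c("- name: x", "  indexed: false", "  stored: false"), bad)
  expect_error(load_schema(bad), class = "bad_schema")

  empty <- tempfile(fileext = ".yml")
  writeLines("", empty)
  expect_length(load_schema(empty)$fields, 0)
})
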