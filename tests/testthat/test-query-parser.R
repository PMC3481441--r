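test_that("the grammar produces the expected trees", {
  a <- parse_query("type:gene AND start:[100 TO 200]")
  expect_identical(a$node, "bool"); expect_identical(a$op, "AND")
  expect_identical(a$children[[1]]$node, "term")
  expect_identical(a$children[[1]]$field, "type")
  expect_identical(a$children[[1]]$text, "gene")
  expect_identical(a$children[[2]]$node, "range")
  expect_identical(a$children[[2]]$low, "100")
  expect_identical(a$children[[2]]$high, "200")

  b <- parse_query("chromosome gene")          # implicit AND, unfielded
  expect_identical(b$op, "AND")
  expect_null(b$children[[1]]$field)
  expect_identical(vapply(b$children, `[[`, "", "text"), c("chromosome", "gene"))

  c1 <- parse_query("start:[* TO 500]")        # open lower bound
  expect_null(c1$low)
  expect_identical(c1$high, "500")

  expect_identical(parse_query("abc*")$node, "prefix")
  f <- parse_query("gene~")
  expect_identical(f$node, "fuzzy"); expect_identical(f$max_edits, 2L)
  expect_identical(parse_query("gene~1")$max_edits, 1L)
  p <- parse_query('definition:"Homo sapiens"')
  expect_identical(p$node, "phrase")

  n <- parse_query("NOT type:gene OR exon")
  expect_identical(n$op, "OR")                 # NOT binds tighter than OR
  expect_identical(n$children[[1]]$op, "NOT")
})

test_that("syntax errors report the offending column", {
  e <- tryCatch(parse_query('type:"unterminated'), query_parse_error = function(e) e)
  expect_s3_class(e, "query_parse_error")
  expect_identical(e$column, 6L)
  expect_error(parse_query("(a AND b"), class = "query_parse_error")
  expect_error(parse_query("start:[1 TO"), class = "query_parse_error")
  expect_error(parse_query("[1 TO 2]"), class = "query_parse_error")  # range needs field
  expect_error(parse_query("gene~3"), class = "query_parse_error")
})

test_that("normalization lowercases, splits multi-token terms, casts ranges", {
  sch <- default_schema()
  # quoted stays a phrase, unquoted multi-token becomes AND of tokens
  ph <- normalize_query(parse_query('definition:"Homo Sapiens"'), sch)
  expect_identical(ph$node, "phrase")
  expect_identical(ph$texts, c("homo", "sapiens"))
  tm <- normalize_query(seqindex:::q_term("Homo Sapiens", "definition"), sch)
  expect_identical(tm$op, "AND")
  expect_identical(vapply(tm$children, `[[`, "", "text"), c("homo", "sapiens"))

  r <- normalize_query(parse_query("start:[100 TO 200]"), sch)
  expect_identical(r$low, 100)                 # numeric cast
  expect_error(normalize_query(parse_query("start:[abc TO 5]"), sch),
               class = "non_numeric_bound")

  nt <- normalize_query(parse_query("NOT type:gene"), sch)
  expect_identical(nt$op, "AND")               # match-all AND NOT x
  expect_identical(nt$children[[1]]$node, "all")
  expect_identical(nt$children[[2]]$op, "NOT")
})

test_that("parse-print-parse is idempotent for random generated queries", {
  qs <- generate_queries(300, 99)
  for (q in qs) {
    a1 <- parse_query(q)
    a2 <- parse_query(print_query(a1))
    expect_identical(print_query(a2), print_query(a1))
    # and after schema normalization too
    n1 <- normalize_query(a1, default_schema())
    n2 <- parse_query(print_query(n1))
    expect_identical(print_query(normalize_query(n2, default_schema())), print_query(n1))
  }
  # the documented example queries round-trip as well
  for (q in c("type:gene AND start:[100 TO 200]", "chromosome gene",
              "start:[* TO 500]", 'definition:"Homo sapiens"',
              "(kinase OR gene) AND NOT seqid:chr2", "kin*", "gane~1")) {
    expect_identical(print_query(parse_query(print_query(parse_query(q)))),
                     print_query(parse_query(q)))
  }
})
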