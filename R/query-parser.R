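# Lucene-style query language: field:term, field:"a phrase",
# field:[x TO y], fuzzy~N, prefix*, AND/OR/NOT, parentheses. Two adjacent
# clauses combine with AND; an unfielded clause targets all indexed
# full-text fields. Precedence: NOT > AND > OR.

q_term <- function(text, field = NULL) list(node = "term", field = field, text = text)
q_phrase <- function(texts, field = NULL) list(node = "phrase", field = field, texts = texts)
q_range <- function(field, low, high) list(node = "range", field = field, low = low, high = high)
q_fuzzy <- function(text, max_edits = 2L, field = NULL) {
  list(node = "fuzzy", field = field, text = text, max_edits = as.integer(max_edits))
}
q_prefix <- function(text, field = NULL) list(node = "prefix", field = field, text = text)
q_bool <- function(op, children) list(node = "bool", op = op, children = children)
q_all <- function() list(node = "all")
q_none <- function() list(node = "none")

parse_error <- function(msg, col) {
  stop(structure(class = c("query_parse_error", "seqindex_error", "error", "condition"),
                 list(message = sprintf("query syntax error at column %d: %s", col, msg),
                      call = NULL, column = col)))
}

# ---- lexer --------------------------------------------------------------

lex_query <- function(q) {
  toks <- list()
  chars <- strsplit(q, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  push <- function(type, value, col) toks[[length(toks) + 1L]] <<- list(type = type, value = value, col = col)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    col <- i
    if (ch == "(") { push("LPAREN", "(", col); i <- i + 1L; next }
    if (ch == ")") { push("RPAREN", ")", col); i <- i + 1L; next }
    if (ch == "[") { push("LBRACKET", "[", col); i <- i + 1L; next }
    if (ch == "]") { push("RBRACKET", "]", col); i <- i + 1L; next }
    if (ch == ":") { push("COLON", ":", col); i <- i + 1L; next }
    if (ch == "*") { push("STAR", "*", col); i <- i + 1L; next }
    if (ch == "~") {
      j <- i + 1L
      while (j <= n && grepl("^[0-9]$", chars[j])) j <- j + 1L
      nval <- if (j > i + 1L) as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = "")) else NA_integer_
      push("FUZZ", nval, col)
      i <- j
      next
    }
    if (ch == '"') {
      j <- i + 1L
      while (j <= n && chars[j] != '"') j <- j + 1L
      if (j > n) parse_error("unterminated quote", col)
      push("QUOTED", if (j > i + 1L) paste(chars[(i + 1L):(j - 1L)], collapse = "") else "", col)
      i <- j + 1L
      next
    }
    if (ch %in% c("{", "}")) parse_error(sprintf("unsupported character '%s'", ch), col)
    j <- i
    while (j <= n && !grepl('^[][(){}:~*"[:space:]]$', chars[j])) j <- j + 1L
    word <- paste(chars[i:(j - 1L)], collapse = "")
    if (word %in% c("AND", "OR", "NOT")) push(word, word, col) else push("WORD", word, col)
    i <- j
  }
  toks
}

# ---- recursive-descent parser ------------------------------------------

#' Parse a query string into a query tree
#'
#' Grammar: `field:term`, `field:"a phrase"`, `field:[x TO y]` (`*` as open
#' bound), `term~N` (N in \{1,2\}, bare `~` means 2), `prefix*`, uppercase
#' `AND`/`OR`/`NOT` and parentheses. Adjacent clauses with no operator
#' combine with `AND`; clauses with no field target every indexed full-text
#' field. Syntax errors report the offending column.
#'
#' @param q query string.
#' @return a query tree (nested lists; see [print_query()] for the
#'   canonical string form).
#' @export
parse_query <- function(q) {
  if (!is_string(q) || !nzchar(trimws(q))) parse_error("empty query", 1L)
  st <- new.env(parent = emptyenv())
  st$toks <- lex_query(q)
  st$pos <- 1L
  ast <- p_or(st)
  if (st$pos <= length(st$toks)) {
    parse_error(sprintf("unexpected '%s'", peek(st)$value), peek(st)$col)
  }
  ast
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL
advance <- function(st) { t <- peek(st); st$pos <- st$pos + 1L; t }
expect <- function(st, type, what) {
  t <- peek(st)
  if (is.null(t) || t$type != type) {
    parse_error(sprintf("expected %s", what), if (is.null(t)) last_col(st) else t$col)
  }
  advance(st)
}
last_col <- function(st) {
  if (length(st$toks)) st$toks[[length(st$toks)]]$col + 1L else 1L
}

starts_clause <- function(t) {
  !is.null(t) && t$type %in% c("WORD", "QUOTED", "LPAREN", "NOT", "LBRACKET")
}

p_or <- function(st) {
  left <- p_and(st)
  children <- list(left)
  while (!is.null(peek(st)) && peek(st)$type == "OR") {
    advance(st)
    children[[length(children) + 1L]] <- p_and(st)
  }
  if (length(children) == 1L) left else q_bool("OR", children)
}

p_and <- function(st) {
  children <- list(p_not(st))
  repeat {
    t <- peek(st)
    if (!is.null(t) && t$type == "AND") {
      advance(st)
      children[[length(children) + 1L]] <- p_not(st)
    } else if (starts_clause(t)) {          # implicit AND
      children[[length(children) + 1L]] <- p_not(st)
    } else break
  }
  if (length(children) == 1L) children[[1L]] else q_bool("AND", children)
}

p_not <- function(st) {
  t <- peek(st)
  if (!is.null(t) && t$type == "NOT") {
    advance(st)
    q_bool("NOT", list(p_not(st)))
  } else {
    p_primary(st)
  }
}

p_primary <- function(st) {
  t <- peek(st)
  if (is.null(t)) parse_error("unexpected end of query", last_col(st))
  if (t$type == "LPAREN") {
    advance(st)
    inner <- p_or(st)
    expect(st, "RPAREN", "')'")
    return(inner)
  }
  p_clause(st)
}

p_clause <- function(st) {
  t <- peek(st)
  field <- NULL
  if (!is.null(t) && t$type == "WORD" &&
      st$pos < length(st$toks) && st$toks[[st$pos + 1L]]$type == "COLON") {
    field <- t$value
    advance(st); advance(st)
  }
  p_atom(st, field)
}

p_atom <- function(st, field) {
  t <- peek(st)
  if (is.null(t)) parse_error("expected a clause", last_col(st))
  if (t$type == "QUOTED") {
    advance(st)
    return(q_phrase(t$value, field))
  }
  if (t$type == "LBRACKET") {
    if (is.null(field)) parse_error("range query requires a field", t$col)
    advance(st)
    low <- range_bound(st)
    to <- expect(st, "WORD", "'TO'")
    if (!identical(to$value, "TO")) parse_error("expected 'TO'", to$col)
    high <- range_bound(st)
    expect(st, "RBRACKET", "']'")
    return(q_range(field, low, high))
  }
  if (t$type == "WORD") {
    advance(st)
    nxt <- peek(st)
    if (!is.null(nxt) && nxt$type == "STAR") {
      advance(st)
      return(q_prefix(t$value, field))
    }
    if (!is.null(nxt) && nxt$type == "FUZZ") {
      advance(st)
      n <- if (is.na(nxt$value)) 2L else nxt$value
      if (!n %in% c(1L, 2L)) parse_error("fuzzy edit distance must be 1 or 2", nxt$col)
      return(q_fuzzy(t$value, n, field))
    }
    return(q_term(t$value, field))
  }
  parse_error(sprintf("unexpected '%s'", t$value), t$col)
}

range_bound <- function(st) {
  t <- peek(st)
  if (is.null(t)) parse_error("expected a range bound", last_col(st))
  if (t$type == "STAR") { advance(st); return(NULL) }       # open bound
  if (t$type == "WORD") { advance(st); return(t$value) }
  parse_error("bad range bound", t$col)
}

# ---- canonical printing -------------------------------------------------

#' Canonical string form of a query tree
#'
#' Fully parenthesized with explicit operators; `parse_query()` of the
#' printed form yields an equal tree.
#' @param ast a query tree.
#' @return a query string.
#' @export
print_query <- function(ast) {
  fld <- function(f) if (is.null(f)) "" else paste0(f, ":")
  switch(ast$node,
    term = paste0(fld(ast$field), ast$text),
    phrase = paste0(fld(ast$field), '"', paste(ast$texts, collapse = " "), '"'),
    prefix = paste0(fld(ast$field), ast$text, "*"),
    fuzzy = paste0(fld(ast$field), ast$text, "~", ast$max_edits),
    range = {
      b <- function(x) if (is.null(x) || is.infinite(x)) "*" else as.character(x)
      paste0(ast$field, ":[", b(ast$low), " TO ", b(ast$high), "]")
    },
    bool = if (ast$op == "NOT") {
      paste0("NOT ", print_query(ast$children[[1L]]))
    } else {
      paste0("(", paste(vapply(ast$children, print_query, ""),
                        collapse = paste0(" ", ast$op, " ")), ")")
    },
    all = "*:*",
    none = "NONE:NONE",
    seqindex_error("bad_ast", sprintf("unknown node '%s'", ast$node)))
}

# ---- schema-aware normalization ----------------------------------------

#' Normalize a query tree against a schema
#'
#' Lowercases terms with the index analyzer, rewrites a multi-token term on
#' a text field to an AND of its tokens, casts range bounds to the field's
#' numeric type (an unparseable bound on a numeric field is an error) and
#' rewrites a pure-NOT query to `match-all AND NOT x`.
#'
#' @param ast a query tree from [parse_query()].
#' @param schema a [schema()].
#' @return the normalized tree.
#' @export
normalize_query <- function(ast, schema = default_schema()) {
  out <- normalize_node(ast, schema)
  if (identical(out$node, "bool") && identical(out$op, "NOT")) {
    out <- q_bool("AND", list(q_all(), out))
  }
  out
}

normalize_node <- function(ast, schema) {
  switch(ast$node,
    term = {
      kind <- if (is.null(ast$field)) "text" else schema_kind(schema, ast$field)
      if (kind == "keyword") {
        q_term(tolower(ast$text), ast$field)
      } else if (kind == "numeric") {
        v <- suppressWarnings(as.numeric(ast$text))
        if (is.na(v)) {
          seqindex_error("non_numeric_bound",
                         sprintf("'%s' is not numeric (field '%s')", ast$text, ast$field))
        }
        q_term(canonical_number(v), ast$field)
      } else {
        toks <- tokenize(ast$text)
        if (length(toks) == 0L) q_none()
        else if (length(toks) == 1L) q_term(toks, ast$field)
        else q_bool("AND", lapply(toks, q_term, field = ast$field))
      }
    },
    phrase = {
      kind <- if (is.null(ast$field)) "text" else schema_kind(schema, ast$field)
      if (kind == "keyword") return(q_term(tolower(paste(ast$texts, collapse = " ")), ast$field))
      toks <- tokenize(paste(ast$texts, collapse = " "))
      if (length(toks) == 0L) q_none()
      else if (length(toks) == 1L) q_term(toks, ast$field)
      else q_phrase(toks, ast$field)
    },
    range = {
      kind <- schema_kind(schema, ast$field)
      cast <- function(x, side) {
        if (is.null(x)) return(NULL)
        if (kind == "numeric") {
          v <- suppressWarnings(as.numeric(x))
          if (is.na(v)) {
            seqindex_error("non_numeric_bound",
                           sprintf("%s bound '%s' is not numeric (field '%s')", side, x, ast$field))
          }
          v
        } else tolower(x)
      }
      q_range(ast$field, cast(ast$low, "lower"), cast(ast$high, "upper"))
    },
    fuzzy = {
      if (!ast$max_edits %in% c(1L, 2L)) {
        seqindex_error("bad_fuzzy", "fuzzy edit distance must be 1 or 2")
      }
      q_fuzzy(tolower(ast$text), ast$max_edits, ast$field)
    },
    prefix = q_prefix(tolower(ast$text), ast$field),
    bool = {
      kids <- lapply(ast$children, normalize_node, schema = schema)
      q_bool(ast$op, kids)
    },
    ast)
}

canonical_number <- function(v) {
  format(v, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}

# structural equality of trees, used by the round-trip property
query_equal <- function(a, b) identical(print_query(a), print_query(b))
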