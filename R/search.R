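# Query evaluation over index segments: boolean set algebra over posting
# and numeric lookups, TF-IDF scoring against (possibly cross-shard)
# global statistics, and the linear-scan reference evaluator used as an
# independent oracle.
#
# Scoring model: for every positive term/phrase/prefix/fuzzy leaf matching
# in field f, the document gains (1 + ln tf) * idf with
# idf = 1 + ln((N + 1) / (df + 1)). Range and negated leaves contribute 0;
# a query with no scoring leaf at all (pure filter) scores every match 1.0.
# There is no document-length normalization — deliberately simple, stable
# and reproducible across shard layouts.

# give every leaf a stable id so the stats, match and score phases agree
annotate_query <- function(ast) {
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  walk <- function(node) {
    if (identical(node$node, "bool")) {
      node$children <- lapply(node$children, walk)
    } else {
      counter$n <- counter$n + 1L
      node$leaf_id <- counter$n
    }
    node
  }
  walk(ast)
}

scoring_leaf_kinds <- c("term", "phrase", "prefix", "fuzzy")

# positive scoring leaves = scoring leaves under an even number of NOTs
positive_scoring_leaves <- function(ast, neg = FALSE) {
  if (identical(ast$node, "bool")) {
    flip <- if (identical(ast$op, "NOT")) !neg else neg
    return(unlist(lapply(ast$children, positive_scoring_leaves, neg = flip),
                  recursive = FALSE))
  }
  if (!neg && ast$node %in% scoring_leaf_kinds) list(ast) else list()
}

# ---- phase 1: per-segment statistics -----------------------------------

# resolve each leaf to concrete (field, term) pairs present in this
# segment, with their local document frequencies
seg_stats <- function(ix, ast) {
  leaves <- list()
  walk <- function(node) {
    if (identical(node$node, "bool")) {
      lapply(node$children, walk)
      return(invisible(NULL))
    }
    if (!node$node %in% scoring_leaf_kinds) return(invisible(NULL))
    flds <- leaf_fields(ix, node)
    pairs <- list(field = character(0), term = character(0), df = integer(0))
    add <- function(f, t) {
      df <- seg_df(ix, f, t)
      if (df > 0L) {
        pairs$field <<- c(pairs$field, f)
        pairs$term <<- c(pairs$term, t)
        pairs$df <<- c(pairs$df, df)
      }
    }
    if (node$node == "term") {
      for (f in flds) add(f, leaf_term_for_field(ix, node, f))
    } else if (node$node == "phrase") {
      for (f in flds) for (t in node$texts) add(f, t)
    } else if (node$node == "prefix") {
      for (f in flds) {
        for (t in seg_vocab(ix, f)[startsWith(seg_vocab(ix, f), node$text)]) add(f, t)
      }
    } else if (node$node == "fuzzy") {
      for (f in flds) {
        for (t in evaluate_fuzzy(node$text, seg_vocab(ix, f), node$max_edits)) add(f, t)
      }
    }
    leaves[[as.character(node$leaf_id)]] <<- pairs
    invisible(NULL)
  }
  walk(ast)
  list(N = index_ndocs(ix), leaves = leaves)
}

leaf_fields <- function(ix, node) {
  if (is.null(node$field)) return(seg_default_fields(ix))
  if (!schema_is_indexed(ix$schema, node$field)) {
    seqindex_error("field_not_searchable",
                   sprintf("field '%s' is stored but not indexed", node$field))
  }
  node$field
}

# a term leaf's concrete token for a field of a given kind
leaf_term_for_field <- function(ix, node, field) {
  kind <- schema_kind(ix$schema, field)
  if (kind == "numeric") {
    v <- suppressWarnings(as.numeric(node$text))
    if (is.na(v)) return(node$text)
    canonical_number(v)
  } else node$text
}

# merge per-shard stats: global N is the corpus size, global df the sum of
# per-shard dfs, expansions the union of per-shard expansions
merge_stats <- function(stats_list) {
  N <- sum(vapply(stats_list, `[[`, 0, "N"))
  ids <- unique(unlist(lapply(stats_list, function(s) names(s$leaves))))
  leaves <- list()
  for (lid in ids) {
    f <- character(0); t <- character(0); df <- integer(0)
    for (s in stats_list) {
      p <- s$leaves[[lid]]
      if (is.null(p)) next
      f <- c(f, p$field); t <- c(t, p$term); df <- c(df, p$df)
    }
    if (!length(f)) {
      leaves[[lid]] <- list(field = character(0), term = character(0),
                            df = integer(0))
      next
    }
    key <- paste(f, t, sep = "\r")
    agg <- tapply(df, key, sum)
    uk <- names(agg)
    parts <- strsplit(uk, "\r", fixed = TRUE)
    leaves[[lid]] <- list(field = vapply(parts, `[[`, "", 1L),
                          term = vapply(parts, `[[`, "", 2L),
                          df = as.integer(agg))
  }
  list(N = N, leaves = leaves)
}

stats_idf <- function(gstats, leaf_id, field, term) {
  p <- gstats$leaves[[as.character(leaf_id)]]
  k <- which(p$field == field & p$term == term)
  df <- if (length(k)) p$df[k[1L]] else 0L
  1 + log((gstats$N + 1) / (df + 1))
}

# ---- phase 2: matching --------------------------------------------------

seg_match <- function(ix, ast, gstats) {
  all_ids <- seg_all_ids(ix)
  eval_node <- function(node) {
    switch(node$node,
      all = all_ids,
      none = character(0),
      bool = {
        sets <- lapply(node$children, eval_node)
        switch(node$op,
          AND = Reduce(intersect, sets),
          OR = unique(unlist(sets)),
          NOT = setdiff(all_ids, sets[[1L]]))
      },
      range = eval_range(ix, node),
      phrase = eval_phrase(ix, node, gstats),
      { # term / prefix / fuzzy: union of postings over the leaf's pairs
        p <- gstats$leaves[[as.character(node$leaf_id)]]
        ids <- character(0)
        if (!is.null(p) && length(p$field)) {
          leaf_fields(ix, node)   # field-searchability check still applies
          for (k in seq_along(p$field)) {
            ids <- c(ids, names(seg_postings(ix, p$field[k], p$term[k])))
          }
        } else {
          leaf_fields(ix, node)
        }
        unique(ids)
      })
  }
  sort(eval_node(ast))
}

eval_range <- function(ix, node) {
  field <- node$field
  if (!schema_is_indexed(ix$schema, field)) {
    seqindex_error("field_not_searchable",
                   sprintf("field '%s' is stored but not indexed", field))
  }
  if (schema_kind(ix$schema, field) == "numeric") {
    tab <- ix$com$num[[field]]
    if (is.null(tab)) return(character(0))
    lo <- node$low %||% -Inf
    hi <- node$high %||% Inf
    unique(tab$doc_id[tab$value >= lo & tab$value <= hi])
  } else {
    voc <- seg_vocab(ix, field)
    if (!is.null(node$low)) voc <- voc[voc >= node$low]
    if (!is.null(node$high)) voc <- voc[voc <= node$high]
    unique(unlist(lapply(voc, function(t) names(seg_postings(ix, field, t)))))
  }
}

eval_phrase <- function(ix, node, gstats) {
  p <- gstats$leaves[[as.character(node$leaf_id)]]
  flds <- unique(if (!is.null(p)) p$field else leaf_fields(ix, node))
  if (is.null(node$field)) flds <- intersect(flds, seg_default_fields(ix))
  ids <- character(0)
  for (f in flds) {
    ids <- c(ids, phrase_docs_in_field(ix, f, node$texts))
  }
  unique(ids)
}

phrase_docs_in_field <- function(ix, field, tokens) {
  entries <- lapply(tokens, function(t) seg_postings(ix, field, t))
  if (any(vapply(entries, is.null, logical(1)))) return(character(0))
  cand <- Reduce(intersect, lapply(entries, names))
  cand[vapply(cand, function(id) {
    shifted <- lapply(seq_along(entries), function(k) entries[[k]][[id]] - (k - 1L))
    length(Reduce(intersect, shifted)) > 0L
  }, logical(1))]
}

# ---- scoring ------------------------------------------------------------

seg_score_ids <- function(ix, ids, ast, gstats) {
  leaves <- positive_scoring_leaves(ast)
  if (!length(leaves)) return(setNames(rep(1.0, length(ids)), ids))
  scores <- setNames(numeric(length(ids)), ids)
  for (leaf in leaves) {
    p <- gstats$leaves[[as.character(leaf$leaf_id)]]
    if (is.null(p) || !length(p$field)) next
    if (leaf$node == "phrase") {
      flds <- unique(p$field)
      if (is.null(leaf$field)) flds <- intersect(flds, seg_default_fields(ix))
      for (f in flds) {
        okdocs <- intersect(phrase_docs_in_field(ix, f, leaf$texts), ids)
        for (id in okdocs) {
          for (t in leaf$texts) {
            tf <- seg_tf(ix, f, t, id)
            if (tf > 0L) {
              scores[id] <- scores[id] +
                (1 + log(tf)) * stats_idf(gstats, leaf$leaf_id, f, t)
            }
          }
        }
      }
    } else {
      for (k in seq_along(p$field)) {
        entry <- seg_postings(ix, p$field[k], p$term[k])
        hit <- intersect(names(entry), ids)
        for (id in hit) {
          tf <- length(entry[[id]])
          scores[id] <- scores[id] +
            (1 + log(tf)) * stats_idf(gstats, leaf$leaf_id, p$field[k], p$term[k])
        }
      }
    }
  }
  scores
}

#' Score one document against a query
#'
#' Exposes the scoring model directly: the sum over positive scoring
#' leaves of `(1 + ln tf) * (1 + ln((N+1)/(df+1)))`, computed from
#' `global_stats` (cross-shard statistics when searching a shard set, the
#' segment's own otherwise). A match through filters only scores 1.0.
#'
#' @param ix an index holding the document.
#' @param doc_id a committed document id that matches `ast`.
#' @param ast a normalized query tree (a query string is accepted).
#' @param global_stats optional statistics from a wider shard set.
#' @return non-negative numeric score.
#' @export
score_document <- function(ix, doc_id, ast, global_stats = NULL) {
  if (is.character(ast)) ast <- normalize_query(parse_query(ast), ix$schema)
  ast <- annotate_query(ast)
  gstats <- global_stats %||% seg_stats(ix, ast)
  unname(seg_score_ids(ix, doc_id, ast, gstats)[doc_id])
}

# ---- single entry point -------------------------------------------------

#' Search an index or shard set
#'
#' Parses (if needed) and normalizes the query, evaluates it, scores
#' matches, and returns one page of hits ordered by score descending with
#' ties broken by ascending document id. When `x` is a [shardset()] the
#' query fans out over every shard with global statistics exchanged first,
#' so results are identical to a single merged index.
#'
#' @param x a `seqindex_index` or [shardset()].
#' @param q query string or parsed query tree.
#' @param offset 0-based rank of the first hit to return.
#' @param limit page size.
#' @return a `search_result`: list with `total`, `hits` (data.frame of
#'   `doc_id`, `score`, `content_type`), `docs` (stored fields per hit),
#'   `offset`, `limit`.
#' @export
index_search <- function(x, q, offset = 0L, limit = 10L) {
  shards <- as_shard_list(x)
  schema <- shards[[1L]]$schema
  ast <- if (is.character(q)) normalize_query(parse_query(q), schema)
         else normalize_query(q, schema)
  ast <- annotate_query(ast)
  if (offset < 0L || limit < 0L) seqindex_error("bad_paging", "offset and limit must be >= 0")
  gstats <- merge_stats(lapply(shards, seg_stats, ast = ast))
  per <- lapply(shards, function(sh) {
    ids <- seg_match(sh, ast, gstats)
    sc <- seg_score_ids(sh, ids, ast, gstats)
    k <- min(length(ids), offset + limit)
    o <- order(-sc, names(sc), method = "radix")
    top <- o[seq_len(k)]
    list(total = length(ids),
         doc_id = names(sc)[top], score = unname(sc[top]), shard = sh)
  })
  total <- sum(vapply(per, `[[`, 0L, "total"))
  doc_id <- unlist(lapply(per, `[[`, "doc_id"))
  score <- unlist(lapply(per, `[[`, "score"))
  shard_of <- rep(seq_along(per), vapply(per, function(p) length(p$doc_id), 0L))
  o <- order(-score, doc_id, method = "radix")
  pick <- o[seq_len(min(length(o), offset + limit))]
  pick <- pick[seq_len(length(pick)) > offset]
  hits <- data.frame(doc_id = doc_id[pick], score = score[pick],
                     stringsAsFactors = FALSE)
  docs <- lapply(seq_along(pick), function(i) {
    index_get(shards[[shard_of[pick[i]]]], hits$doc_id[i])
  })
  hits$content_type <- vapply(docs, `[[`, "", "content_type")
  structure(list(total = total, hits = hits, docs = docs,
                 offset = offset, limit = limit),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %d match(es), showing %d from offset %d\n",
              x$total, nrow(x$hits), x$offset))
  if (nrow(x$hits)) print(x$hits)
  invisible(x)
}

# ---- linear-scan reference evaluator -----------------------------------

#' Evaluate a query by brute-force linear scan
#'
#' Re-evaluates the query tree directly against raw documents, with no
#' posting lists, no numeric tables and no vocabulary structures. Slow but
#' transparently correct; used as the independent oracle the index is
#' checked against.
#'
#' @param docs list of documents.
#' @param q query string or tree.
#' @param schema schema giving field kinds.
#' @return sorted character vector of matching doc_ids.
#' @export
scan_search <- function(docs, q, schema = default_schema()) {
  ast <- if (is.character(q)) normalize_query(parse_query(q), schema)
         else normalize_query(q, schema)
  all_ids <- vapply(docs, `[[`, "", "doc_id")
  names(docs) <- all_ids
  eval_node <- function(node) {
    switch(node$node,
      all = all_ids,
      none = character(0),
      bool = {
        sets <- lapply(node$children, eval_node)
        switch(node$op,
          AND = Reduce(intersect, sets),
          OR = unique(unlist(sets)),
          NOT = setdiff(all_ids, sets[[1L]]))
      },
      all_ids[vapply(docs, function(d) scan_leaf(d, node, schema), logical(1))])
  }
  sort(eval_node(ast))
}

scan_leaf <- function(doc, node, schema) {
  target_fields <- function() {
    if (!is.null(node$field)) return(node$field)
    nms <- names(doc$fields)
    nms[vapply(nms, function(f) schema_kind(schema, f) %in% c("text", "keyword"),
               logical(1))]
  }
  field_tokens <- function(f) {
    if (identical(f, "content_type")) return(tolower(doc$content_type))
    vals <- unlist(doc$fields[[f]], use.names = FALSE)
    if (is.null(vals)) return(character(0))
    kind <- schema_kind(schema, f)
    if (kind == "keyword") tolower(as.character(vals))
    else if (kind == "numeric") canonical_number(as.numeric(vals))
    else unlist(lapply(as.character(vals), tokenize))
  }
  switch(node$node,
    term = any(vapply(target_fields(), function(f) node$text %in% field_tokens(f),
                      logical(1))),
    prefix = any(vapply(target_fields(), function(f) {
      any(startsWith(field_tokens(f), node$text))
    }, logical(1))),
    fuzzy = any(vapply(target_fields(), function(f) {
      toks <- field_tokens(f)
      any(vapply(toks, function(t) dl_distance(node$text, t, cap = node$max_edits) <=
                   node$max_edits, logical(1)))
    }, logical(1))),
    phrase = any(vapply(target_fields(), function(f) {
      if (schema_kind(schema, f) != "text" && !identical(f, "content_type")) return(FALSE)
      vals <- unlist(doc$fields[[f]], use.names = FALSE)
      if (is.null(vals)) return(FALSE)
      any(vapply(as.character(vals), function(v) {
        toks <- tokenize(v)
        n <- length(node$texts)
        if (length(toks) < n) return(FALSE)
        any(vapply(seq_len(length(toks) - n + 1L), function(s) {
          identical(toks[s:(s + n - 1L)], node$texts)
        }, logical(1)))
      }, logical(1)))
    }, logical(1))),
    range = {
      vals <- unlist(doc$fields[[node$field]], use.names = FALSE)
      if (is.null(vals)) return(FALSE)
      if (schema_kind(schema, node$field) == "numeric") {
        v <- as.numeric(vals)
        any(v >= (node$low %||% -Inf) & v <= (node$high %||% Inf))
      } else {
        toks <- field_tokens(node$field)
        ok <- rep(TRUE, length(toks))
        if (!is.null(node$low)) ok <- ok & toks >= node$low
        if (!is.null(node$high)) ok <- ok & toks <= node$high
        any(ok)
      }
    },
    FALSE)
}
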