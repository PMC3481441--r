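# The embedded inverted index: posting lists with positions, numeric
# tables for range filters, stored fields, add/update/delete with commit
# semantics, and a self-describing on-disk segment format.
#
# Mutations queue up as pending operations and become visible atomically
# at commit; the on-disk segment is replaced by temp-file + rename, so a
# crash between add and commit leaves the previous committed state intact.

POS_GAP <- 100000   # position offset between successive values of a field;
                    # phrases never match across value boundaries

#' Create an index
#'
#' @param dir directory to persist committed segments into (`NULL` for a
#'   memory-only index).
#' @param schema a [schema()]; defaults to [default_schema()].
#' @return a `seqindex_index` handle.
#' @export
index_create <- function(dir = NULL, schema = default_schema()) {
  ix <- new.env(parent = emptyenv())
  ix$dir <- dir
  ix$schema <- schema
  ix$com <- new_segment()
  ix$pending <- list()
  ix$gen <- 0L
  class(ix) <- "seqindex_index"
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    index_save(ix)
  }
  ix
}

new_segment <- function() {
  com <- new.env(parent = emptyenv())
  com$post <- new.env(parent = emptyenv())       # field -> term -> doc -> positions
  com$num <- new.env(parent = emptyenv())        # field -> list(value, doc_id)
  com$docs <- new.env(parent = emptyenv())       # doc_id -> stored record
  com$docterms <- new.env(parent = emptyenv())   # doc_id -> list(field, term)
  com$numfields <- new.env(parent = emptyenv())  # doc_id -> numeric fields
  com
}

#' Open a persisted index
#' @param dir directory written by a committed [index_create()] index.
#' @return a `seqindex_index` handle.
#' @export
index_open <- function(dir) {
  path <- file.path(dir, "segment.json")
  if (!file.exists(path)) {
    seqindex_error("no_index", sprintf("'%s' does not contain an index segment", dir))
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(raw$format, "seqindex-segment") || !identical(raw$version, 1L) &&
      !identical(raw$version, 1)) {
    seqindex_error("bad_segment", "unrecognized segment header")
  }
  ix <- index_create(dir = NULL, schema = schema_from_list(raw$schema))
  ix$dir <- dir
  com <- ix$com
  for (id in names(raw$docs)) {
    d <- raw$docs[[id]]
    assign(id, list(content_type = d$content_type,
                    source = d$source,
                    stored = lapply(d$fields, function(f) {
                      if (identical(f$kind, "n")) as.numeric(unlist(f$values))
                      else as.character(unlist(f$values))
                    }),
                    indexed_unstored = as.character(unlist(d$indexed_unstored))),
           envir = com$docs)
  }
  for (f in names(raw$post)) {
    fe <- new.env(parent = emptyenv())
    for (t in names(raw$post[[f]])) {
      entry <- lapply(raw$post[[f]][[t]], function(p) as.integer(unlist(p)))
      assign(t, entry[order(names(entry))], envir = fe)
    }
    assign(f, fe, envir = com$post)
  }
  for (f in names(raw$num)) {
    assign(f, list(value = as.numeric(unlist(raw$num[[f]]$value)),
                   doc_id = as.character(unlist(raw$num[[f]]$doc_id))),
           envir = com$num)
  }
  rebuild_reverse_maps(com)
  ix
}

# docterms / numfields are derived data; reconstruct them after a load
rebuild_reverse_maps <- function(com) {
  acc <- new.env(parent = emptyenv())
  for (f in ls(com$post)) {
    fe <- com$post[[f]]
    for (t in ls(fe)) {
      for (id in names(fe[[t]])) {
        cur <- acc[[id]] %||% list(field = character(0), term = character(0))
        cur$field <- c(cur$field, f); cur$term <- c(cur$term, t)
        assign(id, cur, envir = acc)
      }
    }
  }
  for (id in ls(acc)) assign(id, acc[[id]], envir = com$docterms)
  for (f in ls(com$num)) {
    for (id in unique(com$num[[f]]$doc_id)) {
      assign(id, c(com$numfields[[id]], f), envir = com$numfields)
    }
  }
  invisible(com)
}

index_save <- function(ix) {
  if (is.null(ix$dir)) return(invisible(ix))
  com <- ix$com
  payload <- list(
    format = "seqindex-segment", version = 1L,
    schema = schema_to_list(ix$schema),
    docs = mget_env(com$docs, function(d) {
      list(content_type = d$content_type, source = d$source,
           fields = lapply(d$stored, function(v) {
             list(kind = if (is.numeric(v)) "n" else "s", values = as.character(v))
           }),
           indexed_unstored = d$indexed_unstored)
    }),
    post = mget_env(com$post, function(fe) mget_env(fe, identity)),
    num = mget_env(com$num, identity)
  )
  atomic_write(function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  }, file.path(ix$dir, "segment.json"))
  invisible(ix)
}

mget_env <- function(e, f) {
  nms <- ls(e)
  out <- lapply(nms, function(n) f(e[[n]]))
  names(out) <- nms
  out
}

#' Number of committed documents
#' @param ix an index.
#' @return integer count.
#' @export
index_ndocs <- function(ix) length(ls(ix$com$docs))

#' Queue a document for indexing
#'
#' The document becomes searchable only after [index_commit()]; adding an
#' id that already exists replaces the previous version atomically at
#' commit.
#'
#' @param ix an index.
#' @param doc a [make_document()] document.
#' @return the index, invisibly.
#' @export
index_add <- function(ix, doc) {
  if (!inherits(doc, "document")) seqindex_error("bad_doc", "not a document")
  for (fn in names(doc$fields)) {
    decl <- schema_field(ix$schema, fn)
    if (decl$kind == "numeric") {
      v <- suppressWarnings(as.numeric(unlist(doc$fields[[fn]])))
      if (anyNA(v)) {
        seqindex_error("schema_violation",
                       sprintf("field '%s' is numeric but got a non-numeric value (doc '%s')",
                               fn, doc$doc_id))
      }
    }
  }
  ix$pending[[length(ix$pending) + 1L]] <- list(op = "add", doc = doc)
  invisible(ix)
}

#' Queue a deletion
#' @param ix an index.
#' @param doc_id id to delete; an unknown id is a warning and a no-op.
#' @return the index, invisibly.
#' @export
index_delete <- function(ix, doc_id) {
  ix$pending[[length(ix$pending) + 1L]] <- list(op = "delete", id = doc_id)
  invisible(ix)
}

#' Queue a partial update
#'
#' Replaces the named fields of an existing document and keeps every other
#' field. Only possible when all current fields of the document are stored:
#' an indexed-but-unstored field cannot be reconstructed for reindexing.
#'
#' @param ix an index.
#' @param doc_id existing document id.
#' @param fields named list of replacement values.
#' @return the index, invisibly.
#' @export
index_update <- function(ix, doc_id, fields) {
  cur <- resolve_doc(ix, doc_id)
  if (is.null(cur)) {
    seqindex_error("unknown_doc", sprintf("cannot update unknown document '%s'", doc_id))
  }
  if (length(cur$indexed_unstored)) {
    seqindex_error("partial_update_unsupported",
                   sprintf("document '%s' has indexed-only field(s) %s; partial update impossible",
                           doc_id, paste(sQuote(cur$indexed_unstored), collapse = ", ")))
  }
  merged <- cur$stored
  for (fn in names(fields)) merged[[fn]] <- fields[[fn]]
  src <- if (!is.null(cur$source)) {
    source_location(cur$source$path, cur$source$offset, cur$source$length)
  }
  doc <- structure(list(doc_id = doc_id, content_type = cur$content_type,
                        fields = merged, source = src),
                   class = "document")
  index_add(ix, doc)
}

# current view of a doc: last pending add wins, else committed state
resolve_doc <- function(ix, doc_id) {
  for (op in rev(ix$pending)) {
    if (op$op == "add" && identical(op$doc$doc_id, doc_id)) {
      d <- op$doc
      return(list(content_type = d$content_type, source = d$source,
                  stored = d$fields, indexed_unstored = character(0)))
    }
    if (op$op == "delete" && identical(op$id, doc_id)) return(NULL)
  }
  ix$com$docs[[doc_id]]
}

#' Commit pending mutations
#'
#' Applies queued adds/updates/deletes in order, persists the segment when
#' the index has a directory, and invalidates any cached query results.
#' @param ix an index.
#' @return the index, invisibly.
#' @export
index_commit <- function(ix) {
  com <- ix$com
  for (op in ix$pending) {
    if (op$op == "add") {
      if (!is.null(com$docs[[op$doc$doc_id]])) remove_doc(com, op$doc$doc_id)
      insert_doc(com, op$doc, ix$schema)
    } else {
      if (is.null(com$docs[[op$id]])) {
        seqindex_warn("unknown_doc", sprintf("delete of unknown document '%s' ignored", op$id))
      } else {
        remove_doc(com, op$id)
      }
    }
  }
  ix$pending <- list()
  sort_numeric_tables(com)
  ix$gen <- ix$gen + 1L
  index_save(ix)
  invisible(ix)
}

#' Fetch the stored view of a document
#' @param ix an index.
#' @param doc_id committed document id.
#' @return a `document` carrying the stored fields, or error if unknown.
#' @export
index_get <- function(ix, doc_id) {
  d <- ix$com$docs[[doc_id]]
  if (is.null(d)) seqindex_error("unknown_doc", sprintf("unknown document '%s'", doc_id))
  src <- if (!is.null(d$source)) {
    source_location(d$source$path, d$source$offset, d$source$length)
  }
  structure(list(doc_id = doc_id, content_type = d$content_type,
                 fields = d$stored, source = src),
            class = "document")
}

insert_doc <- function(com, doc, schema) {
  id <- doc$doc_id
  fields_rec <- list(field = character(0), term = character(0))
  add_posting <- function(field, term, positions) {
    fe <- com$post[[field]]
    if (is.null(fe)) {
      fe <- new.env(parent = emptyenv())
      assign(field, fe, envir = com$post)
    }
    entry <- fe[[term]]
    entry[[id]] <- c(entry[[id]], as.integer(positions))
    assign(term, entry[order(names(entry))], envir = fe)
    fields_rec$field <<- c(fields_rec$field, field)
    fields_rec$term <<- c(fields_rec$term, term)
  }
  numeric_fields <- character(0)
  stored <- list()
  indexed_unstored <- character(0)
  for (fn in names(doc$fields)) {
    decl <- schema_field(schema, fn)
    vals <- unlist(doc$fields[[fn]], use.names = FALSE)
    if (decl$indexed) {
      if (decl$kind == "text") {
        for (vi in seq_along(vals)) {
          toks <- tokenize(as.character(vals[vi]))
          if (!length(toks)) next
          base <- (vi - 1L) * POS_GAP
          for (t in unique(toks)) {
            add_posting(fn, t, base + which(toks == t))
          }
        }
      } else if (decl$kind == "keyword") {
        for (vi in seq_along(vals)) {
          add_posting(fn, tolower(as.character(vals[vi])), (vi - 1L) * POS_GAP + 1L)
        }
      } else {                                   # numeric
        nv <- as.numeric(vals)
        tab <- com$num[[fn]] %||% list(value = numeric(0), doc_id = character(0))
        tab$value <- c(tab$value, nv)
        tab$doc_id <- c(tab$doc_id, rep(id, length(nv)))
        assign(fn, tab, envir = com$num)
        numeric_fields <- c(numeric_fields, fn)
        for (vi in seq_along(nv)) {
          add_posting(fn, canonical_number(nv[vi]), (vi - 1L) * POS_GAP + 1L)
        }
      }
    }
    if (decl$stored) stored[[fn]] <- vals
    if (decl$indexed && !decl$stored) indexed_unstored <- c(indexed_unstored, fn)
  }
  # content-type is matchable as a keyword field without being a document field
  add_posting("content_type", tolower(doc$content_type), 1L)
  assign(id, list(content_type = doc$content_type,
                  source = if (!is.null(doc$source)) unclass(doc$source),
                  stored = stored,
                  indexed_unstored = indexed_unstored),
         envir = com$docs)
  assign(id, fields_rec, envir = com$docterms)
  if (length(numeric_fields)) assign(id, unique(numeric_fields), envir = com$numfields)
  invisible(com)
}

remove_doc <- function(com, id) {
  dt <- com$docterms[[id]]
  if (!is.null(dt)) {
    for (k in seq_along(dt$field)) {
      fe <- com$post[[dt$field[k]]]
      if (is.null(fe)) next
      entry <- fe[[dt$term[k]]]
      entry[[id]] <- NULL
      if (length(entry)) assign(dt$term[k], entry, envir = fe)
      else rm(list = dt$term[k], envir = fe)
    }
    rm(list = id, envir = com$docterms)
  }
  for (f in com$numfields[[id]] %||% character(0)) {
    tab <- com$num[[f]]
    keep <- tab$doc_id != id
    assign(f, list(value = tab$value[keep], doc_id = tab$doc_id[keep]), envir = com$num)
  }
  if (!is.null(com$numfields[[id]])) rm(list = id, envir = com$numfields)
  rm(list = id, envir = com$docs)
  invisible(com)
}

sort_numeric_tables <- function(com) {
  for (f in ls(com$num)) {
    tab <- com$num[[f]]
    o <- order(tab$value, tab$doc_id)
    assign(f, list(value = tab$value[o], doc_id = tab$doc_id[o]), envir = com$num)
  }
  invisible(com)
}

# term frequency of (field, term) in one document (0 when absent)
seg_tf <- function(ix, field, term, doc_id) {
  fe <- ix$com$post[[field]]
  if (is.null(fe)) return(0L)
  length(fe[[term]][[doc_id]])
}

seg_postings <- function(ix, field, term) {
  fe <- ix$com$post[[field]]
  if (is.null(fe)) return(NULL)
  fe[[term]]
}

seg_df <- function(ix, field, term) length(seg_postings(ix, field, term))

seg_vocab <- function(ix, field) {
  fe <- ix$com$post[[field]]
  if (is.null(fe)) character(0) else ls(fe)
}

seg_all_ids <- function(ix) ls(ix$com$docs)

# fields an unfielded (full-text) clause targets: every posted field of
# kind text or keyword, except the internal content_type field
seg_default_fields <- function(ix) {
  flds <- setdiff(ls(ix$com$post), "content_type")
  flds[vapply(flds, function(f) schema_kind(ix$schema, f) %in% c("text", "keyword"),
              logical(1))]
}
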