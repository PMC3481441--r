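# Query facade tying index, shards, storage and region driver together.
# The routes mirror a Solr-flavoured REST dialect (q / start / rows) and
# each handler returns a {status, body} pair, so the same surface can sit
# behind any HTTP layer or be called in-process; the package itself is an
# embeddable library and ships no network server.

#' Open a query service over an index (or shards) and a chunk store
#'
#' @param index an index handle, [shardset()], index directory, or list of
#'   index directories (opened as shards).
#' @param store a [store_open()] handle or a store directory.
#' @return a `seqindex_service`.
#' @export
service_open <- function(index, store = NULL) {
  shards <- if (inherits(index, "shardset")) index
            else if (inherits(index, "seqindex_index")) shardset(list(index))
            else shardset(as.list(index))
  st <- if (is.null(store)) store_open(NULL)
        else if (inherits(store, "chunk_store")) store
        else store_open(store)
  structure(list(shards = shards, store = st), class = "seqindex_service")
}

http_ok <- function(body, content_type = "application/json") {
  list(status = 200L, content_type = content_type, body = body)
}
http_err <- function(status, msg, extra = list()) {
  list(status = as.integer(status), content_type = "application/json",
       body = c(list(error = msg), extra))
}

#' GET /search — query the index
#'
#' @param svc a [service_open()] service.
#' @param q query string (Lucene-style syntax).
#' @param start 0-based offset of the first hit.
#' @param rows page size.
#' @param format `"json"` (structured body) or `"csv"` (export: header row
#'   plus one line per hit, multi-values joined with `";"`).
#' @return response list `{status, content_type, body}`; on success the
#'   JSON body has `total`, `offset`, `rows` and `hits` (each hit: `id`,
#'   `score`, `content_type` and the stored fields).
#' @export
http_search <- function(svc, q, start = 0L, rows = 10L, format = c("json", "csv")) {
  format <- match.arg(format)
  res <- tryCatch(index_search(svc$shards, q, offset = as.integer(start),
                               limit = as.integer(rows)),
                  query_parse_error = function(e) e,
                  field_not_searchable = function(e) e,
                  non_numeric_bound = function(e) e)
  if (inherits(res, "condition")) {
    return(http_err(400L, conditionMessage(res),
                    if (!is.null(res$column)) list(column = res$column) else list()))
  }
  hits <- lapply(seq_along(res$docs), function(i) {
    d <- res$docs[[i]]
    c(list(id = d$doc_id, score = res$hits$score[i], content_type = d$content_type),
      d$fields)
  })
  if (format == "csv") {
    return(http_ok(search_csv(hits), content_type = "text/csv"))
  }
  http_ok(list(total = res$total, offset = res$offset, rows = res$limit, hits = hits))
}

search_csv <- function(hits) {
  if (!length(hits)) return("id,score,content_type\n")
  cols <- unique(unlist(lapply(hits, names)))
  esc <- function(x) {
    x <- paste(as.character(x), collapse = ";")      # multi-values flattened
    if (grepl('[",\n]', x)) paste0('"', gsub('"', '""', x), '"') else x
  }
  rows <- vapply(hits, function(h) {
    paste(vapply(cols, function(cn) if (is.null(h[[cn]])) "" else esc(h[[cn]]), ""),
          collapse = ",")
  }, "")
  paste0(paste(cols, collapse = ","), "\n", paste(rows, collapse = "\n"), "\n")
}

#' GET /document/<id> — full stored document plus links
#'
#' Returns every stored key/value of the document, its content-type, the
#' source location of the original record, and the storage links under
#' which raw payloads (sequence, translation) can be fetched.
#'
#' @param svc a service.
#' @param id committed document id.
#' @return response list; 404 when the id is unknown.
#' @export
http_document <- function(svc, id) {
  doc <- NULL
  for (sh in svc$shards$shards) {
    doc <- tryCatch(index_get(sh, id), seqindex_error = function(e) NULL)
    if (!is.null(doc)) break
  }
  if (is.null(doc)) return(http_err(404L, sprintf("unknown document '%s'", id)))
  links <- character(0)
  for (key in c(id, paste0(id, ":translation"))) {
    if (store_has(svc$store, key)) links <- c(links, paste0("/storage/", key))
  }
  http_ok(list(id = doc$doc_id, content_type = doc$content_type,
               fields = doc$fields,
               source = if (!is.null(doc$source)) unclass(doc$source),
               links = as.list(links)))
}

#' GET /storage/<key> — raw payload bytes, optionally a subrange
#'
#' @param svc a service.
#' @param key storage key.
#' @param start,stop optional 0-based, stop-exclusive byte range.
#' @return response list with the payload text as body; 404 for unknown
#'   keys, 416 for an out-of-bounds range.
#' @export
http_storage <- function(svc, key, start = NULL, stop = NULL) {
  res <- tryCatch(store_get_text(svc$store, key, start, stop),
                  unknown_key = function(e) e, bad_range = function(e) e)
  if (inherits(res, "unknown_key")) return(http_err(404L, conditionMessage(res)))
  if (inherits(res, "bad_range")) return(http_err(416L, conditionMessage(res)))
  http_ok(res, content_type = "text/plain")
}

#' GET /region — features overlapping a region, as GFF3
#'
#' @param svc a service.
#' @param seqid reference sequence name.
#' @param from,to 1-based inclusive interval.
#' @param type optional feature-type filter.
#' @return response list whose body is GFF3 text.
#' @export
http_region <- function(svc, seqid, from, to, type = NULL) {
  reg <- tryCatch(region(seqid, from, to), seqindex_error = function(e) e)
  if (inherits(reg, "condition")) return(http_err(400L, conditionMessage(reg)))
  feats <- features_in_region(svc$shards, reg, type = type)
  http_ok(export_region_gff(feats), content_type = "text/plain")
}

#' Fetch the original record bytes behind a document
#'
#' Reads exactly `length` bytes at `offset` from the original bank file
#' and verifies the slice still re-parses (the file may have changed since
#' indexing).
#'
#' @param source a [source_location()] (e.g. from [index_get()]).
#' @return the record text.
#' @export
fetch_original <- function(source) {
  if (!file.exists(source$path)) {
    seqindex_error("integrity_error", sprintf("original file '%s' is gone", source$path))
  }
  if (file.size(source$path) < source$offset + source$length) {
    seqindex_error("integrity_error",
                   sprintf("'%s' is shorter than the recorded record span (truncated?)",
                           source$path))
  }
  con <- file(source$path, open = "rb")
  on.exit(close(con))
  seek(con, where = source$offset)
  bytes <- readBin(con, "raw", n = source$length)
  if (length(bytes) != source$length) {
    seqindex_error("integrity_error", "short read: file changed since indexing")
  }
  rawToChar(bytes)
}
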