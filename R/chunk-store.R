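# Chunked key/value store for raw payloads (sequences, PDB bodies).
# Values are split into fixed-size chunks so a subrange can be served by
# reading only the chunks it overlaps — never the whole datum. Subranges
# are 0-based, stop-exclusive, in bytes; 1-based inclusive biological
# coordinates are translated exactly once, in the region driver.
#
# The backend is pluggable (put/get/delete/list of opaque blocks); the two
# built-ins are an embedded file-per-chunk backend and a memory backend.

DEFAULT_CHUNK_SIZE <- 65536L

#' Open a chunk store
#'
#' @param dir backing directory (created if missing); `NULL` gives a
#'   memory-only store.
#' @return a `chunk_store` handle with a chunk-read counter (see
#'   [store_read_count()]).
#' @export
store_open <- function(dir = NULL) {
  st <- new.env(parent = emptyenv())
  st$backend <- if (is.null(dir)) memory_backend() else file_backend(dir)
  st$reads <- 0L
  class(st) <- "chunk_store"
  st
}

file_backend <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  keydir <- function(key) file.path(dir, encode_key(key))
  list(
    put = function(key, meta, chunks) {
      kd <- keydir(key)
      tmp <- paste0(kd, ".tmp")
      unlink(tmp, recursive = TRUE)
      dir.create(tmp, recursive = TRUE)
      for (i in seq_along(chunks)) {
        writeBin(chunks[[i]], file.path(tmp, sprintf("%06d.chunk", i)))
      }
      jsonlite::write_json(meta, file.path(tmp, "meta.json"), auto_unbox = TRUE, digits = NA)
      unlink(kd, recursive = TRUE)       # no stale tail chunks survive an overwrite
      if (!file.rename(tmp, kd)) seqindex_error("put_failure", sprintf("cannot store '%s'", key))
    },
    meta = function(key) {
      mf <- file.path(keydir(key), "meta.json")
      if (!file.exists(mf)) return(NULL)
      jsonlite::fromJSON(mf)
    },
    chunk = function(key, i) {
      f <- file.path(keydir(key), sprintf("%06d.chunk", i))
      readBin(f, "raw", n = file.size(f))
    },
    delete = function(key) unlink(keydir(key), recursive = TRUE),
    keys = function() {
      vapply(list.dirs(dir, recursive = FALSE, full.names = FALSE),
             function(k) URLdecode(chartr("@", "%", k)), "", USE.NAMES = FALSE)
    }
  )
}

memory_backend <- function() {
  env <- new.env(parent = emptyenv())
  list(
    put = function(key, meta, chunks) assign(key, list(meta = meta, chunks = chunks), envir = env),
    meta = function(key) env[[key]]$meta,
    chunk = function(key, i) env[[key]]$chunks[[i]],
    delete = function(key) if (!is.null(env[[key]])) rm(list = key, envir = env),
    keys = function() ls(env)
  )
}

as_bytes <- function(data) {
  if (is.raw(data)) data
  else if (is.character(data)) charToRaw(paste(data, collapse = ""))
  else seqindex_error("bad_data", "data must be raw or character")
}

#' Store a datum under a key
#'
#' The datum is split into `chunk_size`-byte chunks (the last may be
#' shorter); an existing key is overwritten atomically.
#'
#' @param store a [store_open()] handle.
#' @param key non-empty storage key.
#' @param data raw vector or character string (stored as its bytes).
#' @param chunk_size chunk size in bytes (default 65536).
#' @return metadata list `{key, total_length, chunk_size, n_chunks}`,
#'   invisibly.
#' @export
store_put <- function(store, key, data, chunk_size = DEFAULT_CHUNK_SIZE) {
  if (!is_string(key) || !nzchar(key)) seqindex_error("bad_key", "key must be non-empty")
  if (chunk_size < 1L) seqindex_error("bad_chunk_size", "chunk_size must be >= 1")
  bytes <- as_bytes(data)
  total <- length(bytes)
  n_chunks <- ceiling(total / chunk_size)
  chunks <- lapply(seq_len(n_chunks), function(i) {
    bytes[((i - 1L) * chunk_size + 1L):min(i * chunk_size, total)]
  })
  meta <- list(total_length = total, chunk_size = as.integer(chunk_size),
               n_chunks = as.integer(n_chunks))
  store$backend$put(key, meta, chunks)
  invisible(c(list(key = key), meta))
}

#' Retrieve a datum or a byte subrange of it
#'
#' `start`/`stop` select `data[start:stop)` in 0-based, stop-exclusive byte
#' coordinates (defaults: the whole datum). Only the chunks overlapping
#' the requested range are read, which is what makes extracting a gene
#' from the middle of a stored chromosome cheap.
#'
#' @param store a [store_open()] handle.
#' @param key stored key.
#' @param start 0-based first byte (default 0).
#' @param stop exclusive end byte (default: total length).
#' @return raw vector of `stop - start` bytes.
#' @export
store_get <- function(store, key, start = NULL, stop = NULL) {
  meta <- store$backend$meta(key)
  if (is.null(meta)) seqindex_error("unknown_key", sprintf("unknown storage key '%s'", key))
  total <- meta$total_length
  cs <- meta$chunk_size
  start <- start %||% 0
  stop <- stop %||% total
  if (start < 0 || start > stop) {
    seqindex_error("bad_range", sprintf("need 0 <= start <= stop (got %s..%s)", start, stop))
  }
  if (stop > total) {
    seqindex_error("bad_range",
                   sprintf("stop %s beyond total_length %s of key '%s'", stop, total, key))
  }
  if (stop == start) return(raw(0))
  first <- floor(start / cs)                 # 0-based chunk indexes
  last <- ceiling(stop / cs) - 1
  parts <- lapply(first:last, function(ci) {
    store$reads <- store$reads + 1L
    store$backend$chunk(key, ci + 1L)
  })
  bytes <- do.call(c, parts)
  lo <- start - first * cs
  bytes[(lo + 1L):(lo + (stop - start))]
}

#' Retrieve a subrange as text
#' @inheritParams store_get
#' @return character scalar.
#' @export
store_get_text <- function(store, key, start = NULL, stop = NULL) {
  rawToChar(store_get(store, key, start, stop))
}

#' Delete a key
#' @param store a [store_open()] handle.
#' @param key key to remove; unknown keys warn and do nothing.
#' @return invisibly, the store.
#' @export
store_delete <- function(store, key) {
  if (is.null(store$backend$meta(key))) {
    seqindex_warn("unknown_key", sprintf("delete of unknown storage key '%s' ignored", key))
  } else {
    store$backend$delete(key)
  }
  invisible(store)
}

#' Does the store hold a key?
#' @inheritParams store_delete
#' @return logical.
#' @export
store_has <- function(store, key) !is.null(store$backend$meta(key))

#' List stored keys
#' @param store a [store_open()] handle.
#' @return character vector.
#' @export
store_keys <- function(store) sort(store$backend$keys())

#' Stored length of a key, in bytes
#' @inheritParams store_delete
#' @return numeric byte count.
#' @export
store_length <- function(store, key) {
  meta <- store$backend$meta(key)
  if (is.null(meta)) seqindex_error("unknown_key", sprintf("unknown storage key '%s'", key))
  meta$total_length
}

#' Chunk reads performed so far
#'
#' Observable access contract: a subrange get touches at most
#' `ceiling((stop - start) / chunk_size) + 1` chunks.
#' @param store a [store_open()] handle.
#' @param reset zero the counter after reading it.
#' @return integer count.
#' @export
store_read_count <- function(store, reset = FALSE) {
  n <- store$reads
  if (reset) store$reads <- 0L
  n
}
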