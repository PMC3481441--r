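# Shard management: several self-contained index segments behind one
# query entry point. The entry point fans a query out, first exchanging
# global term statistics (corpus size and summed document frequencies), so
# scores — and therefore the merged ranking — are identical to what one
# big index would produce regardless of how documents are partitioned.

#' Build a shard set
#'
#' @param shards list of `seqindex_index` handles and/or index directory
#'   paths; doc_ids must be unique across the whole set.
#' @return a `shardset`.
#' @export
shardset <- function(shards) {
  if (!length(shards)) seqindex_error("bad_shardset", "at least one shard required")
  shards <- lapply(shards, function(s) {
    if (inherits(s, "seqindex_index")) return(s)
    if (is_string(s)) {
      if (!file.exists(file.path(s, "segment.json"))) {
        seqindex_error("shard_unreachable", sprintf("shard '%s' is unreachable", s))
      }
      return(index_open(s))
    }
    seqindex_error("bad_shardset", "shards must be index handles or directories")
  })
  structure(list(shards = shards), class = "shardset")
}

as_shard_list <- function(x) {
  if (inherits(x, "shardset")) x$shards
  else if (inherits(x, "seqindex_index")) list(x)
  else seqindex_error("bad_shardset", "expected an index or a shardset")
}

#' Route a document to a shard
#'
#' Deterministic hash routing: `hash(doc_id) mod n_shards`, so the same
#' document always lands on the same shard and any shard count works for
#' any mix of input banks. `by_bank` pins a document's whole bank (source
#' file) to one shard instead, mimicking deployments that dedicate shards
#' to bank groups.
#'
#' @param doc a document (or a doc_id string).
#' @param n_shards number of shards (>= 1).
#' @param by_bank route on the source file path instead of the doc_id.
#' @return 1-based shard index.
#' @export
route_document <- function(doc, n_shards, by_bank = FALSE) {
  if (n_shards < 1L) seqindex_error("bad_shardset", "n_shards must be >= 1")
  key <- if (is.character(doc)) doc
         else if (by_bank && !is.null(doc$source)) doc$source$path
         else doc$doc_id
  (fnv1a32(key) %% n_shards) + 1L
}

#' Search a shard set with merged global statistics
#'
#' Phase 1 collects per-shard corpus sizes, document frequencies and
#' fuzzy/prefix expansions for the query's terms and sums/unions them;
#' phase 2 has every shard match and score with the *global* statistics
#' and return its top `offset + limit`; the entry point merges by (score
#' desc, doc_id asc) and slices the page. Totals are summed. An
#' unreachable shard fails the whole query: partial results are never
#' passed off as complete.
#'
#' @param shardset a [shardset()].
#' @inheritParams index_search
#' @return a `search_result`, identical to searching one merged index.
#' @export
distributed_search <- function(shardset, q, offset = 0L, limit = 10L) {
  index_search(shardset, q, offset = offset, limit = limit)
}
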