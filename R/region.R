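# Genome-browser-facing adapter: "which features overlap seqid:start-end"
# answered from the index, "what is the sequence there" answered from the
# chunk store, results exported as GFF3. Coordinates here are 1-based and
# end-inclusive (the GFF3 convention); the single conversion to the chunk
# store's 0-based stop-exclusive bytes happens in sequence_of_region().

#' A genomic region
#' @param seqid reference sequence name.
#' @param start,end 1-based inclusive coordinates, `1 <= start <= end`.
#' @return a `region` list.
#' @export
region <- function(seqid, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is_string(seqid) || is.na(start) || is.na(end) || start < 1 || end < start) {
    seqindex_error("bad_region", "need seqid and 1 <= start <= end")
  }
  list(seqid = seqid, start = start, end = end)
}

#' Features overlapping a region
#'
#' Runs the index query `content_type:biosequence/gff AND seqid:<id> AND
#' start:[* TO end] AND end:[start TO *]` — closed-interval intersection —
#' and returns whole (unclipped) feature documents ordered by (start,
#' end, doc_id). Strand is reported but never filters.
#'
#' @param x an index or [shardset()].
#' @param reg a [region()].
#' @param type optional feature-type filter (e.g. `"gene"`).
#' @return list of feature documents.
#' @export
features_in_region <- function(x, reg, type = NULL) {
  clauses <- list(
    q_term("biosequence/gff", "content_type"),
    q_term(tolower(reg$seqid), "seqid"),
    q_range("start", NULL, reg$end),
    q_range("end", reg$start, NULL)
  )
  if (!is.null(type)) clauses[[length(clauses) + 1L]] <- q_term(tolower(type), "type")
  ast <- q_bool("AND", clauses)
  res <- index_search(x, ast, offset = 0L, limit = 0L)
  if (res$total == 0L) return(list())
  res <- index_search(x, ast, offset = 0L, limit = res$total)
  docs <- res$docs
  starts <- vapply(docs, function(d) as.numeric(d$fields$start[[1]]), 0)
  ends <- vapply(docs, function(d) as.numeric(d$fields$end[[1]]), 0)
  ids <- vapply(docs, `[[`, "", "doc_id")
  docs[order(starts, ends, ids, method = "radix")]
}

#' Sequence of a region
#'
#' Reads residues `start..end` (1-based, inclusive) of the reference
#' payload stored under `seqid` — the byte subrange `[start-1, end)`.
#'
#' @param store a [store_open()] chunk store holding the reference under
#'   key `seqid`.
#' @param reg a [region()].
#' @return residue string of length `end - start + 1`.
#' @export
sequence_of_region <- function(store, reg) {
  total <- store_length(store, reg$seqid)
  if (reg$end > total) {
    seqindex_error("bad_range",
                   sprintf("region end %s beyond stored sequence length %s for '%s'",
                           reg$end, total, reg$seqid))
  }
  store_get_text(store, reg$seqid, reg$start - 1, reg$end)
}

#' Export features as GFF3
#'
#' Reconstructs the nine columns from the document fields (attributes
#' ordered ID, Name, Parent, then alphabetically); the output re-parses
#' with [parse_gff3()] to documents equal to the input, minus source
#' locations.
#'
#' @param features list of feature documents (content-type
#'   `biosequence/gff`).
#' @return GFF3 text (single string, `##gff-version 3` header included).
#' @export
export_region_gff <- function(features) {
  core <- c("seqid", "source_tag", "type", "start", "end", "score", "strand", "phase")
  lines <- vapply(features, function(d) {
    f <- d$fields
    for (must in c("seqid", "type", "start", "end")) {
      if (is.null(f[[must]])) {
        seqindex_error("serialization_error",
                       sprintf("feature '%s' lacks mandatory field '%s'", d$doc_id, must))
      }
    }
    col <- function(name) {
      v <- f[[name]]
      if (is.null(v)) "." else as.character(v[[1]])
    }
    attrs <- setdiff(names(f), core)
    lead <- intersect(c("ID", "Name", "Parent"), attrs)
    attrs <- c(lead, sort(setdiff(attrs, lead), method = "radix"))
    attr_str <- vapply(attrs, function(a) {
      vals <- vapply(as.character(unlist(f[[a]])), gff3_encode, "", USE.NAMES = FALSE)
      paste0(gff3_encode(a), "=", paste(vals, collapse = ","))
    }, "")
    paste(c(col("seqid"), col("source_tag"), col("type"),
            canonical_number(as.numeric(f$start[[1]])),
            canonical_number(as.numeric(f$end[[1]])),
            if (is.null(f$score)) "." else canonical_number(as.numeric(f$score[[1]])),
            col("strand"), col("phase"),
            if (length(attr_str)) paste(attr_str, collapse = ";") else "."),
          collapse = "\t")
  }, "")
  paste0(paste(c("##gff-version 3", lines), collapse = "\n"), "\n")
}
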