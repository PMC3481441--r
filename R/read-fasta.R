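# FASTA reader. Emits one document per ">" header with the concatenated
# sequence as payload; the source span runs from the ">" byte to the last
# sequence byte of the record.

#' Parse a FASTA bank
#'
#' @param path path of the bank file (used for provenance even when `text`
#'   is supplied).
#' @param text optional: parse this string instead of reading `path`.
#' @param offset0 byte offset of `text` within the original file, so source
#'   locations of a re-read slice match the full file.
#' @return list of [parsed_record()]s with fields `id` (first header
#'   token), `description` (rest of the header, when present) and `length`
#'   (residue count); the payload is the sequence with newlines stripped.
#' @export
parse_fasta <- function(path, text = NULL, offset0 = 0, ...) {
  if (is.null(text)) text <- read_file_text(path)
  sl <- scan_lines(text, offset0)
  records <- list()
  cur <- NULL
  flush <- function(cur) {
    payload <- paste(cur$seq, collapse = "")
    fields <- list(id = cur$id)
    if (nzchar(cur$desc)) fields$description <- cur$desc
    fields$length <- nchar(payload)
    doc <- make_document(fields, "biosequence/fasta",
                         source_location(path, cur$offset, cur$end - cur$offset))
    parsed_record(doc, payload = payload, payload_id = doc$doc_id)
  }
  for (i in seq_along(sl$line)) {
    line <- sl$line[i]
    if (startsWith(line, ">")) {
      if (!is.null(cur)) records[[length(records) + 1L]] <- flush(cur)
      header <- sub("^>\\s*", "", line)
      id <- sub("\\s.*$", "", header)
      desc <- if (grepl("\\s", header)) trimws(sub("^\\S+\\s+", "", header)) else ""
      cur <- list(id = id, desc = desc, seq = character(0),
                  offset = sl$offset[i], end = sl$offset[i] + sl$nbytes[i])
    } else if (nzchar(trimws(line))) {
      if (is.null(cur)) {
        seqindex_error("malformed_input",
                       sprintf("sequence data before first '>' header (line %d)", i))
      }
      cur$seq <- c(cur$seq, gsub("\\s", "", line))
      cur$end <- sl$offset[i] + sl$nbytes[i]
    }
  }
  if (!is.null(cur)) records[[length(records) + 1L]] <- flush(cur)
  reader_result(records)
}
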