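# PDB reader. One document per file, with the complete file text as the
# payload so a structure viewer can be served the original body.

#' Parse a PDB file
#'
#' Reads the fixed-column header records: `HEADER` (classification in
#' columns 11-50, deposition date in 51-59, id code in 63-66), `TITLE`
#' continuations joined with a space, `COMPND` `MOLECULE:` entries and
#' `SOURCE` `ORGANISM_SCIENTIFIC:` entries. Missing optional records simply
#' leave the field absent; a missing `HEADER` is a malformed-input error.
#'
#' @inheritParams parse_fasta
#' @return a single-element list of [parsed_record()]; the document fields
#'   are `pdb_id`, `classification`, `deposition_date`, `title`, `compound`
#'   (multi-valued) and `organism`.
#' @export
parse_pdb <- function(path, text = NULL, offset0 = 0, ...) {
  if (is.null(text)) text <- read_file_text(path)
  total <- nchar(text, type = "bytes")
  sl <- scan_lines(text, offset0)
  lines <- sl$line
  hi <- which(startsWith(lines, "HEADER"))
  if (!length(hi)) {
    seqindex_error("malformed_input", sprintf("'%s' has no HEADER record", path))
  }
  h <- lines[hi[1]]
  fields <- list(pdb_id = trimws(substr(h, 63L, 66L)))
  cls <- trimws(substr(h, 11L, 50L))
  if (nzchar(cls)) fields$classification <- cls
  dep <- trimws(substr(h, 51L, 59L))
  if (nzchar(dep)) fields$deposition_date <- dep
  titles <- trimws(substr(lines[startsWith(lines, "TITLE")], 11L, 80L))
  # continuation lines may start with the leftover of the continuation number
  titles <- sub("^[0-9]+\\s+", "", titles)
  if (length(titles)) fields$title <- paste(titles, collapse = " ")
  compnd <- paste(substr(lines[startsWith(lines, "COMPND")], 11L, 80L), collapse = " ")
  mol <- regmatches(compnd, gregexpr("MOLECULE:\\s*[^;]+", compnd))[[1]]
  if (length(mol)) fields$compound <- trimws(sub("MOLECULE:\\s*", "", mol))
  srcl <- paste(substr(lines[startsWith(lines, "SOURCE")], 11L, 80L), collapse = " ")
  org <- regmatches(srcl, regexec("ORGANISM_SCIENTIFIC:\\s*([^;]+)", srcl))[[1]]
  if (length(org)) fields$organism <- trimws(org[2])
  src <- source_location(path, offset0, total)
  doc <- make_document(fields, "biosequence/pdb", src, doc_id = fields$pdb_id)
  reader_result(list(parsed_record(doc, payload = as.character(text), payload_id = doc$doc_id)))
}
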