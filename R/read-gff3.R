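# GFF3 reader. One document per feature line (content-type
# "biosequence/gff"); an optional ##FASTA section yields sequence records
# whose payloads are keyed by their seqid. Coordinates stay 1-based,
# end-inclusive, exactly as in the file.

#' Parse a GFF3 bank
#'
#' Lines with a column count other than 9 are recoverable errors: they are
#' skipped and reported through [skipped_lines()] rather than aborting the
#' parse, because real banks are large and dirty.
#'
#' @inheritParams parse_fasta
#' @return list of [parsed_record()]s. Feature documents carry `seqid`,
#'   `source_tag`, `type`, numeric `start`/`end`, `score`/`strand`/`phase`
#'   when not `"."`, and one (possibly multi-valued) field per attribute
#'   key.
#' @export
parse_gff3 <- function(path, text = NULL, offset0 = 0, ...) {
  if (is.null(text)) text <- read_file_text(path)
  sl <- scan_lines(text, offset0)
  records <- list()
  skip_line <- integer(0); skip_reason <- character(0)
  for (i in seq_along(sl$line)) {
    line <- sl$line[i]
    if (startsWith(line, "##FASTA")) {
      if (i < length(sl$line)) {
        fa_off <- sl$offset[i + 1L]
        fa_text <- paste(sl$line[(i + 1L):length(sl$line)], collapse = "\n")
        fa <- parse_fasta(path, text = fa_text, offset0 = fa_off)
        records <- c(records, fa)
      }
      break
    }
    if (!nzchar(line) || startsWith(line, "#")) next
    cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(cols) != 9L) {
      skip_line <- c(skip_line, i)
      skip_reason <- c(skip_reason,
                       sprintf("expected 9 tab-separated columns, got %d", length(cols)))
      next
    }
    fields <- list(seqid = cols[1], source_tag = cols[2], type = cols[3],
                   start = as.numeric(cols[4]), end = as.numeric(cols[5]))
    if (cols[6] != ".") fields$score <- as.numeric(cols[6])
    if (cols[7] != ".") fields$strand <- cols[7]
    if (cols[8] != ".") fields$phase <- cols[8]
    fields <- c(fields, parse_gff3_attributes(cols[9]))
    src <- source_location(path, sl$offset[i], sl$nbytes[i])
    doc_id <- if (!is.null(fields$ID)) fields$ID[[1]] else NULL
    doc <- make_document(fields, "biosequence/gff", src, doc_id = doc_id)
    records[[length(records) + 1L]] <- parsed_record(doc)
  }
  reader_result(records, data.frame(line = skip_line, reason = skip_reason))
}

# column 9: semicolon-separated key=value pairs; values are comma-separated
# multi-values, percent-encoded per the GFF3 spec
parse_gff3_attributes <- function(col9) {
  out <- list()
  if (!nzchar(col9) || col9 == ".") return(out)
  for (pair in strsplit(col9, ";", fixed = TRUE)[[1]]) {
    pair <- trimws(pair)
    if (!nzchar(pair)) next
    eq <- regexpr("=", pair, fixed = TRUE)
    if (eq < 0) next
    key <- gff3_decode(substr(pair, 1L, eq - 1L))
    vals <- vapply(strsplit(substr(pair, eq + 1L, nchar(pair)), ",", fixed = TRUE)[[1]],
                   gff3_decode, "", USE.NAMES = FALSE)
    out[[key]] <- c(out[[key]], vals)
  }
  out
}

gff3_decode <- function(x) if (grepl("%", x, fixed = TRUE)) URLdecode(x) else x

gff3_encode <- function(x) {
  # encode the characters GFF3 reserves in attribute values
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  gsub("\t", "%09", x, fixed = TRUE)
}
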