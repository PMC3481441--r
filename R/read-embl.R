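# EMBL flat-file reader. Two-letter line codes; the field mapping mirrors
# the GenBank reader (ID -> locus/length, AC -> accession, DE ->
# definition, OS -> organism, FT -> feature documents, sequence block ->
# payload) so downstream modules never care which of the two a record came
# from.

#' Parse an EMBL bank
#'
#' @inheritParams parse_genbank
#' @return list of [parsed_record()]s; see [parse_genbank()] for the field
#'   mapping and feature-explosion behaviour. Content-type of header
#'   documents is `biosequence/embl`.
#' @export
parse_embl <- function(path, text = NULL, offset0 = 0, explode = TRUE) {
  if (is.null(text)) text <- read_file_text(path)
  sl <- scan_lines(text, offset0)
  lapply_flat_records(sl, path, terminator_regex = "^//\\s*$",
                      start_regex = "^ID", format = "embl",
                      parse_one = function(lines, src) {
                        parse_embl_record(lines, src, explode)
                      })
}

parse_embl_record <- function(lines, src, explode) {
  fields <- list()
  features <- list()
  seq_lines <- character(0)
  in_seq <- FALSE
  for (line in lines) {
    code <- substr(line, 1L, 2L)
    val <- trimws(substr(line, 6L, nchar(line)))
    if (in_seq) {
      if (code == "//") break
      seq_lines <- c(seq_lines, gsub("[^A-Za-z]", "", line))
      next
    }
    if (code == "ID") {
      fields$locus <- sub(";$", "", sub("\\s.*$", "", val))
      m <- regmatches(val, regexec("(\\d+)\\s+(BP|AA)\\.?\\s*$", val, ignore.case = TRUE))[[1]]
      if (length(m)) fields$length <- as.numeric(m[2])
    } else if (code == "AC") {
      acc <- sub(";.*$", "", val)
      if (is.null(fields$accession) && nzchar(acc)) fields$accession <- acc
    } else if (code == "DE") {
      fields$definition <- if (is.null(fields$definition)) val
                           else paste(fields$definition, val)
    } else if (code == "OS") {
      if (is.null(fields$organism)) fields$organism <- val
    } else if (code == "FT") {
      body <- substr(line, 6L, nchar(line))
      m <- regmatches(body, regexec("^(\\S+)\\s+(\\S.*)$", body))[[1]]
      if (length(m) && !startsWith(trimws(body), "/") && grepl("^\\S", body)) {
        features[[length(features) + 1L]] <-
          list(key = m[2], location = trimws(m[3]), qualifiers = character(0))
      } else if (length(features)) {
        k <- length(features)
        tb <- trimws(body)
        if (!startsWith(tb, "/") && !length(features[[k]]$qualifiers)) {
          features[[k]]$location <- paste0(features[[k]]$location, tb)
        } else {
          features[[k]]$qualifiers <- c(features[[k]]$qualifiers, tb)
        }
      }
    } else if (code == "SQ") {
      in_seq <- TRUE
    }
  }
  build_flat_records(fields, features, paste(seq_lines, collapse = ""),
                     src, "biosequence/embl", explode)
}
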