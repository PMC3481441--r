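# GenBank flat-file reader, plus the location grammar and feature-table
# machinery shared with the EMBL reader.
#
# Each record yields a header document (content-type "biosequence/genbank")
# whose payload is the ORIGIN sequence, and — with feature explosion on —
# one document per feature-table entry, typed "biosequence/gff" so the
# region driver and genome-browser routing treat GenBank features exactly
# like GFF3 ones.

#' Parse a GenBank bank
#'
#' @inheritParams parse_fasta
#' @param explode emit one document per feature-table entry (default). When
#'   `FALSE` only the header document is produced and `/translation`
#'   payloads are keyed under the header id.
#' @return list of [parsed_record()]s. Header documents carry `locus`,
#'   `accession`, `version`, `definition`, `organism` and numeric `length`;
#'   feature documents carry `seqid` (the accession), `type`, numeric
#'   `start`/`end`, `strand` and the feature qualifiers. Compound or fuzzy
#'   locations are reduced to their outermost span and flagged
#'   `location_exact: false`.
#' @export
parse_genbank <- function(path, text = NULL, offset0 = 0, explode = TRUE) {
  if (is.null(text)) text <- read_file_text(path)
  sl <- scan_lines(text, offset0)
  lapply_flat_records(sl, path, terminator_regex = "^//\\s*$",
                      start_regex = "^LOCUS", format = "genbank",
                      parse_one = function(lines, src) {
                        parse_genbank_record(lines, src, explode)
                      })
}

# split a two-letter-code / keyword flat file into records on its "//"
# terminator and parse each; a trailing record without "//" is a
# truncated-record error.
lapply_flat_records <- function(sl, path, terminator_regex, start_regex,
                                format, parse_one) {
  records <- list()
  start_i <- NULL
  for (i in seq_along(sl$line)) {
    line <- sl$line[i]
    if (is.null(start_i)) {
      if (nzchar(trimws(line))) start_i <- i
      next
    }
    if (grepl(terminator_regex, line)) {
      lines <- sl$line[start_i:i]
      src <- source_location(path, sl$offset[start_i],
                             sl$offset[i] + sl$nbytes[i] - sl$offset[start_i])
      records <- c(records, parse_one(lines, src))
      start_i <- NULL
    }
  }
  if (!is.null(start_i)) {
    seqindex_error("truncated_record",
                   sprintf("%s record starting at byte %.0f of '%s' has no '//' terminator",
                           format, sl$offset[start_i], path))
  }
  reader_result(records)
}

parse_genbank_record <- function(lines, src, explode) {
  fields <- list()
  features <- list()
  origin <- character(0)
  section <- "header"
  kw <- ""
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[i]
    if (grepl("^//\\s*$", line)) break
    if (grepl("^\\S", line)) {                     # top-level keyword
      kw <- trimws(substr(line, 1L, 12L))
      val <- trimws(substr(line, 13L, nchar(line)))
      section <- "header"
      if (kw == "LOCUS") {
        m <- regmatches(val, regexec("^(\\S+)\\s+(\\d+)\\s+(bp|aa)", val))[[1]]
        if (length(m)) {
          fields$locus <- m[2]
          fields$length <- as.numeric(m[3])
        } else {
          fields$locus <- sub("\\s.*$", "", val)
        }
      } else if (kw == "DEFINITION") {
        fields$definition <- val
      } else if (kw == "ACCESSION") {
        fields$accession <- sub("\\s.*$", "", val)
      } else if (kw == "VERSION") {
        fields$version <- sub("\\s.*$", "", val)
      } else if (kw == "FEATURES") {
        section <- "features"
      } else if (kw == "ORIGIN") {
        section <- "origin"
      }
    } else if (section == "header") {
      val <- trimws(line)
      if (kw == "DEFINITION" && nzchar(val)) {
        fields$definition <- paste(fields$definition, val)
      } else if (kw == "SOURCE" && grepl("^\\s+ORGANISM\\s", line)) {
        fields$organism <- trimws(sub("^\\s+ORGANISM\\s+", "", line))
      }
    } else if (section == "features") {
      m <- regmatches(line, regexec("^ {5}(\\S+)\\s+(\\S.*)$", line))[[1]]
      if (length(m) && !startsWith(trimws(line), "/")) {
        features[[length(features) + 1L]] <-
          list(key = m[2], location = trimws(m[3]), qualifiers = character(0))
      } else if (length(features)) {
        k <- length(features)
        tl <- trimws(line)
        if (!startsWith(tl, "/") && !length(features[[k]]$qualifiers)) {
          features[[k]]$location <- paste0(features[[k]]$location, tl)
        } else {
          features[[k]]$qualifiers <- c(features[[k]]$qualifiers, tl)
        }
      }
    } else if (section == "origin") {
      origin <- c(origin, gsub("[^A-Za-z]", "", line))
    }
    i <- i + 1L
  }
  build_flat_records(fields, features, paste(origin, collapse = ""),
                     src, "biosequence/genbank", explode)
}

# assemble the parsed pieces into header + feature parsed_records; shared
# by the GenBank and EMBL readers
build_flat_records <- function(fields, features, sequence, src,
                               content_type, explode) {
  sequence <- toupper(sequence)
  if (is.null(fields$length) && nzchar(sequence)) fields$length <- nchar(sequence)
  header_id <- fields$accession %||% fields$locus
  doc <- make_document(fields, content_type, src, doc_id = header_id)
  out <- list()
  extra <- list()
  feats <- lapply(features, parse_feature_entry)
  if (explode) {
    hrec <- parsed_record(doc, payload = sequence, payload_id = doc$doc_id)
    out[[1L]] <- hrec
    for (k in seq_along(feats)) {
      ft <- feats[[k]]
      fid <- paste0(doc$doc_id, ":f", k)
      ffields <- c(list(seqid = header_id), ft$fields)
      translation <- ft$translation
      fdoc <- make_document(ffields, "biosequence/gff", src, doc_id = fid)
      out[[length(out) + 1L]] <-
        if (is.null(translation)) parsed_record(fdoc)
        else parsed_record(fdoc, payload = translation,
                           payload_id = paste0(fid, ":translation"))
    }
  } else {
    tr <- 0L
    for (ft in feats) {
      if (!is.null(ft$translation)) {
        tr <- tr + 1L
        key <- paste0(doc$doc_id, ":translation", if (tr > 1L) tr)
        extra[[key]] <- ft$translation
      }
    }
    out[[1L]] <- parsed_record(doc, payload = sequence, payload_id = doc$doc_id,
                               extra_payloads = extra)
  }
  out
}

# one feature-table entry -> typed fields; /translation is pulled out as a
# payload, never a searchable field
parse_feature_entry <- function(ft) {
  loc <- parse_feature_location(ft$location)
  fields <- list(type = ft$key, start = loc$start, end = loc$end,
                 strand = loc$strand)
  if (!loc$exact) fields$location_exact <- "false"
  translation <- NULL
  quals <- join_qualifier_lines(ft$qualifiers)
  for (q in quals) {
    m <- regmatches(q, regexec('^/([A-Za-z0-9_]+)(=(.*))?$', q))[[1]]
    if (!length(m)) next
    key <- m[2]
    val <- if (nzchar(m[3])) m[4] else "true"
    val <- sub('^"', "", sub('"$', "", val))
    if (key == "translation") {
      translation <- gsub("\\s", "", val)
    } else {
      fields[[key]] <- c(fields[[key]], val)
    }
  }
  list(fields = fields, translation = translation)
}

# qualifier continuation lines: a line not starting with "/" continues the
# previous qualifier; /translation continuations join without a space,
# everything else with one space
join_qualifier_lines <- function(lines) {
  out <- character(0)
  for (line in lines) {
    if (startsWith(line, "/") || !length(out)) {
      out <- c(out, line)
    } else {
      sep <- if (startsWith(out[length(out)], "/translation")) "" else " "
      out[length(out)] <- paste0(out[length(out)], sep, line)
    }
  }
  out
}

# GenBank/EMBL location grammar, reduced to one outer interval:
# complement(a..b) flips strand; join/order and fuzzy bounds (< >) keep the
# outermost min..max span and mark the location inexact.
parse_feature_location <- function(loc) {
  loc0 <- gsub("\\s", "", loc)
  exact <- TRUE
  strand <- "+"
  body <- loc0
  if (grepl("^complement\\(", body)) {
    strand <- "-"
    body <- sub("^complement\\(", "", body)
    body <- sub("\\)$", "", body)
  }
  if (grepl("[<>]", body)) { exact <- FALSE; body <- gsub("[<>]", "", body) }
  if (grepl("join\\(|order\\(|complement\\(", body)) exact <- FALSE
  nums <- as.numeric(regmatches(body, gregexpr("[0-9]+", body))[[1]])
  if (!length(nums)) {
    seqindex_error("bad_location", sprintf("cannot parse location '%s'", loc))
  }
  list(start = min(nums), end = max(nums), strand = strand, exact = exact)
}
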