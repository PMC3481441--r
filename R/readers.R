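# Reader infrastructure: the parsed-record container, the format registry
# (built-ins + plugins) and dynamic field recoding.

#' A parsed record
#'
#' What a format reader emits for one record: the key/value document plus,
#' when the record carries bulk data (a nucleotide/protein sequence, a
#' GenBank translation, a PDB body), the raw payload destined for the chunk
#' store and the key it is stored under (defaults to the document id).
#'
#' @param document a [make_document()] result.
#' @param payload optional character or raw payload.
#' @param payload_id storage key for the payload.
#' @param extra_payloads named list of additional payloads (e.g. GenBank
#'   `/translation` contents when feature explosion is off), keyed by their
#'   storage key.
#' @return a `parsed_record`.
#' @export
parsed_record <- function(document, payload = NULL, payload_id = NULL,
                          extra_payloads = list()) {
  if (!inherits(document, "document")) seqindex_error("bad_record", "document required")
  if (!is.null(payload) && is.null(payload_id)) payload_id <- document$doc_id
  if (!is.null(payload) && !nzchar(payload_id)) {
    seqindex_error("bad_record", "payload present but payload_id empty")
  }
  structure(list(document = document, payload = payload, payload_id = payload_id,
                 extra_payloads = extra_payloads),
            class = "parsed_record")
}

# standard return shape of every parser: list of parsed_record with a
# "skipped" attribute (data.frame line/reason for recoverable per-line errors)
reader_result <- function(records, skipped = NULL) {
  if (is.null(skipped)) {
    skipped <- data.frame(line = integer(0), reason = character(0))
  }
  structure(records, skipped = skipped, class = c("reader_result", "list"))
}

#' Recoverable lines skipped during parsing
#' @param x a parser result.
#' @return data.frame with columns `line` and `reason`.
#' @export
skipped_lines <- function(x) attr(x, "skipped") %||% data.frame(line = integer(0), reason = character(0))

# ---- format registry / plugins -----------------------------------------

builtin_formats <- function() c("fasta", "gff3", "genbank", "embl", "pdb")

new_reader_registry <- function() {
  reg <- new.env(parent = emptyenv())
  structure(list(plugins = reg), class = "reader_registry")
}

default_reader_registry <- function() {
  if (is.null(the$readers)) the$readers <- new_reader_registry()
  the$readers
}

#' Register a format plugin
#'
#' Extends the indexer with a new input format without touching the
#' built-ins: the plugin supplies a reader procedure with the same contract
#' as the built-in parsers (including byte-accurate source locations) and
#' the content-type its documents carry. After registration the indexer
#' accepts `-t <format_name>`.
#'
#' @param format_name token used to select the format (`-t` on the CLI).
#' @param reader `function(path, text = NULL, offset0 = 0, ...)` returning a
#'   list of [parsed_record()]s.
#' @param content_type registered content-type the reader emits.
#' @param registry reader registry (default: package registry).
#' @return the registry, invisibly.
#' @export
register_format_plugin <- function(format_name, reader, content_type,
                                   registry = default_reader_registry()) {
  if (!is_string(format_name) || !grepl("^[A-Za-z0-9_.-]+$", format_name)) {
    seqindex_error("bad_plugin", "format_name must be a simple token")
  }
  if (format_name %in% builtin_formats()) {
    seqindex_error("plugin_collision",
                   sprintf("'%s' is a built-in format", format_name))
  }
  if (!is.function(reader)) seqindex_error("bad_plugin", "reader must be a function")
  if (!content_type_known(content_type)) {
    seqindex_error("unknown_content_type",
                   sprintf("plugin content-type '%s' is not registered", content_type))
  }
  assign(format_name, list(reader = reader, content_type = content_type),
         envir = registry$plugins)
  invisible(registry)
}

#' List available formats
#' @param registry reader registry.
#' @return character vector of format tokens.
#' @export
available_formats <- function(registry = default_reader_registry()) {
  sort(c(builtin_formats(), ls(registry$plugins)))
}

#' Parse a bank file in a named format
#'
#' Dispatches to the built-in parser or a registered plugin.
#' @param format format token (see [available_formats()]).
#' @param path file to parse.
#' @param ... passed through to the reader.
#' @param registry reader registry.
#' @return list of [parsed_record()]s (with a skipped-lines attribute).
#' @export
parse_bank <- function(format, path, ..., registry = default_reader_registry()) {
  switch(format,
    fasta = parse_fasta(path, ...),
    gff3 = parse_gff3(path, ...),
    genbank = parse_genbank(path, ...),
    embl = parse_embl(path, ...),
    pdb = parse_pdb(path, ...),
    {
      plug <- registry$plugins[[format]]
      if (is.null(plug)) {
        seqindex_error("unknown_format",
                       sprintf("unknown format '%s'; available: %s",
                               format, paste(available_formats(registry), collapse = ", ")))
      }
      res <- plug$reader(path, ...)
      if (!is.list(res)) seqindex_error("bad_plugin", "plugin reader must return a list")
      res
    })
}

# ---- field recoding -----------------------------------------------------

#' Define a field-recoding rule
#'
#' Recoders rewrite document fields at indexing time, e.g. splitting a
#' GenBank `db_xref` value `taxon:9606` into a database part and an id part
#' so each becomes independently searchable.
#'
#' @param field source field the rule applies to (absent field = no-op).
#' @param operation one of `"split"`, `"rename"`, `"map"`, `"drop"`.
#' @param sep separator for `split`.
#' @param outputs names of the produced fields (`split`: one per part;
#'   `map`: single output name).
#' @param new new name for `rename`.
#' @param pattern,template regex and replacement template for `map`.
#' @return a `recoder_rule`.
#' @export
recoder_rule <- function(field, operation = c("split", "rename", "map", "drop"),
                         sep = NULL, outputs = NULL, new = NULL,
                         pattern = NULL, template = NULL) {
  operation <- match.arg(operation)
  switch(operation,
    split = if (is.null(sep) || length(outputs) < 2L)
      seqindex_error("bad_recoder", "split needs 'sep' and >= 2 'outputs'"),
    rename = if (!is_string(new))
      seqindex_error("bad_recoder", "rename needs 'new'"),
    map = if (!is_string(pattern) || !is_string(template) || length(outputs) != 1L)
      seqindex_error("bad_recoder", "map needs 'pattern', 'template' and one output"))
  structure(list(field = field, operation = operation, sep = sep,
                 outputs = outputs, new = new, pattern = pattern,
                 template = template),
            class = "recoder_rule")
}

#' Apply recoding rules to a document
#'
#' Rules run in declaration order; produced fields are appended and the
#' original value is kept, except for `rename` (moved) and `drop`
#' (removed). A `split` value not containing the separator passes through
#' unsplit (with a message).
#'
#' @param document a document.
#' @param rules list of [recoder_rule()]s.
#' @return the recoded document.
#' @export
apply_recoders <- function(document, rules) {
  for (r in rules) {
    vals <- document$fields[[r$field]]
    if (is.null(vals)) next                      # absent field: no-op
    vals <- as.character(unlist(vals, use.names = FALSE))
    document$fields <- switch(r$operation,
      drop = document$fields[setdiff(names(document$fields), r$field)],
      rename = {
        f <- document$fields
        names(f)[names(f) == r$field] <- r$new
        f
      },
      split = {
        f <- document$fields
        nparts <- length(r$outputs)
        for (v in vals) {
          if (!grepl(r$sep, v, fixed = TRUE)) {
            message(sprintf("recoder split: '%s' has no '%s'; value passed through", v, r$sep))
            next
          }
          parts <- strsplit(v, r$sep, fixed = TRUE)[[1]]
          # split on the first nparts-1 separators; remainder stays joined
          if (length(parts) > nparts) {
            parts <- c(parts[seq_len(nparts - 1L)],
                       paste(parts[nparts:length(parts)], collapse = r$sep))
          }
          for (k in seq_along(parts)) {
            f[[r$outputs[k]]] <- c(f[[r$outputs[k]]], parts[k])
          }
        }
        f
      },
      map = {
        f <- document$fields
        f[[r$outputs]] <- c(f[[r$outputs]], sub(r$pattern, r$template, vals))
        f
      })
  }
  document
}

#' Load recoder rules from a YAML or JSON file
#'
#' The file holds a list of `{field, operation, ...}` entries mirroring the
#' arguments of [recoder_rule()].
#' @param path rules file.
#' @return list of `recoder_rule`s.
#' @export
load_recoders <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  lapply(raw, function(r) {
    recoder_rule(r$field, r$operation, sep = r$sep,
                 outputs = if (!is.null(r$outputs)) as.character(unlist(r$outputs)),
                 new = r$new, pattern = r$pattern, template = r$template)
  })
}
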