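# Internal helpers shared across modules: byte-accurate file scanning,
# a portable 32-bit string hash, and error constructors.

#' @importFrom utils head tail URLdecode URLencode
NULL

seqindex_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "seqindex_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

seqindex_warn <- function(class, msg) {
  warning(structure(
    class = c(class, "seqindex_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Read a whole file as text, tracking bytes
#'
#' Files are decoded as UTF-8 with a Latin-1 fallback; all offsets handled by
#' the package are byte offsets into the original file, never character
#' positions.
#'
#' @param path file to read.
#' @return single string with a `"size"` attribute (file size in bytes).
#' @keywords internal
read_file_text <- function(path) {
  size <- file.size(path)
  if (is.na(size)) seqindex_error("io_error", sprintf("cannot read '%s'", path))
  raw <- readBin(path, "raw", n = size)
  txt <- rawToChar(raw)
  Encoding(txt) <- if (isTRUE(validUTF8(txt))) "UTF-8" else "latin1"
  structure(txt, size = size)
}

# Split text into lines while recording the 0-based byte offset and byte
# length (newline excluded) of every line. `offset0` shifts all offsets, so
# a slice cut out of a larger file can report positions in that file.
scan_lines <- function(text, offset0 = 0L) {
  if (!nzchar(text)) {
    return(list(line = character(0), offset = numeric(0), nbytes = integer(0)))
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  # strsplit drops a trailing empty element only when text ends in "\n";
  # either way every listed line is a real line of the input.
  nb <- nchar(lines, type = "bytes")
  offs <- offset0 + c(0, cumsum(nb + 1L))[seq_along(lines)]
  # tolerate CRLF input: the \r byte stays inside the line's byte count
  crlf <- endsWith(lines, "\r")
  if (any(crlf)) lines[crlf] <- substr(lines[crlf], 1L, nchar(lines[crlf]) - 1L)
  list(line = lines, offset = offs, nbytes = nb)
}

# FNV-1a 32-bit over the UTF-8 bytes of a string, in double arithmetic with
# a 16-bit split so the product never exceeds 2^53.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    h <- floor(h) %% 4294967296
    h <- bitwXor2_32(h, b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- ((lo * 16777619) %% 4294967296 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

# xor of a 32-bit double-held value with a small int
bitwXor2_32 <- function(a, b) {
  lo <- a %% 2147483648
  hi <- (a - lo) / 2147483648
  lo2 <- bitwXor(as.integer(lo), as.integer(b))
  hi * 2147483648 + (as.numeric(lo2) %% 2147483648) + (if (lo2 < 0) 2147483648 else 0)
}

hash_hex <- function(x) {
  h <- fnv1a32(x)
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# filesystem-safe encoding of store keys (keys may contain ':', '/', ...)
encode_key <- function(key) {
  chartr("%", "@", URLencode(key, reserved = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Write a file atomically: temp file in the same directory, then rename.
atomic_write <- function(write_fn, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  write_fn(tmp)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    seqindex_error("io_error", sprintf("atomic write to '%s' failed", path))
  }
  invisible(path)
}
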