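# Text analysis: the tokenizer applied to text fields at indexing and
# query time, and the edit distance behind fuzzy matching.

#' Tokenize text
#'
#' Lowercases, then splits on any character that is not a letter or digit;
#' the joining characters `.`, `_` and `-` are kept when they sit inside an
#' alphanumeric run (`gene_id-1.2` stays one token, a trailing dot does
#' not). Empty tokens are dropped. Keyword fields bypass this analyzer:
#' their whole value is matched, lowercased.
#'
#' @param text character vector (elements are concatenated in order).
#' @return character vector of tokens.
#' @export
tokenize <- function(text) {
  if (!length(text)) return(character(0))
  text <- tolower(paste(as.character(text), collapse = " "))
  m <- gregexpr("[[:alnum:]]+(?:[._-][[:alnum:]]+)*", text, perl = TRUE)
  toks <- regmatches(text, m)[[1]]
  toks[nzchar(toks)]
}

#' Damerau-Levenshtein distance
#'
#' Optimal-string-alignment edit distance: insertions, deletions,
#' substitutions and transpositions of adjacent characters each count one
#' edit. Used to expand fuzzy query terms against the index vocabulary.
#'
#' @param a,b strings.
#' @param cap stop early and return `cap + 1` once the distance provably
#'   exceeds `cap` (NULL: compute exactly).
#' @return integer distance.
#' @export
dl_distance <- function(a, b, cap = NULL) {
  sa <- strsplit(a, "", fixed = TRUE)[[1]]
  sb <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(sa); nb <- length(sb)
  if (!is.null(cap) && abs(na - nb) > cap) return(cap + 1L)
  if (na == 0L) return(nb)
  if (nb == 0L) return(na)
  prev2 <- NULL
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    cur[1L] <- i
    for (j in seq_len(nb)) {
      cost <- if (sa[i] == sb[j]) 0L else 1L
      v <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost)
      if (i > 1L && j > 1L && sa[i] == sb[j - 1L] && sa[i - 1L] == sb[j]) {
        v <- min(v, prev2[j - 1L] + 1L)
      }
      cur[j + 1L] <- v
    }
    if (!is.null(cap) && min(cur) > cap) return(cap + 1L)
    prev2 <- prev
    prev <- cur
  }
  prev[nb + 1L]
}

#' Fuzzy expansion of a term against a vocabulary
#'
#' @param term query term (already lowercased).
#' @param vocabulary candidate terms.
#' @param max_edits 1 or 2.
#' @return the vocabulary terms within `max_edits` edits (distance 0, i.e.
#'   the term itself, included).
#' @export
evaluate_fuzzy <- function(term, vocabulary, max_edits) {
  if (!max_edits %in% c(1L, 2L)) {
    seqindex_error("bad_fuzzy", "max_edits must be 1 or 2")
  }
  if (!length(vocabulary)) return(character(0))
  lens <- nchar(vocabulary)
  cand <- vocabulary[abs(lens - nchar(term)) <= max_edits]
  cand[vapply(cand, function(v) dl_distance(term, v, cap = max_edits) <= max_edits,
              logical(1))]
}
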