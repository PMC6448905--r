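#' Abbreviations that block sentence splitting
#'
#' The segmenter does not split after these tokens even when the period is
#' followed by whitespace and a capital or digit. The list ships as a plain
#' text config file (one abbreviation per line, trailing period omitted,
#' matched case-insensitively) so it can be replaced per corpus.
#'
#' @param path Optional path to an alternative abbreviation file.
#' @return Character vector of abbreviation tokens.
#' @export
default_abbreviations <- function(path = NULL) {
  path <- path %||% metamine_extdata("abbreviations.txt")
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  sub("\\.$", "", x[x != ""])
}

#' Tokenise a sentence
#'
#' Tokens are maximal runs of letters, digits, hyphens and underscores;
#' every other non-space character is its own token. This keeps hyphenated
#' compounds intact, so a gene symbol embedded in a longer token (e.g.
#' "OCT1-mediated") is not a match for the bare symbol.
#'
#' @param sentence_text A string.
#' @return Character vector of tokens (empty for empty input).
#' @examples
#' tokenize("HbA1c > 7%") # "HbA1c" ">" "7" "%"
#' @export
tokenize <- function(sentence_text) {
  tokenize_spans(sentence_text)$token
}

# Tokens with 0-based half-open character offsets into the sentence.
tokenize_spans <- function(sentence_text) {
  if (is.na(sentence_text) || nchar(sentence_text) == 0L) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0)))
  }
  m <- gregexpr("[A-Za-z0-9_-]+|[^A-Za-z0-9_\\s-]", sentence_text,
                perl = TRUE)[[1]]
  if (m[1L] == -1L) {
    return(data.frame(token = character(0), start = integer(0),
                      end = integer(0)))
  }
  len <- attr(m, "match.length")
  data.frame(token = substring(sentence_text, m, m + len - 1L),
             start = as.integer(m) - 1L,
             end = as.integer(m) + len - 1L)
}

#' Segment article text into sentences
#'
#' Splits at sentence-final punctuation (`.`, `!`, `?`) followed by
#' whitespace and a capital letter or digit, except when the period ends a
#' known abbreviation. Character offsets are 0-based half-open into the
#' article text, and concatenating the spans plus the whitespace between
#' them reconstructs the text exactly.
#'
#' @param article A one-row corpus data.frame (or list) with `article_id`
#'   and `text`, or a plain string.
#' @param abbreviations Abbreviation list; see [default_abbreviations()].
#' @return A data.frame with columns `article_id`, `sentence_index` (0-based),
#'   `char_start`, `char_end`, `text`.
#' @export
segment_sentences <- function(article, abbreviations = default_abbreviations()) {
  if (is.character(article)) {
    article <- list(article_id = NA_character_, text = article)
  }
  text <- article$text
  id <- as.character(article$article_id %||% NA_character_)
  empty <- data.frame(article_id = character(0), sentence_index = integer(0),
                      char_start = integer(0), char_end = integer(0),
                      text = character(0))
  if (is.na(text) || !nzchar(text)) return(empty)

  abbr <- tolower(abbreviations)
  cand <- gregexpr("[.!?]+", text)[[1]]
  splits <- integer(0)
  if (cand[1L] != -1L) {
    lens <- attr(cand, "match.length")
    for (i in seq_along(cand)) {
      s <- as.integer(cand[i]); e <- s + lens[i] - 1L
      rest <- substring(text, e + 1L)
      if (!grepl("^[[:space:]]+[A-Z0-9]", rest)) next
      punct <- substring(text, s, e)
      if (grepl("\\.$", punct)) {
        prefix <- substring(text, 1L, s - 1L)
        word <- regmatches(prefix, regexpr("[A-Za-z0-9.]+$", prefix))
        if (length(word) == 1L && tolower(word) %in% abbr) next
      }
      splits <- c(splits, e) # sentence ends at the punctuation run
    }
  }
  bounds <- c(splits, nchar(text))
  spans <- list()
  cur <- 1L
  for (b in bounds) {
    if (b < cur) next
    chunk <- substring(text, cur, b)
    # trim whitespace off both ends but keep offsets into the original text
    lead <- attr(regexpr("^[[:space:]]*", chunk), "match.length")
    trail <- attr(regexpr("[[:space:]]*$", chunk), "match.length")
    start <- cur + lead
    end <- b - trail
    if (end >= start) {
      spans[[length(spans) + 1L]] <-
        data.frame(article_id = id,
                   sentence_index = length(spans),
                   char_start = start - 1L, char_end = end,
                   text = substring(text, start, end))
    }
    cur <- b + 1L
  }
  if (length(spans) == 0L) return(empty)
  out <- do.call(rbind, spans)
  rownames(out) <- NULL
  out
}
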