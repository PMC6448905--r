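#' Load an article corpus from TSV
#'
#' Reads a four-column corpus table (`article_id`, `year`, `source_kind`,
#' `text`) with one article per row. Tabs and newlines inside the text are
#' stored escaped as `\\t` and `\\n`; comment lines start with `#`.
#'
#' @param path Path to the corpus TSV.
#' @return A data.frame with columns `article_id` (character), `year`
#'   (integer), `source_kind` (`"full_text"` or `"abstract"`) and `text`
#'   (unescaped UTF-8), one row per article, in file order.
#' @details Validation enforces non-empty unique article ids, publication
#'   years in \[1900, 2100\], and that only abstract records may carry empty
#'   text (a full-text record with no text is a retrieval failure, not data).
#' @seealso [write_corpus()], [generate_corpus()]
#' @export
load_corpus <- function(path) {
  df <- read_tsv(path, "corpus")
  if (is.null(df)) fail("corpus: %s has no header row", path)
  check_columns(df, c("article_id", "year", "source_kind", "text"), "corpus")
  df <- df[, c("article_id", "year", "source_kind", "text")]
  if (nrow(df) == 0L) {
    df$year <- integer(0)
    return(df)
  }
  if (any(df$article_id == "")) fail("corpus: empty article_id")
  dup <- unique(df$article_id[duplicated(df$article_id)])
  if (length(dup) > 0L) {
    fail("corpus: duplicate article_id: %s", paste(dup, collapse = ", "))
  }
  year <- suppressWarnings(as.integer(df$year))
  bad <- is.na(year) | year < 1900L | year > 2100L
  if (any(bad)) {
    fail("corpus: invalid year for article(s): %s",
         paste(df$article_id[bad], collapse = ", "))
  }
  df$year <- year
  bad_kind <- !df$source_kind %in% c("full_text", "abstract")
  if (any(bad_kind)) {
    fail("corpus: invalid source_kind for article(s): %s",
         paste(df$article_id[bad_kind], collapse = ", "))
  }
  df$text <- unescape_text(df$text)
  empty_full <- df$text == "" & df$source_kind == "full_text"
  if (any(empty_full)) {
    fail("corpus: empty text for full_text article(s): %s",
         paste(df$article_id[empty_full], collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Write an article corpus to TSV
#'
#' @param articles Corpus data.frame as returned by [load_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(articles, path) {
  check_columns(articles, c("article_id", "year", "source_kind", "text"),
                "corpus")
  out <- articles[, c("article_id", "year", "source_kind", "text")]
  out$text <- escape_text(out$text)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# Canonical match key for a surface form: tokenise, rejoin on single spaces,
# then apply the case rule -- short (<= 4 chars) purely alphanumeric forms
# match case-sensitively (so "ins" does not hit the INS gene), longer forms
# case-insensitively.
lexicon_key <- function(form) {
  vapply(form, function(f) {
    joined <- paste(tokenize(f), collapse = " ")
    if (nchar(joined) <= 4L && grepl("^[A-Za-z0-9]+$", joined)) joined
    else tolower(joined)
  }, character(1), USE.NAMES = FALSE)
}

#' Load a gene or drug synonym dictionary
#'
#' Reads a two-column TSV (`canonical_id`, `surface_form`; `#` comments
#' allowed) and builds a lexicon: entries grouped by canonical id, a match
#' index keyed by normalised surface keys, and ambiguity flags.
#'
#' @param path Path to the dictionary TSV.
#' @param entity_kind `"gene"` or `"drug"`.
#' @return An object of class `metamine_lexicon`: a list with `entity_kind`,
#'   `pairs` (the id/form table with a per-form `ambiguous` flag), `entries`
#'   (per-id surface-form lists) and `match_index`.
#' @details Case handling: surface forms of length <= 4 consisting only of
#'   letters/digits match case-sensitively; longer forms case-insensitively.
#'   A surface key mapping to more than one canonical id of the same kind is
#'   ambiguous on every entry carrying it and never resolves to a single id.
#'   Cross-kind ambiguity (a form shared between a gene and a drug, e.g. a
#'   non-standard drug abbreviation colliding with a gene symbol) is flagged
#'   by [harmonize_lexicons()].
#' @seealso [normalize_mention()], [write_lexicon()]
#' @export
load_lexicon <- function(path, entity_kind) {
  if (!entity_kind %in% c("gene", "drug")) {
    fail("lexicon: unknown entity_kind '%s' (use \"gene\" or \"drug\")",
         entity_kind)
  }
  df <- read_tsv(path, "lexicon", header = FALSE,
                 col.names = c("canonical_id", "surface_form"))
  if (is.null(df)) df <- data.frame(canonical_id = character(0),
                                    surface_form = character(0))
  if (any(df$surface_form == "")) {
    fail("lexicon: empty surface form for id(s): %s",
         paste(unique(df$canonical_id[df$surface_form == ""]), collapse = ", "))
  }
  if (any(df$canonical_id == "")) fail("lexicon: empty canonical_id")
  df <- unique(df)
  build_lexicon(df, entity_kind)
}

build_lexicon <- function(pairs, entity_kind) {
  pairs$key <- lexicon_key(pairs$surface_form)
  ids_by_key <- lapply(split(pairs$canonical_id, pairs$key), unique)
  ambiguous_key <- vapply(ids_by_key, function(x) length(x) > 1L, logical(1))
  pairs$ambiguous <- unname(ambiguous_key[pairs$key])
  match_index <- lapply(names(ids_by_key), function(k) {
    ids <- ids_by_key[[k]]
    list(canonical_id = if (length(ids) == 1L) ids else NA_character_,
         entity_kind = entity_kind,
         ambiguous = unname(ambiguous_key[[k]]))
  })
  names(match_index) <- names(ids_by_key)
  entries <- lapply(split(pairs, pairs$canonical_id), function(d) {
    list(canonical_id = d$canonical_id[1L], entity_kind = entity_kind,
         surface_forms = d$surface_form, ambiguous = any(d$ambiguous))
  })
  max_tokens <- if (nrow(pairs) == 0L) 0L else
    max(vapply(pairs$surface_form, function(f) length(tokenize(f)),
               integer(1)))
  structure(list(entity_kind = entity_kind, pairs = pairs, entries = entries,
                 match_index = match_index, max_tokens = max_tokens),
            class = "metamine_lexicon")
}

#' @export
print.metamine_lexicon <- function(x, ...) {
  cat(sprintf("<metamine_lexicon> %s: %d entries, %d surface forms (%d ambiguous)\n",
              x$entity_kind, length(x$entries), nrow(x$pairs),
              sum(x$pairs$ambiguous)))
  invisible(x)
}

#' Write a lexicon back to its two-column TSV form
#'
#' Emits one `canonical_id<TAB>surface_form` row per pair, sorted, so that
#' `load_lexicon(write_lexicon(lex))` reproduces the same pair set.
#'
#' @param lexicon A `metamine_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "metamine_lexicon"))
  out <- lexicon$pairs[order(lexicon$pairs$canonical_id,
                             lexicon$pairs$surface_form),
                       c("canonical_id", "surface_form")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Flag surface forms shared between two lexicons as ambiguous
#'
#' A form listed both as a gene symbol and as a drug synonym (the classic
#' case is "MET", a non-standard metformin abbreviation that is also a gene
#' symbol) cannot be resolved by a dictionary tagger; this marks it ambiguous
#' in both lexicons so the tagger's ambiguity policy applies.
#'
#' @param a,b Two `metamine_lexicon` objects (typically gene and drug).
#' @return A list of the two updated lexicons, named by their entity kinds.
#' @export
harmonize_lexicons <- function(a, b) {
  stopifnot(inherits(a, "metamine_lexicon"), inherits(b, "metamine_lexicon"))
  shared <- intersect(names(a$match_index), names(b$match_index))
  mark <- function(lex, keys) {
    if (length(keys) == 0L) return(lex)
    for (k in keys) lex$match_index[[k]]$ambiguous <- TRUE
    lex$pairs$ambiguous <- lex$pairs$ambiguous | lex$pairs$key %in% keys
    for (i in seq_along(lex$entries)) {
      forms_keys <- lexicon_key(lex$entries[[i]]$surface_forms)
      if (any(forms_keys %in% keys)) lex$entries[[i]]$ambiguous <- TRUE
    }
    lex
  }
  out <- list(mark(a, shared), mark(b, shared))
  names(out) <- c(a$entity_kind, b$entity_kind)
  out
}

#' Normalise a surface mention to its canonical identifier
#'
#' @param surface A surface string (e.g. `"OCT1"`, `"Glucophage"`).
#' @param lexicon A `metamine_lexicon`.
#' @return `NULL` if the surface is not in the lexicon; otherwise a list with
#'   `canonical_id` (NA when the form maps to several ids of the same kind)
#'   and `ambiguous`.
#' @examples
#' lex <- load_lexicon(metamine_extdata("gene_dictionary.tsv"), "gene")
#' normalize_mention("OCT1", lex)$canonical_id # "SLC22A1"
#' normalize_mention("XYZ123", lex)            # NULL
#' @export
normalize_mention <- function(surface, lexicon) {
  stopifnot(inherits(lexicon, "metamine_lexicon"))
  hit <- lexicon$match_index[[lexicon_key(surface)]]
  if (is.null(hit)) return(NULL)
  list(canonical_id = hit$canonical_id, ambiguous = hit$ambiguous)
}

#' Path to a packaged data file
#'
#' @param file File name under the package's `extdata/` directory; with no
#'   argument, lists the available files.
#' @return A file path (or vector of file names).
#' @export
metamine_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "metamine")))
  }
  path <- system.file("extdata", file, package = "metamine")
  if (path == "") fail("no packaged file '%s'", file)
  path
}
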