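#' Tag gene and drug mentions in a sentence
#'
#' Dictionary NER over token boundaries: candidate token n-grams are matched
#' against both lexicons longest-first, left-to-right and non-overlapping.
#' Matches never start or end inside a token, so a symbol embedded in a
#' longer hyphenated token does not match. Ambiguous forms (within-kind
#' collisions, or forms shared between the gene and drug dictionaries) are
#' skipped and logged unless `include_ambiguous = TRUE`.
#'
#' @param sentence A sentence span (one row of [segment_sentences()], or a
#'   list with `article_id`, `sentence_index`, `text`).
#' @param gene_lex,drug_lex `metamine_lexicon` objects.
#' @param include_ambiguous Emit resolvable ambiguous matches instead of
#'   skipping them. Default `FALSE`.
#' @return A data.frame of mentions (`article_id`, `sentence_index`,
#'   `entity_kind`, `canonical_id`, `surface`, `token_start`, `token_end`;
#'   token offsets 0-based half-open), with a `"skipped"` attribute listing
#'   suppressed ambiguous surfaces.
#' @export
tag_mentions <- function(sentence, gene_lex, drug_lex,
                         include_ambiguous = FALSE) {
  stopifnot(inherits(gene_lex, "metamine_lexicon"),
            inherits(drug_lex, "metamine_lexicon"))
  text <- sentence$text
  toks <- tokenize_spans(text)
  n <- nrow(toks)
  shared <- intersect(names(gene_lex$match_index), names(drug_lex$match_index))
  max_n <- max(gene_lex$max_tokens, drug_lex$max_tokens, 1L)

  rows <- list()
  skipped <- list()
  i <- 1L
  while (i <= n) {
    matched_len <- 0L
    for (len in seq.int(min(max_n, n - i + 1L), 1L)) {
      j <- i + len - 1L
      key <- lexicon_key(substring(text, toks$start[i] + 1L, toks$end[j]))
      g <- gene_lex$match_index[[key]]
      d <- drug_lex$match_index[[key]]
      if (is.null(g) && is.null(d)) next
      surface <- substring(text, toks$start[i] + 1L, toks$end[j])
      cross <- key %in% shared
      if (cross && !include_ambiguous) {
        # one suppressed match, not one per dictionary
        skipped[[length(skipped) + 1L]] <-
          data.frame(surface = surface, entity_kind = "gene+drug",
                     reason = "ambiguous")
        matched_len <- len
        break
      }
      hits <- list()
      if (!is.null(g)) hits <- c(hits, list(c(kind = "gene",
                                              id = g$canonical_id,
                                              amb = g$ambiguous || cross)))
      if (!is.null(d)) hits <- c(hits, list(c(kind = "drug",
                                              id = d$canonical_id,
                                              amb = d$ambiguous || cross)))
      for (h in hits) {
        amb <- as.logical(h[["amb"]])
        if ((amb && !include_ambiguous) || is.na(h[["id"]])) {
          skipped[[length(skipped) + 1L]] <-
            data.frame(surface = surface, entity_kind = h[["kind"]],
                       reason = if (is.na(h[["id"]])) "unresolvable"
                                else "ambiguous")
        } else {
          rows[[length(rows) + 1L]] <-
            data.frame(article_id = as.character(sentence$article_id),
                       sentence_index = as.integer(sentence$sentence_index),
                       entity_kind = h[["kind"]],
                       canonical_id = h[["id"]], surface = surface,
                       token_start = i - 1L, token_end = j)
        }
      }
      matched_len <- len
      break
    }
    i <- i + max(matched_len, 1L)
  }
  out <- if (length(rows) == 0L) {
    data.frame(article_id = character(0), sentence_index = integer(0),
               entity_kind = character(0), canonical_id = character(0),
               surface = character(0), token_start = integer(0),
               token_end = integer(0))
  } else do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped) == 0L) {
    data.frame(surface = character(0), entity_kind = character(0),
               reason = character(0))
  } else do.call(rbind, skipped)
  out
}

#' Extract gene-drug dyad sentences from articles
#'
#' Segments each article, tags mentions, and emits one record per distinct
#' (gene, drug) canonical pair co-occurring in a sentence. A sentence with
#' two genes and one drug therefore yields two dyads; identical
#' (article, sentence, gene, drug) tuples collapse to one record.
#'
#' @param articles Corpus data.frame (one or more rows; see [load_corpus()]).
#' @param gene_lex,drug_lex `metamine_lexicon` objects.
#' @param abbreviations Sentence-splitting abbreviation list.
#' @param include_ambiguous Passed to [tag_mentions()].
#' @return A data.frame with columns `article_id`, `sentence_index`,
#'   `gene_id`, `drug_id`, `gene_surface`, `drug_surface`, `sentence_text`,
#'   ordered by article (input order), sentence index, gene id, drug id.
#' @export
extract_dyads <- function(articles, gene_lex, drug_lex,
                          abbreviations = default_abbreviations(),
                          include_ambiguous = FALSE) {
  empty <- data.frame(article_id = character(0), sentence_index = integer(0),
                      gene_id = character(0), drug_id = character(0),
                      gene_surface = character(0), drug_surface = character(0),
                      sentence_text = character(0))
  if (nrow(articles) == 0L) return(empty)
  out <- list()
  for (r in seq_len(nrow(articles))) {
    art <- articles[r, ]
    sents <- segment_sentences(art, abbreviations)
    for (s in seq_len(nrow(sents))) {
      men <- tag_mentions(sents[s, ], gene_lex, drug_lex, include_ambiguous)
      genes <- men[men$entity_kind == "gene", ]
      drugs <- men[men$entity_kind == "drug", ]
      if (nrow(genes) == 0L || nrow(drugs) == 0L) next
      gid <- sort(unique(genes$canonical_id))
      did <- sort(unique(drugs$canonical_id))
      for (g in gid) for (d in did) {
        out[[length(out) + 1L]] <- data.frame(
          article_id = art$article_id,
          sentence_index = sents$sentence_index[s],
          gene_id = g, drug_id = d,
          gene_surface = genes$surface[match(g, genes$canonical_id)],
          drug_surface = drugs$surface[match(d, drugs$canonical_id)],
          sentence_text = sents$text[s])
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- unique(res)
  ord <- order(match(res$article_id, articles$article_id),
               res$sentence_index, res$gene_id, res$drug_id)
  res <- res[ord, ]
  rownames(res) <- NULL
  res
}

#' Write dyads (optionally annotated) to TSV
#'
#' @param dyads Dyad data.frame from [extract_dyads()] (annotation columns,
#'   if present, are written too).
#' @param path Output path.
#' @param meta Optional named list written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_dyads <- function(dyads, path, meta = NULL) {
  out <- dyads
  out$sentence_text <- escape_text(out$sentence_text)
  write_output_tsv(out, path, meta)
}

#' Read a dyad TSV written by [write_dyads()]
#'
#' @param path Path to the TSV.
#' @return The dyad data.frame, with `sentence_text` unescaped.
#' @export
read_dyads <- function(path) {
  df <- read_tsv(path, "dyads")
  if (is.null(df)) fail("dyads: %s has no header row", path)
  check_columns(df, c("article_id", "sentence_index", "gene_id", "drug_id",
                      "sentence_text"), "dyads")
  df$sentence_index <- as.integer(df$sentence_index)
  df$sentence_text <- unescape_text(df$sentence_text)
  df
}
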