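#' Load an interaction cue lexicon
#'
#' Cue words drive the rule-based interaction annotation: interaction cues
#' assert a relation, negation cues flip it to an explicit absence of
#' interaction, and hedge cues mark the statement as inferred rather than
#' explicit. A TSV with columns `cue`, `class`
#' (`interaction`/`negation`/`hedge`) and `direction`
#' (`increased`/`decreased`/`none`) ships with the package.
#'
#' @param path Path to a cue TSV; defaults to the packaged lexicon.
#' @return A `metamine_cues` object: lists of `interaction`, `negation` and
#'   `hedge` cues (all lower case) and a named `direction` map.
#' @export
load_cues <- function(path = NULL) {
  path <- path %||% metamine_extdata("cue_lexicon.tsv")
  df <- read_tsv(path, "cues")
  if (is.null(df)) fail("cues: %s has no header row", path)
  check_columns(df, c("cue", "class", "direction"), "cues")
  df$cue <- tolower(df$cue)
  bad <- !df$class %in% c("interaction", "negation", "hedge")
  if (any(bad)) fail("cues: unknown class: %s",
                     paste(unique(df$class[bad]), collapse = ", "))
  sets <- split(df$cue, df$class)
  inter <- unique(sets$interaction %||% character(0))
  neg <- unique(sets$negation %||% character(0))
  hedge <- unique(sets$hedge %||% character(0))
  overlap <- c(intersect(inter, neg), intersect(inter, hedge),
               intersect(neg, hedge))
  if (length(overlap) > 0L) {
    fail("cues: cue classes must be disjoint; offending cue(s): %s",
         paste(unique(overlap), collapse = ", "))
  }
  dmap <- df$direction[df$class == "interaction"]
  names(dmap) <- df$cue[df$class == "interaction"]
  dmap <- dmap[dmap %in% c("increased", "decreased")]
  structure(list(interaction = inter, negation = neg, hedge = hedge,
                 direction = dmap),
            class = "metamine_cues")
}

#' @rdname load_cues
#' @export
default_cues <- function() load_cues()

# Locate a surface string as a token subsequence; returns c(start, end)
# 1-based token indices, or NULL.
locate_surface <- function(tokens, surface) {
  sub <- tokenize(surface)
  k <- length(sub)
  if (k == 0L || length(tokens) < k) return(NULL)
  for (i in seq_len(length(tokens) - k + 1L)) {
    if (all(tokens[i:(i + k - 1L)] == sub)) return(c(i, i + k - 1L))
  }
  NULL
}

#' Annotate one dyad sentence with an interaction label
#'
#' Rule order: (1) no interaction cue in the sentence marks the pair
#' unrelated; (2) a negation cue within the three tokens before the
#' interaction cue yields an explicit absence of interaction (modifier
#' `negation`); (3) a hedge cue anywhere yields an indirect, inferred
#' interaction; (4) otherwise the interaction is explicit, direct when the
#' cue lies on the token path between the two entities, and carries the
#' cue's direction (`increased`/`decreased`) as modifier.
#'
#' @param dyad A one-row dyad data.frame (or list) with `sentence_text`,
#'   `gene_surface`, `drug_surface`.
#' @param cues A `metamine_cues` object.
#' @return A list with `relation`, `directness`, `explicitness`, `modifier`,
#'   `provenance = "rule"`.
#' @export
annotate_dyad <- function(dyad, cues = default_cues()) {
  stopifnot(inherits(cues, "metamine_cues"))
  tokens <- tokenize(dyad$sentence_text)
  low <- tolower(tokens)
  cue_idx <- which(low %in% cues$interaction)

  if (length(cue_idx) == 0L) {
    return(list(relation = "unrelated", directness = "indirect",
                explicitness = "inferred", modifier = "none",
                provenance = "rule"))
  }

  gs <- locate_surface(tokens, dyad$gene_surface %||% "")
  ds <- locate_surface(tokens, dyad$drug_surface %||% "")
  between <- function(idx) {
    if (is.null(gs) || is.null(ds)) return(TRUE) # entity span unknown
    left_end <- min(gs[2L], ds[2L])
    right_start <- max(gs[1L], ds[1L])
    idx > left_end && idx < right_start
  }
  on_path <- vapply(cue_idx, between, logical(1))
  cue <- if (any(on_path)) cue_idx[which(on_path)[1L]] else cue_idx[1L]

  scope <- seq.int(max(1L, cue - 3L), max(1L, cue - 1L))
  scope <- scope[scope < cue]
  if (length(scope) > 0L && any(low[scope] %in% cues$negation)) {
    return(list(relation = "no_interaction", directness = "direct",
                explicitness = "explicit", modifier = "negation",
                provenance = "rule"))
  }

  modifier <- unname(cues$direction[low[cue]])
  if (is.na(modifier) || length(modifier) == 0L) modifier <- "none"

  if (any(low %in% cues$hedge)) {
    return(list(relation = "interaction", directness = "indirect",
                explicitness = "inferred", modifier = modifier,
                provenance = "rule"))
  }

  list(relation = "interaction",
       directness = if (any(on_path)) "direct" else "indirect",
       explicitness = "explicit", modifier = modifier, provenance = "rule")
}

#' Annotate a table of dyads
#'
#' @param dyads Dyad data.frame from [extract_dyads()].
#' @param cues A `metamine_cues` object.
#' @return `dyads` with columns `relation`, `directness`, `explicitness`,
#'   `modifier`, `provenance` appended.
#' @export
annotate_dyads <- function(dyads, cues = default_cues()) {
  labs <- lapply(seq_len(nrow(dyads)),
                 function(i) annotate_dyad(dyads[i, ], cues))
  dyads$relation <- vapply(labs, `[[`, "", "relation")
  dyads$directness <- vapply(labs, `[[`, "", "directness")
  dyads$explicitness <- vapply(labs, `[[`, "", "explicitness")
  dyads$modifier <- vapply(labs, `[[`, "", "modifier")
  dyads$provenance <- vapply(labs, `[[`, "", "provenance")
  if (nrow(dyads) == 0L) {
    for (col in c("relation", "directness", "explicitness", "modifier",
                  "provenance")) dyads[[col]] <- character(0)
  }
  dyads
}

#' Apply manual annotation overrides
#'
#' Models the manual curation pass over rule annotations: overrides are
#' keyed on (article_id, sentence_index, gene_id, drug_id) and replace the
#' rule label with `provenance = "manual"`. Every override must refer to an
#' existing dyad.
#'
#' @param annotated Annotated dyads from [annotate_dyads()].
#' @param overrides A data.frame (or TSV path) with the dyad key columns and
#'   any of `relation`, `directness`, `explicitness`, `modifier`.
#' @return The annotated dyads with overrides applied.
#' @export
apply_overrides <- function(annotated, overrides) {
  if (is.character(overrides)) {
    overrides <- read_tsv(overrides, "overrides")
    if (is.null(overrides)) return(annotated)
    overrides$sentence_index <- as.integer(overrides$sentence_index)
  }
  if (nrow(overrides) == 0L) return(annotated)
  check_columns(overrides,
                c("article_id", "sentence_index", "gene_id", "drug_id"),
                "overrides")
  key <- function(d) paste(d$article_id, d$sentence_index, d$gene_id,
                           d$drug_id, sep = "\r")
  idx <- match(key(overrides), key(annotated))
  if (anyNA(idx)) {
    miss <- overrides[is.na(idx), ]
    fail("overrides: no matching dyad for key(s): %s",
         paste(sprintf("(%s, %d, %s, %s)", miss$article_id,
                       miss$sentence_index, miss$gene_id, miss$drug_id),
               collapse = "; "))
  }
  for (col in c("relation", "directness", "explicitness", "modifier")) {
    if (col %in% names(overrides)) {
      keep <- !is.na(overrides[[col]]) & overrides[[col]] != ""
      annotated[[col]][idx[keep]] <- overrides[[col]][keep]
    }
  }
  annotated$provenance[idx] <- "manual"
  annotated
}

#' Keep only direct, explicit annotations
#'
#' The downstream evidence scoring uses only statements made outright
#' between the two entities in one sentence: relation `interaction` or
#' `no_interaction` (explicit negations feed the weakest evidence code),
#' directness `direct`, explicitness `explicit`. Order is preserved and the
#' operation is idempotent.
#'
#' @param annotated Annotated dyads from [annotate_dyads()].
#' @return The retained subset.
#' @export
filter_direct_explicit <- function(annotated) {
  needed <- c("relation", "directness", "explicitness")
  if (!all(needed %in% names(annotated))) {
    fail("filter_direct_explicit: input is not annotated (missing %s)",
         paste(setdiff(needed, names(annotated)), collapse = ", "))
  }
  keep <- annotated$relation %in% c("interaction", "no_interaction") &
    annotated$directness == "direct" & annotated$explicitness == "explicit"
  out <- annotated[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
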