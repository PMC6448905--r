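# Small in-code fixtures shared across tests.

fixture_gene_lexicon <- function() {
  load_lexicon(metamine_extdata("gene_dictionary.tsv"), "gene")
}

fixture_drug_lexicon <- function() {
  load_lexicon(metamine_extdata("drug_dictionary.tsv"), "drug")
}

fixture_lexicons <- function() {
  harmonize_lexicons(fixture_gene_lexicon(), fixture_drug_lexicon())
}

write_lexicon_tsv <- function(pairs) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(paste(pairs$canonical_id, pairs$surface_form, sep = "\t"), path)
  path
}

write_corpus_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  write_corpus(df, path)
  path
}

make_article <- function(text, id = "a1", year = 2010L,
                         kind = "full_text") {
  data.frame(article_id = id, year = year, source_kind = kind, text = text)
}

# Evidence records builder: one row per (category, finding, direction) triple.
make_records <- function(gene, specs) {
  do.call(rbind, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    data.frame(gene_id = gene, article_id = sprintf("pm%03d", i),
               study_category = s[[1]], finding = s[[2]],
               direction = if (length(s) > 2L) s[[3]] else "")
  }))
}

dyad_key <- function(d) {
  paste(d$article_id, d$sentence_index, d$gene_id, d$drug_id, sep = "|")
}
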