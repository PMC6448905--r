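EVIDENCE_CATEGORIES <- c("clinical_outcome", "pk_pd", "molecular_cellular")

#' Read curated evidence records
#'
#' One row per (gene, study) finding: `gene_id`, `article_id`,
#' `study_category` (`clinical_outcome`, `pk_pd`, `molecular_cellular`),
#' `finding` (`effect`/`no_effect`) and optional `direction`
#' (`increased`/`decreased`, empty when `finding = no_effect`).
#'
#' @param path Path to the curated-evidence TSV.
#' @return A validated data.frame of evidence records.
#' @export
read_evidence <- function(path) {
  df <- read_tsv(path, "evidence")
  if (is.null(df)) fail("evidence: %s has no header row", path)
  check_columns(df, c("gene_id", "article_id", "study_category", "finding"),
                "evidence")
  if (!"direction" %in% names(df)) df$direction <- ""
  df$direction[is.na(df$direction)] <- ""
  bad <- which(!df$study_category %in% EVIDENCE_CATEGORIES)
  if (length(bad) > 0L) {
    fail("evidence: invalid study_category at data line %s",
         paste(bad, collapse = ", "))
  }
  bad <- which(!df$finding %in% c("effect", "no_effect"))
  if (length(bad) > 0L) {
    fail("evidence: invalid finding at data line %s",
         paste(bad, collapse = ", "))
  }
  bad <- which(df$finding == "no_effect" & df$direction != "")
  if (length(bad) > 0L) {
    fail("evidence: direction given for no_effect record at data line %s",
         paste(bad, collapse = ", "))
  }
  bad <- which(!df$direction %in% c("", "increased", "decreased"))
  if (length(bad) > 0L) {
    fail("evidence: invalid direction at data line %s",
         paste(bad, collapse = ", "))
  }
  df
}

#' Assess the consistency of evidence within one study category
#'
#' @param records Evidence records sharing one `gene_id` and one
#'   `study_category` (possibly zero rows).
#' @param min_studies Minimum number of concordant effect records required
#'   to call the category consistent (default 1).
#' @return One of `"absent"` (no records), `"refuted"` (all records report
#'   no effect), `"inconsistent"` (effect and no-effect mixed, effect
#'   directions disagree, or fewer than `min_studies` supporting records),
#'   `"consistent"`.
#' @export
assess_consistency <- function(records, min_studies = 1L) {
  if (is.null(records) || nrow(records) == 0L) return("absent")
  if (length(unique(records$gene_id)) > 1L ||
      length(unique(records$study_category)) > 1L) {
    fail("assess_consistency: records span several genes or categories")
  }
  eff <- records$finding == "effect"
  if (!any(eff)) return("refuted")
  if (any(!eff)) return("inconsistent")
  dirs <- records$direction[eff]
  dirs <- dirs[!is.na(dirs) & dirs != ""]
  if (length(unique(dirs)) > 1L) return("inconsistent")
  if (sum(eff) < min_studies) return("inconsistent")
  "consistent"
}

#' Assign a gene its evidence code
#'
#' Study categories are ranked clinical outcome > PK/PD >
#' molecular/cellular. The first consistent category gives code 1, 2 or 3
#' (a consistent category always outranks an inconsistent one); failing
#' that, the first inconsistent category gives code 4, 5 or 6; a gene whose
#' every represented category is refuted gets code 7. Codes map to
#' assessments: 1-2 clinically relevant, 3 potential clinical relevance,
#' 4-6 clinical relevance unknown, 7 clinical relevance unsupported.
#'
#' @param gene_id Gene identifier.
#' @param records All evidence records for the gene (non-empty).
#' @param min_studies Passed to [assess_consistency()].
#' @return A list with `gene_id`, `code` (1-7), `assessment`, and
#'   `category_states` (named status vector over the three categories).
#' @export
assign_evidence_code <- function(gene_id, records, min_studies = 1L) {
  if (is.null(records) || nrow(records) == 0L) {
    fail("assign_evidence_code: no evidence for gene '%s'", gene_id)
  }
  if (any(records$gene_id != gene_id)) {
    fail("assign_evidence_code: records for other genes passed with '%s'",
         gene_id)
  }
  bad <- setdiff(unique(records$study_category), EVIDENCE_CATEGORIES)
  if (length(bad) > 0L) {
    fail("assign_evidence_code: unknown study_category '%s' for gene '%s'",
         paste(bad, collapse = "', '"), gene_id)
  }
  states <- vapply(EVIDENCE_CATEGORIES, function(cat) {
    assess_consistency(records[records$study_category == cat, , drop = FALSE],
                       min_studies)
  }, character(1))
  code <- if (any(states == "consistent")) {
    which(states == "consistent")[1L]
  } else if (any(states == "inconsistent")) {
    3L + which(states == "inconsistent")[1L]
  } else {
    7L # every represented category refuted
  }
  assessment <- c("clinically_relevant", "clinically_relevant",
                  "potential_clinical_relevance", "clinical_relevance_unknown",
                  "clinical_relevance_unknown", "clinical_relevance_unknown",
                  "clinical_relevance_unsupported")[code]
  list(gene_id = gene_id, code = as.integer(code), assessment = assessment,
       category_states = states)
}

#' Assign evidence codes to every gene in a record table
#'
#' @param records Evidence records (see [read_evidence()]).
#' @param min_studies Passed to [assess_consistency()].
#' @return A data.frame with one row per gene: `gene_id`, `code`,
#'   `assessment`, and the per-category states `clinical_outcome`, `pk_pd`,
#'   `molecular_cellular`; ordered by gene id.
#' @export
assign_evidence_codes <- function(records, min_studies = 1L) {
  genes <- sort(unique(records$gene_id))
  rows <- lapply(genes, function(g) {
    ec <- assign_evidence_code(g, records[records$gene_id == g, , drop = FALSE],
                               min_studies)
    data.frame(gene_id = g, code = ec$code, assessment = ec$assessment,
               clinical_outcome = ec$category_states[["clinical_outcome"]],
               pk_pd = ec$category_states[["pk_pd"]],
               molecular_cellular = ec$category_states[["molecular_cellular"]])
  })
  out <- if (length(rows) == 0L) {
    data.frame(gene_id = character(0), code = integer(0),
               assessment = character(0), clinical_outcome = character(0),
               pk_pd = character(0), molecular_cellular = character(0))
  } else do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the evidence-stratified gene-set catalogue
#'
#' Five sets: A, genes with consistent clinical-outcome evidence (code 1);
#' B, genes with consistent PK/PD evidence not in A (code 2); C, genes with
#' consistent molecular/cellular (expression) evidence not in A; D = A + B;
#' E = A + B + C. B and C may overlap: a gene with both consistent PK/PD
#' and consistent expression evidence carries code 2 but belongs to both
#' tiers. Genes coded 4-7 belong to no set.
#'
#' @param codes Per-gene code table from [assign_evidence_codes()]. If the
#'   per-category state columns are absent, set C falls back to genes with
#'   code 3 exactly.
#' @return A `metamine_gene_sets` object: a named list of sorted gene-id
#'   vectors `A`-`E`.
#' @export
build_gene_sets <- function(codes) {
  check_columns(codes, c("gene_id", "code"), "gene sets")
  dup <- unique(codes$gene_id[duplicated(codes$gene_id)])
  if (length(dup) > 0L) {
    fail("build_gene_sets: duplicate gene(s): %s", paste(dup, collapse = ", "))
  }
  A <- codes$gene_id[codes$code == 1L]
  B <- codes$gene_id[codes$code == 2L]
  C <- if ("molecular_cellular" %in% names(codes)) {
    codes$gene_id[codes$molecular_cellular == "consistent" & codes$code != 1L]
  } else {
    codes$gene_id[codes$code == 3L]
  }
  sets <- list(A = sort(A), B = sort(B), C = sort(C),
               D = sort(union(A, B)), E = sort(union(union(A, B), C)))
  structure(sets, class = "metamine_gene_sets")
}

#' @export
print.metamine_gene_sets <- function(x, ...) {
  cat("<metamine_gene_sets>\n")
  desc <- c(A = "clinical outcome", B = "PK/PD",
            C = "expression/molecular", D = "A + B", E = "A + B + C")
  for (nm in names(x)) {
    cat(sprintf("  %s (%s, %d genes): %s\n", nm, desc[[nm]], length(x[[nm]]),
                paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' Write a gene-set catalogue to TSV
#'
#' Two columns (`set_name`, `gene_id`), sorted lexicographically, so the
#' file round-trips losslessly through [read_gene_sets()].
#'
#' @param catalogue A `metamine_gene_sets` object (or named list of gene-id
#'   vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(catalogue, path) {
  lens <- vapply(catalogue, length, integer(1))
  df <- data.frame(
    set_name = as.character(rep(names(catalogue), lens)),
    gene_id = as.character(unlist(catalogue, use.names = FALSE) %||%
                             character(0)))
  df <- df[order(df$set_name, df$gene_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene-set catalogue from TSV
#'
#' @param path Path to a `set_name`/`gene_id` TSV.
#' @return A `metamine_gene_sets` object (sets in file order of first
#'   appearance, members sorted and deduplicated).
#' @export
read_gene_sets <- function(path) {
  df <- read_tsv(path, "gene sets")
  if (is.null(df)) fail("gene sets: %s has no header row", path)
  check_columns(df, c("set_name", "gene_id"), "gene sets")
  sets <- lapply(split(df$gene_id, factor(df$set_name,
                                          levels = unique(df$set_name))),
                 function(g) sort(unique(g)))
  structure(sets, class = "metamine_gene_sets")
}

# Keyword rules mapping a dyad sentence to a study category. The curated
# evidence TSV is the source of truth for real analyses -- categorisation in
# the original workflow was manual -- and this mapper is the automated
# convenience used on rule-templated (e.g. simulated) corpora.
CATEGORY_KEYWORDS <- list(
  clinical_outcome = c("hba1c", "glycaemic", "glycemic", "outcome",
                       "outcomes", "remission", "efficacy", "treatment"),
  pk_pd = c("clearance", "auc", "concentration", "concentrations",
            "transport", "transported", "uptake", "absorption", "excretion",
            "pharmacokinetic", "pharmacokinetics", "production"),
  molecular_cellular = c("expression", "mrna", "translocation", "protein",
                         "activity", "activation", "signalling", "signaling",
                         "phosphorylation", "levels"))

#' Derive evidence records from annotated dyads
#'
#' Keeps direct-explicit dyads, maps each to a study category by keyword
#' rules over the sentence (clinical terms take precedence over PK/PD, then
#' molecular/cellular; sentences matching nothing default to
#' molecular/cellular), and converts the annotation to a finding: modifier
#' `negation` becomes `no_effect`, anything else `effect` with the
#' modifier's direction.
#'
#' @param annotated Annotated dyads (see [annotate_dyads()]).
#' @param keywords Category keyword lists; defaults to the packaged rules.
#' @return An evidence-record data.frame (see [read_evidence()]).
#' @export
evidence_from_annotations <- function(annotated,
                                      keywords = CATEGORY_KEYWORDS) {
  kept <- filter_direct_explicit(annotated)
  if (nrow(kept) == 0L) {
    return(data.frame(gene_id = character(0), article_id = character(0),
                      study_category = character(0), finding = character(0),
                      direction = character(0)))
  }
  cat_of <- vapply(kept$sentence_text, function(s) {
    toks <- tolower(tokenize(s))
    for (cat in names(keywords)) {
      if (any(toks %in% keywords[[cat]])) return(cat)
    }
    "molecular_cellular"
  }, character(1), USE.NAMES = FALSE)
  finding <- ifelse(kept$modifier == "negation", "no_effect", "effect")
  direction <- ifelse(kept$modifier %in% c("increased", "decreased"),
                      kept$modifier, "")
  data.frame(gene_id = kept$gene_id, article_id = kept$article_id,
             study_category = cat_of, finding = finding,
             direction = direction)
}
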