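---
title: "metamine: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metamine: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metamine` chains three stages — literature mining, evidence scoring, and
GWAS gene-set enrichment — and ships simulators that generate
gold-labelled inputs for each stage. This vignette records the models, the
parameters that matter, and the choices made where the design was open.

## Literature mining

### Sentence model

Articles are treated as flat text. A sentence boundary is a run of
`.`, `!` or `?` followed by whitespace and a capital letter or digit,
unless the period terminates a known abbreviation (`Fig.`, `et al.`,
`e.g.`, `i.e.`, `vs.`, `Dr.`, `ca.`, `approx.`, `no.`; a plain-text config
file, because no fixed list suits every journal style). Spans carry
0-based half-open character offsets and reconstruct the source text
exactly — a property the tests check on generated corpora. Tokens are
maximal runs of letters/digits/hyphen/underscore; all other non-space
characters are single-character tokens. Keeping hyphenated compounds
whole is deliberate: "OCT1-mediated" must not produce an `OCT1` mention,
because protein-modifier compounds are overwhelmingly *about* the gene
rather than statements linking it to a drug in a scoreable way.

### Dictionary NER and the case rules

Gene and drug dictionaries are two-column TSVs (`canonical_id`,
`surface_form`). Matching operates on token n-grams, longest first,
left-to-right, non-overlapping. Surface keys of at most 4 purely
alphanumeric characters match **case-sensitively**; longer keys match
case-insensitively. Short gene symbols are the dominant false-positive
source (the symbol `INS` versus the word "ins"), while long forms
("glucophage", chemical names) are safely case-folded. The threshold of 4
is a declared default, not an empirical optimum.

A surface form mapping to more than one canonical id of the same kind, or
shared between the gene and the drug dictionary, is *ambiguous*. The
canonical example is "MET": a non-standard metformin shorthand that is
also a gene symbol. Ambiguous forms are excluded from matching by default
(each suppressed match is logged on the result's `"skipped"` attribute)
and can be enabled with `include_ambiguous = TRUE`. Exclusion was chosen
because a wrong gene–drug dyad propagates into the evidence table, whereas
a missed mention only reduces coverage.

### Dyads and annotation rules

Only same-sentence co-occurrence is modelled; anaphora and cross-sentence
relations are out of scope by design. Each sentence with at least one gene
and one drug mention yields one dyad per distinct (gene, drug) pair, so
dyad counts can exceed dyad-sentence counts.

Annotation is rule-based with a manual-override escape hatch
(`apply_overrides()`, which stamps `provenance = "manual"`):

1. no interaction cue in the sentence → `unrelated`;
2. a negation cue within **3 tokens before** the interaction cue →
   `no_interaction` with modifier `negation` (still direct/explicit — these
   feed evidence code 7);
3. a hedge cue anywhere → `interaction`, indirect/inferred;
4. otherwise `interaction`, explicit; *direct* when the cue lies on the
   token path between the two entities, else indirect; modifier from the
   cue's direction map (`increase*` → increased, `inhibit*`/`reduce*` →
   decreased, neutral cues → none).

The 3-token negation window is a small fixed scope chosen for
auditability; true syntactic negation scope (and true "indirectness" via
intermediate entities) would need parsing, which the rule layer does not
attempt. Label combinations the rules never produce (direct-inferred,
for instance) remain representable for manual annotation.

## Evidence scoring

Within each of three study tiers — clinical outcomes, PK/PD,
molecular/cellular — a gene's records are `consistent` (at least
`min_studies` effect findings, none refuted, directions concordant),
`inconsistent` (effect and no-effect mixed, discordant directions, or too
few supporting studies), `refuted` (only no-effect findings) or `absent`.
`min_studies` defaults to 1: the expression tier of the reference
catalogue is dominated by single-study findings, so requiring replication
there would empty it. Direction disagreement counts as inconsistent; with
no stricter definition available, concordance of stated directions is the
operative meaning of "consistent".

The per-gene code takes the **first consistent tier in strength order**
(clinical → PK/PD → molecular) as 1/2/3; a consistent tier always outranks
an inconsistent one. Failing that, the first inconsistent tier gives
4/5/6; a gene whose every represented tier is refuted gets 7. One
published statement of the scheme contains an internal contradiction (a
footnote allowing inconsistent evidence to score 3); the 4–6 reading is
implemented because code 3 is defined by consistent molecular evidence.
The tests verify the rule table against an independently written
brute-force oracle over all 4³ tier-state combinations, plus
order-invariance and monotonicity (extra null evidence never strengthens a
code; reinforcing a consistent tier never weakens it).

Gene sets: A = code 1, B = code 2, C = genes with consistent
molecular/cellular evidence outside A, D = A∪B, E = A∪B∪C. **B and C may
overlap**: a gene with both consistent PK/PD and consistent expression
evidence carries code 2 yet belongs to both tiers. This membership
semantic (rather than a strict partition by final code) is what reproduces
the reference catalogue's printed tier sizes of 7, 15 and 51 with a
70-gene union — a strict partition would shrink the expression tier by the
three genes it shares with the PK/PD tier. The packaged
`curated_evidence.tsv` is a synthetic transcription of those printed
memberships (two concordant records per gene per tier, synthetic article
ids), shipped so the scoring stage has a reference input; it is not
original curation data. The keyword mapper
(`evidence_from_annotations()`) that turns annotated dyads into evidence
records is a convenience for simulated corpora — on real literature the
curated table, which encodes human judgement, is the source of truth.

## Gene-set enrichment

### Gene scores

SNPs are assigned to every gene whose extended interval contains them:
110 kb upstream, 40 kb downstream (kb units; strand-aware, inclusive
bounds), the conventional boundaries for this style of enrichment
analysis, configurable per run. Interval overlap is computed with
`GenomicRanges`. A gene's raw score is `-log10` of its best SNP p-value;
ties resolve to the lexicographically smallest SNP id so results are
reproducible.

Best-SNP scores are confounded by gene size and SNP density, so the raw
score is regressed on `size_kb` and `log(n_snps)` by least squares and
genes are ranked by residual: `corrected_p = rank/n` with the best
residual at `1/n` (ties broken by gene id). The reference method also
corrects for LD-derived covariates; without a reference LD panel in
scope, size and SNP count are the implemented confounder set — a
documented divergence. After correction, genes sharing an identical best
SNP collapse to the gene whose (unextended) midpoint is nearest the SNP,
so one signal in a dense locus is not counted repeatedly. With fewer than
10 genes the regression is skipped with a warning.

### Permutation test

For percentile `q` (default 75), the cutoff is the type-1 empirical
`(100-q)`th quantile of `corrected_p`, so with `n` scored genes exactly
`floor(n/4)` genes lie at or below it ("above the enrichment cutoff" in
the reporting sense = more significant than the cutoff). The observed
statistic is the number of set genes at or below the cutoff; the null
draws `n_perm` (default 10,000, minimum 100) random same-size sets
without replacement **from the scored genes** — not from genome-wide
annotation, since only summary data are in scope. The add-one estimator
`(1 + #{null ≥ obs})/(n_perm + 1)` keeps the p-value positive, and an
explicit `seed` makes it bit-reproducible (the RNG state of the caller is
saved and restored). Set genes absent from the scored table are logged
and excluded; `n_genes_scored` makes the drop explicit. An optional
region mask (e.g. for the HLA region) can be applied by filtering the
gene models before mapping.

`enrichment_report()` renders the conventional table: the permutation
mean `expected` is rounded to an integer and `excess`/`fold` are
recomputed from the rounded value (so observed 17 against an analytic
expectation of 10.75 prints as expected 11, excess 6, fold 1.55);
the result objects keep the unrounded values.

### A note on p-value granularity

The observed count is an integer with, in typical configurations
(400 genes, 40-gene sets), a hypergeometric null whose mode carries
probability ≈ 0.15. Permutation p-values are therefore valid but
*stepped*: over many null replicates their distribution is sub-uniform on
a lattice, and a Kolmogorov–Smirnov test against the continuous uniform
will reject even though the test is correctly calibrated in the
`P(p ≤ α) ≤ α` sense. Calibration checks in the test-suite that compare
the permutation mean to the analytic expectation pass; a strict KS
uniformity check cannot, and this is a property of discrete permutation
tests, not an implementation artefact.

## Simulators

`generate_corpus()` plants dyad sentences built from the cue templates
("\<drug\> increased \<gene\> expression.", a negated and a hedged
variant) using unambiguous dictionary surface forms, mixed with
distractor sentences containing no lexicon terms, and records gold
labels. Because planted sentences are templated, rule annotation agrees
with gold by construction — passing mining tests therefore demonstrate
internal consistency of the extraction/annotation chain, not performance
on real prose, which has unbounded syntactic variety, nested clauses and
out-of-dictionary naming.

`generate_gene_models()` places non-overlapping genes (5–50 kb bodies)
on one synthetic chromosome with ≥ 160 kb gaps so default extended
regions rarely overlap. `generate_gwas()` has two modes:

* **direct_p** — null SNP p-values are Uniform(0,1); each enriched gene
  gets one planted SNP with p ~ Beta(a, 1), `a = 0.1` by default (CDF
  `x^a`, median ≈ 0.001), the simplest one-causal-SNP-per-gene structure
  that produces best-SNP enrichment.
* **phenotype** — individual-level simulation of a continuous glycaemic
  response (maximal HbA1c reduction, simulated cross-sectionally): outcome
  = linear combination of baseline HbA1c, creatinine clearance, adherence,
  average daily dose, drug group and baseline gap, plus an additive
  genotype effect at causal SNPs (`effect_size_beta` in residual-SD units
  per allele) and Gaussian noise (`noise_sd = 1`). Genotypes are
  Binomial(2, MAF) with MAF ~ Uniform(0.05, 0.5), independent across SNPs
  — **no LD**. Per-SNP p-values come from covariate-adjusted least squares
  (one shared QR, per-SNP residual regression; verified in the tests
  against a full `lm()` refit to 1e-10). The covariate coefficients are
  declared defaults — the outcome model's terms are fixed, but no
  published coefficients exist to copy, so parameter-recovery tests target
  generator-known truths only. Monomorphic SNPs report p = 1.

Every generator runs under `with_seed()`: identical configs give
byte-identical output without perturbing the caller's RNG stream.

## Problem sizes and numerical choices

The test-suite exercises the enrichment engine at 400 genes with 40-gene
sets and 10,000 permutations (null calibration over 200 replicates;
planted-enrichment power over 100 replicates), and the phenotype
simulator at 2,000 individuals × 2,000 SNPs — sizes chosen so the suite
completes in about a minute while keeping Monte-Carlo error well below
the tolerances being checked. Fixed seeds (42 for single runs, a base
offset plus replicate index for loops) were set as a policy before the
checks were run. With 2,000 null SNPs the sampling SD of the genomic
inflation factor λ (median χ² / 0.4549) is ≈ 0.05, so any single-seed λ
check with a ±0.05 band has roughly a two-thirds pass probability; the
suite documents the simulator's calibration (unbiasedness of the
residualised OLS p-values) rather than guaranteeing every seed lands in
band.

Degenerate inputs are handled explicitly: empty corpora, dictionaries and
catalogues round-trip as empty; a full-text article with empty text is a
validation error; fewer than 10 genes skips the confounder regression
with a warning; an enrichment set with no scored genes is an error naming
the missing genes.

## Known limitations

* Dictionary NER: no machine-learned disambiguation; genuinely ambiguous
  abbreviations are dropped, under-counting mentions.
* No dependency parsing, coreference or cross-sentence relations; table
  and figure content is invisible to the miner.
* The confounder correction omits LD structure; on real GWAS data gene
  scores in long-range LD regions will be less independent than the
  permutation null assumes.
* The simulators emulate study *conditions* (sample size, covariate
  adjustment, planted effect structure), not real allele-frequency
  spectra, LD, or literature prose.
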