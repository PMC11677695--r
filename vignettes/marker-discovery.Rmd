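---
title: "Rule-based marker discovery for somatic embryogenesis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based marker discovery for somatic embryogenesis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semarkr)
```

`semarkr` reconstructs, as a reusable and tested pipeline, a marker-gene
discovery workflow for plant somatic embryogenesis (SE): rule-based
selection of differentially expressed genes (DEGs) from a pooled FPKM table,
subset and annotation accounting, and RT-qPCR verification with relative
quantification, post hoc statistics and expression clustering. This
vignette explains the model behind each stage, the parameters that matter,
the numerical choices, and what the synthetic validation does and does not
establish.

## The selection model

The input is a transcript-by-tissue matrix of FPKM values over six tissues:
three organogenic (rosette leaf `rl`, rosette root `rr`, adventitious bud
`abl`) and three embryogenic stages (embryogenic callus `ec`, globular
somatic embryo `gse`, cotyledonary somatic embryo `cse`). Each tissue is a
single pooled library, so there is no replicate dimension and no dispersion
to estimate; selection is a deterministic predicate over each transcript's
six-value profile.

Every rule is a conjunction (or a small disjunction of conjunctions) of
three atom types:

* `MinFpkm(t, m)` — FPKM in tissue `t` at least `m` (default `m = 1`), the
  detection floor that keeps assembly noise out;
* `FoldAtLeast(t, u, f)` — FPKM in `t` at least `f` times the FPKM in `u`
  (default `f = 8`), evaluated **multiplicatively** as
  `FPKM_t >= f * FPKM_u`, never as a ratio, so a zero-FPKM comparator needs
  no special case and division by zero cannot occur. Boundary equality
  (exactly 8×) passes: the criterion is "at least".
* `StrictlyGreater(t, u)` — a strict `>` comparison, used where a rule
  demands "higher in `t` than `u`" without a fold factor.

Both constants are `se_config()` parameters (`fold_threshold`, `min_fpkm`),
so the same engine runs at, say, fold 3 for a more permissive screen; the
defaults are the published study's constants.

### The early-SE rule: an interpretation choice

The early-SE criterion is stated in the source workflow as a three-way "or":
detectable in `ec` or `gse`, or eight-fold over `abl` in one of them. Read
literally, any transcript with FPKM ≥ 1 in `ec` qualifies — which would
select a large fraction of any realistic transcriptome rather than a
subset of a couple of thousand genes out of ~160k transcripts. The default
(`early_rule_mode = "conjunctive"`) therefore requires that a **single**
embryogenic tissue `t ∈ {ec, gse}` passes both the detection floor and the
fold-over-`abl` test. The literal reading remains available
(`early_rule_mode = "literal_or"`) for auditing the difference; it is an
interpretation, not an assertion about the original authors' code.

### Provable structure

Three consequences of the rule algebra are enforced as tested invariants
rather than observed accidents:

1. the tissue-specific subsets are pairwise disjoint whenever
   `fold_threshold >= 2` and `min_fpkm > 0` (if `a >= 8b` and `b >= 8a`
   with `a >= 1`, then `a >= 64a` — impossible);
2. `ec_induction` and `late_se` are mutually exclusive (they demand
   `ec >= 8 cse` and `cse >= 8 ec` respectively);
3. every `all_se` member satisfies the conjunctive early-SE rule
   (`gse >= 1` and `gse >= 8 abl` are among its atoms), so `all_se` never
   contributes unique genes to the SE overlap — exactly the structure the
   published Venn counts show.

`classify()` is vectorised; `classify_bruteforce()` is a deliberately naive
per-transcript, per-atom loop with the identical contract, kept as an
independent oracle that the test suite replays against `classify()` on
randomized matrices.

## Subset accounting

`summarize_subsets()` reports sizes, totals and percentage shares. The
percentage denominator is the **with-multiplicity** total (a transcript is
counted once per subset it belongs to), because that is the only
denominator under which the published shares recompute (8687 of 16,748 =
51.87%, and so on). Percentages are rounded half-up (`round_half_up()`),
not banker's-rounded, to match report conventions. One published share does
not recompute under any reading: 727 `abl`-specific genes out of 16,748 is
4.34%, not the printed 4.56% (which equals the `ec` share — plausibly a
copy duplication). The package reports the recomputed value; the
discrepancy is asserted, documented, and not reproduced.

Unique-member counts and `overlap_table()` Venn regions are computed over
the four SE subsets; the regions partition the union, each transcript in
exactly one region.

## Annotation and candidate selection

Annotation joins are consumed, not computed: the package reads minimal
tabular exports of BLAST-style hits (database, accession, description,
species, E-value, length) and GO assignments. Coverage statistics count
members with at least one hit in a database; species tallies keep one best
hit per transcript (lowest E-value, ties by lexicographic accession) so
counts sum to the number of annotated transcripts; GO top-term rankings
count distinct member transcripts per term within one category, exclude the
three ontology root terms by default (they carry no information beyond the
category), and break count ties by GO id — every ranking is a deterministic
function of its inputs.

Candidate selection mirrors the published procedure: among SE-subset
members, a Swiss-Prot hit with E-value strictly below `1e-15` wins;
otherwise an NCBI-nt hit below the threshold; otherwise the transcript is
dropped unless the caller opts into unannotated candidates — the route by
which novel, annotation-free transcripts (the most interesting marker
candidates) enter the list. The strict `<` comparison follows the stated
criterion.

## RT-qPCR quantification

### Standard curves

`fit_standard_curve()` regresses Ct on log10(copies) over a dilution series
(at least three distinct levels; the emulated design spans 1e9–1e2 copies).
Efficiency is `100 * (10^(-1/slope) - 1)`, held bit-exactly as an
invariant; a slope of −3.3219 = −1/log10 2 gives 100% (perfect doubling per
cycle). QC passes only for a negative slope with efficiency in the optimal
90–110% band. R² is computed directly from residuals, since `summary.lm()`
warns on the perfect fits that ideal synthetic series legitimately produce.

### Undetected measurements

A transcript can drop below the detection range in some tissues. Such
records enter as the token `ND` and are never silently numbers; before
quantification they are imputed with the gene's standard-curve
**y-intercept** — the Ct at a single template copy, i.e. the detection
floor — and an audit table of imputations is attached. Quantifying with a
detection-floor Ct understates how extreme a truly absent transcript is;
the audit trail keeps that visible.

### The 2^−ΔΔCt model

Quantification is pure Livak: per tissue and biological replicate,
`dCt = Ct_target − mean(Ct_ref1, Ct_ref2)`; `ddCt` subtracts the
calibrator tissue's mean `dCt`; the replicate-level log2 fold change is
`−ddCt`. Design choices the source procedure leaves open, decided here:

* the two reference genes are combined as the **arithmetic mean of their
  Cts** — the geometric mean of their quantities, the standard
  multi-reference normalization on the Ct scale;
* replicates are paired by replicate index across target and references
  (plate-run pairing), which makes `dCt` invariant to any plate-wide Ct
  shift affecting a replicate's target and references equally — an
  invariant the suite asserts;
* efficiency is assumed 100% in the fold-change math; curves inform QC and
  imputation only, keeping the two concerns separate;
* the calibrator's mean log2 fold change is 0 by construction, not by
  normalization after the fact.

### Post hoc statistics

Per gene, replicate-level log2 fold changes are compared across tissues by
one-way ANOVA and Tukey HSD at `alpha = 0.05` (`stats::aov` /
`stats::TukeyHSD`). The compact letter display is computed by
insert-and-absorb over tissues ordered by descending mean: start from one
letter containing all tissues; for each significant pair, split every
letter containing both; absorb letters that become subsets of others. The
defining property — two tissues share a letter exactly when their Tukey
comparison is non-significant — is asserted over randomized cases. Because
figure legends in this field often letter "versus the control" while the
stated test is all-pairs Tukey, the table additionally flags each tissue's
Tukey comparison against the calibrator. All-zero within-group variance is
a degenerate-input error with guidance, not a silent NaN.

## Clustering

Tissues are clustered on their gene profiles by Euclidean distance and
Ward agglomeration (`hclust` method `ward.D2`: the Lance–Williams update on
squared Euclidean distances, heights reported on the distance scale). Genes
are clustered by `1 − Pearson` distance with complete linkage — "furthest
neighbour" and "complete linkage" are the same criterion, and the package
treats the two names the source uses as one method. Input label order is
canonicalised (rows sorted) before clustering, so permuting the input
yields identical trees; for up to six leaves the suite checks complete
linkage against a brute-force agglomeration that rescans all candidate
merges. Missing (gene, tissue) entries are an error, not imputed: the
verification design is complete by construction.

`render_heatmap()` draws the gene-by-tissue log2 fold-change matrix with
rows and columns in dendrogram order on a diverging palette anchored at 0 —
red for decreased, blue for increased expression (deliberately inverting
the common heatmap convention to match the field's figure style), so the
all-zero calibrator column sits at the midpoint. Alongside the image it
writes the plotted matrix as TSV and both dendrograms as Newick, so every
graphical claim has a parseable sidecar.

## The synthetic-data generator

The generator exists so the full pipeline can run and be validated with no
external download; it emulates the study conditions, not arbitrary data.

**FPKM (`gen_fpkm`).** Background transcripts are i.i.d. log-normal with
median 2 FPKM and `sdlog = 1.5` — the right-skewed, zero-heavy shape of
bulk expression tables — and are **rejection-sampled** until no rule fires,
giving clean negatives rather than probabilistic ones. Planted transcripts
are constructed to satisfy their target rule's inequalities with
multiplicative slack `margin` (default 2) on every atom: comparator tissues
draw uniformly below the detection floor, and the target tissue is set to
`margin × max(min_fpkm, fold × max(comparators))`. Logical implications are
respected and recorded in the truth: `ec_induction` and `all_se` plants are
also `early_se` members; `all_se` plants set the three embryogenic tissues
exactly equal so the strict `>` atoms of `ec_induction`/`late_se` fail
deterministically. Recovery is therefore exact by construction at any
`margin > 1`, and the suite verifies it across seeds and at margins close
to 1.

**Ct (`gen_ct`).** Target Ct = 25 − planted log2 fold change + N(0,
`ct_sd`); reference Cts = 20 + noise; three biological replicates;
`ct_sd = 0.2` cycles (a typical well-run SYBR assay); any Ct above the
40-cycle ceiling — the assay's amplification-cycle count — is emitted as
undetected. Reference genes must be planted flat (fold change 0
everywhere); anything else is an error, since a drifting reference violates
the normalization model. With zero noise the Livak pipeline recovers
planted fold changes exactly; at the default noise, mean absolute recovery
error over 100 genes × 9 tissues is well under 0.5 log2 units.

**What passing does and does not show.** The generator plants exact rule
satisfaction with slack and homoscedastic Gaussian Ct noise. Real data add
things it deliberately omits: borderline transcripts sitting on rule
boundaries, correlated expression across tissues, assembly artifacts
(chimeric or fragmented transcripts), pipetting and plate effects that are
not replicate-paired, and reference genes that are only approximately
stable. Passing the synthetic suite therefore certifies the *arithmetic and
logic* of the pipeline — not that the rule constants are biologically
optimal for a new species, which remains a scientific judgement.

## Problem sizes and determinism

Validation runs at desk scale by choice: oracle-equivalence on ~1000–2000
random transcripts, planted recovery at 5000 background transcripts × 10
plants per subset across 20 seeds, qPCR recovery at 100 genes × 9 tissues ×
3 replicates, clustering oracles at ≤ 6 leaves. These sizes exercise every
code path and boundary; the rule engine itself is vectorised and handles
full-transcriptome tables (~160k rows) without modification. Every
stochastic step takes an explicit seed, all generation is bit-reproducible
given one, and every ranking or membership list has a total, documented
ordering (sorted transcript ids; count-then-id tie-breaks), so repeated
runs are byte-identical.

## Known limitations

* No statistical DE testing — by design, the selection is rule-based; the
  package should not be the tool of choice where replicated RNA-seq is
  available (use a dispersion-modelling framework there).
* No efficiency-corrected (Pfaffl) qPCR model; curves are QC/imputation
  only. Assays far from 100% efficiency will bias fold changes.
* GO rankings are frequency tallies, not enrichment tests; no background
  model is implied.
* Average sequence length per subset, and anything requiring the deposited
  sequences themselves (assembly, BLAST execution, primer design), is out
  of scope: the package consumes tabular exports.
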