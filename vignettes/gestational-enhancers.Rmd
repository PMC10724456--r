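---
title: "Placental enhancer dynamics across gestation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placental enhancer dynamics across gestation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gestenh)
```

# The analysis problem

The human placenta remodels its regulatory landscape across the three
trimesters of pregnancy. Active enhancers produce short unstable transcripts
(eRNAs), so nascent-transcription assays (PRO-seq) combined with a
regulatory-element caller yield per-sample catalogs of transcribed
regulatory elements (TREs). `gestenh` implements the downstream analysis of
such a study end to end:

1. **Enhancer universe** — pool per-sample TRE calls, merge them into a
   non-redundant union, remove gene-proximal elements, and keep elements
   expressed above an RPKM cutoff.
2. **Expression dynamics** — normalize expression, classify genes by Pearson
   correlation with gestational age, test pairwise trimester contrasts,
   summarize z-score trends across age epochs, and score cell-type
   signatures.
3. **Enhancer–gene linking** — nearest-gene assignment, enhancers-per-gene
   ranking, hypergeometric list-overlap tests, and enhancer–gene expression
   correlation.
4. **TFSEE** — the Total Functional Score of Enhancer Elements, integrating
   enhancer transcription, histone-mark enrichment, motif predictions, and
   TF expression into per-sample TF scores, with sample clustering and an
   early-versus-late differential ranking.
5. **SNP enrichment** — GWAS-catalog SNP density (SNPs per million bp) in
   enhancers versus genes and the genome background.

A synthetic-data generator (`simulate_dataset()`) emulates the full
multi-omic study with recorded ground truth, so every stage is validated by
parameter recovery rather than by fixtures alone.

# Coordinate and data model

All intervals are 0-based half-open (BED convention); GTF input (1-based
closed) and GWAS catalog positions (1-based) are converted at the parser
boundary, so the package has a single coordinate convention internally.
Chromosome names are compared by exact string match; the distal filter warns
when its two inputs share no chromosome names, which usually indicates mixed
naming dialects. Signal matrices are plain numeric matrices, features by
samples, with no missing values permitted: the generator never emits them
and real-data adapters are expected to impute upstream. The sample sheet is
the ordering authority — matrices are reindexed to it on load and absent
samples are an error.

# Universe construction

Merging unions overlapping **and bookended** intervals (gap 0 merges, gap 1
does not), matching the default behavior of the standard interval-merge
utility. The distal filter retains an element only when its gap to **every**
gene exceeds `min_gap_bp` (default 5000, strictly greater), where the gap is
0 on overlap and otherwise the number of bases strictly between the nearest
edges. The gene *span* (5′ and 3′ ends) defines the edges by default; a
TSS-only mode (`mode = "tss"`) is available because the two conventions
differ for long genes, and span-based filtering is the more conservative
reading of "distal". RPKM is counts / (kb of feature × millions of mapped
reads), and the expression filter is **inclusive**: RPKM ≥ 2 in ≥ 1 sample
by default. Total mapped reads define the library size; restricting the
denominator to in-TRE reads would change only the scale, not the ranking,
but would make the cutoff depend on the TRE catalog itself.

# Expression dynamics

Size factors are the median, over features positive in all samples, of each
library's ratio to the per-feature geometric mean (median-of-ratios). Note
that these factors are *relative*: a constant applied to every library
cancels in the geometric mean.

Age correlation uses the Pearson r of expression against gestational age in
weeks with the t transform `t = r sqrt((n-2)/(1-r^2))` on `n-2` df for the
p-value — for simple regression this is identical to the slope test, so no
separate regression p is needed. A gene is classified increasing when
`r > 0.7` and `p < alpha/m` (Bonferroni), decreasing symmetrically. The
family size `m` counts only testable (non-constant) genes; constant genes
are flagged and excluded. With `alpha = 0.05` and `m = 23 000` the cutoff is
2.17 × 10⁻⁶.

Pairwise trimester tests are per-feature two-sample t-tests — pooled
variance (Student) by default with Welch as an option — with
Benjamini–Hochberg q-values and a significance call requiring both
`|log2FC| ≥ 1` (2-fold) and `q < 0.05`. Fold changes use a pseudocount of
0.1 RPKM on group means to avoid division by zero at silent features; the
value is small relative to the RPKM 2 expression floor, so it perturbs only
features already near the noise floor. Epoch trends z-score each gene across
samples and partition samples into five age-ordered bins of near-equal size,
earlier bins absorbing the remainder (36 samples → 8,7,7,7,7); age ties
break by sample id so the partition is deterministic.

# TFSEE

For enhancer set E, samples S and TFs T:

- **Activity** `A(e, s) = N(eRNA) · (N(K27ac) + N(K4me1)) / 2`, where `N` is
  per-enhancer min–max scaling across samples. eRNA is the defining
  activity signal, so an enhancer at its transcription minimum has zero
  activity regardless of its marks; averaging the marks prevents one
  locally flat mark from annihilating the other's information (a full
  three-way product is available via `combine = "product"`).
- **Motif matrix** `M(e, t)`: per enhancer the top 20 motif hits by match
  strength (−log10 match p; ties broken by TF then motif id) are kept; the
  strongest kept site represents each TF (`max`; `sum` optional). Columns
  are scaled onto [0, 1] per TF. Because absent (enhancer, TF) pairs sit at
  0 — the natural floor of the strength scale — the scaling divides by the
  per-TF maximum rather than subtracting a column minimum, which keeps a
  TF present in every enhancer from having its weakest site zeroed out.
- **Scores** `S = N_t( (AᵀM) ⊙ N_t(E) )`: the activity-weighted motif load
  per sample and TF, modulated by min–max-scaled TF expression, then scaled
  per TF across samples onto [0, 1].

All normalization axes are per-feature across samples (per enhancer for
signals, per TF for expression and scores). The choice makes features
comparable between samples, which the sample clustering requires; it also
makes the score invariant to any positive rescaling of a single enhancer's
raw signal row (tested as a property).

Samples are clustered with average linkage (UPGMA) on the distance
`1 − Pearson(S_i, S_j)` between sample score vectors, and the two-clade
partition is the cut at the root. The differential table ranks TFs by
`Δ = mean(S_late) − mean(S_early)` (trimester III versus I+II) with a
two-sided pooled t-test; ranking ascending in Δ puts the most early-active
TFs first and the most late-active last.

# SNP density

SNPs are points (length-1 half-open intervals): a SNP at position p is in
`[start, end)` iff `start ≤ p < end`. Density is SNPs per million bp of a
region set; the baseline is the full catalog over the provided total genome
size (taken verbatim — no gap exclusion), and enrichment is the ratio of the
two.

# The synthetic study generator

`simulation_config()` defaults describe the emulated study: 36 samples (12
per trimester; first-trimester ages uniform on 6–13 weeks, second 14–27,
term fixed at 39), 2000 genes and 500 enhancers laid out on a 4 × 8 Mb
genome with inter-feature gaps of at least 6 kb so that every planted
enhancer survives the 5 kb distal filter, plus 100 promoter-proximal decoy
TREs placed 1.5 kb upstream of gene starts that the filter must remove.

Counts are negative binomial (mean–dispersion parameterization, dispersion
0.05), the standard overdispersed model for sequencing counts. Enhancers are
one-third early-active, one-third late-active, one-third constitutive;
early-active enhancers have eRNA means 2^`effect_size_log2` (default 4×)
higher in trimester I/II samples than in III, and symmetrically for
late-active. Histone matrices are independent negative-binomial draws around
scaled eRNA means (0.8× for H3K27ac, 0.6× for H3K4me1), giving concordant
marks by construction without asserting a quantitative coupling. Early/late
TFs have motifs planted in matching-class enhancers with probability 0.7 and
match p-values log-uniform on [1e−12, 1e−6]; every enhancer also receives 5
decoy-TF background hits with p on [1e−4, 1e−2], so recovery is separated
from background but not trivial. Age-correlated genes (10% of genes, half
up, half down) have means linear in gestational age spanning a 6-fold change
from 6 to 39 weeks — the scale of well-known developmentally regulated
placental genes — over multiplicative NB noise. SNPs are uniform over the
genome with enhancer-internal density multiplied by 3 by default. Baseline
count scales (eRNA 200, genes and TFs 100 at library size 2 × 10⁷) put
expressed features comfortably above the RPKM 2 floor.

One master seed drives everything; each stochastic stage derives a fixed
child seed from it, so identical config + seed reproduce every emitted file
byte for byte, and partial re-runs are reproducible.

**What the generator does not emulate:** genomic sequence (motif hits are
tabulated, not scanned), read-level data, mappability or GC structure,
assay-specific background (input/IgG), batch effects, inter-sample library
size variation, cell-type mixture shifts beyond what the planted gene
programs induce, and linkage disequilibrium between SNPs. Passing recovery
suites therefore demonstrate the correctness and statistical behavior of
the pipeline's computations, not robustness to those real-data artifacts.

# Validation strategy and problem sizes

Exact engines (merge, distal filter, nearest gene, BH, hypergeometric, SNP
containment) are tested against brute-force oracles: base-coverage run
extraction, all-pairs gap scans, exhaustive minima, a textbook step-up
implementation, draw enumeration for universes up to 12 (with Monte-Carlo
at 10⁵ draws for larger toys), and per-SNP containment scans. Statistical
behavior is validated by parameter recovery on 20 generator seeds at the
default configuration (500 enhancers, 2000 genes, 36 samples, 5 early + 5
late + 50 decoy TFs): planted-TF ranking and sign in the differential TFSEE
table, the two-clade separation of early versus term samples, sensitivity
and specificity of age-correlation classification, and the planted 3× SNP
enrichment ratio. False-discovery calibration uses 2000 null
negative-binomial features. These sizes keep the whole suite to a couple of
minutes on one CPU while leaving the per-seed sampling error small relative
to the planted effects.

# Degenerate inputs and tie-breaking

- Zero-range slices min–max normalize to all zeros.
- Zero-variance features in t-tests: identical groups give t = 0, p = 1;
  separated constant groups give p = 0.
- Constant genes are excluded (with a warning) from z-score trends and from
  the Bonferroni family; constant vectors give undefined correlations,
  flagged rather than silently dropped.
- Nearest-gene ties go to the lexicographically smallest gene id; motif
  ties to the smallest TF then motif id; epoch-bin age ties to the smallest
  sample id. Every ordering in output tables is deterministic, and numeric
  output is rendered at 6 significant digits so repeat runs are
  byte-identical.

# Known limitations

- The nearest-gene rule is a heuristic; enhancers frequently skip their
  nearest promoter, and no chromatin-contact data is consulted.
- TFSEE inherits the limits of its inputs: TF mRNA is an imperfect proxy
  for nuclear TF activity, and motif families with near-identical position
  weight matrices cannot be distinguished by the hit table.
- The hypergeometric overlap test treats gene lists as exchangeable draws
  from the universe, ignoring expression-level or length biases.
- SNP density uses the provided genome size verbatim; assembly gaps are not
  excluded from the background.
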