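# gestenh

Analysis of the placental enhancer landscape across gestation: from
per-sample transcribed-regulatory-element (TRE) calls to an expressed distal
enhancer universe, gene- and enhancer-expression dynamics versus gestational
age, enhancer–gene linking, transcription-factor scoring with TFSEE, and
GWAS SNP density enrichment. The package is aimed at regulatory genomicists
working with nascent-transcription (PRO-seq), ChIP-seq and RNA-seq data
collected across a developmental time course, and ships a synthetic
multi-omic study generator with recorded ground truth so the whole pipeline
is testable without sequencing data.

## What it computes

**Enhancer universe.** Per-sample TRE calls are pooled and merged
(overlapping and bookended intervals union), elements within 5 kb of any
gene span are removed, and the survivors are kept when
RPKM = counts / (kb × millions of mapped reads) is ≥ 2 in at least one
sample.

**Expression dynamics.** Median-of-ratios size factors; per-gene Pearson
correlation of expression with gestational age, classified by
r > 0.7 (or < −0.7) and p < α/m (Bonferroni over testable genes, with
p from t = r√((n−2)/(1−r²))); pairwise trimester t-tests with
Benjamini–Hochberg correction and a 2-fold-change requirement; five
age-ordered z-score epochs; cell-type signature scores; a 2^−ΔΔCt utility.

**TFSEE** (Total Functional Score of Enhancer Elements). With per-feature
min–max scaling N across samples:

    A = N(eRNA) ⊙ (N(K27ac) + N(K4me1)) / 2        enhancer activity
    M(e,t) = scaled strongest motif hit, top 20 per enhancer
    S = N_t( (AᵀM) ⊙ N_t(E) )                      per-sample TF scores

Samples are clustered by average linkage on 1 − Pearson distance, and TFs
are ranked by the differential score Δ = TFSEE(late) − TFSEE(early)
(trimester III versus I+II) with per-TF t-tests.

**SNP enrichment.** GWAS-catalog SNP density (SNPs per million bp) inside
enhancers and genes versus the genome-wide baseline.

## Worked example

Simulate a study at the default design (36 samples, 12 per trimester; 2000
genes; 500 enhancers carrying planted early/late programs), build the
universe, fit TFSEE, and measure SNP enrichment:

```r
library(gestenh)

sim <- simulate_dataset(simulation_config(seed = 11))
uni <- enhancer_universe(sim$tre_sets, sim$genes, sim$counts_erna,
                         library_sizes = sim$library_sizes)
print(uni)
#> Expressed distal enhancer universe
#>   500 enhancers (from 500 merged TREs) x 36 samples
#>   filters: RPKM >= 2 in >= 1 sample(s); > 5000 bp from genes

ids <- rownames(uni$rpkm)
fit <- tfsee(uni$rpkm, sim$k27ac[ids, ], sim$k4me1[ids, ],
             sim$motif_hits, sim$tf_expr, sim$samples)
print(fit)
#> TFSEE fit
#>   36 samples x 60 TFs over 500 enhancers
#>   early n=24, late n=12; 21 TF(s) with p < alpha
#>   most early-active:  TF_E04, TF_E01, TF_E05
#>   most late-active:   TF_L01, TF_L03, TF_L05
```

All 500 planted enhancers are distal and expressed, so they survive both
filters, while the 100 promoter-proximal decoy TREs are removed. The fit
recovers the planted programs: the five early TFs head the differential
ranking with strongly negative Δ (higher TFSEE score in trimesters I/II)
and the five late TFs close it with positive Δ:

```r
head(summary(fit)$differential, 3)
#>    tf_id mean_early    mean_late      delta          t      p_value significant rank
#> 1 TF_E04  0.7568108 0.0010124155 -0.7557984 -16.924740 3.919517e-18        TRUE    1
#> 2 TF_E01  0.6425089 0.0010384875 -0.6414704 -11.429784 3.421305e-13        TRUE    2
#> 3 TF_E05  0.5596290 0.0006135570 -0.5590154 -10.410843 4.118706e-12        TRUE    3
```

Age-correlation classification recovers the 100 planted increasing and 100
planted decreasing genes exactly on this seed, and the planted 3× enhancer
SNP enrichment is estimated at 2.92:

```r
ac <- correlate_with_age(sim$fpkm_gene, sim$samples)
table(ac$class)
#> decreasing   increasing unclassified
#>        100          100         1800

snp_density(sim$snp_catalog,
            list(enhancers = sim$enhancers[, 1:5]), sim$genome_size_bp)
#>   region_set n_snps total_bp density_per_mb enrichment_ratio
#> 1  enhancers    464  2.5e+05      1856.0000         2.923842
#> 2     genome  20313  3.2e+07       634.7812         1.000000
```

`run_pipeline(out_dir, simulation_config(seed = 1))` executes the whole
chain (simulate → universe → dynamics → link → tfsee → snps) against a
directory, writing TSV/BED/JSON outputs and a run manifest;
`inst/scripts/run-pipeline.R` wraps it for the shell.

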