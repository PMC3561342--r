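# hkatlas

Housekeeping-gene expression-pattern analysis for two-group (normal vs
cancer) bulk RNA-Seq.

Comparing a panel of normal tissues against cancer cell lines raises a
recurring set of questions: which genes are switched on everywhere
(housekeeping genes), where does "expressed" end and noise begin, which
expression levels count as low or high, how stable is each gene across
samples, and how does the cancer condition shift all of the above?
`hkatlas` implements a complete pipeline answering these questions for
anyone analysing a gene × sample RPKM matrix with normal/cancer group
labels, plus a synthetic-study generator with planted ground truth so every
stage can be validated without touching real sequencing data.

## The methods

**Background threshold.** With gene (exonic) values as the positive set and
intergenic values as the negative set, every candidate threshold *t* gives
FPR(*t*) = #{negative > *t*} / #negative and
FNR(*t*) = #{positive ≤ *t*} / #positive. The per-sample threshold is the
candidate minimising |FPR − FNR| (ties to the smaller value); the study-wide
threshold is the cross-sample median. "Expressed" always means strictly
greater than the threshold.

**Five HK types.** A gene is HK for a group when its expression breadth
(samples above background) equals the group size. With normal-HK and
cancer-HK sets in hand: shared = intersection, normal-unique and
cancer-associated = the set differences, and the two derived sets satisfy
normal HK = shared ∪ normal-unique, cancer HK = shared ∪ cancer-associated.

**Tri-level thresholds.** Expressed genes of one sample, encoded as weighted
points (*x* = expression value, *y* = gene count), are partitioned into
low/moderate/high expression genes (LEG/MEG/HEG) by a one-dimensional
weighted k-medians (K = 3): distances are |log2(*x*+1) − log2(*c*+1)|,
a centroid is the expression value of its cluster's middle gene (weighted
median), and iteration stops when assignments are stable. The low threshold
is (max LEG + min MEG)/2 and the high threshold (max MEG + min HEG)/2 on
the original RPKM scale; unified thresholds are normal-group medians.

**Rank-based variation.** Expressed values become ranks 1/2/3 via the
unified thresholds; a gene's CV = σ/μ over its ranks (population σ). The
normal group's CV quartiles Q1/Q3 split genes into constant
(CV ≤ Q1), moderate variable, and variable (CV > Q3); transitions of
shared HK genes between conditions are cross-tabulated.

**MDAD and extreme ratios.** From each gene's group extremes (min taken
over positive values only): MD = log2(max_n/min_n) − log2(max_c/min_c)
(span-width difference) and AD = ½(log2 max_n + log2 min_n) −
½(log2 max_c + log2 min_c) (mid-level difference); negative values mean a
wider span / higher level in cancer. maxR = max_n/max_c and
minR = min_n/min_c summarise direction per gene (0 = only on in cancer).
Per-gene MD and AD are tested against a zero-median null with a paired
Wilcoxon signed-rank test (exact for n ≤ 20, tie-corrected normal
approximation with signed Z otherwise).

**Profile clustering and structure bias.** Samples are clustered
hierarchically (average linkage) on 1 − Spearman ρ of their expression
profiles and scored for two-group purity; per-HK-class gene-structure
features (gene size, CDS length, exons, minimal/large introns, GC) are
compared to the genome background with rank-sum tests.

## Worked example

```r
library(hkatlas)

# unified tri-level thresholds of the bundled 12-normal-sample reference panel
ref <- reference_trilevel_thresholds()
unify_thresholds(ref[, c("low", "high")])
#>    low   high
#>  1.055 12.720

# a synthetic two-group study with planted truth, analysed end to end
cfg <- sim_config(n_genes = 2000, seed = 1)
sim <- simulate_expression(cfg)
res <- run_pipeline(sim$matrix, simulate_intergenic(cfg, 4000))

round(res$background$unified, 3)   # 0.223  (expressed/silent cutoff, RPKM)
round(res$trilevel$unified, 2)     # low 2.65, high 14.72  (LEG/MEG/HEG cuts)
res$accounting
#>                 set count pct_of_loci
#> 1            shared  1000          50
#> 2     normal_unique   400          20
#> 3 cancer_associated   200          10
#> 4            non_HK   400          20
#> 5         normal_HK  1400          70
#> 6         cancer_HK  1200          60
res$cluster$cut2$purity            # 1  (normal and cancer separate cleanly)

sm <- res$mdad_summary_shared
sm[sm$type %in% c("MD", "AD"), ]
#>  type gene_count reject      p_value         Z
#>    MD       1000      1 6.663884e-03   2.71319
#>    AD       1000      1 1.620583e-44 -13.99723
```

The recovered class counts match the planted design exactly (the generator
plants 50/20/10/20% shared / normal-unique / cancer-associated /
tissue-specific genes), and the strongly negative AD statistic reflects the
planted up-regulation of half the shared and cancer-associated genes in the
cancer group.

The same analysis, staged over files with one script per step, lives under
`analysis/` (`01_simulate.R` … `08_structure.R`); each script reads the
previous step's tables from `results/synthetic_study/` and reports what it
found.

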