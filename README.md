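# metarget

Integrative discovery of metastasis-associated target genes from tumour
single-cell RNA-seq together with Hi-C chromatin structure, with a fully
synthetic, truth-carrying data generator so the entire pipeline is
testable end to end on one machine.

## Who this is for

Computational biologists who want a reusable, tested implementation of
the analysis funnel that leads from a tumour single-cell atlas to a
small set of prioritized target genes:

1. **QC and markers** — cell filtering (detected genes in \[200, 5000\],
   mitochondrial fraction ≤ 30%), depth normalization, and group-vs-rest
   Wilcoxon rank-sum marker statistics with BH adjustment.
2. **Malignancy calling** — expression-derived copy-number profiles
   (per-gene centering on reference cells, clipping, a 101-gene moving
   average along each chromosome, median re-centering, reference
   subtraction). Each cell gets a *CNV signal* (mean squared profile,
   s = mean(v²)) and a *CNV correlation* (Pearson r against the tumour
   consensus profile); a cell is malignant iff `s > 0.05` **and**
   `r > 0.5`.
3. **Expression programs** — per-cluster NMF (multiplicative updates,
   best of random restarts, restart-stability filtering) on relative
   expression, then cross-cluster consensus: hierarchical clustering of
   factor loading vectors at distance `1 − Pearson r` cut at `r = 0.2`;
   each meta-program is summarised by its top-20 **meta-signature** and
   annotated by hypergeometric enrichment against reference gene sets.
4. **Target prioritization** — intersect DEGs with program top genes,
   then per candidate: median dichotomization of cohort expression,
   Kaplan–Meier/log-rank test, univariate Cox PH (Newton–Raphson on the
   Breslow partial likelihood, HR = exp(β)), and a tumour-vs-normal
   direction filter. A gene passes when HR > 1, log-rank p < 0.05 and
   log2 FC > 0.
5. **Hi-C structure** — ICE matrix balancing, observed/expected, A/B
   compartments from the leading eigenvector of the O/E correlation
   matrix (A = gene-dense sign), compartment-switch labels per locus
   (e.g. `B->A`), insulation-score TADs (valley detection on the
   left-minus-right delta vector), a 200-kb minimum-size filter,
   reciprocal-70%-overlap conserved-TAD matching, and a per-gene
   structural switch report across two conditions.
6. **Clinical statistics** — 2×2 Fisher exact / Pearson chi-square tests
   with the conventional expected-count-5 selection rule, the IHC
   H-score `H = 0·neg% + 1·low% + 2·pos% + 3·high%` (range 0–300), and
   ROC AUC with the Youden-optimal cutoff.

Synthetic generators (`simulate_scrna()`, `simulate_hic()`,
`simulate_survival()`) produce all inputs with planted ground truth:
chromosome-arm CNVs, co-expression programs, compartment sign tracks,
TAD boundaries, and exponential survival with a group hazard ratio.

## Worked example

```r
library(metarget)

sim  <- simulate_scrna(sc_sim_config(seed = 1))   # 1,000 cells x 2,000 genes
qc   <- qc_filter(sim$counts)
norm <- normalize_log(qc$counts)

ref   <- intersect(sim$cells$cell_id[!sim$cells$malignant], rownames(norm))
prof  <- infer_cnv_profiles(norm, sim$annotation, ref)
calls <- call_malignancy(prof)
dplyr::count(calls, label)
#>   label             n
#> 1 malignant       595
#> 2 non-malignant   405
```

595 of the 600 truly malignant cells are called malignant and no
reference cell is miscalled — the joint CNV-signal/correlation rule at
(0.05, 0.5). Program discovery on the malignant cells then recovers the
four planted programs as exactly four multi-member meta-programs:

```r
mal      <- intersect(sim$truth$malignant_cell_ids, rownames(norm))
clusters <- sim$cells$sample[match(mal, sim$cells$cell_id)]
sets     <- discover_programs(norm[mal, ], clusters, seed = 1)
mp       <- consensus_metaprograms(sets, r_threshold = 0.2)
mp[mp$n_members > 1, c("meta_program", "n_members")]
#>   meta_program n_members
#> 1 MP1                  4
#> 2 MP2                  4
#> 3 MP3                  4
#> 4 MP4                  2
```

Survival filtering on a synthetic cohort with a true hazard ratio of 2:

```r
surv <- simulate_survival(surv_sim_config(n_per_group = 250,
                                          hazard_ratio = 2, seed = 1))
glance(cox_univariate(surv))
#>       n n_event    hr hr_conf.low hr_conf.high  p.value
#>     500     379  2.29        1.86         2.83 6.18e-15
```

The estimated HR of 2.29 (95% CI 1.86–2.83) brackets the planted value;
`tidy(logrank_test(surv))` gives the matching log-rank chi-square. The
clinical helpers reproduce printed cohort statistics from raw counts,
e.g. `fisher_exact_2x2(matrix(c(17, 4, 2, 6), 2))` = 0.0089 for a
5-year-survival 2×2 table, and `h_score(c(0, 0, 0, 100))` = 300.

Each fitted object has `tidy()`/`glance()` methods and an `autoplot()`
(KM curves, ROC) or a `plot_*()` display (compartment tracks, insulation
with TAD boundaries, marker volcanoes).

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the models,
default parameters, numerical choices, what the synthetic generators do
and do not emulate, and known limitations.
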