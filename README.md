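# dmycTargets

Integrative identification of directly Myc-activated genes — including
intron-hosted snoRNAs — from ChIP-seq binding data and knockdown RNA-seq.

## The problem

Myc binds many genomic sites, but binding alone does not establish
regulation. This package implements, as tested and reusable R functions,
the integrative analysis used to define a core direct-target set in
*Drosophila* S2 cells:

* **ChIP-seq arm** — peaks from a specific anti-Myc antibody are filtered
  against non-immune IgG controls and against Myc ChIPs from Myc-depleted
  cells (peaks overlapping any control peak by ≥1 bp are discarded);
  surviving peaks from multiple experiments are clustered into *consensus
  sites* by single-linkage overlap, a site being significant when any
  member peak has FDR < 10% (sub-threshold peaks are rescued by
  overlapping significant ones). Sites are profiled for distance to the
  closest TSS and for a canonical E-box (`CACGTG`) within the 100-nt
  window straddling the summit.
* **RNA-seq arm** — gene×sample counts from 3 Myc-knockdown vs 3 control
  replicates are normalized to 1,000,000 reads per sample; genes with
  ≥ 10 combined raw reads and transcript length ≥ 125 nt are kept; a
  pooled-variance t test on log2(normalized + 1) calls significance at
  p < 0.05, and fold classes use the one-third rule
  (kd ≤ (2/3)·ctrl down; kd ≥ ctrl/(2/3) up, both inclusive).
* **Integration** — sites are assigned to genes (interval overlap plus
  closest-TSS ties), intron-hosted snoRNAs are replaced by their host
  genes, significantly changed candidates displace unchanged ones, and a
  100/300-nt TSS-proximity rule prunes the rest. A gene is **directly
  Myc-activated** when it is bound by a significant site *and*
  downregulated by at least one third upon knockdown.
* **Enrichment** — any gene set (canonically: the detected snoRNAs) is
  tested on the log2(kd/ctrl)-ranked gene list with the weighted GSEA
  running-sum statistic, gene-set permutations, NES, nominal p and FDR q.
* **Synthetic data** — a seeded generator (`simulate_experiment`) emulates
  the full design: a toy genome with Uhg-style snoRNA host architecture,
  four ChIP tag sets (true sites enriched only in the specific/naive
  condition, "sticky" regions enriched in all four), and
  negative-binomial counts in which designated targets drop upon
  knockdown — with exported ground truth, so every stage is verifiable
  end to end.

## Worked example

```r
library(dmycTargets)

sim    <- simulate_experiment(sim_config(seed = 7))
report <- run_pipeline(sim, run_config(seed = 7, n_perm = 500))
report
#> Integrative binding/expression pipeline report
#>   specific peaks: 40; consensus sites: 40 (40 significant)
#>   detected genes: 381; down/up significant: 110/14
#>   direct targets: 35 activated, 0 repressed (30/35 in RiBi/translation, 86%)
#>   snoRNA set enrichment: enrichment_result: ES = -0.874, NES = -1.637, p = 0.001996, q = 0 (500 permutations)

evaluate_recovery(report, sim$truth)[c("sensitivity", "fdr",
                                       "sticky_removed_fraction")]
#> $sensitivity
#> [1] 0.9722222
#> $fdr
#> [1] 0
#> $sticky_removed_fraction
#> [1] 1
```

Reading the numbers: the caller finds 40 specific peaks after control
subtraction (the ten planted sticky regions are all removed because they
are also called in the IgG and knockdown controls); 110 of 381 detected
genes drop significantly on knockdown; 35 genes combine binding with a
≥ one-third drop and are called directly activated, recovering 97% of the
planted targets with no false calls; the snoRNA set piles up at the
downregulated end of the ranked list (negative enrichment score,
p ≈ 0.002).

Individual stages are plain functions on plain objects, e.g.

```r
cm  <- normalize_counts(sim$counts)
det <- filter_detected(cm, sim$annotation)        # >=10 reads, >=125 nt
dr  <- differential_test(cm, det)                  # pooled t, p < 0.05
head(report$targets[report$targets$direct_activated,
                    c("gene_id", "n_sites", "fold_class", "category")])
```

The published functional-category counts for the 139-gene core target set
ship as a plain-text table; `tabulate_categories()` reproduces the
headline arithmetic (114 of 139 genes, 82%, in ribosome
biogenesis/translation):

```r
tab <- read.delim(system.file("extdata", "myc_direct_target_categories.tsv",
                              package = "dmycTargets"))
tabulate_categories(rep(tab$category, tab$n_genes))[c("subtotal", "total", "percent")]
#> $subtotal
#> [1] 114
#> $total
#> [1] 139
#> $percent
#> [1] 82
```

## Package layout

| Area | Functions |
|---|---|
| Annotation & intervals | `genome_annotation`, `read_annotation`, `write_annotation`, `gene_tss`, `closest_tss`, `remove_rrna_reads` |
| ChIP tags & peaks | `tag_set`, `subsample_tags`, `call_peaks_naive`, `read_peaks`/`write_peaks`, `read_tags`/`write_tags` |
| Specificity & consensus | `filter_specific_peaks`, `build_consensus_sites`, `overlap_counts`, `tss_distance_profile`, `scan_ebox`, `region_read_ratio`, `select_validation_regions` |
| Expression | `count_matrix`, `normalize_counts`, `filter_detected`, `differential_test`, `classify_regulation`, `ddct_relative_expression` |
| Integration | `assign_sites_to_genes`, `classify_direct_targets`, `tabulate_categories`, `ribi_translation_categories` |
| Enrichment | `ranked_list`, `enrichment_score`, `permutation_significance` |
| Simulation | `sim_config`, `simulate_experiment`, `simulate_genome_annotation`, `simulate_chip_tags`, `simulate_counts`, `write_simulation`, `write_truth`/`read_truth` |
| Orchestration | `run_config`, `run_pipeline`, `write_report`, `evaluate_recovery` |

See `vignettes/direct-target-identification.Rmd` for the full methods
account: model assumptions, parameter defaults and their rationale, what
the simulator does and does not emulate, numerical choices, and known
limitations.
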