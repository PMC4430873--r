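---
title: "Identifying direct Myc targets from ChIP-seq and knockdown RNA-seq"
author: "dmycTargets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying direct Myc targets from ChIP-seq and knockdown RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmycTargets)
```

## The analysis this package implements

A transcription factor binds thousands of places in a genome, but binding
alone does not make a gene a target. This package implements an integrative
analysis that defines *direct* Myc targets in *Drosophila* cells by
requiring two independent lines of evidence per gene:

1. **specific binding** — a ChIP-seq peak for Myc that survives stringent
   negative controls (non-immune IgG ChIPs, and Myc ChIPs from cells in
   which Myc itself has been depleted by RNAi), and
2. **functional dependence** — a drop in the gene's transcript level when
   Myc is knocked down, measured by replicated RNA-seq.

A gene is *directly Myc-activated* when it is assigned to a significant
consensus binding site **and** its expression falls to at most two thirds
of the control level upon knockdown. The analysis pays particular
attention to small nucleolar RNAs (snoRNAs): most animal snoRNAs are
excised from introns of host genes (including dedicated non-coding
"U-snoRNA host genes", Uhg), so binding signal at an intronic snoRNA is
credited to the host transcription unit.

## Binding arm

**Coordinates.** All internal coordinates are 0-based half-open (BED
convention); GTF input/output converts at the boundary. A gene's TSS is
`start` on the plus strand and `end - 1` on the minus strand (one TSS per
gene; isoforms are out of scope).

**Specificity filtering** (`filter_specific_peaks`). A Myc peak is removed
if it lies on an excluded chromosome (unmappable contigs; the list is
configuration and empty for synthetic genomes) or shares at least one base
with any peak called in a control ChIP. One shared base is the overlap
criterion throughout the package — the common `intersectBed` default — and
no reciprocal-fraction requirement is imposed.

**Consensus sites** (`build_consensus_sites`). Peaks from several
experiments (different antibodies, different cell lines) are clustered by
single-linkage interval overlap; each cluster becomes one site spanning
the union of its members. A site is significant if *any* member peak has
FDR < 10% — this is the rescue rule: a sub-threshold peak is kept when an
overlapping peak from another experiment is significant. The
representative summit comes from the member with the smallest FDR (ties:
higher enrichment score, then leftmost). Single linkage was chosen because
the per-peak rescue rule leaves cluster topology open; it is the only
transitive closure consistent with "overlaps a significant peak" applied
symmetrically.

**TSS-distance profile** (`tss_distance_profile`). Distances to the
closest TSS are binned in 100-nt bins up to 1,000 nt and 1,000-nt bins up
to 10,000 nt, plus an overflow bin, and cumulative shares within 100 and
1,000 nt are reported, separately for E-box-positive sites. The distance
is measured from the peak interval (0 when a TSS falls inside it),
matching the behaviour of `closestBed`; a summit-based distance is
available via `distance_from = "summit"` because either convention is
defensible and published profiles do not always state which was used.

**E-box scan** (`scan_ebox`). The canonical Myc:Max motif CACGTG is a
palindrome, so scanning the forward strand suffices. A site is
E-box-positive when the hexamer *starts* anywhere in the 100-nt window
straddling the summit (`[summit - 50, summit + 50)`), clipped at
chromosome ends.

**Naive peak caller** (`call_peaks_naive`). The caller is plumbing for
synthetic end-to-end runs — real caller output is ingested with
`read_peaks` instead. It scores 200-nt windows every 50 nt by a Poisson
upper tail against the larger of the genome-wide and the ±5-kb local
background rate, corrects across windows by Benjamini–Hochberg, requires a
minimum two-fold enrichment over the background expectation (without this
floor the adaptive BH threshold, relaxed by the strong true-signal
windows, admits barely elevated background windows), merges overlapping
significant windows, and places the summit at the position of maximal
strand-extended tag coverage (leftmost on ties). There is no duplicate
collapsing, no fragment-size model beyond the 50-nt tag extension, and no
broad-peak mode.

**Comparative re-analysis selector** (`select_validation_regions`). For
re-assessing an external peak list, regions with a naive/depleted read
ratio of at most 1.2 (computed with a pseudocount guard of one read in the
denominator, since zero-count handling is otherwise undefined) that do not
overlap the package user's own sites are sorted by read count and every
50th region is selected starting from the top — a deterministic,
validation-sized sample spanning the count range.

## Expression arm

**Normalization** (`normalize_counts`). Every sample is scaled to one
million total reads. Fixed-total scaling preserves within-sample
proportions exactly, but it is only composition-safe when differentially
expressed genes carry a small share of the library; this matters for the
simulator design (below) and is a known limitation for datasets with
massive global shifts.

**Detection filter** (`filter_detected`). A gene is analysed when its
*raw* counts summed over all six samples reach 10 and its annotated
transcript length reaches 125 nt (both inclusive). Short transcripts —
including roughly half of all snoRNAs — are excluded because the library
preparation quantifies them unreliably.

**Differential test** (`differential_test`). Per gene: condition means of
normalized counts; the log2 knockdown/control ratio with a pseudocount of
1 (so genes with zero counts in one condition still rank finitely); and a
two-sided Student t test with pooled variance on `log2(normalized + 1)`
replicate values, significant at unadjusted p < 0.05. The pooled test was
chosen over an unequal-variance (Welch) correction deliberately: with
three replicates per group the Welch–Satterthwaite degrees-of-freedom
estimate is so noisy that the test's true size drops to about 0.034, while
the pooled test is exactly calibrated (measured 0.049–0.051 on 2,000-gene
negative-binomial nulls); the balanced design with similar group variances
is the textbook setting for pooling. Benjamini–Hochberg adjusted p-values
are reported alongside (`p_adjusted`) without changing the default calls,
which follow the unadjusted p < 0.05 convention of the analysis this
package models. No dispersion shrinkage or empirical-Bayes moderation is
applied — single-gene tests keep the calibration analysable.

**Fold classes** (`classify_regulation`). "Down by a third" means
`mean_kd <= (2/3) * mean_ctrl`, boundary inclusive; "up by a third" is the
reciprocal on the ratio scale, `mean_kd >= mean_ctrl / (2/3)`, so that
swapping condition labels maps the classes onto each other exactly. The
rule is evaluated on normalized condition means (not on a fitted fold
change), the most direct reading of a mean-based fold criterion.

**qPCR utility** (`ddct_relative_expression`). Standard ΔΔCt: per sample
the target Ct is referenced to the mean of the reference genes, condition
means of ΔCt are referenced to the calibrator condition, and
`2^(-ΔΔCt) × 100` expresses the result as a percentage with the calibrator
at exactly 100%.

## Integration

`assign_sites_to_genes` generates candidates per site as the union of
genes whose intervals the site overlaps and the gene(s) with the closest
TSS (all ties kept; an overlap-only mode is available since the published
candidate rule does not fully pin the union down). Pruning then applies,
in order:

1. intron-hosted snoRNAs are replaced by their host genes (deduplicated);
2. if any candidate changes significantly upon knockdown (p < 0.05), all
   unchanged candidates are dropped;
3. otherwise, if some unchanged candidate's TSS lies within 100 nt of the
   site, unchanged candidates with TSS beyond 300 nt are dropped.

These are exactly the written rules, in the stated order, and nothing
else — "manual pruning" beyond them would be invention. Pruning can never
remove a significantly changed candidate, and the result is independent
of input order. `classify_direct_targets` then labels genes:
`direct_activated` (bound by a significant site and down by a third),
`direct_repressed` (bound and up by a third), `bound_only`, `indirect`
(changed but unbound), `none`. `tabulate_categories` counts functional
categories among the directly activated set and computes the subtotal
over the ten ribosome-biogenesis/translation labels
(`ribi_translation_categories()`), shipped as a named constant so the
subtotal is reproducible.

## Gene-set enrichment

`enrichment_score` implements the weighted Kolmogorov–Smirnov running
sum: walking the metric-ranked gene list, hits add `|metric|^weight`
(normalized over in-set genes) and misses subtract `1/(N - |S|)`; the
score is the signed extremum. Weight 1 is the default, weight 0 recovers
the classic KS statistic. Ranking ties are broken by gene identifier for
determinism. `permutation_significance` uses *gene-set* permutations —
with three replicates per condition a phenotype-permutation null is
degenerate (only ten distinct relabelings) — with the +1/(n+1)
finite-sample correction on the nominal p-value, a normalized score
(observed ES over the mean magnitude of same-sign permuted ES), and a
same-sign FDR q computed on the normalized scale. The finite-sample
correction makes small-n permutation p-values slightly conservative; the
null-uniformity checks in the test suite account for this.

## The synthetic-data generator

`simulate_experiment` produces the full study design from a seeded
configuration: layer seeds are `seed`, `seed + 1`, `seed + 2` for
annotation/genome, ChIP tags and counts, so each layer is individually
reproducible, and no generator call perturbs the caller's RNG state.

What it emulates, with the default `sim_config()`:

* **Genome and annotation** — one 2-Mb chromosome carrying 300
  non-overlapping top-level genes: 70% protein-coding, 5% dedicated
  non-coding snoRNA host genes with 2–16 intronic snoRNAs each, 5%
  protein-coding hosts with a single intronic snoRNA, 20% other. snoRNA
  lengths are uniform on 46–316 nt, deliberately straddling the 125-nt
  detection cutoff so only part of the snoRNAs are analysable, as in real
  annotations.
* **Binding** — 40 true sites, 90% at promoters of designated target
  genes (all dedicated host genes plus random protein-coding genes), the
  rest intergenic and far from any TSS; 90% of sites get a CACGTG planted
  at the summit of the otherwise random sequence (chance occurrences
  elsewhere are left alone). Ten "sticky" regions are enriched in **all
  four** ChIP conditions, emulating antibody-independent background that
  the control subtraction must remove.
* **ChIP tags** — 200,000 tags per condition; uniform background
  everywhere; true sites receive 20× the background rate over a 200-nt
  spread *only* in the specific-antibody/naive condition; sticky regions
  receive 15× in every condition.
* **Expression** — negative-binomial counts, dispersion 0.01 (typical for
  cell-culture knockdown replicates), three replicates per condition,
  library sizes jittered ±20%. Knockdown log2 effects for target genes
  are drawn from N(−1, 0.3) truncated to at most −0.8: target status in
  the modelled analysis is response-defined (down by at least one third),
  so a nominal "target" drawn with a weak effect would contradict its own
  designation; the truncation enforces a margin past the one-third
  boundary. snoRNAs inherit their host's effect (coupling 1.0 by default —
  a parameter, not an assertion, since host-transcription coupling and
  snoRNP-stability effects are confounded in real data). Background genes
  span a wide abundance range (log-normal around 2,000 reads), affected
  genes a moderate one (around 500): the affected fraction of the library
  mass stays near 10%, because fixed-total normalization — which the
  modelled analysis mandates — distorts fold changes when the changing
  genes dominate the library. Detected snoRNAs are modelled as abundant,
  stable transcripts.

What it does **not** emulate: read sequences and base qualities,
alignment and mappability artefacts, GC bias, fragment-size distributions,
isoforms, batch effects. Passing the recovery tests therefore shows the
pipeline's logic is correct under the stated statistical model, not that
any particular real dataset would yield the same numbers.

With these defaults an end-to-end run recovers the planted direct-target
set with sensitivity ≥ 0.9 and FDR ≤ 0.1, removes every sticky region,
calls essentially all detected planted-down snoRNAs significantly down
(with three replicates a ≥3.5σ count coincidence can leave an isolated
snoRNA above p = 0.05 in an occasional run), and finds the snoRNA set
strongly enriched at the downregulated end of the ranked list. The test
suite and `scripts/acceptance.R` compute all of these quantities afresh at
run time.

## Numerical choices and degenerate inputs

* Sorting/tie-breaks are fixed everywhere: representative summits by
  (FDR, −score, position); caller summits leftmost-maximal; ranked lists
  by (−metric, gene_id); validation regions by (−reads, chrom, start).
* `region_read_ratio` guards zero denominators with `max(n_depleted, 1)`.
* Zero-variance genes in the differential test get p = 1 when the group
  means agree and p = 0 otherwise; a zero-count sample column is an error
  naming the sample.
* Empty inputs degrade gracefully: empty treatment → empty peak set;
  empty peak sets → zero consensus sites and a completed pipeline run;
  an empty target set → an all-zero category table.
* Problem sizes in the shipped tests (a 2-Mb genome, 200k tags per
  condition, 2,000-gene nulls, 100-instance oracle sweeps, 120–500
  permutations) were chosen to exercise every code path at full default
  scale while keeping a complete run in well under a minute per stage.

## Known limitations

* One TSS per gene; no isoform or liftover support, no chromosome
  aliasing.
* Fixed-total normalization is composition-sensitive by construction (see
  above); median-ratio methods are out of scope because the modelled
  analysis specifies total-count scaling.
* The unadjusted p < 0.05 significance convention follows the modelled
  analysis; `p_adjusted` is provided for users who prefer FDR control.
* The naive caller is not a MACS substitute-in-kind: no dynamic local
  lambda refinement, no duplicate filtering, no model-based shift
  estimation.
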