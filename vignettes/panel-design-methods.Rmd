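---
title: "Designing and evaluating targeted-capture SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and evaluating targeted-capture SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capdesign)
```

## The problem

Liquid-phase targeted capture genotypes a crop population at a fixed set of
a few tens of thousands of SNP loci, at a fraction of the cost of whole-genome
sequencing and with more design flexibility than solid arrays. The quality of
everything downstream — population structure, GWAS, selection scans — depends
on how the panel loci are chosen from the population variant calls. capdesign
implements a three-phase selection procedure and the companion evaluation
machinery (capture QC, PCA with projection, association scan, windowed
diversity/differentiation scan), plus a seeded synthetic-data generator that
serves as its test substrate.

## The three-phase selection

Given multi-sample biallelic SNP calls (`read_vcf()`), repeat/centromere
exclusion masks (BED), gene models (GFF3) and optional GWAS/QTL target
intervals (BED), `design_panel()` composes:

1. **Structural filtering** (`structural_filter()`): sites inside any mask
   interval are removed, as are sites whose probe context is
   polymorphism-dense — more than `near_variant_max` (default 4) other
   variants within `near_variant_radius` (default 200 bp). Probes over
   polymorphic or repetitive sequence hybridize poorly; the neighborhood rule
   anticipates the dominant failure mode observed in capture QC.
2. **Quality filtering + LD pruning** (`quality_filter()`, `ld_prune()`):
   sites must satisfy `maf >= maf_min` (default 0.05),
   `missing_rate <= missing_max` (default 0.2) and observed heterozygosity
   `<= het_max` (default 0.5, against paralog collapse). Pruning then walks
   consecutive same-chromosome pairs and, wherever the composite-LD
   r² (squared Pearson correlation of dosages, pairwise-complete over
   samples) is at or above `ld_r2_max` (default 0.2), drops the
   lower-scoring member — ties drop the right-hand site — iterating to a
   fixed point. By construction every defined adjacent r² in the output is
   below the threshold. We prune adjacent pairs rather than windowed
   all-pairs because near-independence of *neighboring* panel loci is the
   design objective; a windowed prune would thin the candidate pool more
   aggressively without improving that property.
3. **Adjacency refinement** (`adjacency_refine()`): target-interval loci are
   forced in first (`force_include_intervals()`: per interval, the
   highest-scoring candidate, ties to the smallest coordinate). The remaining
   `target_count − n_forced` backbone slots are apportioned to chromosomes
   proportionally to length (largest-remainder rounding); each chromosome is
   cut into that many equal-width bins and the best candidate per bin is
   taken, skipping candidates within `min_spacing` (default 1 kb) of the
   previous backbone pick; any shortfall is filled by repeatedly putting the
   best eligible candidate into the largest remaining inter-locus gap. A
   deterministic greedy was chosen over global optimization because
   near-uniform spacing is the only objective, the greedy is auditable, and
   identical inputs must give byte-identical panels.

Locus score is `w_genic·[genic] + w_maf·maf − w_missing·missing − w_het·het`
with unit weights by default: prefer common, well-called, gene-linked
variants. `classify_loci()` assigns exon > intron > promoter > intergenic,
with the promoter operationalized as `promoter_len` (default 2 kb, the common
plant-genomics convention) upstream of the strand-aware TSS.

Published panels of this kind report the quality distributions of the chosen
loci (median missing ≈ 0.03, heterozygosity ≈ 0.08, MAF ≈ 0.31) but not the
cutoffs that produced them, so every threshold here is an explicit
`design_config()` parameter rather than a constant; the defaults are
conventional starting points, not reconstructions.

## Coordinate conventions

All internal intervals are 0-based half-open; VCF/GFF positions are converted
at the I/O boundary. Site-in-interval queries for region sets (masks, target
intervals, windows) use `start <= pos < end` applied to the 1-based variant
position, so a site exactly at an interval's `end` is outside it. Gene and
exon features parsed from GFF3 (1-based inclusive) use exact conversion, so a
gene spanning 1..300 contains a site at position 300. The two rules differ at
one boundary base; both are fixed and tested.

## Capture QC

`detection_rate()` calls a panel locus detected at depth `>= min_depth`
(default 1 — "any coverage", matching how uncovered probe sites are counted
in practice); loci absent from a depth table count as depth 0.
`failed_probe_diagnosis()` classifies undetected loci: `sv_likely` when the
matched WGS depth falls below 0.25× the sample's median WGS depth (a
quartile-of-median rule, conventional for deletion evidence and exposed as
`sv_depth_factor`), else `polymorphism_interference` when the probe
neighborhood is variant-dense, else `unexplained`. `variant_set_venn()` and
`genotype_concordance()` compare chip calls against matched WGS calls;
concordance is computed over loci called in both.

## Population-level evaluation

**PCA** (`pca_fit()`) drops fixed sites, mean-imputes missing dosages,
centers by `2p̂` and scales by `sqrt(2p̂(1−p̂))`, and takes the top-k SVD;
each loading's largest-magnitude entry is made positive so signs are
reproducible. `pca_project()` standardizes new samples with the *stored*
means and scales — never re-estimated — so training samples reproduce their
scores exactly and a sample at the model means projects to the origin.

**Association** (`assoc_scan()`) regresses the phenotype on dosage plus the
top-m PC scores, testing the dosage slope (two-sided t). The per-site fit is
closed-form after projecting phenotype and dosages off the covariate space,
which is algebraically identical to per-site `lm()` (tested against it) but
vectorized. Binary 0/1 traits go through the same linear model — equivalent
to the score test at scan scale. Mixed-model kinship correction is out of
scope; PCs are the confounding control.

**Selection scan** (`selection_scan()`): sliding windows (defaults 1 Mb
window, 100 kb step; chromosomes shorter than one window yield a single
truncated window so no data is silently dropped). Per window and group,
π sums the unbiased per-site heterozygosity `2p̂(1−p̂)·n/(n−1)` over variant
sites and divides by the full window length — capture data cannot
distinguish monomorphic from uncovered positions, so the denominator is the
window, not an accessibility mask. Fst is Hudson's estimator aggregated as a
ratio of averages, the standard choice for windowed scans because it is
robust to low-frequency sites; Weir–Cockerham is deliberately not offered as
a silent alternative. `ROD = 1 − π_target/π_reference` with the
candidate-selected group as target, so positive values mark diversity loss
in that group; windows with `π_reference = 0` are undefined and excluded
from thresholding. `top_quantile_regions()` selects windows at or above the
empirical 95th percentile (configurable `q`) and merges overlapping or
adjacent windows into candidate regions.

## The synthetic-data generator

`simulate_bundle()` writes a complete input set (VCF, masks BED, genes GFF3,
target intervals BED, phenotype TSV, truth JSON) from one seed. Genotypes
follow the Balding–Nichols island model: per site an ancestral frequency is
drawn uniformly from `ancestral_freq_range`, each subpopulation's frequency
is Beta-distributed around it with spread set by `fst_param`, and genotypes
are Binomial(2, p_k). This gives direct control of the differentiation that
the Fst-recovery tests measure, with sites unlinked by construction —
matching the near-independence a pruned panel aims for, but meaning the
generator does *not* emulate LD decay, so LD pruning is exercised by
duplicated/correlated fixtures rather than by the island model. Missingness
is uniform (MCAR). Sweeps redraw the target group's genotypes in a region
from Binomial(2, q) with `q = residual_freq` oriented toward the group's
major allele; traits are linear (or logistic with 30% prevalence) in one
causal site's dosage; capture depth is negative-binomial with designated
dropout loci recorded as ground truth.

Default study conditions used by the tests and the acceptance script: three
subpopulations of 20 samples at F = 0.15, ancestral frequencies 0.05–0.95,
2% missingness, 20 genes/Mb, 10% repeat fraction; the full-scale design run
uses ten 10-Mb chromosomes with 260,000 sites and 48 samples, which leaves
well over 200,000 candidates after filtering for a 40,051-locus target;
power/recovery checks use 25–100 seeded replicates at 400–5,000 sites. These
sizes were chosen so each property is measured with comfortable statistical
margin while the whole suite runs in minutes on one CPU.

What passing these tests shows — and does not. Parameter recovery (F within
±0.02, sweep regions hit by top-5% ROD and Fst windows, causal site
top-ranked, detection rate tracking the dropout rate) validates the
estimators and the selection logic under the generator's assumptions:
unlinked sites, MCAR missingness, island-model structure. Real data add LD,
informative missingness, uneven variant density and reference bias; the
panel-design invariants (mask avoidance, quality floors, spacing,
determinism) are data-agnostic, but the statistical operating
characteristics on real cohorts should be expected to be somewhat worse than
the synthetic ones.

## Numerical and degenerate-input choices

Undefined statistics (r² of a monomorphic pair, ROD with zero reference
diversity, concordance with no co-called loci) propagate as `NA`, never as
0 — zero is a meaningful value for all of them. Ties are always broken
(higher score, then smaller coordinate) so every pipeline output is
deterministic. Quantiles use R's default type 7. `ld_prune` guarantees its
own output's adjacent-r² property, but gap-filling and bin selection later
create *new* adjacencies between loci that were never adjacent during
pruning, so the final panel is not re-pruned; the guarantee is stated, and
verified, at the pruning stage. Empty masks, empty interval sets, empty
windows, chromosomes with fewer than two loci and header-only VCFs are all
legal inputs with defined outputs.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42, n_sites = 4000)
geno <- simulate_genome(cfg)
pop <- simulate_population(cfg, geno$layout, geno$masks)

cfgd <- design_config(target_count = 500)
panel <- design_panel(pop$gm, geno$masks, region_set(), geno$genes, cfgd)
spacing_stats(panel)
verify_panel(panel, pop$gm, geno$masks, cfgd)

tgt <- names(pop$labels)[pop$labels == "pop1"]
ref <- names(pop$labels)[pop$labels != "pop1"]
scan <- selection_scan(pop$gm, tgt, ref)
top_quantile_regions(scan, "fst", 0.05)
```

## Known limitations

No haplotype-phase LD (D′), no imputation, no mixed-model GWAS, no
coalescent/recombination simulation, no probe oligo chemistry (Tm/GC/tiling),
and no BAM parsing — depth enters as per-site TSVs produced upstream. The
CLI (`capdesign_cli()`, installed as `inst/cli/capdesign`) wraps the same
functions and adds nothing semantically.
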