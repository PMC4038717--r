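---
title: "Haplotype-based computational genetic mapping: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-based computational genetic mapping: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbcgm)
```

## The problem

Panels of classical inbred mouse strains are a mapping population in which
every genotype is fixed: each strain is homozygous genome-wide, so a strain's
phenotype mean (over replicate animals) is the natural analysis unit.
Haplotype-based computational genetic mapping (HBCGM) asks, for every short
run of consecutive SNPs, whether the partition of strains induced by their
allele strings in that window predicts the strain means of a quantitative
trait. The motivating application is behavioral pharmacology — opioid
adaptations such as opioid-induced hyperalgesia (OIH), analgesic tolerance
and physical dependence measured across ~23 strains with ~8 animals each —
but the machinery is generic.

Two aggregation procedures sit on top of the per-block test and are the
heart of this package:

* **Robustness scoring.** The mapping is repeated on many random strain
  subsets (by default 100 distinct subsets, each excluding 3–6 of the
  strains). Per subset, each gene's best block p-value is recorded; values
  at or above a cutoff (default 0.01) are *censored to the cutoff*. The
  gene's score is \(\sum_i -\log_{10} \tilde p_i\) over iterations. A gene
  whose association survives arbitrary removal of strains accumulates a
  large score; a gene propped up by two or three extreme strains does not.
* **Multi-trait integration.** The same censored \(-\log_{10}\) sum, with
  the index running over related traits instead of resampling iterations,
  rewards genes associated with several correlated adaptations at once.

A fully censored gene scores `n_iterations * 2` (or `n_traits * 2`) at the
default cutoff; every observed score is bounded below by that floor.

## The association model

For a block inducing groups \(g = 1..k\) over strains with trait means
\(y_s\), the test is a one-way fixed-effects ANOVA on the strain means:
\(F = \frac{SSB/(k-1)}{SSW/(N-k)}\) with \(p\) from the
\(F_{k-1, N-k}\) distribution. The reported **genetic effect** is
\(\eta^2 = SSB/SST\), the fraction of inter-strain variance attributable to
the block's grouping; an alternative group-mean-range measure is available
via `hbcgm_config(effect_measure = "range")` because both definitions
circulate in the HBCGM literature. No kinship or
population-structure correction is applied — the method treats strains as
exchangeable, and the robustness procedure is the confidence mechanism.

Numerical choices:

* Blocks inducing the same strain partition (`partition_key`, canonicalized
  over name-sorted strains) are tested once and share one p-value exactly —
  neighbouring genes riding on one haplotype block tie by construction.
* Perfect separation (zero within-group variance, unequal means) reports
  the p floor `1e-300`, never 0, keeping \(-\log_{10} p\) finite.
* The response is centred per partition on the labelled strains only, so
  removing a strain that carried no label in a partition reproduces that
  partition's statistics *bitwise*.
* Ranking tie-breaks are fully specified (p, effect descending,
  chromosome/position, gene name), so outputs are byte-reproducible.

## Block enumeration parameters

Sliding windows of 1–3 SNPs (configurable) are enumerated per chromosome; a
strain missing any call in a window is excluded from that block. Windows
are kept when 2–`max_groups` (default 4) haplotype groups remain, every
group has `min_group_size` (default 3) strains, and at least half the
strains are labelled. The defaults target a ~23-strain panel: groups below
3 strains make the F-test fragile, and short windows with ≤4 groups mirror
established HBCGM practice, whose exact construction parameters vary
between implementations — all are exposed in `hbcgm_config()`.

## What the generator emulates

`simulate_panel()` builds a genome as a sequence of ancestral haplotype
regions: region lengths are geometric with mean `mean_block_length_snps`
(default 10 SNPs); within a region each strain carries one of
`n_ancestral_haplotypes` (default 3) distinct allele strings, drawn
uniformly and independently across regions. Nearby SNPs are therefore
perfectly correlated within a region and independent across regions — the
caricature of haplotype-block structure the mapping assumes. Genes tile the
genome (default 100 genes over 5 × 1000 SNPs); genotypes are masked missing
independently (default 2%).

One region is the causal block. It is placed *entirely inside* the causal
gene (default: the middle gene): without that constraint a region straddling
a gene boundary hands the identical partition — and therefore an identical
robustness score — to the neighbouring gene, and no method could decide
which gene is causal. That is a deliberate idealization.

Strain-level trait values are built per trait as
\(\sqrt{h}\,c_s + \sqrt{1-h}\,r_s\), where \(c_s\) is the causal-block
group effect and \(r_s\) a residual, and
\(h\) = `causal_effect_variance_fraction` (default 0.7). Two non-obvious
choices:

* **The fraction is exact in-sample.** The causal component is standardized
  across strains and the residual is orthogonalized against the causal
  grouping before standardization, so a one-way ANOVA of the strain-level
  values on the true grouping yields \(\eta^2 = h\) exactly, in every
  dataset. Scaling only in expectation leaves the realized fraction with a
  \(\chi^2_{k-1}\)-shaped spread (the causal pattern involves only
  \(k \le 4\) group effects), which makes per-seed power statements about
  "a panel with causal fraction 0.7" meaningless.
* **Cross-trait correlation lives on the latent scale.** Group effects and
  residuals are drawn from equicorrelated Gaussians
  (`trait_correlation`, default 0.5, matching the "moderate" correlations
  seen among opioid adaptation traits). Because the causal component has
  only \(k\) degrees of freedom, its in-sample cross-trait correlation is
  degenerate (with \(k=2\) it is ±1); the correlation target is meaningful
  for the residual/latent values and is validated on a null genome.

Replicate animals (default 8 per strain) add independent Gaussian noise
(`replicate_noise_sd`, default 1.0, i.e. within-strain SD equal to the
between-strain SD — an individual-animal heritability of 0.5, typical for
murine nociceptive behaviour). Strain means, SEM and n are derived from the
replicates exactly as a lab would.

What a green simulation test does **not** establish: realistic linkage
disequilibrium decay, kinship/phylogenetic structure among strains (real
panels are not exchangeable), genotyping error beyond random missingness,
or non-Gaussian trait distributions. The generator makes no attempt to
reproduce any particular laboratory's strain means.

## Phenotype indices

* `fraction_of_baseline(baseline, post)` — post/pre threshold ratio; OIH
  < 1. `percent_decrease()` is `100 * (1 - fraction)`.
* `percent_mpe(latency, baseline, cutoff)` — the universal definition
  `100 * (latency - baseline) / (cutoff - baseline)`, clipped to [0, 100],
  is used (consistent with a 20 s thermal cutoff).
* `fit_dose_response()` — "variable slope" sigmoid
  `bottom + (top-bottom)/(1 + (ed50/dose)^hill)` with bottom/top fixed at
  0/100 %MPE by default (a 4-parameter fit is available). Optimization is
  over (log ED50, log hill), seeded by an exact logit-linearization and
  polished by Nelder–Mead at `reltol 1e-14`; degenerate data and
  non-convergence are flagged, never silently fitted.
* `tolerance_index()` — post/pre ED50 fold shift (> 1 = tolerance).
* `trait_correlations()` — pairwise Pearson r on strain means, two-sided
  t-transform p-values (sidedness is unstated in the source; two-sided is
  conservative), Benjamini–Hochberg adjustment across the *unique* trait
  pairs only (the upper triangle, 10 pairs for 5 traits), not all matrix
  cells. The BH implementation clamps adjusted ≥ raw to keep the monotone
  contract exact under floating-point rounding.

## Resampling design choices

Subset draws depend only on the seed — never on phenotypes — so two traits
scored with one seed see identical subsets. Duplicate subsets are redrawn
(with a combinatorial feasibility pre-check and a `max_redraws` guard).
The per-iteration gene p-value is the minimum over the gene's blocks,
matching `gene_summary()`'s rule. Genes never reaching the cutoff are
omitted from the table by default (`include_fully_censored = TRUE` scores
them at the floor). Because p-values at or above the cutoff are censored *to the cutoff*
(rather than dropped), every iteration contributes a term once a gene is
tabulated; scores are therefore comparable across genes with different
numbers of sub-cutoff hits.

## Known limitations

* No kinship correction; exchangeable-strain simulations cannot expose the
  false-positive inflation that real strain phylogeny causes.
* The censored \(-\log_{10}\) sum is one member of a family of censored
  meta-statistics; no Fisher/Stouffer-style combination or trait weighting
  is offered, by design.
* Rank-1 recovery of the causal gene at `h = 0.7` is strong but not
  guaranteed: across seeds, the best of several thousand distinct null
  partitions occasionally rivals the (replicate-noise-diluted) causal
  block. This is a property of the method at this panel size, not of the
  implementation; the acceptance suite measures it at fixed seeds.
* Up-down von Frey threshold estimation is out of scope; the pipeline
  consumes already-estimated thresholds.
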