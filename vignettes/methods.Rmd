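---
title: "Models and methods behind chromarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`chromarch` compares the chromatin architecture of two cell types from
binned Hi-C contact maps, matched RNA-seq counts, and (optionally)
populations of 3D genome models. This vignette explains the models the
package implements, the parameters that matter, the behaviour of the
synthetic-data generators, and the design choices that were genuinely open.

## Coordinate conventions

All internal coordinates are 0-based, half-open `[start, end)`; bin indices
are global, dense, and 0-based. The two 1-based inputs — GTF annotations and
HiC-Pro `_abs.bed` bin indices — are shifted on ingest and shifted back on
export. Sex and mitochondrial chromosomes are dropped on ingest by default
(`autosomes_only = TRUE`), because A/B compartmentalization and eigenvector
sign conventions behave differently on sex chromosomes; structure-population
analyses accept whatever domains the population carries.

## Matrix balancing

`ice_normalize()` is plain alternating scaling: at each iteration the bias
of every covered bin is multiplied by its current balanced marginal
(normalized to mean 1), until the largest relative marginal deviation drops
below `tol` (default `1e-5`, max 200 iterations; non-convergence returns the
last iterate with a warning and metadata). Bins with zero coverage are
excluded and flagged `NA`; downstream analyses treat `NA`-bias bins as
masked. The final bias vector is rescaled so balanced marginals have mean 1,
which makes balanced values comparable across maps.

## The significance model

The caller follows the binomial model family with an equal-occupancy
distance background:

1. *Tested pairs.* All same-chromosome bin pairs at separation
   `min_sep` bins or more (default 2 — self and adjacent pairs are dominated
   by self-ligation artifacts in real data). Trans mode tests
   cross-chromosome pairs; by default only pairs with a nonzero observed
   count form the test family, which is documented as anti-conservative and
   can be widened with `n_zero_pairs`.
2. *Background.* Tested pairs are sorted by genomic distance and split into
   `b = 200` bins holding near-equal numbers of pairs (whole distance groups
   are never split, ties broken by distance order). The mean bias-corrected
   contact probability per bin is monotonized by weighted
   pooled-adjacent-violators, written in the package because `stats::isoreg`
   does not take weights. Prior probabilities sum to exactly 1 over tested
   pairs (PAV preserves the weighted mean, so this holds by construction).
3. *Test.* `p = P(X >= k)` under Binomial(`N`, prior), `N` the total count
   over tested pairs; BH step-up q-values within each test family (cis and
   trans are corrected separately, mirroring two separate caller runs);
   records kept at `q < 0.01`.

A pair with zero prior but nonzero count indicates model misfit and gets
`p = 0` with a warning rather than silently vanishing.

This is deliberately the *single-pass* equal-occupancy background: the
published caller's spline refinement of the null is out of scope, so exact
p-values on real data will differ; the calibration tests instead pin down
what this implementation guarantees — on pure-decay maps the fraction of
pairs called at `q < 0.01` stays below 0.1%, and planted 10-fold enriched
pairs are recovered.

## Compartments

Per chromosome: the balanced map is aggregated to a working resolution,
each diagonal of the aggregate is divided by its mean (observed/expected,
`0/0 -> 0`), columns with zero variance are masked, and the leading
eigenvector of the Pearson correlation matrix over unmasked bins is taken.
The eigenvector sign is arbitrary, so it is oriented positively with
per-bin gene density — the A compartment is gene-dense; if gene density is
uninformative the sign is left as computed. Chromosomes with fewer than 10
unmasked working bins, or a degenerate (featureless) correlation structure,
return all-`NA` with a warning. Labels are projected back to map-resolution
bins, so switch bookkeeping stays at 5 kb.

The working resolution matters. For real 5 kb maps the default is 100 kb:
5 kb correlation matrices are noise-dominated and quadratically large, and
compartments span hundreds of kilobases. The bundled synthetic genome,
however, plants an exactly periodic checkerboard (blocks of 10 x 5 kb): at
any working resolution that is a multiple of the block length every
aggregated diagonal is homogeneous in block relation, and the O/E step
cancels the compartment signal entirely. The synthetic pipeline
configuration therefore runs the eigen-decomposition at the map resolution,
where the within-diagonal mixture of same- and cross-block pairs carries
the signal. Real genomes, with irregular block lengths, do not have this
degeneracy.

Switch classification is a per-bin joint category (`A->A`, `A->B`, `B->A`,
`B->B`; `NA` if either side is masked) with percentages over non-`NA` bins.
TADs and genes get labels by majority vote over the fine bins they contain;
exact ties fall back to the sign of the mean eigenvector, and a zero mean
stays `NA` — a deliberate refusal to guess.

## TAD calling

`binsignal()` is the TopDom diamond statistic: for bin `i`, the mean
balanced contact over the `w x w` (default `w = 3`) rectangle spanning the
junction between bins `i` and `i+1`, clipped at chromosome ends. Boundaries
sit at strict local minima (plateaus take their leftmost bin, for
determinism); domains are the intervals between consecutive boundaries plus
chromosome ends, and domains shorter than 2 bins are merged into the
neighbor with the higher junction signal. TopDom's third stage — the
rank-based statistical filter on candidate boundaries — is omitted: the
package detects every planted boundary within one bin, at the cost of some
spurious boundaries on noisy maps, and the planted-recovery tests define
correctness for this component. Callers needing filtered boundaries can
import TopDom's own output via `read_tads()`.

## Gene-centric analyses

Expression is prefiltered (genes with fewer than 10 reads summed across all
replicates are dropped — the conventional prefilter of the count-based
normalization literature; the alternative per-replicate reading is noted as
ambiguous), collapsed by organ through summation, and normalized by
median-of-ratios size factors via `DESeq2::estimateSizeFactorsForMatrix`.
Tissue-enriched genes follow the at-least-5-fold rule against the maximum
of all other tissues, which makes the designation invariant to global
rescaling.

Interaction counting treats the gene locus as the TSS-TES body with no
flanks (promoters get their own treatment in the loop definition, and
nothing in the underlying study defines flanks); an interaction with both
anchors in one gene counts once. Log2 interaction ratios use pseudocount 1
so genes with zero calls in one condition remain defined, and the
between-set comparison is a two-sided Wilcoxon rank-sum test (the
underlying comparison is unnamed in the study design; rank-sum is the
package's choice and matches the other expression comparisons). Fully tied
data yields `p = 1` rather than `NaN`.

Promoter-TES loops require one anchor bin overlapping the strand-aware
promoter window (2,000 bp upstream to 200 bp downstream of the TSS) *and*
the other anchor bin containing the TES point. For a `+` strand gene the
TES is the half-open body end, so its bin may be the one after the last
body bin — the package uses the bin containing the TES coordinate, clamped
at chromosome ends. Anchor feature annotation applies the precedence
promoter > exon > intron > intergenic per anchor, two anchors per
interaction, so class counts sum to exactly twice the number of calls.

## Trans statistics

The overlap table counts, per condition and gene set, the trans calls with
at least one anchor bin touching at least one gene body of the set; an
interaction joining genes of both sets contributes to both cells, which is
the natural reading when the sets are disjoint gene families. Fisher's
exact test is the two-sided sum-of-less-likely-tables rule (`stats::
fisher.test`), with the sample odds ratio `ad/bc` reported. The random-gene
null redraws both sets uniformly without replacement per repetition
(default 10,000), takes per-cell medians across repetitions, rounds halves
up (the rounding rule is not externally specified; half-up is declared),
and re-runs the Fisher test on the median table. Bridge classification
labels each trans call AA, BB, or AB from its anchors' compartment labels;
calls with a masked anchor are excluded and tallied separately rather than
silently dropped.

## Structure-population geometry

Domains are points (one per TAD per structure) inside a nuclear sphere of
radius `R_nuc`. Radial positions are normalized to `[0, 1]`. Shells are
equal-*count*, not equal-volume: per structure, domains are ranked by
radius (ties broken by domain order) and split into 5 consecutive blocks,
remainders going to the innermost shells. Shell localization profiles are
per-structure probabilities averaged across structures, with the
across-structure SD reported. Trans neighbors are domains of *other*
chromosomes within 500 nm center-to-center — the models' sphere radii are
not available, so surface-to-surface distances are not computable, and the
threshold is configurable. The headline neighbor statistic is the mean
neighbor composition per query label; because "X% of queried A-domains
interact with compartment A" can also be read as a majority-vote fraction,
both statistics are computed and returned.

## The synthetic-data generators

The generators produce data with exactly the statistical structure the
analyses assume, so every estimator can be validated as a round trip. They
emulate: power-law cis decay (`d^-alpha`, default `alpha = 1`), a
checkerboard compartment pattern (10-bin blocks, within-type contact ratio
2, with 10% of blocks flipped in condition Y), block TADs (8-15 bins,
within-TAD ratio 2), lognormal per-bin coverage biases (`sigma = 0.3`),
Poisson counts scaled to a total depth (default 2e6 over two 2.5 Mb
chromosomes at 5 kb), a trans baseline at 1% of the shortest-distance cis
rate, and planted enriched pairs: each organ-set gene carries a cluster of
up to 5 promoter-anchored contacts at 10-fold enrichment in its own
condition (tissue-specific genes in real data show multiple enriched
contacts, and a single planted pair would drown in the compartment-driven
calls the single-pass background produces), plus 80 trans pairs per
condition at 20-fold, half anchored at own-set genes. Expression is
Poisson-gamma with baseline mean 300, dispersion 0.02 (replicate-level CV
around 15-20%, typical of deep bulk RNA-seq) and 6-fold planted enrichment;
under these conditions the 5-fold rule recovers on the order of 90% of
planted genes. Structures are random-walk chains of TAD centers whose radii
are drawn from a density proportional to `r^2 exp(c r)` with `c = beta` for
compartment A and `-beta` for B, so `beta = 0` is exactly uniform-in-sphere
and negative `beta` pulls A inward; the chain model is deliberately crude,
since the analysis operators, not polymer physics, are under test.

What the generators do *not* emulate — and hence what passing tests do not
show about real data: restriction-fragment structure and ligation
artifacts, chromosome-scale territory effects, irregular compartment block
lengths, copy-number variation, sub-compartments, and realistic polymer
connectivity in 3D. The calibration statements (null call rates, recovery
fractions) are statements about this generative model, not about any
particular experimental dataset.

## Numerical choices and degenerate inputs

- BH step-up is computed by sorted cumulative minima; permutation-invariant
  and capped at 1.
- ICE convergence is measured in the max norm of the marginal deviation;
  all-zero matrices are an error, non-convergence a warning with metadata.
- Duplicate contact triplets (including transposed duplicates) are summed,
  tolerating both upper- and lower-triangle dialects.
- Equal-occupancy binning never splits a distance group; if fewer distinct
  distances than bins exist, `b` is reduced with a warning.
- Output interaction records are sorted (chrom1, bin1, chrom2, bin2); all
  stochastic steps take explicit seeds; `run_full_analysis()` with a fixed
  seed is byte-reproducible, and the manifest records every parameter used.

## Problem sizes used in the shipped validation

The test-suite and acceptance runs use two-chromosome genomes of 100-500
bins per chromosome at 5 kb, depths of 2e5-2e6 contacts, 20-seed
replication for calibration statements, structure populations of 30-200
models, and 100-1,000 permutation repetitions — sizes chosen so the entire
validation executes in minutes on a single core while every statistic
remains well inside its asymptotic regime. The defaults of
`synth_params()` and `default_config()` are the documented study
conditions; scaling any of them up is a one-line configuration change.

## Known limitations

Single-pass background (no spline refinement), no loop clustering of
adjacent significant pairs, no sub-compartment calling or HMM smoothing of
labels, no nested TADs, center-to-center neighbor distances, and a
uniform-random gene null (no distance- or compartment-matched resampling).
These mirror the scope of the comparative analysis the package implements;
each is an extension point, not an accident.
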