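---
title: "Characterizing off-type grasses in clonal turfgrass: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing off-type grasses in clonal turfgrass: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offtypeR)
```

## The problem

Hybrid bermudagrass putting greens are planted with clonally propagated
triploid cultivars, most of them somatic-mutation derivatives of a single
family. Over time, patches of *off-type* grass appear that differ in color,
texture or growth rate from the planted cultivar. An off-type may be a
somatic mutant of the cultivar itself or an unrelated contaminant, and the
distinction matters for management. `offtypeR` implements a desk-scale,
fully testable version of the combined genotypic
(genotyping-by-sequencing, GBS) and phenotypic (morphometric) workflow used
to make that call, together with a seeded synthetic-data generator so that
every stage can be exercised and validated without access to raw sequencing
data.

## Genotype model

Samples are diploid, triploid or tetraploid, so genotypes are modelled as
unphased, sorted allele tuples at biallelic loci: a triploid heterozygote is
`0/0/1` or `0/1/1`. Three derived views drive the analyses:

* **Genotype class** — `HOM_REF` / `HET` / `HOM_ALT`, collapsing dosage
  within heterozygotes. GBS reads cannot be assigned to subgenomes without
  phasing, so dosage differences between heterozygotes are deliberately
  ignored by the differentiating-locus rule.
* **Dosage fraction** — alternate-allele count divided by ploidy, a
  coordinate in $[0,1]$ that makes genotypes comparable across ploidies.
* **Depth** — total and per-allele read counts, carried through pooling.

VCF 4.2 with `GT`/`DP`/`AD` is the on-disk representation (`read_vcf()`,
`write_vcf()`). Multi-allelic records are skipped with a logged count: the
differentiating-locus rule is defined on the three biallelic classes and has
no meaningful extension to a third allele, so we prefer an explicit refusal
over a silent decomposition. Coordinates are 0-based internally and 1-based
in VCF.

## Pooling and the dosage re-caller

Per-sample GBS depth is low (means near 5-10 reads per call), so clonal
replicates of each cultivar are pooled: per-allele depths are summed across
members and the pooled genotype is re-called. The re-caller is deliberately
deterministic: alternate dosage $= \mathrm{round}(p \cdot a/t)$ for ploidy
$p$, alternate depth $a$ and total depth $t$, ties rounded half away from
zero, missing when $t = 0$. Downstream stages consume only genotype classes
and depths, so replacing a probabilistic caller with a transparent rounding
rule changes nothing they observe while making every pooled result exactly
reproducible and unit-testable. Zero total depth is a missing call, never a
division error.

## Informative (differentiating) variants

A locus differentiates two pooled cultivars when their genotype *classes*
differ: homozygous-reference vs homozygous-alternate, or homozygous vs
heterozygous. Two heterozygotes of different dosage are *not* flagged. Both
pools must be called, and both must pass a read-depth window; sites failing
either condition are skipped *for that pair only*, since depth filtering is
applied per cultivar. The default window is $[40, 100)$ — at least 40 reads
to see heterozygotes reliably, below 100 to avoid collapsed repetitive
loci. Published descriptions of this filter disagree on whether depth 100
itself passes, so both dialects are supported
(`depth_window(40, 100, high_inclusive = TRUE)` selects the "no more than
100" reading); the default follows the stricter "less than 100".
`pairwise_matrix()` gives the per-pair counts, `differing_loci()` the union
with per-site flagging-pair counts.

## Cross-ploidy variant partition

`group_variant_set()` collects, per ploidy group, the sites where at least
one member carries an alternate allele (with an optional depth floor,
default 1 — no extra filter, since the totals it emulates were produced
without one). A site "present in a group" means non-reference evidence in
at least one member, mirroring how per-group variant calling emits records.
`venn()` partitions three such sets into the seven disjoint membership
regions by set algebra; additivity of each group's four regions to its
total is a tested invariant.

## Distance, ordination and the divergence screen

The pairwise distance is the mean absolute difference of dosage fractions
over co-called sites. For diploids this is the usual identity-by-state
sharing rescaled to $[0,1]$; across ploidies it remains bounded and metric
(it is an $L_1$ mean of per-site metrics — symmetry, zero self-distance
and the triangle inequality are property-tested). Pairs with no co-called
sites are a hard error by default rather than a silently imputed value;
`allow_missing_pairs = TRUE` masks them as `NA` instead.

Ordination is classical (Torgerson) MDS: double-center the squared
distances, eigendecompose, scale eigenvectors by root eigenvalues. Only
positive eigenvalues are kept; asking for more dimensions reduces the
output with a warning. Each axis's sign is fixed so its largest-magnitude
coordinate is positive, making coordinates deterministic. On distances that
are exactly Euclidean the embedding reproduces the configuration to
numerical precision, which the tests verify by orthogonal Procrustes
against planted plane geometries.

The original divergence call — which samples sit away from the standard
cultivars — was made visually from the MDS plot. `divergence_screen()`
makes it reproducible: each sample is scored by its mean distance to the
reference standards (self excluded); the score is converted to a robust z
against the references' own scores, $z = (s - \mathrm{med}) /
(1.4826\,\mathrm{MAD})$, and samples with $z > 3.5$ (the conventional
robust-outlier cut, exposed as a parameter) are flagged. Reference samples
are scored and can flag too. A zero MAD with scores above the median flags
those samples with a warning; if every score is equal nothing is flagged.
The reference panel should span the standard cultivars, including any
genuinely distinct ones: between-cultivar spread is what gives the MAD its
scale, and a baseline drawn from a single clone collapses to measurement
noise and over-flags.

## Flow-cytometry genome size

2C DNA content is the plain fluorescence ratio: sample mean FL2-A over the
internal standard's, times the standard's genome size (default 1.67 pg/2C,
the *Sorghum bicolor* BTx623 standard). No correction for the standard's
own CV is applied. Classification against a reference table picks the entry
with the smallest relative deviation, refusing (`NA`) beyond 15% by
default; ties break toward the lower ploidy and are logged. The shipped
reference table carries only the two published triploid values
(Tifgreen-family 1.61 pg/2C, Tifway 1.37 pg/2C): diploid and tetraploid
reference sizes are not invented, and must be supplied by the user to
classify those ploidies.

## Morphology clustering

Replicate measurements (4 pots x 3 stolons x 2 dates = 24 records per
sample) are averaged per sample before clustering; the leaf length:width
ratio is derived from the aggregated leaf means rather than averaged per
record, which is stabler under measurement noise. Clustering is K-means
(Lloyd's algorithm) with k-means++ initialization from a fixed seed and 10
restarts, keeping the lowest within-cluster sum of squares; an empty
cluster is reseeded from the farthest point and the within-cluster sum of
squares is asserted non-increasing at every iteration. Traits are clustered
on their raw scales by default, matching the behavior of the clustering
procedure the workflow descends from; `standardize = TRUE` is available
because the traits' units are heterogeneous, and both fits are reported
when the choice matters.

Fit is summarized by $R^2 = 1 - SSW/SST$ and by the cubic clustering
criterion (CCC), computed from the published approximation: the data's
covariance eigenvalues define a hyperbox null; the effective dimensionality
$p^*$ is found by a fixed-point iteration (capped at 100 iterations,
tolerance $10^{-10}$, $p^* < q$) on the cell-edge scaling; the null
expectation $E[R^2]$ then yields
$CCC = \ln\!\big[(1 - E[R^2])/(1 - R^2)\big]\sqrt{n p^*/2}\,/\,(0.001 +
E[R^2])^{1.2}$. CCC is positive when the partition explains more variance
than uniform hyperbox sampling would, negative when less. It is undefined
at $k = 1$ (the package refuses rather than divide) and diverges with a
warning at $R^2 = 1$. Per-cluster trait means and SDs are reported with a
difference flag per trait and cluster pair: flagged when the mean $\pm$ SD
intervals do not overlap, the same SD-based reading used for the published
cluster profiles.

## The synthetic-data generator

The generator emulates the study design so the pipeline can be validated
end to end:

* **Design** (`study_cultivars()`): six triploid standard cultivars with
  six clonal replicates each — five of shared family origin plus one
  genetically distinct cultivar — 47 unknown putting-green samples (42
  clonal members of the standard families, 5 independent contaminants),
  and diploid/tetraploid progenitor selections.
* **Genotypes**: a per-locus consensus alternate fraction shared across
  ploidies; per-family founders follow the per-ploidy consensus dosage
  except at loci selected with the family's divergence probability, where
  dosage is uniform over the $p+1$ genotypes; samples add rare somatic
  single-allele dosage steps. Depths are negative-binomial (GBS depth is
  overdispersed, so Poisson would understate missingness); allele depths
  are binomial around the true dosage fraction perturbed by the
  per-read error rate. With error rate exactly 0, reads reflect the true
  allele mix deterministically up to integer rounding, so noise-free
  configurations are exactly reproducible and pooled re-calls provably
  recover founders wherever pooled depth exceeds twice the number of
  contributing members. A zero-read call is missing.
* **Defaults**: per-ploidy depth means 9.5/4.9/7.4 (2x/3x/4x), pooled
  depth then lands near 30; raw read totals log-uniform over 1.3-13.9
  million; within-family divergence 0.005 and distinct-cultivar divergence
  0.05 (both chosen to match the observed proportions of differentiating
  loci between family cultivars, about 0.6%, and against the outside
  cultivar, about 5%); contaminant and progenitor divergence 0.30; somatic
  mutation rate $10^{-3}$ per locus per sample; sequencing error 0.01;
  negative-binomial size 2; 2000 loci by default — large enough for stable
  distances and small enough that the full workflow runs in seconds.
* **Morphology**: three clusters at the published profile (internode
  34.6/21.9/24.7 mm, leaf length 14.9/9.9/29.8 mm, stolon diameter
  0.7-0.8 mm, leaf width 2.0-2.2 mm; sizes proportional to 14/26/12).
  Variation is hierarchical: each sample draws its true trait value from
  its cluster's distribution, and each replicate record adds measurement
  noise around the sample value. A flat record model was rejected because
  averaging 24 replicates would shrink between-sample spread by
  $\sqrt{24}$ and mark even the 0.1 mm stolon-diameter gap as
  significant, contradicting the pattern the workflow is meant to
  reproduce (only internode length, leaf length and the length:width
  ratio differ among clusters). SDs default to values that reproduce that
  pattern (internode 4-5 mm, leaf length 2.5-4 mm, stolon 0.08 mm, width
  0.25 mm).
* **Flow cytometry**: sample FL2-A is the standard's reading scaled by the
  ratio of configured 2C size to 1.67 pg, with 2% multiplicative CV. 2C
  sizes default to the published triploid value (1.61 pg) scaled
  proportionally to ploidy — a modelling convenience for the generator
  only; the classifier's shipped reference table remains restricted to
  published values.

What the generator does *not* emulate: read-level sequence content,
alignment and tag-discovery artifacts, linkage between loci, aneuploidy,
and any correlation between genotype and morphology (cluster labels are
assigned independently of family). Passing recovery tests on this
generator therefore validates the *statistical machinery* — the flag rule,
pooling arithmetic, distances, the screen, the clustering diagnostics —
not the upstream variant calling, and says nothing about whether real
off-types are somatic mutants.

## Numerical conventions

* Rounding ties in the dosage re-caller: half away from zero (fixed,
  testable convention).
* MDS axis signs: largest-magnitude coordinate positive.
* K-means ties in assignment: first (lowest-index) nearest center.
* Degenerate inputs: zero pooled depth is a missing call; a zero reference
  MAD triggers the documented flag-above-median convention; CCC refuses
  $k = 1$ and $n \le k$; $R^2 = 1$ returns `+Inf` with a warning.
* All randomness flows from explicit integer seeds (`sim_config(seed = )`,
  `kmeans_cluster(seed = )`); repeated runs are byte-identical, and the
  pipeline writes no timestamps into artifacts.

## Problem sizes used in validation

The test suite and the acceptance script run the generator at 200-2000
loci and 47-95 samples — the package's chosen desk scale, at which every
stage completes in seconds while leaving depth, divergence and cluster
structure at the emulated study's parameter values. The divergence-screen
recovery checks use the full study layout (36 references, 47 unknowns)
because the robust z baseline needs the between-cultivar spread of a real
reference panel; the morphology recovery checks shrink the trait SDs
five-fold to make cluster membership unambiguous, as a recovery oracle
requires.

## Known limitations

* The informative-variant rule is defined for pools of equal ploidy only;
  cross-ploidy comparisons go through the dosage-fraction distance
  instead.
* Multi-allelic loci are dropped, not decomposed.
* The divergence screen assumes the reference panel spans the expected
  cultivar variation; with fewer than a dozen references, or references
  from a single clone, its false-positive behavior degrades (see above).
* CCC inherits the approximation's assumptions (roughly hypercubic
  clusters, modest dimensionality); its absolute value is a diagnostic,
  not a test statistic.
* Genome-size classification is only as good as the reference table; the
  shipped table covers triploids only.

## A worked example

```{r example, eval = FALSE}
library(offtypeR)

cfg <- sim_config(seed = 1)
sim <- simulate_study(cfg)
paths <- write_study_data(sim, "study")

rc <- run_config(
  vcf = paths[["vcf"]], metadata = paths[["metadata"]],
  morphology = paths[["morphology"]], flow = paths[["flow"]],
  out_dir = "study/out"
)
res <- run_pipeline(rc)

res$pairwise_matrix          # differentiating loci between cultivar pairs
res$venn                     # variant sharing across ploidies
subset(res$screen, flagged)  # genetically divergent samples
res$clusters                 # morphology K-means fit, R^2, CCC
```
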