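---
title: "Methods: window-based differential methylation and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based differential methylation and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dmrkit implements the statistical core of a transgenerational
epigenomics study design: MeDIP-seq coverage compared between a
control and an exposure lineage in fixed 100 bp genomic windows,
differentially methylated regions (DMRs) assembled from significant
windows by edge extension, differential expression of mRNA / lncRNA /
small noncoding RNA count tables, interval overlap analysis, and a
histopathology disease-frequency statistic. Everything is validated
end to end on synthetic data with known ground truth. This vignette
records the models, the parameter choices, and the design decisions
that were genuinely open.

## The window model and the exact test

The genome is tiled into consecutive 100 bp windows (terminal
remainders are kept as truncated windows so the tiling partitions
each chromosome; densities are length-normalized). Each window
carries one MeDIP fragment count per pooled sample; counts are
modeled as negative binomial with mean $\mu$ and dispersion $\varphi$
(variance $\mu + \varphi\mu^2$; $\varphi = 0$ is the Poisson limit).
The study design has three pooled samples per lineage, so the test
must work at $n = 3$ per group.

Testing proceeds in four steps, all implemented in the package:

1. **TMM normalization.** Each sample is compared with the
   highest-depth sample; among features nonzero in both, the 30% most
   extreme log-ratios and 5% most extreme average abundances are
   trimmed from each tail and the scale factor is the
   precision-weighted mean of the remaining log-ratios, rescaled so
   factors have geometric mean 1. A `total` fallback (library size
   only) is available.
2. **Common dispersion.** For every feature and group, the normalized
   within-group mean $m$ and variance $v$ supply the moment identity
   $v = m + \varphi m^2$. The default estimator solves it in
   aggregate, $\hat\varphi = \max(0, \sum(v - m) / \sum m^2)$, over
   feature/group pairs with $m$ above a floor of 1. We also ship a
   per-feature median variant (`method = "median"`); we measured it
   recovering only about two-thirds of a true $\varphi$ of 0.1 at
   $n = 3$ (the per-feature ratio is strongly right-skewed, so its
   median sits well below its mean), which makes the exact test
   anticonservative, and we therefore made the pooled estimator the
   default. The estimate is clamped to $[0, 10]$.
3. **Conditional exact test.** Counts are rescaled to a common
   effective library size (the geometric mean of effective sizes) and
   rounded. Under the null the group sums $A$ and $B$ over $n_1$ and
   $n_2$ samples are negative binomial with means $n_1\mu$, $n_2\mu$
   and dispersions $\varphi/n_1$, $\varphi/n_2$. Conditioning on
   $T = A + B$, the two-sided p-value sums the probabilities of every
   split no more probable than the observed one (probability-mass
   ordering; ties included via a $1 + 10^{-7}$ relative tolerance, the
   standard guard against floating-point ties). $T = 0$ gives $p = 1$
   by convention. In the Poisson limit the conditional law of $A$ is
   exactly binomial, which supplies an independent enumeration oracle
   used in the tests.
4. **Fold change and FDR.** The direction of change is
   $\log_2((\bar{x}_{exp} + 0.5)/(\bar{x}_{ctl} + 0.5))$ on normalized
   means (the pseudo-count keeps zeros finite), and Benjamini-Hochberg
   step-up q-values are computed in-package and cross-checked against
   `p.adjust`.

No exact numeric agreement with any external count-testing package is
claimed; the procedure above is fully specified on its own terms and
is tested against independent oracles instead.

## DMR construction

A window with $p < 10^{-6}$ seeds a DMR. Edges extend by absorption:
any window with $p < 0.1$ whose interval lies within 1000 bp of the
current region span is absorbed, repeatedly, until no such window
remains; regions whose extensions meet are merged. Three points were
open and decided as follows:

* **Fixed point semantics.** The extension sentence describes a fixed
  point, and the absorption closure equals the connected component of
  sub-0.1 windows under "gap at most 1000 bp" linkage that contains
  the seed. The implementation computes components in one pass; a
  brute-force iterate-until-stable oracle verifies exact agreement on
  hundreds of random instances.
* **Merging.** Two seeds closer than the extension reach cannot both
  satisfy the stopping condition separately, so chained seeds merge
  into one region.
* **"Multiple-window" status.** A DMR is multiple-window when at
  least two windows significant at the seed threshold sit on
  immediately adjacent tiles (the literal reading of "neighboring");
  `neighbor_rule = "any"` relaxes this to any two significant windows
  in the region.

The reported direction of a DMR is the fold-change sign at its most
significant window, matching the one-ratio-per-region convention of
supplemental DMR tables in this literature. CpG density is the mean
over spanned windows per 100 bp; lengths are binned at 1 kb; clusters
are maximal runs of at least 3 DMRs with consecutive start-to-start
gaps within 2 Mb (the clustering parameters are stated, not inferred
from any source, and are exposed as arguments).

One behavior worth knowing: with a calibrated test, about 10% of null
windows sit below the 0.1 extension threshold by construction, so at
dense coverage the extension rule absorbs genuine null windows and
called DMRs run several times longer than the planted effect regions
(planted 300-500 bp regions yield called regions with median length
around 2 kb under the standard design below, with the modal length
still in the 1 kb bin). On sparse real data, where discrete counts
push many window p-values to 1, extension is much less greedy.

## Overlap and annotation conventions

Gene association uses an inclusive gap rule: a gene is associated
with a DMR when the interval gap is at most 10 kb (overlap counts as
gap 0), strand ignored, gene body as anchor — the 10 kb margin lets
flanking regulatory sequence such as the promoter count as proximal.
Interval Venn overlap calls an element "common" when it overlaps at
least one element of the other set by 1 bp or more; because one
interval can overlap several on the other side the two per-side
counts can differ, so both are reported along with their mean (which
is why a shared count can legitimately be a half-integer).
Small noncoding RNAs without a genomic location are excluded from
interval overlaps, with a message recording how many. Category and
pathway tallies are raw distinct-gene counts from user-supplied
static mapping files; no enrichment statistic is computed, and genes
absent from a mapping are tallied as `unknown`.

## The pathology statistic

For each abnormality category (epithelial atrophy, hyperplasia,
vacuoles) and each observer, the disease cutoff is the control mean
plus two sample standard deviations (ddof = 1) of that observer's own
control scores; an observer calls an animal diseased when any
category count is strictly above the cutoff, and the animal is
declared diseased on 2-of-3 observer consensus. Control animals are
classified under the same rule, which is what produces a nonzero
control background frequency. Lineages are compared with a two-sided
Fisher's exact test (probability-mass ordering over the
hypergeometric support; any zero margin gives $p = 1$).

Decisions made where the procedure was underdetermined: cutoffs are
per observer rather than pooled (observers score independently before
consensus; the pooled variant is exposed); the cutoff comparison is
strict; and the test is two-sided. Because counts are discrete and
control means are low, the mean+2SD rule is lenient at low rates —
with Poisson(0.5) baselines and 26 controls the control disease
frequency averages several percent, not zero; this is a property of
the rule, reported rather than hidden.

## What the generator simulates — and what it does not

The synthetic-data module reproduces the study's structure: a
CpG-sparse genome (CpGs placed by a blockwise local-density process
with occasional 4x-denser patches, mean 1.5 CpG per 100 bp, so the
modal window carries 1-2 CpGs); three pooled samples per lineage;
negative binomial window counts (mean 50 fragments per window,
dispersion 0.1); 100 planted DMRs of 300-500 bp (window-aligned,
separated by at least 5 kb so extension cannot bridge two truths) at
8-fold, directions split exactly 50/50; 3,000 transcripts (2,000
mRNA, 500 lncRNA, 500 sncRNA subclassed into miRNA/piRNA/tRNA/other,
20% of sncRNA left unplaced) with 5% planted 8-fold expression
effects at mean count 100; and observer-scored pathology for 26
control and 27 exposed animals, three observers, Poisson(0.5)
baselines with 40% of exposed animals carrying a +2.0 excess rate in
at least one category. Observer replicates are independent Poisson
draws around a per-animal latent rate — an invented noise model, as
inter-observer variability is not characterized in this literature.

Fragment emission materializes each window count as that many 300 bp
fragments (the sonication target size) centered on the window
midpoint. Near chromosome ends fragments are shrunk symmetrically
about the midpoint rather than clipped on one side: one-sided
clipping would move terminal midpoints into the neighboring window
and break the exact count round-trip that the test suite relies on.

Deliberate simplifications, which bound what the synthetic validation
can show: baseline coverage is constant across windows (no coupling
of MeDIP efficiency to CpG density, no GC or mappability structure);
there is no read-level error model, alignment noise, or library-size
imbalance beyond what the NB draws produce; planted effects are
homogeneous multiplicative folds; and transcript classes share one
baseline mean. Passing the recovery criteria therefore demonstrates
the correctness and calibration of the statistical machinery under
its stated model, not robustness to the artifacts of real libraries.

## Validation design and problem sizes

The test suite validates every operation against an independent
oracle (enumeration, brute force, closed form, or an established base
R routine), and the end-to-end behavior on fixed-seed synthetic
studies of these sizes, chosen to exercise the standard design at
desk scale: a 5 Mb chromosome (50,000 windows) for planted-DMR
recovery and for null calibration; 3,000 transcripts for expression
recovery; 100 replicate pathology studies for power and size; 200
random window instances (up to 1,000 windows) for the DMR fixed-point
oracle; exhaustive 2x2 tables to total 12 plus 1,000 random tables to
total 60 for the Fisher oracle. `scripts/acceptance.R` re-runs the
same designs from scratch at a caller-supplied seed and writes every
headline quantity it computes as JSON.

## Known limitations

* The exact test conditions on a rounded common-scale total; with
  severe library-size imbalance the rounding step loses information
  (TMM factors mitigate composition bias but not depth loss).
* The pooled dispersion estimator assumes one shared dispersion per
  feature class; tagwise or trended shrinkage is out of scope.
* DMR length inflation under dense coverage, discussed above, is a
  property of the published extension rule, not of this
  implementation.
* Interval operations assume a single shared chromosome naming
  scheme; no liftover or alias resolution is attempted.
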