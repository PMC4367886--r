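---
title: "Locus-specific LINE-1 promoter methylation: models and methods"
author: "line1meth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus-specific LINE-1 promoter methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(line1meth)
```

## The problem

LINE-1 retrotransposons make up about 17% of the human genome, and the
CpG-rich promoters of full-length human-specific (L1Hs) copies are
normally densely methylated. In tumors this methylation is broadly
eroded, but global (degenerate) assays average thousands of dispersed
copies into a single number and hide two questions that matter for
biology and for biomarker design: do *individual* LINE-1 loci change
methylation to the same degree, and within one promoter, are all CpGs
equally affected?

`line1meth` implements an analysis pipeline for these questions at the
level of individual bisulfite amplicon loci and individual sequenced
molecules:

1. a **simulator** producing bisulfite reads and paired tumor–normal
   cohort tables with fully known ground truth;
2. **read processing**: bisulfite-aware alignment and per-read per-CpG
   methylation calls into read × CpG matrices;
3. **pattern metrics**: per-CpG methylation profiles, sliding-window
   methylation entropy, paired Wilcoxon comparisons, and ±10-point
   hypo/hypermethylation calls;
4. a **pattern classifier** for the read-level architectures seen in
   deep bisulfite sequencing (uniform, allelic, patchy);
5. **seed analysis**: projection onto a shared consensus CpG frame,
   detection of recurrently hypomethylated "seed" CpGs and protected
   CpGs, and their base-pair spacing;
6. a **diagnostic cascade**: per-marker paired tests, FDR control,
   penalized multivariate logistic regression, ROC/AUC.

Because no real patient cohort ships with the package, every claim the
package makes is validated against its own generative models (known
truth) and against independent brute-force oracles in the test suite.

## The generative model

Single molecules at a locus with $k$ CpGs are drawn from one of three
epiallele architectures (`epiallele_model()`):

* **uniform** — each CpG is methylated i.i.d. Bernoulli($p$). With $p$
  near 1 or 0 this is the uniformly methylated/unmethylated molecule
  population of healthy tissue or of a fully demethylated tumor.
* **allelic** — a two-class mixture: with probability $w$ a molecule is
  drawn from a high-methylation class (Bernoulli($p$), $p$ high), else
  from the mirrored low class (Bernoulli($1-p$)). This models loci where
  reads fall into two clearly separated groups.
* **patchy** — molecules start at Bernoulli($p$) and are then locally
  demethylated around *seed CpGs*: seed $s$ demethylates CpG $j$ with
  probability $q \cdot d^{|j-s|}$, with seed strength $q$ and per-CpG
  spread decay $d$. Distance is counted in CpG steps (the matrices the
  pipeline analyses are CpG-indexed), and spreading is symmetric.

The analytic per-CpG methylation probability of each architecture is
available (`epiallele_mean()`), and the simulator's empirical output is
required (in tests) to match it within four binomial standard deviations
at 10,000 molecules.

Bisulfite chemistry is applied per molecule (`bisulfite_convert()`):
unmethylated cytosines read as T, methylated CpG cytosines as C. Three
error processes, all configurable in `simulation_config()`, default to
realistic magnitudes: conversion failure 0.5% (an unmethylated C
retained — the basis of the per-read conversion QC), inappropriate
conversion 0.5% (a methylated C read as T), and per-base sequencing
substitution error 0.2%. Only the top (sense) strand is simulated, as
locus-specific assays target one strand per amplicon.

Cohort-level tables emulate pyrosequencing output: per sample and locus
a mean methylation percentage drawn as a binomial proportion at an
effective depth of 100, around the architecture's analytic mean. Study
dimensions emulate a typical locus-specific LINE-1 cohort design:
~20 tumor–normal pairs per tissue, 11 loci (5 autosomal, 6 X-linked,
including one short 7-CpG locus; amplicons ~190–430 bp with 7–31 CpGs),
and 100–1000 reads per locus (default 500; the analysis scripts use 200
and the tests 12–500, trading replicates against depth). Read depths
are power-motivated choices, not platform-fidelity claims.

### Determinism

A `simulation_config()` carries an integer seed; identical
configurations produce byte-identical FASTQ/TSV output. Entry points
(`simulate_sample()`, `simulate_cohort()`) derive a sub-seed per
condition and sample from the config seed, so streams do not collide;
this uses R's global RNG in the idiomatic way (seeded at entry) rather
than threading an explicit generator object. `run_diagnostics()` seeds
its fold split locally and restores the caller's RNG state.

## Read processing

Reads are aligned semi-globally (the read end-to-end, free end gaps on
the reference side) with bisulfite-aware asymmetric scoring: read T
opposite reference C scores as a match, read C opposite reference T does
not. Scores are +1/−1 with affine gaps (open 4, extend 1); both
orientations are tried and the better kept. Alignment uses
`Biostrings::pairwiseAlignment()`; a hand-written Gotoh dynamic program
serves as the independent oracle in the tests, never in the pipeline.
Identity below 0.80 over aligned columns discards a read.

Methylation calls (`call_read()`) read C→methylated, T→unmethylated,
anything else missing, at each CpG. Non-CpG reference cytosines measure
bisulfite conversion per read: if more than 5% are retained as C the
read is discarded (`max_retention`), a standard conversion-QC practice;
the threshold is exposed because the appropriate value depends on the
non-CpG cytosine density of the locus. With all error rates zero,
`build_matrix()` must reproduce the simulator's ground truth
cell-for-cell — the round-trip property in the acceptance tests.

## Pattern metrics

**Per-CpG means** are column-wise fractions of methylated calls;
coverage below 10 non-missing calls flags a CpG missing (both
thresholds configurable; 10 is an engineering floor, not a biological
constant).

**Methylation entropy** over sliding windows of $b = 4$ CpGs (stride 1):

$$ME = \frac{1}{b} \sum_i \frac{n_i}{N} \log_2 \frac{N}{n_i}$$

where $n_i$ counts reads carrying epiallele $i$ (the exact 4-CpG
methylation pattern) and $N$ is the number of reads with complete calls
in the window. $ME = 0$ when all molecules agree, $ME = 1$ when all
$2^b$ patterns are equally frequent. Reads with a missing call inside a
window are dropped from that window only (listwise per window); windows
with fewer than 10 complete reads are flagged missing. Uniform noise
produces flat entropy, allelic mixtures stable moderate entropy, and
patchy architectures *fluctuating* entropy along the locus — the
signature the classifier uses.

**Comparisons** between tumor and normal are paired Wilcoxon signed-rank
tests over CpG sites (profiles) or windows (entropy); pairing over sites
matches the plotted per-CpG averages. Zero differences are dropped
(Wilcoxon's original treatment), the exact null is used up to 25
non-zero differences, and the normal approximation with continuity
correction above.

**Change calls** use the conservative locus-level rule: a locus is
hypomethylated when tumor minus normal is below −10 percentage points,
hypermethylated above +10, strictly — a delta of exactly ±10 is
unchanged. The rule is antisymmetric under swapping tumor and normal.
Sample-level summaries count pairs with only hypomethylated loci, only
hypermethylated loci, both, or none.

## Pattern classification

The read-level architectures are classified by an explicit rule, every
constant of which is configurable and reported with the call
(`pattern_config()`): per-read mean methylation is computed; `f_hi` is
the fraction of reads with mean ≥ 0.8 and `f_lo` the fraction ≤ 0.2.
Uniformly methylated requires `f_hi ≥ 0.9` (unmethylated analogously);
allelic requires both tails ≥ 0.2 and their sum ≥ 0.8; patchy requires
an entropy *range* across windows ≥ 0.3 when no uniform rule fires.
Anything else — including genuinely intermediate uniform methylation, as
in tissue at base methylation 0.85 — is *indeterminate*, a first-class
outcome rather than a forced nearest class. These architecture classes
are qualitative descriptions in the field; the rule above is this
package's quantitative operationalization of them.

The canonical well-separated parameterizations used for validation
(`canonical_models()`) are: uniform at 0.95/0.05, allelic at 0.95 with
mixture weight 0.5, and patchy at base 0.98 with seed strength 0.9 and
decay 0.5, seeds ≥ 8 CpG steps apart. The high patchy background is
deliberate: patches of demethylation are described as consistent across
molecules on an otherwise uniformly methylated background. At base 0.9
the Bernoulli background alone holds every window's entropy near 0.5–0.8
and the entropy-range signature vanishes; at 0.98 the between-seed
windows drop to near-zero entropy and the range cleanly exceeds the 0.3
threshold. Under these conditions per-class recall is ≥ 0.95 at 500
reads (measured at 1.0 over 100 replicates in the acceptance tests).

```{r classify-demo}
set.seed(1)
m <- read_meth_matrix(draw_epialleles(canonical_models(25)$patchy, 25, 300),
                      "demo", "s1")
classify_pattern(m)[, c("label", "f_hi", "f_lo", "entropy_range")]
```

## Consensus projection and hypomethylation seeds

Each locus carries a map from its local CpGs to a consensus CpG index
and representative base-pair position in the shared L1Hs promoter frame.
The map is curated input (multiple sequence alignment of loci to the
consensus is upstream of this package); `example_loci()` constructs a
synthetic panel where the map is known by construction. Projection
averages per-CpG means over all (locus, sample) observations at each
consensus index, unweighted per observation (read-count weighting would
let deeply sequenced loci dominate; unweighted averaging is the
package's documented choice), requiring ≥ 3 observations.

Hotspots are detected on the per-index tumor−normal delta:
a hypomethylation seed is a local minimum at or below
median − 1.5·MAD, a protected CpG a local maximum at or above
median + 1.5·MAD (MAD scaled 1.4826; `k` configurable). Median/MAD
centering makes the rule invariant to constant shifts; extrema must be
strict against a neighbour, so a flat profile yields nothing. Spacing
between consecutive seeds is reported in base pairs with the fractions
falling in the 40–60 and 80–100 nt bands; no spectral analysis is
attempted. The local-extremum+robust-threshold rule is this package's
operationalization of visually identified peaks.

Recovery is validated by planting seeds: with 2 loci × 3 samples,
effect ≈ 73 points at the seed, recall is ≥ 0.9 with ≤ 1 false positive
per run (measured 1.0 and 0.0 over 100 replicates), and seeds planted
50 nt apart are recovered at median spacing 50.

## The diagnostic cascade

For paired designs each marker (locus) is tested by exact paired
Wilcoxon; for unpaired blood-style designs by Kruskal–Wallis across
groups. P-values are corrected by Benjamini–Hochberg and markers with
q < 0.05 enter a multivariate logistic model giving each sample a
probability π of being tumor. Because FDR-selected markers on ~20 pairs
frequently separate the classes perfectly, the model is fitted with a
small L2 penalty (λ = 10⁻⁴ on standardized predictors, intercept
unpenalized) by Newton iteration (`ridge_logistic()`), guaranteeing a
finite optimum under separation.

Two AUCs are reported. The in-sample AUC of the final model is
optimistic, because the same data selected the markers. The headline
number is therefore the out-of-fold AUC from 5-fold cross-validation in
which the *entire* cascade — testing, FDR selection, model fitting — is
re-run inside each training fold; folds split by pair so a patient never
straddles the boundary, and training folds selecting no marker predict
their training class rate. Under a null cohort (no effect, 14 markers,
20 pairs) this out-of-fold AUC sits at 0.50 and the marker selection
fraction stays below the 5% FDR level; under a single −15-point marker
(SD 5) the marker is selected essentially always and the out-of-fold
AUC is ≈ 0.97.

AUC itself is the tie-corrected Mann–Whitney rank statistic, which
equals the trapezoidal area under the step ROC (a property test).

```{r cascade-demo}
study <- example_study_config(seed = 3, n_pairs = 20)
cohort <- simulate_cohort(study$config)
model <- run_diagnostics(as_marker_table(cohort$table))
model
```

## What the synthetic data does and does not show

The generator reproduces the *statistical structure* of a
locus-specific LINE-1 methylation study — the
three read-level architectures, paired cohorts with locus-specific
effects in both directions, homologous loci on a shared consensus frame,
measurement noise of the assays — with known truth, which is what the
validation requires. It does not reproduce several features of real
data: per-pair heterogeneity (each synthetic pair shares the cohort's
tumor models, so sample-level category counts are more uniform than a
real cohort's), PCR and sequencing-platform artifacts (homopolymer
errors, chimeras, duplicates), cell-mixture effects within a tissue,
X-inactivation differences between sexes, and any correlation between
loci beyond the shared architecture. Passing tests therefore demonstrate
that the pipeline measures what it claims under its stated model, not
that real cohorts will behave as cleanly.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open externally (BED); matrices and CpG
  indices are 1-based inside R.
* All-zero paired differences give p = 1 rather than an error; constant
  markers give flagged-NA correlations; flat deltas give empty hotspot
  sets; fewer than two hotspots give an empty spacing summary.
* Wilcoxon exactness: the exact null is used up to n = 25 non-zero
  differences and degrades gracefully (with a warning suppressed) to
  the continuity-corrected normal approximation when ties preclude it.
* The Kruskal–Wallis statistic uses the tie-corrected form; its
  chi-square p-value is an approximation checked against an exact
  permutation null at small n in the tests.
* Problem sizes in tests and the acceptance script (12–500 reads,
  25-CpG loci, 100–200 replicates) were chosen to give tight
  Monte-Carlo error on every asserted proportion while keeping a full
  validation run in minutes on one core.

## Known limitations

* The aligner assumes amplicon reads spanning (part of) one known
  locus; there is no multi-mapping resolution across the LINE-1 family
  and no whole-genome mode. Locus specificity must come from the
  amplicon design.
* Only the top strand is modelled and called.
* The pattern classifier is rule-based by design, mirroring the
  descriptive treatment of the architectures; mixed architectures land
  in `indeterminate` rather than being resolved by a mixture model.
* The consensus map is trusted input; a wrong map silently produces a
  wrong projection.
* Blood-style group designs share the cascade code path but have seen
  less validation than the paired design.
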