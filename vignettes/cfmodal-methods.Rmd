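---
title: "Methods: multimodal cfDNA analysis with cfmodal"
author: "cfmodal authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal cfDNA analysis with cfmodal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmodal)
```

# Scope and model

`cfmodal` implements an analysis pipeline for whole-genome cell-free DNA
(cfDNA) methylation sequencing that exploits the fact that a direct
(bisulfite-free) conversion chemistry leaves the underlying DNA intact, so a
single sequencing run yields several readouts at once:

1. **DNA methylation** — per-CpG converted/unconverted call counts, pooled
   into fixed-width genomic windows;
2. **tissue of origin** — the sample methylome modelled as a nonnegative
   mixture of reference tissue methylomes;
3. **fragmentation** — the cfDNA fragment-length distribution, shaped by
   nucleosomal protection;
4. **copy number** — binned read-depth ratios.

Because the plasma cohort such a study rests on cannot be redistributed, the
package pairs every analysis stage with a synthetic-data generator that
reproduces the *statistical structure* each stage consumes. All pipeline
claims verified by the test suite are claims about that structure.

# Window methylome

Per-CpG call tables (chrom, start, end, converted, unconverted; 0-based
half-open) are masked against SNP/blacklist/centromere interval sets and sex
chromosomes, then pooled into windows tiling each chromosome from position 0.
The level of window $w$ in sample $s$ is
$\sum_i m_{si} / \sum_i (m_{si}+u_{si})$ over the CpGs $i \in w$; window
coverage is total calls over the number of known CpG positions in $w$.

Key parameter choices:

* **Window width** 1 kb for classification and PCA (1 Mb available for
  coarse summaries).
* **Coverage filter**: windows with *cohort-wide mean* coverage < 2 are
  dropped. Whether this filter should be per sample or cohort-wide is
  genuinely open; the cohort-wide mean keeps one common window universe for
  PCA and cross-validated classification, which is what every downstream
  stage needs. A retained window that happens to have zero covered CpGs in
  one sample is missing for that sample, and missing values are excluded
  pairwise (PCA and DMR tests drop incomplete windows; NNLS drops regions
  per sample) rather than imputed — imputation would invent methylation
  values on exactly the features the classifiers select from. The one
  exception is model *scoring*: a fitted fold model needs a value for every
  selected feature, so held-out missing entries take the training-column
  mean, the least informative completion.
* **Spike-in QC**: conversion is measured on a fully methylated control and
  the false-positive rate on an unmodified control; under the direct-
  conversion polarity a modified cytosine reads as T, so the converted
  count is the `n_meth` column. Samples are gated at conversion ≥ 0.90
  (configurable). Published thresholds for this step vary between 0.85 and
  0.90 even within one study; the stricter value is the default, and the
  boundary sample passes (≥, not >).

# Unsupervised structure

PCA is computed on complete, non-constant windows, centred and — by default —
unit-scaled (the convention of the common PCA front-ends in this field;
exposed as a flag because published analyses rarely state it). Component
signs are fixed by requiring each component's largest-magnitude loading to
be positive, making score plots reproducible across BLAS implementations.

Windows driving a component are found by Pearson-correlating each window
with the component scores; the p-value uses the t-transform
$t = r\sqrt{(n-2)/(1-r^2)}$ (checked against a permutation oracle in the
tests), with a threshold of 0.01 and the top 200 windows by $|r|$ retained.
Overlap enrichment of a window set in a feature set (enhancers, promoters,
CpG islands) uses a **window-level** 2×2 table — windows are fixed-width and
disjoint, so counting windows rather than base pairs gives a well-defined
table that an exact hypergeometric oracle can verify — with the two-sided
Fisher exact p and the sample odds ratio $(ad)/(bc)$.

# Two-class DMR classifier

The cancer/control classifier follows strict leave-one-out hygiene: in each
fold the held-out sample plays no part in feature selection or model
fitting. Within a fold, candidate windows (restricted to the relevant
regulatory class: enhancers for the liver-cancer contrast, promoters for the
pancreatic contrast) are tested with a two-sample t-test; windows with
p < 0.002 and absolute methylation difference > 0.05 become that fold's
DMRs. The t-test flavour is not pinned down by published descriptions;
Welch is the default (a pooled-variance option exists) since group variances
differ whenever tumor fraction does.

The fold model is an elastic-net-regularised logistic regression (lasso
mixing α = 1 by default, penalty chosen at minimum cross-validated deviance
with seeded fold assignment, `min(10, smallest class)` internal folds).

**Degenerate folds.** A fold can select zero DMRs, or the penalty search can
retain an intercept-only model. Both yield a constant prediction equal to
the training-class prior — and in leave-one-out the training prior is
*anti-correlated* with the held-out label (holding out a positive lowers
it), so reporting the prior would bias a truly uninformative classifier's
AUC toward 0, not 0.5. Such folds are therefore scored 0.5 exactly and
flagged; the fold count and flags are kept on the result object. This is the
one place the package deliberately departs from the most literal reading of
"score by the training prior".

ROC/AUC uses the midrank (Mann–Whitney) formulation with ties counted 1/2;
an $O(n^2)$ pairwise enumeration verifies it exactly in the tests. External
cohorts (e.g. cirrhosis/pancreatitis-like samples) are scored by a single
model refit on all primary samples over the union of per-fold DMRs — how
fold models should be combined for external data is unstated in the sources
this design follows, and refit-on-all is the simplest defensible rule; an
error is raised if fewer than half of the model's features are present.
DMR stability between a full-depth reference set and a down-sampled run is
the recovered fraction |intersection|/|reference|.

# Tissue-of-origin deconvolution

The reference atlas aggregates per-CpG calls over enhancer regions (pooled
ratio per region; regions under `min_cpgs` covered CpGs are missing), then
selects tissue-specific regions per tissue group:

* rank regions by |median(tissue) − median(all other samples)|;
* drop regions whose within-tissue replicate spread (max − min) exceeds
  0.25 — "consistent methylation" operationalised as a spread bound;
* enforce a minimum-difference floor of 0.1 so that degenerate contrasts
  (e.g. duplicated tissue groups) select nothing rather than noise ranks;
* keep the top 100 per direction (hyper/hypo) — atlas-style marker counts
  in this field are of order 100 per tissue and the value is configurable;
* repeat the ranking against the tissue's two most-correlated neighbours
  (Pearson over tissue median profiles), so closely related tissues stay
  separable.

The reference matrix $A$ holds per-tissue medians over replicates on the
selected regions. For a sample vector $y_s$ of observed region levels, the
contribution estimate solves
$\min_x \|Ax - y_s\|_2 \ \text{s.t.}\ x \ge 0$
(Lawson–Hanson NNLS), with missing regions dropped pairwise and the used
fraction recorded. Contributions are reported raw and sum-normalised;
figures and group tests use the normalised values. Group comparison of a
tissue's contributions defaults to an *unpaired* Welch t-test: a paired test
between independent patient groups is not explicable, so pairing is an
option, not the default. A contributions-as-features classifier reuses the
LOO machinery with no selection step.

# Fragmentomics

Fragment lengths come from a one-column table or from paired-end alignments
(absolute template length of the first mate, each pair counted once,
duplicate-marked records excluded). Profiles are per-integer-length
histograms plus 10-bp bin fractions over a full window of 0–1000 bp with
half-open bins `[lo, lo+10)` — a 300-bp fragment falls in the first "long"
bin. Bin fractions always use the *full-window* total as denominator so that
long-bin features remain comparable between samples with different
short-fragment loads and stay on one simplex. Summary ranges default to
70–150 bp (short) and 300–500 bp (long); published text and figure legends
disagree slightly on these ranges (below-150 and 310–500 appear as
variants), and the figure-legend values are the defaults, both
configurable. Group testing uses the tie-corrected Kruskal–Wallis H; the
long-range 10-bp bins (20 features) feed the shared LOO classifier.

# Copy number

Reads or fragment midpoints are counted in 100-kb bins; bins with
mappability < 80 or overlapping a blacklist are dropped. Ratios are counts
over the median retained autosomal count — a deliberate simplification that
preserves the published decision rule (cutoffs 0.8/1.2, patient positivity)
while replacing a GC/mappability loess correction chain that is meaningless
on synthetic single-chromosome profiles; the interface accepts per-bin
covariates so a correction can slot in. Per-bin calls use
ratio < 0.8 (loss) and ratio > 1.2 (gain); runs of identical non-neutral
calls merge into segments, bridging at most one *dropped* bin so a
low-mappability gap does not split a real aberration (neutral retained
bins always split). A patient is CNV-positive iff a segment exceeds 500 kb
strictly — a 500-kb run is not "bigger than 500 kb".

# Three-class integration

For each modality a linear-kernel maximum-margin classifier with pairwise-
coupled probability calibration is fit per LOO fold (seeded — the
calibration uses internal cross-validation). The methylation modality
selects features within the fold: each of the three pairwise group
comparisons is t-tested, ranked purely by p (no difference floor — with
only five windows per pair, rank semantics are what the published
description states), and the top five per pair form the feature union. The
tissue and fragmentation matrices are used raw. Integration is the
element-wise mean of the three probability matrices; the predicted class is
the argmax of the mean, with exact ties broken toward the control class and
then lexicographically (a declared rule; the sources are silent). Reported
metrics are overall accuracy, the confusion matrix, and the binary accuracy
after collapsing the two cancer classes.

# The synthetic cohort: what it does and does not emulate

`make_atlas` draws a bimodal per-region baseline (two Beta modes near 0.08
and 0.92, mixture weight set so the mean is the 0.755 global methylation
level typical of control plasma, then recentred exactly) and plants, per
tissue, a disjoint set of regions shifted by ± the effect size (default
0.4), adjusting the shared baseline where needed so the full shift always
fits in [0, 1]. `atlas_replicates` adds Beta noise at concentration 100
(region-level replicate SD of 3–5% near the modes, the scale seen in deep
WGBS tissue replicates). `make_cohort` gives each sample a Dirichlet tissue
mixture (concentration 150, i.e. a between-patient SD of roughly 2–3
percentage points for a typical component — contribution variability is not
quantified in the literature this emulates, so it is an explicit, exposed
parameter), computes expected window levels as $A x$, adds group-specific
planted DMR shifts (alternating hyper/hypo) confined to that group's
regulatory window class, and draws per-CpG binomial counts at
Poisson-distributed coverage. Windows map 1:1 to atlas regions, with
alternating enhancer/promoter labels written as interval annotations — the
interval machinery is exercised without a real genome.

`make_fragments` mixes a narrow 167-bp peak, a geometric comb at
167 − 10k bp (k = 1..6), a broad ~320-bp secondary peak, and short/long
background; a group shift moves mass from the long components to the short
background, emulating the short-fragment excess of cancer cfDNA.
`make_cnv_profile` draws Poisson bin counts at depth × copy-ratio, and
`make_spikein` draws binomial conversion counts.

What the generator deliberately does **not** emulate: raw reads and
alignment artifacts, GC and mappability bias, within-window CpG
heterogeneity, correlated methylation along the genome, read-level
methylation haplotypes, carrier-DNA contamination, and batch effects.
Passing tests therefore demonstrate that the pipeline's statistics and
cross-validation structure behave correctly — recovery of planted signal,
honest null behaviour, exact oracles — not that any particular clinical
performance would be attained on real plasma.

# Numerical conventions and problem sizes

* Coordinates 0-based half-open everywhere (BED); `GRanges` conversion adds
  1 to starts.
* All generators are deterministic given `seed`; derived per-fold seeds stay
  within 32-bit range.
* Constant windows are excluded from correlation ranking (undefined r), not
  errors; identical groups give t = 0, p = 1 by convention in the
  contribution and rank tests.
* Sample odds ratios at zero cells are reported as `Inf`/0/`NaN` with the
  exact p still defined.
* The test suite and the acceptance script run the pipeline at desk scale,
  chosen as the package's own standard conditions: 2000-window cohorts of
  20 vs 20 at coverage 10 for classification (10 null seeds, 5 signal
  seeds), 10 × 300 atlases for the NNLS oracle (50 draws), 3 × 300 atlases
  with 3 replicates for marker recovery (5 seeds), 500-bin CNV profiles
  (100 flat draws), and 30-sample three-class cohorts (10 seeds).

# Known limitations

* The leakage-prone alternative (selecting DMRs on all samples before LOO)
  is implemented only as a negative control in the tests; the public API
  always selects within the fold unless `select = FALSE` is passed with
  externally chosen features.
* Median ratio normalisation assumes most bins are copy-neutral; profiles
  with pervasive aneuploidy would need the covariate hook.
* NNLS assumes the atlas spans the sample's true sources; contributions
  from missing tissues are absorbed by correlated columns.
* The SVM probability calibration is cross-validated within each fold, so
  three-class probabilities are seeded but not platform-exact to the last
  digit; all assertions about them use tolerances.
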