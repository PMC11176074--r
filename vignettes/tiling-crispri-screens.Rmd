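---
title: "Models and methods: tiling CRISPRi screens, boundary scans and 4C comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: tiling CRISPRi screens, boundary scans and 4C comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cireScreen)
```

This vignette is the package's account of its science: the generative
model behind the simulator, the statistical model behind the guide-level
test, the peak-calling and boundary-scan rules, the numerical choices,
and what the synthetic benchmarks do and do not establish about real
screens.

## Coordinates and library design

All intervals are 0-based half-open, so width = end − start. Printed
coordinate strings (`"chr2:203,815,414-203,815,922"`) are parsed directly
under that convention — the printed pair for a 508-bp element differs by
exactly 508 — which keeps browser coordinates, BED output and interval
arithmetic mutually consistent with no ±1 adjustment anywhere.

`design_tiling_library()` enumerates every 20-nt protospacer adjacent to
a 5'-NGG PAM on both strands. The recorded position of a guide is the
genomic coordinate of the protospacer's 5' base *on its own strand*
(for a minus-strand guide this is the rightmost protospacer base in
genome coordinates), mirroring how tiling-screen reference files record
guide positions. Guides whose protospacer contains a cloning restriction
site (BstXI `CCANNNNNNTGG`, BlpI `GCTNAGC`, `N` wildcard, either strand
of the protospacer) are dropped, because such an oligo could not survive
the cloning digest; the match is against the protospacer only, not
protospacer+PAM, since only the protospacer is synthesized into the
vector. Protospacers occurring at several positions are all retained —
deduplication is a genome-wide off-target question delegated to the
`offtarget_filter` hook, and dropping repeats silently would bias tiling
density near repetitive elements.

## The screen simulator

`simulate_screen()` is a first-class, tested model of a bin-sorted
pooled screen. Per donor:

1. **Transduction.** Each of `n_cells` cells receives one guide
   uniformly at random (low-MOI transduction followed by selection; no
   multiple-integration modeling).
2. **Knockdown.** Guide efficacy toward element *E* is Gaussian in the
   distance from the protospacer center to the nearest base of *E*'s
   core: \(e_E(g) = e_{\max} \exp(-d_E^2 / 2\sigma^2)\), with
   \(e_{\max} = 0.9\) (a strong KRAB-repressor system) and
   \(\sigma = 150\) bp (CRISPRi silencing is element-proximal; at
   50-bp tiling a 500-bp merge gap spans several informative guides).
   Every TSS acts as an element with effect size κ = 1 toward its own
   gene. Efficacy is computed per element, so a guide sitting on one
   element does not silence a distant one; the recorded ground-truth
   efficacy per guide is its value at the nearest element.
3. **Expression.** Per-cell log expression = context baseline + donor
   offset (Normal, sd `donor_sd` = 0.15) +
   \(\sum_E \log(1 - e_E(g)\,\kappa_E)\) + Normal noise
   (`expr_noise_sd` = 1.0, i.e. roughly 100% CV of biological plus
   staining variation). κ < 1 by construction keeps the multiplier
   positive; κ > 0 is activating, κ < 0 repressive.
4. **Sorting.** Cells are ranked (stable tie-break by cell index) and
   the bottom and top 20% (`bin_fraction`) become the low and high
   samples.
5. **Sequencing.** Guide tallies per bin, each multiplied by an
   independent Gamma(shape 1/`alpha_sim`, mean 1) factor
   (`alpha_sim` = 0.01) and renormalized, feed a multinomial draw of
   `depth` reads. The Gamma–multinomial layer makes marginal counts
   approximately negative-binomial, matching the analysis model; most
   overdispersion in the simulated regime in fact arises naturally from
   cell-sampling noise in the bins.

All draws come from named substreams of one global seed
(`substream_seed()`), so identical configurations are bit-reproducible
and adding a stage never perturbs another stage's randomness.

What the simulator deliberately omits: lentiviral copy number,
selection kinetics, sorter impurity, staining antibody saturation,
guide-specific efficacy sequence features, and chromatin context. A
passing benchmark therefore shows the *analysis chain* is correct under
a faithful noise model, not that any particular biological locus will
yield these effect sizes.

## Guide-level statistics

The per-guide model is a negative-binomial GLM with log link, offsets
\(\log s_j\), and coefficients intercept + donor + bin, fit by
iteratively reweighted least squares (vectorized across guides; one
small weighted solve per guide per iteration). The tested coefficient is
bin low vs high, coded so positive log2FC = enriched in low-expression
cells. Convergence failures are flagged and assigned p = 1 rather than
dropped, so downstream peak geometry is never silently perturbed.

**Filtering.** "Fewer than ten reads across all samples per condition"
is read as: exclude when the condition-wise *sum* is below 10. The
alternate reading (every sample below 10) sits behind
`filter_low_counts(mode = "each")`; the two differ only for guides with
highly skewed counts.

**Normalization.** Median-of-ratios size factors over guides positive in
every sample. Degenerate inputs (no such guide) error with a remediation
hint rather than producing NaN factors.

**Dispersion.** With two donors × two bins there is a single residual
degree of freedom per guide, so gene-wise estimates are unusable alone
and a mean–dispersion trend \(\alpha(\mu) = a_1/\mu + a_0\) supplies the
working values (floored at `alpha_min` = 1e-8; a `"maximum"` mode takes
the elementwise max of gene-wise and trend for conservative use).
Two estimator choices were made deliberately after validating them
against data simulated with known dispersion:

* Gene-wise values come from the **Cox–Reid adjusted profile
  likelihood** on a dispersion grid at the Poisson-fitted means, not
  from Pearson moments. At one residual df the moment estimator's
  second-order bias (~10% low) propagates into an anticonservative Wald
  tail; the CR adjustment — the standard remedy in the count-GLM
  literature — restores near-nominal calibration (measured type-I at
  0.05 on known-α NB data: moments ≈ 0.061, CR ≈ 0.046). The moment
  estimator remains available (`genewise_method = "moments"`).
* The trend is fit by **mean-targeting least squares over all finite
  gene-wise estimates** (with a 0.1% extreme-magnitude trim and
  non-negativity by refit). At one df the gene-wise sampling
  distribution is χ²-skewed, so median-targeting robust regressions
  (Huber and relatives) are biased far low, and restricting to positive
  estimates truncates the noise distribution and biases high; either
  miscalibrates the test. Ordinary least squares on everything is the
  estimator whose expectation is the trend itself.

**Testing.** Wald z from the Fisher information at the fixed working
dispersion, two-sided normal p, Benjamini–Hochberg adjustment
(`stats::p.adjust`; an independent brute-force step-up implementation
serves as the test oracle). A pseudocount of 0.5 appears only in
*reported* log-ratios of raw counts, never inside the GLM.

A note on invariances: rescaling the size-factor vector by any global
constant leaves every statistic unchanged (exact offset invariance,
absorbed by the intercept). Multiplying one sample's *observed counts*
by c, however, also multiplies that sample's likelihood weight, so
results are only approximately invariant — closely so in the
overdispersion-dominated regime where IRLS weights saturate at 1/α. The
tests assert the exact property exactly and the approximate one at its
honest tolerance.

## CiRE calling

Significant guides (adjusted P < alpha, default 0.05) are pooled across
screens (union), deduplicated by guide id keeping the best adjusted p,
sorted by 5' position, and split into runs wherever the gap to the
previous significant guide is ≥ `max_gap` (500 bp; a gap of exactly
500 splits — the rule is strictly "less than 500 stays together"). CiRE
boundaries are the 5' start positions of the first and last member
guides, exactly as stated — the last protospacer's body is *not*
included (a `pad_protospacer` flag adds 20 bp for browser display).
`min_guides` defaults to 2: the calling rule speaks of *runs* of guides,
and singleton calls under 10k-guide multiplicity would inflate false
positives; the flag exposes the choice because no minimum is inherent to
the rule. Mixed-direction runs are kept whole and flagged `mixed`
(the rule as stated is direction-blind); `split_by_sign` splits them.

`evaluate_recovery()` scores calls against simulator ground truth:
recall over planted regulatory elements (TSS pseudo-elements excluded —
promoters are positive controls, not discoveries), precision against
all truth elements including TSSs (a promoter call is a true finding),
direction must match (activating = low-bin-enriched), and matching
allows 500 bp of slack.

## Contact model and boundary scans

The built-in contact predictor is analytic:
\(C_{ij} = c_0 (d_{ij} + d_0)^{-\gamma} \prod_b (1 - s_b)\) over
boundaries *b* whose core midpoint lies strictly between the bin centers
(γ = 1, d₀ = 5 kb, c₀ = 1, 2,048-bp bins — a ~512-bin map over ~1 Mb,
the working resolution of deep contact-map predictors). It exists to
give the deletion scan a transparent, closed-form target; any predictor
returning a symmetric non-negative `contact_map` plugs into
`scan_deletions()` unchanged, including sequence-based models.

Deletions are annotation-level: removing a boundary sets its strength to
0; deleting a single base scales strength by 1 − w(x), where w is a
triangular profile peaking at 1 at the core center (emulating motif
information content, and guaranteeing a unique argmax for tests).
Coordinates never shift — the analog of re-padding a deleted sequence to
constant length. Map disagreement is the mean squared difference over
the strict upper triangle: the diagonal is excluded because self-contact
bins dominate magnitude and carry no insulation signal, and the MSE's
aggregation (triangle vs full matrix) only rescales scores by a
constant, leaving argmax positions and orderings untouched. Argmax ties
break toward the smaller coordinate, deterministically.

Two closed-form consequences anchor the tests: full deletion multiplies
every cross-boundary contact by exactly 1/(1 − s), and no single-base
deletion can exceed the full-element MSE (a 1-bp hit removes at most
s·w ≤ s of strength); at the core center w = 1, so the best single base
ties the full deletion exactly.

## 4C viewpoint analysis

`simulate_fourc()` partitions the span into restriction-fragment-like
pieces (lognormal lengths, mean 1 kb — between a 4-cutter's and a
6-cutter's fragment sizes), sets expected signal by the same
distance-decay × insulation kernel between viewpoint and fragment
midpoint (with per-boundary knockdown fractions scaling strengths), and
draws reads multinomially.

Processing follows the standard viewpoint pipeline: per-million
normalization (all-zero tracks normalize to zero with a warning), a
centered 21-fragment running mean truncating at the track edges, and a
cubic smoothing spline on fragment midpoints with smoothing parameter
0.75 on the conventional 0–1 `spar` scale (near-interpolation at 0,
near-linear at 1; smoothing ≥ 1 returns the exact least-squares line as
the infinite-penalty limit). Gene-body comparisons use *unsmoothed*
normalized signal of captured fragments — captured meaning nonzero,
since log 0 is undefined and an uncaptured fragment carries no contact
evidence (a raw pseudocount mode exists behind a flag); values are
natural-log transformed (the base shifts everything by a constant and
cannot change a t statistic). Conditions are compared per gene body by a
two-sided Welch t-test — the safer default when only "t-test" is
specified; the pooled variant is a flag — with Bonferroni correction by
the number of gene bodies in the call (a local family, not an
experiment-wide count). Track QC reports the three standard viewpoint
fractions with passing bounds cis > 0.55, coverage-within-1-Mb > 0.40,
captured-within-100-kb > 0.55.

In the synthetic costimulatory-locus model the viewpoint sits on the
stimulation-responsive enhancer with a strong (s = 0.8) boundary
separating it from the first gene. Knocking that boundary down releases
cross-boundary contacts (×(1 − 0.08)/(1 − 0.8) ≈ 4.6 at 90% knockdown),
so the cross-boundary gene body gains normalized signal while the
viewpoint-proximal gene loses share under the fixed per-million budget —
the directional signature the gene-body comparison must recover.

## Problem sizes and determinism

The shipped study conditions are: null calibration on 5,000 guides ×
2 donors at 10⁶ reads per bin and 200 cells per guide per donor (20
seeds for the false-call count); element recovery on 600 guides at
5×10⁶ reads; 1,000 random instances for the caller-vs-oracle
equivalence; 20 seeded replicates for 4C directionality. These sizes
give Monte-Carlo standard errors well inside the asserted bands while
keeping the whole suite in a couple of minutes of CPU. Every stochastic
stage draws from named substreams of one global seed, so any reported
number is reproducible byte for byte from the seed alone.

## Known limitations

* The dispersion trend assumes a shared mean–dispersion relationship;
  guide-specific biological overdispersion (e.g. position-dependent
  efficacy variance) is absorbed only through the trend.
* The contact stand-in has no A/B compartments, loops, or
  observed/expected structure; conclusions about scan *power* on real
  Hi-C-trained predictors require plugging one in.
* CiRE boundaries understate element extent by construction (guide
  start positions), and closely spaced elements under 500 bp apart merge
  into one call.
* The 4C simulator draws fragments independently of sequence; blind
  spots of real restriction maps (long uncut stretches) are not
  represented.
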