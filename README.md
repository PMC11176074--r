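# cireScreen

Analysis toolkit for **tiling CRISPRi screens** in bin-sorted primary
cells, with companion tools for **in-silico boundary-element deletion
scans** over contact-map predictors and **4C-seq viewpoint comparison**.

## The problem

Tiling CRISPRi screens discover *cis*-regulatory elements by targeting a
catalytically dead Cas9–repressor fusion at every possible protospacer
across a locus (every 20-mer flanked by a 5'-NGG PAM), sorting cells into
the **lowest and highest 20%** of target-protein expression by flow
cytometry, and sequencing guide abundances in each bin. A guide enriched
in the low bin silences an element that *promotes* target expression; a
guide enriched in the high bin marks a *repressive* element. Runs of
significant guides define CRISPRi-responsive elements (CiREs). Locus
architecture enters twice more: CTCF boundary elements insulate enhancers
from non-target genes (probed here by single-base in-silico deletion
scans of contact maps, scored by matrix MSE), and viewpoint-anchored
4C-seq measures how boundary disruption redirects enhancer contacts
between neighboring gene bodies.

`cireScreen` implements the full analysis chain and, because real screens
need donors, sorters and sequencers, a generative simulator that produces
every input with known ground truth — so each stage is verifiable end to
end on a laptop.

## The statistical core

For guide *g* with counts \(K_{gj}\) in sample *j* (donor × bin), the
per-guide model is a negative-binomial GLM with log link and
variance \(\mu + \alpha\mu^2\):

\[
K_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g), \qquad
\log \mu_{gj} = \log s_j + \beta_0 + \beta_{\mathrm{donor}(j)}
  + \beta_{\mathrm{bin}} \cdot \mathbb{1}[\mathrm{bin}_j = \mathrm{low}]
\]

with median-of-ratios size factors \(s_j\), gene-wise dispersions from a
Cox–Reid adjusted profile likelihood pooled through a
\(\alpha(\mu) = a_1/\mu + a_0\) trend, a Wald test
\(z_g = \hat\beta_{\mathrm{bin}} / \mathrm{SE}(\hat\beta_{\mathrm{bin}})\)
from the Fisher information, and Benjamini–Hochberg correction. Positive
\(\log_2\mathrm{FC} = \hat\beta_{\mathrm{bin}}/\ln 2\) means enriched in
the low-expression bin. Guides with fewer than ten reads across a
condition are excluded. CiREs merge runs of significant guides
(adjusted *P* < 0.05) less than 500 bp apart, with CiRE boundaries at
the 5' genomic start positions of the first and last member guides.

## Worked example

Simulate a screen over a 30-kb tiled region carrying three planted
elements (activating κ = 0.6 and 0.3, repressive κ = −0.4; 500-bp cores),
guides every 50 bp, two donors, 5×10⁶ reads per sorted bin:

```r
library(cireScreen)
bench <- synthetic_benchmark_screen()
cfg <- screen_config(n_cells = 200 * n_guides(bench$library),
                     depth = 5e6, seed = 1)
sim   <- simulate_screen(bench$model, bench$library, cfg,
                         bench$context, bench$target_gene)
stats <- nb_wald_test(sim$counts)
cires <- call_cires(stats)
cires[, c("cire_id", "start", "end", "n_guides", "direction",
          "mean_log2fc", "min_p_adj")]
#>   cire_id start   end n_guides  direction mean_log2fc min_p_adj
#> 1 CiRE_01  4800  5650       18 activating        2.80  1.60e-44
#> 2 CiRE_02 11850 12550       14 activating        1.32  8.27e-11
#> 3 CiRE_03 18800 19650       17 repressive       -1.34  9.71e-11
evaluate_recovery(cires, sim$truth)[c("precision", "recall")]
#> $precision [1] 1      $recall [1] 1
```

All three planted elements come back with the right direction
(low-bin-enriched guides over the activating cores, high-bin-enriched
over the repressive one), CiRE midpoints within 50 bp of the planted core
midpoints, and no false calls. A boundary deletion scan localizes the
stronger of two insulators to the base:

```r
m <- synthetic_two_boundary_model()        # strengths 0.3 and 0.7
scan <- scan_deletions(m, genomic_interval("chr_syn", 0, 131072),
                       genomic_interval("chr_syn", 79000, 81500))
scan
#> <disruption_profile> 2500 positions over chr_syn:79,000-81,500
#>   max MSE 1.063702e-10 at position 80250   # = stronger core's midpoint
```

`run_demo(outdir)` runs the complete pipeline — screen plus the matching
4C boundary-knockdown comparison over a synthetic 1.44-Mb
costimulatory-locus model — and writes counts, guide statistics, CiRE
BED/TSV, bedGraph tracks and JSON run metadata.

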