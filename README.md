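# isobench

Benchmarking compositional segmentation algorithms on simulated isochore
genomes.

The isochore model describes mammalian genomes as mosaics of long,
GC-homogeneous domains from five families — L1 (<37% GC), L2 (37–41%),
H1 (41–46%), H2 (46–53%), H3 (>53%). Testing whether a segmentation
algorithm *finds* such domains or *invents* them requires sequences whose
true domain structure is known. isobench provides:

* a **simulator** of DNA sequences tiled by known GC-homogeneous domains:
  1 Mb sequences with 1–100 equal-length domains, and 5 Mb sequences whose
  domain lengths follow a power law (density ∝ x^−2.55, x ≥ 10,000 bp,
  rescaled to 5 Mb), families drawn by genome-fraction weight with adjacent
  domains always in different families;
* two **segmenters**: `segment_windowmerge()` (non-overlapping 100-kb
  windows classified into families by mean GC, same-family neighbours
  merged) and `segment_recursive()` (recursive binary splitting at the
  maximal Jensen–Shannon divergence point,
  D_JS = H(c/n) − (n₁/n)H(c₁/n₁) − (n₂/n)H(c₂/n₂) in bits, halted by a
  Monte-Carlo calibrated threshold that depends on segment length and GC);
* a **scorer** implementing the ±5% boundary rule — a prediction is a true
  positive when both its boundaries lie within 5% of its own length from a
  ground-truth domain's boundaries — and the derived metrics
  sensitivity = TP/(TP+FN), precision = TP/(TP+FP),
  Jaccard = TP/(TP+FP+FN);
* a **benchmark driver** (`run_benchmark()`, `summarize_benchmark()`,
  `length_comparison()`) that streams simulate → segment → score and pools
  per-sequence metrics, with Wilcoxon rank-sum comparisons between the
  algorithms.

All coordinates are 0-based half-open (BED convention). FASTA/BED import
and export are built in (`read_fasta()`, `write_bed()`, …), and
`inst/cli/isobench.R` exposes `simulate` / `segment` / `score` /
`benchmark` subcommands for shell use.

## Worked example

```r
library(isobench)
s <- simulate_sequence("equal", 10, 1, sim_config(seed = 5))
s
#> Simulated sequence sim_equal_10dom_r1: 1e+06 bp, 10 domain(s)
#>   families: L2 H3 H2 L2 H1 L1 H1 L2 H2 H1

segment_windowmerge(s)
#> Segmentation of sim_equal_10dom_r1 (1e+06 bp) by 'windowmerge': 10 segment(s)
#>  start   end mean_gc family
#>  0e+00 1e+05 0.40948     L2
#>  1e+05 2e+05 0.53557     H3
#>  ...

score_segmentation(segment_windowmerge(s), s)
#> TP 10  FP 0  FN 0  (boundary tolerance 5% of predicted length)
#> sensitivity 1.0000  precision 1.0000  Jaccard 1.0000

seg <- segment_recursive(s, recursive_params(seed = 5))
seg
#> Segmentation of sim_equal_10dom_r1 (1e+06 bp) by 'recursive': 9 segment(s)
#>   start     end   mean_gc family
#>       0  100004 0.4094736   <NA>
#>  100004  199524 0.5356712   <NA>
#>  ...

score_segmentation(seg, s)
#> TP 8  FP 1  FN 2  (boundary tolerance 5% of predicted length)
#> sensitivity 0.8000  precision 0.8889  Jaccard 0.7273
```

Ten 100-kb domains aligned to the 100-kb window grid are the window-merge
segmenter's best case: every window boundary is a family change, so it
recovers all ten domains exactly. The recursive segmenter places boundaries
freely (within a few hundred bp of the true junctions here); it recovers
8 of 10 domains, merging one junction whose GC step (0.4125 vs 0.4086) is
too small to clear the calibrated threshold.
The picture reverses as domains shrink below the window size: window-merge
performance collapses to zero while the recursive segmenter keeps tracking
the true boundaries — run `run_benchmark()` to see both regimes.

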