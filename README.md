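# cfmix

Analysis of plasma cell-free DNA (cfDNA) from long-read sequencing with
direct methylation calls: who is the DNA from, and how much of it is
tumor-derived? The package is written for liquid-biopsy method
developers who have per-CpG methylation tables, fragment tables and
copy-number segments (all plain text) and want the downstream analyses
— deconvolution, regional methylation, fragmentomics, nucleosome
profiling — as tested, reusable functions rather than one-off scripts.

## What it computes

* **Cell-type deconvolution.** With a reference atlas $X$ (probes ×
  cell types) and a sample methylome $Y$, solve
  $\hat\beta = \arg\min_{\beta\ge 0}\lVert X\beta - Y\rVert_2$
  (Lawson–Hanson NNLS) over marker probes (top-$n$ hyper- and
  hypomethylated per cell type by one-vs-rest margin) and report
  $\hat\beta/\sum\hat\beta$ as cell-type fractions, optionally collapsed
  into groups. A two-component variant against mean target-tissue and
  healthy-plasma methylomes reports the target fraction
  $\beta_1/(\beta_1+\beta_2)$; bulk tumor references can be
  purity-corrected by inverting $M_m = M_c\,p + M_l(1-p)$.
* **Regional methylation.** Solo-WCGW methylation deltas in 10-Mbp
  partially-methylated-domain bins (bin mean minus genome-wide mean,
  negative = hypomethylated), stratified by copy-number status from SEG
  files (|log2 ratio| threshold 0.10, overlap-weighted), one-sided
  Wilcoxon comparisons, and the tumor-fraction stability floor (set to 0
  below 15% genome altered). Flank-normalized methylation metaplots
  around TF binding sites (±1 kb, 20 bp bins, flank = 800–1000 bp).
* **Fragmentomics.** CIGAR-derived molecule lengths, standard cfDNA
  filters (MAPQ ≥ 20, ≤ 700 bp, primary, unclipped, double-barcoded),
  short mono- and dinucleosome ratios
  (#[100–150]/#[100–220], #[275–325]/#[275–400]), 4-mer end motifs read
  from the reference at the molecule 5′ end, and differential motif
  testing on per-sample frequencies with BH adjustment.
* **Nucleosome profiles.** RPGC-normalized coverage of deduplicated
  130–155 bp fragments and reference-point metaplots around CTCF-style
  sites (mean profile = fold change over genome average).
* **Statistics.** The shared testing policy (Student's t when a group
  has < 5 samples, else Wilcoxon with exact small-sample enumeration)
  and BH FDR adjustment.
* **Synthetic data.** Truth-known generators for every input dialect
  (atlas CSV, modbam2bed BED, bedgraph, fragment TSV, reference FASTA
  sequences, site BED, SEG), so the full pipeline runs and is tested
  without any sequencing data.

## Worked example

The `analysis/` directory is a numbered workflow over a simulated
7-sample cohort (4 healthy donors, 3 cancer patients with tumor
fractions 0.10/0.20/0.35). Each script is a thin driver over package
functions and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # inputs under scratch/sim/
Rscript analysis/02_deconvolution.R
Rscript analysis/03_regional_methylation.R
Rscript analysis/04_fragmentomics.R
Rscript analysis/05_nucleosome_profiles.R
```

Output printed by the runs above:

```
tumor-component fraction: truth vs estimate MAE = 0.0092 (max 0.0190)
PMD neutral-bin deltas track tf * (beta_tumor - beta_healthy); at tf = 0.3: observed -0.1190 vs expected -0.1200
TFBS center fold change by signal fraction: 0 -> 1.000, 0.25 -> 0.759, 0.5 -> 0.526
short mono ratio: healthy mean 0.084, cancer mean 0.201 (t p = 0.00799)
top differential end motif: ACAC (p = 0.0083, q = 0.521)
central depletion minimum at -5 bp; phased peaks at -575, -375, -195, 195, 385, 575 bp (simulated nucleosome grid: multiples of 190 bp)
```

Reading these: NNLS recovers the planted tumor-component fraction to
about one percentage point at 30× probe coverage; PMD solo-WCGW
hypomethylation in copy-neutral bins matches the mixture prediction
$f(\beta_\mathrm{tumor}-\beta_\mathrm{healthy})$; the TF-site
methylation dip deepens with signal fraction exactly as the closed-form
mixture predicts; cancer samples show the expected short-fragment
shift; no end motif survives FDR in a 4-vs-3 cohort whose tumor
fractions are heterogeneous (q = 0.52) even though the shift direction
is planted; and the nucleosome metaplot puts the central depletion and
phased peaks within one 10-bp bin of the simulated 190-bp grid.

As a minimal in-session example:

```r
library(cfmix)
sa  <- simulate_atlas(seed = 1)
mix <- simulate_mixture_calls(sa$atlas, c(0.3, 0.7, 0, 0, 0),
                              coverage = 30, seed = 2)
pb  <- collapse_strands(mix$calls, mix$probe_map)
nnls_fractions(setNames(pb$beta, pb$probe_id), sa$atlas,
               marker_union(sa$atlas, 50))
#> NNLS deconvolution over 500 probes
#> celltype_A celltype_B celltype_C celltype_D celltype_E
#>     0.2884     0.6812     0.0304     0.0000     0.0000
```

## Layout

```
R/                  implementation (meth_io, deconvolution,
                    regional_meth, fragmentomics, coverage_profiles,
                    simulate, stats)
analysis/           numbered workflow scripts (drivers over R/)
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R
vignettes/          methods vignette (models, parameters, design choices)
```
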