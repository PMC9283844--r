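---
title: "Methods: cfDNA methylation deconvolution, regional methylation and fragmentomics"
author: "cfmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cfDNA methylation deconvolution, regional methylation and fragmentomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmix)
```

# Scope and data model

cfmix analyzes plasma cell-free DNA (cfDNA) profiled by long-read
sequencing with direct methylation calls. Four signal classes are
covered: per-CpG methylation (for cell-type and tumor-fraction
deconvolution), regional methylation (partially methylated domains and
transcription-factor binding sites), fragment length and end-motif
composition, and nucleosome-protected coverage. Base calling, alignment,
modification calling and copy-number segmentation happen upstream; the
package consumes their text outputs — stranded per-CpG BED in the
modbam2bed dialect, bedgraph, fragment tables derived from alignments
(with a minimal SAM-text adapter), SEG copy-number tables and BED
interval files. All coordinates are 0-based half-open.

A per-CpG record is `(chrom, pos, strand, n_reads, beta)` with
`beta = methylated reads / total reads`. The modbam2bed dialect stores a
percent methylated (column 11) and a score/coverage pair from which the
confident read count is reconstructed as `round(col5 * col10 / 1000)`;
positions with zero confident reads are dropped, so "missing" is always
an absent record, never a sentinel. Methylated counts are reconstructed
as `round(beta * n_reads)`: the file stores a percentage but counts must
be integral for strand pooling and resampling.

# Cell-type deconvolution

The observed probe methylome $Y$ is modeled as a non-negative
combination of reference methylomes: $\hat\beta = \arg\min_{\beta \ge 0}
\lVert X\beta - Y \rVert_2$, solved with the Lawson–Hanson algorithm
(`pracma::lsqnonneg`). $X$ holds one column per cell type from a
25-tissue-style reference atlas restricted to marker probes; fractions
are the coefficients renormalized to sum to one, since plain NNLS
coefficients have no sum constraint. The fit is complete-case: a probe
enters only if it is non-missing in the sample and every atlas column.

Markers are chosen one-vs-rest: probes are ranked by the margin
`beta_target - mean(beta_others)` and the top `n_each` per direction are
taken (default 1000 per direction per cell type, matching the scale used
with genome-wide arrays; the synthetic workflow uses 50 on its 2000-probe
atlas). The margin statistic is deliberately simple and sits behind one
interface so an alternative selection (e.g. variance-weighted) can be
swapped in. Ties break lexicographically on probe id so selection is
deterministic.

The two-component variant replaces the atlas with two mean methylomes —
a target tissue (e.g. lung epithelium, or purity-corrected lung tumors)
and healthy plasma — each averaged over replicate samples with at least
2 valid values per probe, and reports $\beta_1/(\beta_1+\beta_2)$, the
target-tissue fraction. A fit is refused below 10 shared probes and
warned below 330 (the smallest probe count we consider borderline
stable); when both coefficients vanish the result is `NA`, never a
silent 0. Bulk tumor references are corrected for non-cancer content by
inverting $M_m = M_c\,p + M_l\,(1-p)$ for the pure cancer methylome
$M_c$ given leukocyte methylation $M_l$ and purity $p$, clipping to
$[0,1]$. Differential probes between (corrected) tumors and plasma are
selected by Welch t-test — the corrected tumor betas have no reason to
share variance with plasma — at BH FDR < 0.001 and $|\Delta\beta| \ge
0.3$, with an exclusion list to keep probe sets disjoint across
analyses.

# Coverage downsampling

Downsampling treats each read at each CpG as one observation (of which
`round(beta * n_reads)` are methylated) and draws
`k = round(target_cov * n_cpgs_genome)` observations uniformly *without*
replacement (`n_cpgs_genome` defaults to the 28,217,005 CpGs of GRCh38).
Without-replacement sampling is the chosen semantic — it corresponds to
subsampling a fixed sequenced library — and makes the read-weighted mean
beta exactly hypergeometric-unbiased. Output counts satisfy
$\sum n_i = k$ exactly when $k \le T$; $k \ge T$ returns the input
unchanged.

# Regional methylation

**TFBS metaplots.** CpGs within 1 kb of site centers are pooled into
20 bp signed-distance bins; each bin's mean beta is divided by the mean
over the flank bins (800–1000 bp on both sides), giving a fold change
that is 1 under flat methylation. Bins without CpGs are missing, not
zero; an empty or zero flank yields an undefined fold change with a
warning. Site strand is ignored for orientation — the analyses that use
these profiles (CTCF, NKX2-1-style factors) are center-symmetric — a
choice that is recorded as revisitable. Where several motif hits fall in
one peak, the highest-scoring hit wins, ties to the leftmost.

**PMD bins.** Solo-WCGW CpGs (CpGs in an A/T–CG–A/T context with no
CpG neighbors, the class most prone to hypomethylation inside partially
methylated domains) are averaged per 10-Mbp bin as an unweighted mean of
per-CpG betas, and the bin delta is `bin mean − genome mean`, where the
genome mean is over *all* CpG calls, not only solo-WCGW. The sign
convention makes hypomethylated bins negative. Bins need at least 10
covered solo-WCGW CpGs for a defined delta — below that, bin means at
fractional coverage are too unstable. Copy-number status per bin is the
overlap-length-weighted mean segment log2 ratio (the weighting resolves
multi-segment bins, which the thresholds alone do not address),
thresholded at > 0.10 for gain and < −0.10 for loss. Group comparisons
use one-sided Wilcoxon tests, since hypomethylation in cancer is a
directional hypothesis fixed before testing. Tumor-fraction estimates
from copy number are floored to 0 when alterations cover less than 15%
of the genome (strict less-than), the regime where such estimates are
unstable.

# Fragmentomics

Molecule length is the sum of query-consuming CIGAR operations
(M, I, =, X): deletions and skips consume reference, not molecule, and
the oracle for this choice is the query length of a synthesized read.
Filters mirror standard cfDNA practice: primary alignments only,
MAPQ ≥ 20, length ≤ 700 bp (strict "longer than" removal), no soft
clipping at either end, barcodes at both ends; every filter logs its
removal count. The short-fragment statistics are
`#[100,150] / #[100,220]` (mononucleosome) and `#[275,325] / #[275,400]`
(dinucleosome), all intervals closed — the dashes in the usual
presentation do not specify open/closed, so closed is fixed here and
exercised at the boundaries in tests.

End motifs are the 4 reference bases at the fragment's sequenced 5′ end
(end1 only; end2 of a long single-end read does not reliably represent
the molecule end): plus strand reads `[start, start+4)`, minus strand
the reverse complement of `[end−4, end)`, so the motif always reads
5′→3′ along the molecule. Whether the original convention
reverse-complemented minus-strand motifs is not documented; both modes
exist behind `revcomp_minus`, default `TRUE`. Bases come from the
reference, not the read, to avoid basecalling error; windows containing
non-ACGT are missing. Motif tables always carry all 256 4-mers
(zero-filled) so samples align. Differential motifs are tested per
motif by two-tailed Student's t on per-sample frequencies — the sample,
not the pooled fragment count, is the statistical unit, and the groups
here are smaller than five samples, which the testing policy (below)
maps to the t-test — followed by BH across the 256 motifs. A motif
constant within both groups but different between them has an undefined
t statistic and is reported `NA` rather than forced to 0 or 1.

# Nucleosome coverage profiles

Deduplicated fragments (identical chrom/start/end/strand collapse to
one) in the 130–155 bp band — the short-mononucleosome range that gives
the highest spatial resolution — are piled into a per-base coverage
track and normalized as RPGC: every base is scaled by
`effective_genome_size / total fragment length`, so the genome-wide mean
is 1 and the track reads directly as fold change over the genome
average. The reference-point matrix samples the track in 10 bp bins
(chosen to resolve ~190 bp nucleosome phasing) across ±1 kb of each
site; its column means are the metaplot. Windows that run off a
chromosome are padded with missing values. An optional BED mask supports
blacklist exclusion.

# The statistical policy

`choose_test` encodes the testing policy: Student's t-test when either
group has fewer than five samples, otherwise Wilcoxon. The t-test is
pooled-variance Student by default (Welch by flag, used for the
differential-CpG selection); one-sided directions are always explicit
arguments, never inferred from the data. The Wilcoxon implementation
enumerates exactly for tie-free groups below 50 per side and otherwise
uses the tie-corrected normal approximation; at the sizes used here the
two agree to well under 0.02. BH adjustment is the standard step-up with
enforced monotonicity. Identical constant groups give p = 1 by
definition.

# The synthetic-data generators

Every generator returns a `truth` object keyed to the emitted records,
making the whole pipeline testable without sequencing data, and all
draws are reproducible given `(config, seed)`.

* `simulate_atlas` — 5 components × 2000 probes, 50 hypo- and 50
  hypermethylated markers per component (target 0.1/0.9 against a 0.5
  background, Gaussian beta noise sd 0.03, clipped). These sizes keep a
  five-component recovery study at coverage 30 well-conditioned while
  desk-scale.
* `simulate_mixture_calls` — per probe: Poisson read depth (so
  fractional and low coverage are exercised), each read from component
  $k$ with probability $w_k$ and methylated with that component's probe
  beta; reads split binomially across the two CpG strands so strand
  collapsing is on the tested path.
* `simulate_pmd_genome` — 150 bins of 10 Mbp in three equal copy-number
  classes (tumor copy 1, 2, 3). A bin with tumor copy number $c$ at
  tumor fraction $f$ has local tumor-DNA proportion
  $p = c f / (c f + 2(1-f))$ — note $p(c{=}2) = f$ — and solo-WCGW beta
  $(1-p)\,0.8 + p\,0.4$ (healthy 0.8, tumor 0.4). Background CpGs
  (beta 0.8, unaffected by tumor content, as for CpGs outside PMDs)
  outnumber solo-WCGW CpGs 19:1, so the genome-wide mean moves only
  ~5% of the PMD effect and the neutral-bin delta tracks
  $f(\beta_t - \beta_h)$ within that bias. Segments carry
  $\log_2((cf + 2(1-f))/2)$; at $f \lesssim 0.14$ this stays inside the
  ±0.10 dead zone — the same regime the tumor-fraction floor treats as
  unstable.
* `simulate_fragments` — two-class (healthy/tumor) mono/di-nucleosome
  normal mixtures: healthy modes 167/335 bp, tumor 147/305 bp, sd 12/25,
  85% mononucleosomal, lengths clamped to [60, 700]. These reproduce the
  qualitative cancer short-shift; they are generator conventions, not
  measured values. End motifs are drawn per class from a multinomial
  that is uniform except CCCA at 0.025 (healthy) vs 0.015 (tumor) — the
  depletion direction reported for tumor-derived cfDNA, with magnitudes
  chosen to be detectable at 20,000 fragments/sample. With
  `build_reference = TRUE`, fragments are placed non-overlapping on a
  synthetic chromosome whose sequence is constructed so `end_motif()`
  re-derives the drawn motif exactly on both strands.
* `simulate_ctcf_coverage` — sites every 6 kb; 10 phased nucleosomes per
  side at 190 bp spacing, 40 fragments each with 20 bp positional
  jitter, lengths ~N(142, 6) clamped to 130–155; uniform background
  (2/kb) thinned within ±80 bp of sites by the depletion parameter.
* `simulate_tfbs_methylation` — CpGs every 20 bp across ±1 kb of each
  site; within ±200 bp the true beta is the mixture
  $(1-f)\,0.85 + f\,0.05$, so the expected center fold change is the
  closed form $((1-f)\,0.85 + f\,0.05)/0.85$.

What the generators do *not* emulate: basecalling error profiles and raw
signal, mappability and GC biases, chromatin heterogeneity between
cell types beyond the planted markers, length-dependent end-motif
coupling, and real PMD spatial structure (bins are exchangeable). A
passing suite therefore demonstrates that the estimators are correct
under their stated sampling models — unbiasedness, identifiability,
ordering and calibration — not that real plasma data meet those models.

# Problem sizes and runtime choices

The default test and acceptance runs use: 100 replicate mixtures at
coverage 30 for deconvolution recovery; 1000 seeds for the downsampling
contract on a 200-CpG toy library; 150 PMD bins (50 per copy-number
class) at coverage 1; 100 replicate 7-sample cohorts of 20,000 fragments
for the end-motif detection rate; 100 CTCF sites with 5 background
fragments/kb; 10,000 replicates for t-test type-I calibration. These
sizes put Monte-Carlo noise comfortably inside each assertion's margin
while keeping the full suite around a minute of compute.

# Known limitations

* The NNLS atlas fit has no uncertainty quantification; residual norm is
  reported but not propagated.
* Marker selection is mean-margin only; highly variable probes can enter
  the marker set.
* The two-component model assumes exactly two sources; a third
  contributing tissue biases the fraction toward whichever reference it
  resembles.
* `assign_cn_status` assumes non-overlapping segments per sample and
  validates this rather than resolving overlaps.
* The degenerate all-constant-unequal case in `motif_differential`
  (possible at very low fragment counts) is reported `NA` and excluded
  from BH, which slightly reduces the effective number of tests.
* Strand is ignored in metaplot orientation; factors with asymmetric
  footprints would need an oriented variant.
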