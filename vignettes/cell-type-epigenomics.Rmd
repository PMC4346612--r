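---
title: "Characterizing cell types from coverage-level transcriptome and methylome data"
author: "epicell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing cell types from coverage-level transcriptome and methylome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicell)
library(data.table)
```

## The problem

Differentiated cell types purified from the same tissue — here the motivating
system is the two mammary epithelial lineages, luminal and myoepithelial —
differ in which genes they transcribe, which exons and introns their mature
mRNAs contain, and which regulatory elements their genomes keep unmethylated.
`epicell` implements a matched set of callers for these signals, operating on
summarized inputs (per-base coverage tracks, per-CpG methylation calls, a gene
annotation) rather than raw reads, so the whole analysis is reproducible on a
desk machine and testable against simulated data with planted ground truth.

The pipeline has three branches that meet in a regulatory-association stage:

* **Transcriptome**: exclusion-normalized RPKM for genes, merged exons and
  introns; differential expression between two libraries; cassette-exon
  (isoform) calls; intron-retention calls with NMD prediction; entropy-based
  cell-type specificity for any expression matrix.
* **Methylome**: unmethylated-region (UMR) segmentation from WGBS;
  calibration of MeDIP-seq enrichment to absolute methylation scores;
  exon-intron boundary methylation metaprofiles.
* **Chromatin**: H3K36me3 fold enrichment over exon groups.

## Quantification: modified RPKM

Read counts per feature are estimated from per-base coverage sums divided by
the read length (default 75 bp). The library normalizer is deliberately not
the total read count: it is the read total over protein-coding exons after
removing mitochondrial reads, reads in ribosomal-protein genes, and reads in
the top 0.5% of exons ranked by provisional RPKM (ties broken by coordinate
for determinism; the excluded count is `ceiling(0.005 n)`). Gene RPKM uses
the merged-exon read total over the summed exonic length:

$$\mathrm{RPKM}(g) = \frac{\text{reads in merged exons of } g}
{L_g/10^3 \cdot T/10^6},$$

with $T$ the included-read total. Exons, introns and junctions use the same
$T$; junctions have no genomic length, so a configurable effective length is
used (default: the read length — the paper-scale quantity it approximates is
the number of read placements that can span a junction). *Normalized
coverage* is mean per-base depth divided by $T/10^6$, and *breadth* is the
fraction of bases covered at least once.

Because the input is a coverage track, duplicate and multi-mapping read
handling is out of this package's hands: tracks are taken at face value.

## Differential expression and isoform calls

The original study used an in-house two-library test whose internal statistic
is not published. `epicell` uses a standard Audic–Claverie-style conditional
binomial: feature reads $a$ and $b$ in the two libraries are conditioned on
$a+b$, and $a$ is tested against $\mathrm{Binom}(a+b,\,T_A/(T_A+T_B))$
(two-sided, doubled tail), with Benjamini–Hochberg correction. The doubled
tail makes the test exactly symmetric under swapping the libraries. Default
retention thresholds are FDR $\le$ 0.015, max RPKM $>$ 0.005 and max read
count $>$ 25. Whether the original FDR was BH or empirical is unknowable from
the text; BH is used and stated.

Cassette-exon (isoform) calls are gene-relative by definition: among
differentially expressed exons, the expressed side must reach $\ge$ 10% of
its gene's RPKM and the silent side stay $\le$ 1%; exons between 1% and 10%
on either side are discarded as likely false positives, and genes that are
themselves differential are removed. Junction support marks calls where at
least one junction touching the exon has RPKM $> 0.1$ in the expressed sample
and $< 0.1$ in the other.

## Intron retention

An intron of a protein-coding gene is called retained when all four rules
hold: intron RPKM $> 1$; intron RPKM $> 5\%$ of gene RPKM; intron normalized
coverage $> 30\%$ of the flanking merged exons' normalized coverage; and
$\ge 90\%$ of intron bases covered. The flank statistic is the arithmetic
mean of the two adjacent exons (the validation convention of averaging the
two flank ratios points the same way); at gene ends the single available
flank is used and logged, and `cov_ratio_mode = "both"` is available for the
stricter per-flank reading. Introns overlapping an exon annotated on the
opposite strand are excluded up front — in non-strand-specific libraries
their coverage cannot be attributed to a strand.

NMD fate of a retained-intron transcript uses the classic 50-nt rule (no
rule is given in the source study, so this is a stated substitute): the
transcript is NMD-predicted when translation terminates more than 50 nt
upstream of the last remaining exon–exon junction; retaining intron $i$
removes junction $i$. Transcripts without CDS annotation are indeterminate
and excluded from NMD rates.

## Entropy-based specificity

For expression $E_i$ over $N$ cell types, $F_i = E_i/\sum_j E_j$,
$H = -\sum_i F_i \log_2 F_i$ and $Q_i = H - \log_2 F_i$. $H \approx 0$
marks single-type expression; $H \approx \log_2 N$ uniform expression;
small $Q_i$ marks the type the feature is specific to. The published method
thresholds in the two-dimensional space $[H, \max_i E_i]$ with the coupling
"higher expression may be allowed higher entropy", but publishes no
constants; `epicell` encodes the coupling as a linear-in-log relaxation,
$H \le h_{\max} + s\cdot\log_{10}(\max E/E_{\min})$, with defaults
$h_{\max} = 1$ bit, $E_{\min} = 1$ RPKM/RPM and $s = 0.25$ bits per decade —
all exposed, all ours, labelled as such. $Q$ rows of passing features are
clustered with average linkage on Euclidean distance; infinite $Q$ (zero
fraction) is clipped to one bit above the largest finite value so "absent"
renders at the heat-map maximum.

## UMR detection

The published analysis delegated UMR segmentation to an earlier tool whose
algorithm is not restated, fixing only the region-level cutoff
($P < 0.0005$) and the observed output scale (~270 bp median width, 5 median
CpGs). `epicell`'s segmentation: the background is the coverage-weighted mean
methylation; each CpG gets a lower-tail binomial test of its methylated read
count against the background rate; seed CpGs must pass that test (per-CpG
$\alpha = 0.05$) **and** an absolute ceiling (fraction $\le 0.25$) — the
ceiling is what makes a region *unmethylated* rather than merely below
average, and without it a Fisher combination over selected CpGs admits
clusters of marginally low CpGs; seeds within 500 bp merge; the region
p-value is Fisher's combination of its CpG p-values, thresholded at 0.0005
with $\ge 4$ significant CpGs. Defaults were chosen to be consistent with
the published output scale, not fitted to it.

## MeDIP calibration

MeDIP enrichment is relative; the calibration maps it onto the absolute
WGBS scale. Per CpG, the signal is the mean fragment pileup over a 100-bp
window centred on the CpG (MeDIP fragments are 100–500 bp, so the
single-base value carries needless shot noise); the background is the mean
signal over all bases $\ge$ 500 bp from any CpG. CpGs with mappability
below 0.5 are dropped; signals at mappability in $[0.5, 1)$ are divided by
it. The enrichment-to-score transform is empirical quantile mapping onto a
reference WGBS fractional-methylation sample — the minimal transform that
guarantees the stated property that the score distribution matches WGBS.
Scores below 0.35 are classed hypomethylated, above 0.8 hypermethylated.

## Regulatory association

UMRs link to every gene whose TSS (the 5′-most position of the merged gene
model) lies within $\pm 2$ kb (proximal) or $\pm 20$ kb (distal) of the UMR.
Directionality asks whether a cell-type-specific UMR's nearest linked
differential gene is upregulated in the UMR's own cell type; because the
source text is ambiguous about whether the denominator counts UMRs or
UMR–gene pairs, both are reported, labelled. UMRs detected in both cell
types (constitutively unmethylated regions) are removed by reciprocal
overlap before the directionality summary. TF-binding asymmetry counts each
TF's sites overlapping each UMR set ($\ge$ 1 bp), reports the ratio (+1
pseudocount on both counts only when either is zero, flagged), and estimates
the chance expectation by uniformly re-placing length-preserved UMR
intervals on their own chromosomes (default 1,000 permutations, seeded).

## The synthetic study

`simulate_genome()` defines the study conditions all tests run under.
Defaults: 200 genes (4–8 exons of 100–300 bp, introns 500–2,000 bp) on two
2-Mb chromosomes; three cell types; 90% of genes expressed with log-normal
mean exonic depth (median 30 reads/base); 40 differential genes at 4-fold;
30 cassette exons; 50 retained introns at retention fraction 0.5; low-level
intronic background at 1% of exonic depth; 10 antisense single-exon genes
planted inside introns as ground truth for the opposite-strand exclusion.
The methylome is a block-structured bimodal landscape: 500–3,000-bp blocks,
20% constitutively hypomethylated (mean 0.1), the rest near 0.85, with
per-CpG Beta jitter, jittered-grid CpGs (~1 per 100 bp), Poisson coverage
(mean 30), and 50 planted cell-type-specific UMRs (300 bp, 10 CpGs, target
methylation 0.05) placed 500 bp upstream of differential genes upregulated
in the same cell type. H3K36me3 is Poisson background (rate 1) with 5-fold
enrichment over exons of expressed genes, omitting cassette exons in the
cell type where they are silenced (the mark is transcription-coupled).
`simulate_medip()` smooths methylation spikes with a Gaussian kernel
(sd 150 bp, the sonicated-fragment scale) and adds Poisson noise and
planted low-mappability patches.

Two generator choices deserve emphasis. First, when a cassette exon is
silenced, the host gene's remaining exons are scaled up so the gene-level
read count is conserved; without this the host gene would be differentially
expressed and the isoform call excluded by its own definition — real cassette
exons in non-differential genes behave this way by construction of the
comparison. Second, planted UMR neighbourhoods are forced onto the
methylated mode so that the cell-type specificity of each planted UMR is
unambiguous.

What the simulation does **not** emulate: sequence content (no motifs, no
real CpG islands), read-level artifacts (duplicates, mappability-coupled
coverage bias in RNA), spatially autocorrelated expression noise, partially
methylated domains, and the genome-scale correlation structure of real
chromatin. Passing tests therefore demonstrate correctness of the decision
rules and calibration machinery under the stated statistical structure, not
performance on real libraries.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GTF I/O converts to and from
  1-based closed. "chr" prefixes are stripped on input.
* Ranking ties in the top-exon exclusion break by (chromosome, start);
  clustering leaf order is deterministic for a fixed input order.
* The doubled-tail binomial p-value is capped at 1; features with zero reads
  in both libraries are not tested.
* Zero-expression features get `H = NA` and are excluded downstream;
  `0·log2 0 := 0`.
* A methylome needs $\ge$ 1,000 CpGs to estimate a background; a global
  background below 0.5 warns but the test still runs. Region p-values
  underflowing 1e-300 are clamped before the log.
* Empty junction windows, empty groups and missing flanks degrade to
  `NA`/warnings, never silent zeros.
* One pseudo-random stream per simulation keyed by `rng_seed`; MeDIP and
  NMD fixtures derive child seeds, all below $2^{31}$.

## Problem sizes

The test suite and the acceptance script run the default study (200 genes,
4 Mb, three cell types, ~40,000 CpGs per methylome) — chosen as the smallest
scale at which every caller sees a statistically meaningful number of
planted events (30–50 per class); the full pipeline completes in well under
a minute.

## A worked run

```{r run, eval = FALSE}
sim <- simulate_genome(sim_config(rng_seed = 42))
run <- run_pipeline(sim)
print(run)
run$results$regnet$directionality
```

## Known limitations

* The DE statistic is a stated substitute for the unpublished original; on
  overdispersed real replicates a negative-binomial test (e.g. edgeR/DESeq2)
  would be preferred — here there are no biological replicates by design.
* The UMR segmentation reproduces the published cutoff and output scale, not
  the unpublished algorithm; region p-values are not corrected across
  regions (the printed cutoff is applied as printed).
* `predict_nmd` requires transcript sequences, which the simulator does not
  generate; NMD rates in this package are exercised on synthetic transcript
  sets.
* MeDIP calibration assumes the reference WGBS distribution is from
  comparable material; a mismatched reference shifts scores monotonically.
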