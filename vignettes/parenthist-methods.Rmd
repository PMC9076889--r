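---
title: "Methods: strand-resolved quantification of parental histone inheritance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-resolved quantification of parental histone inheritance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parenthist)
library(dplyr)
```

## The scientific problem

When a replication fork passes through chromatin, the nucleosomes ahead of
it are disassembled and their parental histones — carrying the cell's
epigenetic marks — are redeposited behind the fork, onto either the
leading or the lagging daughter strand. Specific replisome subunits
chaperone this hand-off: the Mcm2 histone-binding motif and DNA
polymerase alpha route parental histones to the lagging strand, while the
Pole3/Pole4 subunits of polymerase epsilon route them to the leading
strand. `parenthist` implements the three quantitative read-outs used to
study this process and a fork simulator with known ground truth, so the
whole analysis chain can be validated without sequencing data.

## The strand-bias statistic

Sequencing of protein-associated nascent DNA (eSPAN) yields reads that
map to the Watson (plus, `W`) or Crick (minus, `C`) strand of the
reference. Because a rightward-moving fork synthesizes its nascent
leading strand as the Watson strand, the per-bin statistic

$$\mathrm{bias} = \frac{W - C}{W + C}$$

is positive where the profiled histone sits on the leading strand right
of an origin, and negative left of it, producing the characteristic
antisymmetric profile around replication origins. The pipeline follows
the standard procedure:

* reads are assigned to **5 kb** bins by their midpoint;
* bins with **fewer than 4 reads** are masked, never zero-filled — a
  near-empty bin carries no strand information and a 0 would pull
  averages toward the null;
* the eSPAN bias is **normalized by subtracting** the matched BrdU-IP
  control bias per bin. The control samples nascent DNA without the
  chromatin pull-down, so its asymmetry is technical. Subtraction was
  chosen over a ratio because bias is a signed quantity crossing zero;
  the operator is isolated in `normalize_bias()` so an alternative
  transform can be swapped in;
* the track is smoothed with a **five-flanking-bin** (11-bin centered)
  masked-aware mean, read as five bins *per side*; the window truncates
  at chromosome ends, and the read filter is never re-applied after
  smoothing;
* bias is averaged per offset across origins; the per-origin matrix is
  ranked by origin firing efficiency, the order used for heatmaps.

`leading_bias_score()` condenses a profile to
$\tfrac12(\overline{\mathrm{bias}}_{\text{right}} -
\overline{\mathrm{bias}}_{\text{left}})$; it is the only place where the
left arm's sign is flipped — stored tracks keep their genomic
orientation.

## Coverage normalization and the dilution law

Two linear scalings are provided. Reads-per-million divides by the
sample's own mapped-read count (factor $10^6/N_{\text{sample}}$) and
therefore cancels any genome-wide abundance change. Spike-in
normalization divides by the reads aligned to a fixed admixture of
labeled human cells (factor $10^6/N_{\text{human}}$, so factor ×
human library = $10^6$ identically) and preserves absolute changes.

For a one-shot labeled parental histone pool diluted by replication, the
expected spike-in-normalized density at a locus follows $1/(1+f)$ where
$f$ is the replicated fraction — 0.5 when the genome has doubled — while
the RPM-normalized density stays flat. The CUT&RUN simulator reproduces
exactly this contrast, and the acceptance tests verify both limbs.

## The simulator

The generator is first-class, tested code; its defaults encode the study
conditions being emulated:

| parameter | default | rationale |
|---|---|---|
| pulse length | 40 min | nucleotide-analog pulse of the protocol |
| spike-in fraction | 20% | human cells mixed into each sample |
| fork speed | 1 kb/min | mammalian replication fork ballpark |
| nucleosome spacing | 200 bp | one histone position per ~200 bp |
| read length | 100 bp | centered on the histone position |
| frame interval | 20 min | live-cell imaging cadence |
| movie length | 16 h | one full division captured |
| phase offsets | 11 h / 1 h / 1 h | G1/S, G2, next-G1 relative to mitosis (12 h for the double mutant) |

Each origin fires per cell-equivalent as an independent Bernoulli draw
with probability equal to its efficiency; a fired origin replicates
`fork_speed × pulse_minutes` on each side. Parental histones are placed
at nucleosome spacing, recycled with probability `retain_prob`, and sent
to the leading strand with probability `p_leading`. Genotype presets (WT
0.55, Mcm2-2A/Pola1-2A 0.75, Pole3/4 KO 0.40, double mutant 0.55 with
lower retention) are simulator knobs chosen to reproduce the qualitative
mutant ordering; they are **not** estimates of the underlying biology.
Toy genomes place origins far enough apart that replicated windows never
collide, so no fork-merging is modeled.

The live-cell generator locks S phase to the cell cycle (from
`cycle_hours` before mitosis to 1 h before it) and treats the geminin
reporter rise as a noisy observation of the G1/S transition; retention
loss is applied linearly across S phase over a discrete pool of labeled
quanta, so per-cell retained fractions scatter binomially around
`retain_prob`. Daughters split the mitotic signal by a symmetric
Beta-distributed fraction with mean forced to 0.5. Photobleaching is a
continuous exponential decay of the whole lineage; consequently the
daughter sum equals the G2 signal exactly only without bleaching, and
with bleaching falls short of it by the two inter-frame hours of decay
(≈ `exp(-2·bleach_rate)`), while falling short of G1/S by the full
interval — the signature that distinguishes imaging loss from recycling
loss.

What the simulator does **not** model: fragment-length and GC effects,
sequencing errors, Okazaki-fragment maturation, fork stalling,
replication timing, image segmentation. Tests passing on simulated data
therefore validate the analysis chain's arithmetic, masking, and
conventions — not robustness to those real-data artifacts.

## Numerical choices and degenerate inputs

* Bins tile from coordinate 0; all intervals are 0-based half-open; read
  assignment is by midpoint (`(start + end) %/% 2`).
* `W = C = 0` is masked, not 0; bias is exactly ±1 iff one strand count
  is zero and the total passes the filter.
* Phase times snap to the nearest imaging frame with ties rounded toward
  mitosis; the frame grid extends arithmetically past a trace's end so
  an 11-hour offset is well-defined for short traces.
* Geminin thresholds: appearance at the first crossing above 50% of the
  trace maximum sustained ≥ 2 frames; mitosis at the first subsequent
  drop below 25%. Both are exposed parameters.
* The Student t test is the classic equal-variance form (Welch behind a
  flag); zero pooled variance with equal means yields p = 1 by
  convention.
* One root seed feeds deterministic per-assay child streams; identical
  configuration implies byte-identical outputs, which the pipeline
  manifest (MD5 per file) makes checkable.

## Problem sizes

The shipped tests and reproduction script run on toy genomes of one or
two 1 Mb chromosomes with ~10 origins and 40 genes, 10–20
cell-equivalents (tens of thousands of stranded reads), 100,000-read
coverage libraries, and cohorts of 50–200 cells — sizes at which every
derived quantity (bias antisymmetry, the 1/(1+f) dilution, retention
recovery, genotype ordering over 10 seeds) is measurable with
comfortable Monte-Carlo margins while the full suite completes in about
a minute.

## Worked example

```{r example}
genome <- make_genome(n_chroms = 1, chrom_length = 1e6,
                      n_origins = 10, n_genes = 40, seed = 7)
sim <- simulate_espan(genome, transfer_params("Mcm2-2A"),
                      sim_config(seed = 1, n_cells = 10))
espan <- compute_bias(count_stranded_reads(sim$espan, genome))
ctrl  <- compute_bias(count_stranded_reads(sim$brdu, genome))
profile <- espan |>
  normalize_bias(ctrl) |>
  smooth_bias() |>
  aggregate_origins(genome$origins, flank_bp = 50000)
glance(profile)
```

```{r plot, fig.width = 6, fig.height = 3.5}
ggplot2::autoplot(profile)
```

A positive score with the antisymmetric profile is the leading-strand
shift expected for the Mcm2-2A preset. The live-cell arm follows the
same grammar:

```{r live}
traces <- simulate_live_cell(transfer_params("WT"), n_cells = 50, seed = 2)
stats <- quantify_inheritance(traces, call_phases(traces, "offset"))
glance(stats)
```

## Known limitations

* The strand convention (rightward fork ⇒ nascent leading = Watson) is a
  single documented constant; data produced under the opposite
  orientation convention must be flipped on input.
* The heatmap ranking key is the simulator's origin efficiency; with
  real data an external efficiency ranking (e.g. from Okazaki-fragment
  sequencing) should be supplied in its place — the ranking key is just
  a column of the origin table.
* Integrated live-cell intensity is taken as given per frame;
  segmentation, background subtraction and projection are upstream of
  the trace contract and their artifacts are invisible here.
* The BrdU-IP normalization operator (subtraction) is an explicit design
  choice; alternatives can be swapped at one function boundary.
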