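---
title: "Detecting codon-resolved ribosome stalling with stallscan"
author: "stallscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting codon-resolved ribosome stalling with stallscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stallscan)
library(data.table)
```

## The biological question

When a cell runs short of an amino acid, the cognate tRNAs lose their
aminoacylation and can no longer fill the ribosomal A site. Elongating
ribosomes then dwell longer on the codons read by those tRNAs. Ribosome
profiling captures this directly: the ~20-34 nt mRNA fragments protected by
ribosomes from nuclease digestion (ribosome-protected fragments, RPFs) pile
up wherever ribosomes pause, and the position of an RPF's 5' end reports the
ribosome's location at codon resolution. Comparing codon-level RPF occupancy
between a nutrient-limited condition and a control therefore reads out which
amino acids are limiting — an in-cell sensor of amino acid availability.

`stallscan` implements this comparison as a tested pipeline: footprint
assignment and QC, the per-codon *subsequence shift* statistic with
amino-acid-level mixed-model inference, metagene density profiles around
codons of interest, and a Z-test of the in-frame signal against an
out-of-frame background. A footprint simulator with configurable per-codon
dwell provides ground truth for every stage.

## The subsequence shift

For each retained footprint the nucleotide triplet `offset` nt downstream of
its 5' end is recorded; with the package's offsets, 15 nt targets the A site
and 12 nt the P site (a 5'-end-to-A-site distance of 15 nt, i.e. the triplet
occupying read positions 15-17 counted from 0). Counts are tallied per gene
and codon, and each gene's counts are normalized to frequencies so that
highly expressed genes do not dominate. Over the set $G$ of genes with at
least `min_gene_count` (default 100) counted footprints in **both** samples,
the mean frequency of codon $c$ in sample $s$ is

$$\bar f_s(c) = \frac{1}{|G|}\sum_{g \in G} \frac{n_s(g,c)}{n_s(g,\cdot)},$$

and the shift is the relative difference

$$\Delta(c) = \frac{\bar f_{\text{cond}}(c) - \bar f_{\text{ctrl}}(c)}
                   {\bar f_{\text{ctrl}}(c)}.$$

A positive shift means ribosomes spend relatively more time on $c$ in the
condition sample. The statistic depends only on within-gene frequencies, so
it is invariant to library size, and averaging is unweighted — one vote per
gene (a count-weighted variant is available behind a flag).

Design choices worth stating explicitly, since the offset convention is
ambiguous in parts of the literature:

* "Position 15 from the 5' end" is interpreted 0-based: the A-site triplet
  occupies read nucleotides 15-17. This is consistent with the 15-nt 5'
  overhang admitted upstream of the CDS start (a read whose A site is the
  start codon has its 5' end exactly 15 nt upstream). The offset is a
  configuration value, not a constant.
* The offset is fixed across read lengths. Length-dependent offsets can be
  emulated by filtering to a length range and re-running with another
  offset.
* Frequencies are averaged over the *same* gene set $G$ for all codons; the
  threshold applies to gene totals, not per-codon counts.
* Codons observed in neither sample are omitted; codons with zero control
  frequency are reported with an undefined (NA) shift and flagged rather
  than silently dropped.

### Footprint validity filters

Only footprints longer than 26 nt (length $\ge$ 27) enter codon counting.
A footprint is assigned to a gene when its 5' end lies within
$[\mathrm{CDS}_{\text{start}} - 15,\ \mathrm{CDS}_{\text{end}} - 27]$ of a
transcript on the matching strand. Reads compatible with more than one gene,
or with more than one reading frame across a gene's transcripts, are
excluded as ambiguous; secondary, unmapped and spliced-through alignments
are never assigned. The filter report reconciles exactly: every input read
is counted in exactly one category. The same length filter is applied
uniformly to the density analysis, exposed as a flag.

### Amino-acid-level inference

Per-codon shifts from replicate condition/control pairs are stacked and
modelled as

```
shift ~ 0 + amino_acid + (1 | codon)
```

fit by REML (`lmerTest`): fixed effects for the 20 amino acids, random
intercepts for the 61 codons. Each amino acid is tested against the grand
mean of the amino-acid effects with a Wald $t$ statistic (Satterthwaite
degrees of freedom), and p-values are Benjamini–Hochberg adjusted across the
20 tests. Replicates enter as independent rows; no replicate random effect
is included. When the codon random-effect variance is estimated at zero the
fit is singular and the model falls back, with a warning, to the equivalent
fixed-effects linear model; when all shifts are identical (e.g. a sample
compared with itself) every $t$ is 0 and every $p$ is 1 by convention.

A calibration caveat found while validating on synthetic nulls: codon
shifts are heteroscedastic — rare codons have noisier shifts because fewer
gene-positions contribute — and neither the mixed model nor its
fixed-effects fallback models this. On pure-sampling-noise null simulations
the unadjusted per-amino-acid false-positive rate at $\alpha = 0.05$ runs
slightly high (about 0.07 in our null experiments), concentrated in amino
acids with rare codons. In real libraries codon-level biological variation
(context effects, which the random intercept absorbs) dominates sampling
noise, so the practical impact is smaller, but borderline amino-acid calls
should be cross-checked against the per-codon z-tests below.

## Density profiles around a codon

For a query codon, every in-frame occurrence whose 61-nt window (30 nt on
each side of the codon's first nucleotide) lies fully inside the transcript
defines a *codon region*; occurrences too close to transcript ends are
excluded, regions from overlapping transcripts are all retained, and regions
with identical reference coordinates are collapsed. 5'-end counts are
accumulated per window position. Regions need at least `min_region_count`
(default 50) counts in both samples; when fewer than `min_windows_common`
(default 1000) regions survive for a common codon, the threshold is lowered
stepwise (50, 40, 30, 20, 10) until enough survive — the schedule used is
recorded in the output. Each surviving region is normalized to mean density
1 (counts divided by total/61) and smoothed with a rectangular kernel of
width 3 and height 1/3. The position-wise mean over regions is computed per
sample, and the difference of means is the *density shift*. A stall at the
query codon appears as a positive density-shift peak 15 nt upstream of the
window centre — the 5'-end position of a ribosome decoding the centre codon
(width-3 smoothing spreads this spike over positions -16 to -14).

Two numerical choices:

* **Smoothing boundary.** The kernel is applied with reflection padding at
  the window edges (the edge value is counted twice). Reflection is the
  boundary rule that conserves the window mean exactly, keeping the
  "average density 1" contract true after smoothing; truncating and
  renormalizing the kernel at the edges does not (edge positions would
  receive total weight 5/6).
* **Order of operations.** Smoothing is applied per region before
  cross-region averaging. The two operations are linear and commute except
  at the window edges, where per-region smoothing keeps each region's mean
  at exactly 1.

## The out-of-frame Z-test

The significance of a codon's shift is assessed against an empirical null
built from the same data: shifts computed for every nucleotide triplet read
1 nt upstream and 1 nt downstream of the in-frame position (offsets 14 and
16 for an A-site signal at 15), using the identical gene-normalization
machinery. These out-of-frame triplets share the library's technical biases
but carry no codon-level translational signal. Two exclusions keep the null
honest:

* Triplets that physically overlap the target codon by two bases would leak
  its signal into the background: at the -1 offset, triplets whose last two
  bases equal the target's first two (`NGC` for target `GCA`); at the +1
  offset, triplets whose first two bases equal the target's last two
  (`CAN` for `GCA`). This two-base-overlap rule generalizes the published
  GCA example to any codon.
* Only footprints whose 5' end is in frame with the target offset
  contribute to the background counts; otherwise frame-jittered reads would
  place genuinely in-frame codons at the ±1 positions.

With background mean $\mu_b$ and sample standard deviation $s_b$ ($n-1$
denominator — the background has at most ~120 values), the statistic is
$z = (\Delta_{\text{obs}} - \mu_b)/s_b$ with a two-tailed normal p-value.
Normality of the background is diagnosed — Anderson–Darling statistic,
Shapiro–Wilk p, Q-Q coordinates — but never used to gate results; a
Shapiro–Wilk p below 0.05 raises a flag on the result instead. Identical
samples produce an all-zero background; this degenerate case is reported
explicitly rather than producing a division by zero. At least 8 background
values are required for a test.

On null simulations the resulting p-values are approximately uniform
(Kolmogorov–Smirnov distance below 0.1 over 500 null pairs in the
acceptance suite), so the z-test is the better-calibrated of the two
inference routes.

## The synthetic data generator

`sim_transcriptome()` builds single-transcript genes: a CDS of 90-1800 nt
(ATG-initiated, stop-terminated, no internal stops, length a multiple of 3)
flanked by UTRs, with log-normal(0, 1) expression weights — a realistic
span of ~2 orders of magnitude in abundance. `sim_footprints()` places each
read by (1) choosing a transcript proportionally to expression weight,
(2) choosing an A-site codon within the CDS proportionally to the dwell
profile (uniform baseline 1; stalling is dwell > 1 at chosen codons),
(3) setting the 5' end 15 nt upstream, optionally jittered ±1 nt, and
(4) drawing the read length from a triangular distribution over 20-34 nt
with mode 30 — the size-selection window of typical RPF libraries, with the
mode at the canonical monosome footprint length. Real libraries vary in
their empirical length and frame-noise distributions, so both are
configuration values.

A-site candidates are restricted to codons at least 15 nt from the CDS
start and at least (max length - 15) nt from the CDS end, so every read —
including jittered ones — fits its transcript and the analytic occupancy
probability of each codon is an exact finite sum (`asite_probabilities()`).
The start codon is excluded as an A site by default to avoid confounding
initiation peaks with stalling; a separate `init_dwell` parameter re-admits
it for metagene QC demonstrations. Stop codons never serve as A sites. With
dwell $d$ on a single codon of pooled candidate frequency $f$ and uniform
expression, the expected A-site fraction is $d f / (1 + (d-1) f)$ — the
acceptance suite checks the simulator against this closed form.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: sequencing errors, ligation/adapter
artefacts beyond a simple per-codon capture bias, rRNA contamination, UMI
collisions, spliced genome-coordinate alignment, nonuniform baseline dwell
(codon-context effects), and multi-isoform genes (the gene/frame ambiguity
filters are exercised by constructed fixtures instead). Simulation results
demonstrate correctness of the statistical machinery, not robustness to
every artefact of real libraries.

## Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `min_length` | 27 nt | minimum footprint length (reads > 26 nt) |
| `overhang_5p` | 15 nt | admitted 5' overhang upstream of the CDS start |
| `offset` | 15 (A), 12 (P) nt | 5'-end-to-site distance, 0-based |
| `min_gene_count` | 100 | per-gene count floor, both samples, for shifts |
| `min_region_count` | 50 | per-region count floor, both samples, for density |
| `min_windows_common` | 1000 | target region count before threshold lowering |
| `jitter_prob` | 0 | simulator 5'-end ±1 nt displacement probability |
| `a_site_offset` | 15 nt | simulator 5'-end-to-A-site distance |

## Problem sizes used by the test and acceptance suites

The suites are sized to exercise the statistics at meaningful power while
remaining desk-runnable: unit fixtures use 5-60 genes and $10^3$-$10^5$
reads; the stall-recovery experiment uses 200 genes with 3 replicate pairs
of $10^6$ reads plus 20 repeat pairs for the z-test detection rate; null
calibration uses 500 pairs of $3 \times 10^4$ reads (out-of-frame p
uniformity) and 25 two-replicate experiments of $10^5$ reads (amino-acid
false-positive rate). These sizes are the package's own choices of
simulation scale, stated here so results are reproducible.

## Known limitations

* Transcript-coordinate alignments with contiguous CDS records are assumed;
  spliced (genome-coordinate) alignments are rejected per read, and
  transcripts with non-contiguous CDS annotations are dropped with a
  warning.
* The amino-acid mixed model ignores codon-level heteroscedasticity (see
  above); its p-values are mildly anticonservative on pure sampling-noise
  nulls.
* The out-of-frame background shares gene-normalization machinery with the
  signal, so backgrounds from very few genes (or a `min_gene_count` that
  leaves few genes) are unstable; the 8-value floor is a guard, not a
  guarantee.
* One representative transcript (longest CDS) is used per gene for codon
  counting; genes whose isoforms differ in CDS content are summarized by
  that representative.

## A minimal session

```{r example, eval = FALSE}
tx <- sim_transcriptome(50, c(300, 900), seed = 1)
cond <- sim_footprints(tx, stalling_profile(c(GCA = 5)),
                       sim_config(2e5, seed = 11))
ctrl <- sim_footprints(tx, stalling_profile(), sim_config(2e5, seed = 12))

ann <- annotation_of(tx)
cs <- cds_sequences(tx)
rc <- assign_rpfs(as_alignments(cond), ann)$rpfs
rk <- assign_rpfs(as_alignments(ctrl), ann)$rpfs

shifts <- compute_shifts(count_codons(rc, cs), count_codons(rk, cs))
head(shifts[order(-shift)])

oof_test(rc, rk, cs, "GCA")
```
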