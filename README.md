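# stallscan

Codon-resolved detection of ribosome stalling from ribosome profiling
(Ribo-seq) data.

When an amino acid becomes limiting, its tRNAs lose their charge and
ribosomes dwell longer on the corresponding codons. Ribosome-protected
fragments (RPFs) accumulate at those codons, so comparing codon-level RPF
occupancy between a condition and a control library reveals which amino
acids are scarce — an in-cell sensor of amino acid availability.
`stallscan` is for computational biologists analysing paired Ribo-seq
libraries (nutrient limitation, co-culture, in vivo compartments) who want
this readout as a tested, reproducible pipeline rather than a collection of
scripts.

## What it computes

**Subsequence shift.** Each retained footprint (length > 26 nt, 5' end
within `[CDS_start − 15, CDS_end − 27]`, unambiguous gene and frame)
contributes the codon 15 nt downstream of its 5' end (the A site; 12 nt
gives the P site). Counts are normalized per gene and averaged over genes
with ≥ 100 counts in both samples:

    f̄_s(c) = (1/|G|) Σ_{g∈G} n_s(g,c) / n_s(g,·)
    Δ(c)   = (f̄_cond(c) − f̄_ctrl(c)) / f̄_ctrl(c)

**Amino-acid test.** Replicate codon shifts are modelled with
`shift ~ 0 + amino_acid + (1 | codon)` (REML; Wald t of each amino acid
against the grand mean, Satterthwaite df, Benjamini–Hochberg adjusted).

**Density profiles.** 61-nt windows centred on each in-frame occurrence of
a query codon, jointly filtered (≥ 50 counts in both samples), normalized
to mean density 1, smoothed with a width-3 rectangular kernel; the
difference of the position-wise means is the density shift, peaking 15 nt
upstream of the centre for a stalled codon.

**Out-of-frame Z-test.** The shift of a codon is tested against the shifts
of all triplets read ±1 nt out of frame (excluding triplets that overlap
the target by two bases, e.g. `NGC`/`CAN` for `GCA`):
`z = (Δ_obs − mean(bg)) / sd(bg)`, two-tailed p, with Anderson–Darling /
Shapiro–Wilk / Q-Q normality diagnostics attached.

**Simulator.** A synthetic transcriptome and footprint generator with
configurable per-codon dwell, 5'-end jitter, read-length distribution and
ligation bias provides ground truth; `asite_probabilities()` gives the
exact analytic codon occupancy for any configuration.

## Worked example

Simulate a 5× GCA (alanine) stall and recover it:

```r
library(stallscan)

tx   <- sim_transcriptome(50, c(300, 900), seed = 1)
cond <- sim_footprints(tx, stalling_profile(c(GCA = 5)),
                       sim_config(2e5, seed = 11))
ctrl <- sim_footprints(tx, stalling_profile(), sim_config(2e5, seed = 12))

ann <- annotation_of(tx)
cs  <- cds_sequences(tx)
rc  <- assign_rpfs(as_alignments(cond), ann)$rpfs
rk  <- assign_rpfs(as_alignments(ctrl), ann)$rpfs

shifts <- compute_shifts(count_codons(rc, cs), count_codons(rk, cs))
head(shifts[order(-shift)], 3)
#>     codon amino_acid      shift mean_freq_condition mean_freq_control
#> 1:    GCA          A 3.64530491          0.06816827        0.01467466
#> 2:    GGC          G 0.03107934          0.01530390        0.01484260
#> 3:    AGC          S 0.02770274          0.01719650        0.01673295

oof_test(rc, rk, cs, "GCA")
#> Out-of-frame z-test for GCA: observed 3.6453,
#>   background -0.0525 +/- 0.0435 (n=120), z = 85.02, p = 0
```

GCA's occupancy frequency rises from 1.5% to 6.8% — a shift of 3.65, the
only codon standing far above the background of out-of-frame triplet shifts
(mean −0.05, sd 0.04), hence the extreme z. All other codons shift by < 4%.

File-based workflows use the same functions via `load_annotation()` /
`load_alignments()` (SAM or BAM), or the whole pipeline via
`run_pipeline(run_config(...))` / the `inst/cli/stallscan` script, which
writes shift tables, amino-acid tests, density profiles, z-tests, filter
reports and a checksummed manifest.

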