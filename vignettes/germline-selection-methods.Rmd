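---
title: "Models and methods: detecting germline selection in testis mosaics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: detecting germline selection in testis mosaics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germselect)
```

# The problem

Some gain-of-function substitutions in *PTPN11* (encoding the SHP-2
phosphatase) give a spermatogonial stem cell (SSC) a small self-renewal
advantage. Over decades such a cell founds a clonal cluster inside the
testis, so an older man's germline becomes a mosaic of independent mutant
clones and a disproportionate share of his sperm carries disease-causing
variants. This package implements the computational machinery needed to
measure and interpret that process from error-corrected deep sequencing of
spatially dissected testes: a UID-family consensus caller, a candidate
variant registry for the 127-site exon-3 amplicon, branching-process models
of SSC dynamics, a Monte-Carlo envelope test for spatial clustering, and a
birth-incidence extrapolation for Noonan syndrome (NS).

# Measurement model

Each testis is cut into 6 slices x 32 pieces = 192 pieces, and each piece
is sequenced with single-molecule tagging: reads carry an 8-nt piece barcode
and a 20-nt unique identifier (UID), and all reads sharing a UID within a
piece derive from one original DNA strand (a *UID family*). The caller

1. corrects barcodes against a whitelist with pairwise Hamming distance
   >= 3 (one error is uniquely correctable; two errors force a discard —
   `correct_barcode()`);
2. groups reads into UID families (`group_uid_families()`);
3. calls a family consensus: a family counts only with >= `min_size` reads
   (default 3) and an alternate allele is called at a site only when at
   least `min_fraction` (default 0.9) of the family's reads agree
   (`call_family_consensus()`). The underlying assay convention is
   near-unanimity within a family without a canonical cutoff, so both
   knobs are exposed;
4. tabulates, per piece and candidate substitution, mutant and total UID
   families (`tabulate_piece_counts()`). Pieces with fewer than 1,000
   families are flagged missing, since the per-piece frequency precision is
   1/(family count).

The per-piece variant frequency is mutant families / total families; the
*average testis frequency* pools counts over non-missing pieces, and the
*maximum piece frequency* (MaxPF) is the largest per-piece frequency. A
clone confined to a few adjacent pieces produces a MaxPF far above the
average — the signature of germline selection.

# Stem-cell dynamics

`sim_params()` configures a two-phase model:

* **Growth phase** (zygote to puberty, default age 13): 30 synchronous
  symmetric doublings build an adult pool of 2^30 SSC. A mutation arising
  at doubling *g* founds a clone that reaches 2^(30-g-1) cells at puberty.
* **Adult phase**: every stem cell divides once per 16 days. A wild-type
  division renews (two stem daughters) with probability 0.5, otherwise both
  daughters differentiate towards sperm; the pool is a critical branching
  process, constant in expectation. Mutant cells renew with probability
  0.5 + s. The neutral model has s = 0; the selection model a small
  positive s, making mutant clones supercritical with growth factor
  (1 + 2s) per cycle.

New mutant lineages arise at rate `mu` per site per division in both
phases. The engine (`simulate_testis()`, `simulate_variant_stats()`) tracks
the wild-type pool in expectation and each mutant lineage individually as a
Galton-Watson process — simulating 2^30 individual cells is unnecessary
because only mutant-lineage trajectories matter. Standard branching-process
facts anchor the unit tests: neutral extinction follows the recursion
q(t+1) = 0.5 + 0.5 q(t)^2, and a selected lineage survives forever with
probability 1 - (0.5 - s)/(0.5 + s) = 2s/(0.5 + s).

**Pool size matters.** A neutral adult clone alive after t cycles has
absolute size of order t/2 cells *independent of the pool size N*, so its
piece frequency scales as 1/N. The adult pool therefore defaults to
2^`growth_generations` = 2^30, the value implied by the growth phase
itself; a much smaller pool would push the neutral MaxPF envelope above the
frequencies at which real clusters are observed. (Frequencies of selected
clones, by contrast, are N-insensitive.)

**Spatial model.** Cells sit on a circular 1-D axis cut into 192 equal
segments (slices = consecutive blocks of 32 pieces). Each lineage occupies
a contiguous arc anchored at a uniform random position, so clones span
adjacent pieces and cells are conserved (`map_to_pieces()`). The true
spatial mechanism of SSC clones is unknown; contiguity is the minimal
assumption reproducing the observed adjacent-piece clusters.

**Sequencing sampling.** Observed mutant family counts are
Binomial(families per piece, piece fraction + assay background), with
per-substitution-type backgrounds: 3.3e-6 for ordinary types and 5.5x that
for the damage-prone C>T/G>A and G>T/C>A classes (`sample_sequencing()`,
`default_background_rates()`).

# The cluster significance test

Every candidate variant in a testis yields (average frequency, MaxPF). The
null envelope (`neutral_envelope()`, `build_envelope()`) is built from
neutral-model simulations across a mutation-rate grid so that simulated
average frequencies span the observed range; per log-spaced
average-frequency bin the threshold is the empirical 1 - alpha/K quantile
of the neutral MaxPF (inverse ECDF), with alpha = 0.01 and Bonferroni
divisor K = 762 (127 sites x 3 alternates x 2 testes). A variant is a
significant cluster when its MaxPF strictly exceeds the interpolated
threshold at its average frequency (`classify_variant()`).

Numerical choices:

* **Binning/interpolation**: 20 log-spaced bins over [1e-8, 1e-3];
  thresholds interpolate log-log between bin centers and are forced
  monotone by an isotonic pass.
* **Right tail**: above the highest bin with at least `min_bin` = 100
  replicates the threshold continues with slope one in log-log space. This
  is the geometric ceiling of the statistic — a single clone concentrated
  in one piece has MaxPF ~ 192 x average — and it is also what the sparse
  high-average simulations (dominated by rare large embryonic clones)
  converge to. Folding those few jackpot replicates into lower-average
  bins instead would corrupt the mid-range thresholds, which is why sparse
  bins are widened leftwards only below the top dense bin.
* **Degenerate inputs**: variants whose pieces are all missing are excluded
  with a warning; all-zero tables get MaxPF 0 at the first piece by the
  deterministic (slice, piece) tie-break.

The family-wise contract — a fully neutral testis has < 1% chance of any
significant call across all 381 candidates — is verified by simulation in
the acceptance suite (`measure_type_one_error()`), as is the young-donor
property that a 21-year-old testis virtually never shows significant
clusters (too few adult cycles for clones to grow).

# Calibration and the NS birth rate

The selection model has two free parameters, `mu` and `s`.
`calibrate_selection()` grid-searches them against three observed summaries
of the two older donors (ages 65 and 68): the fraction of disease/cancer
candidate variants forming significant clusters (25/100), and the printed
worked-example cluster's average frequency (1.7e-5) and MaxPF (4.8e-3) as
the typical values of significant clusters. The score is the sum of squared
log-ratios, all terms weighted equally. The mutation-rate grid is bounded
to a few-fold of the genome-average per-division rate the model assumes
(a per-generation substitution rate near 1.2e-8 spread over the few hundred
germline divisions before typical fatherhood gives roughly 3e-11 per
division); the fit is only weakly identified along a (mu, s) ridge, and the
bound keeps it in the biologically cited range.

`predict_birth_rate()` extrapolates the calibrated model to the NS birth
rate under the equal-contribution assumption: 110 NS1 variant sites, each
behaving like the calibrated exon-3 site, each contributing its expected
mutant sperm fraction. The expectation is computed in closed form (by
linearity over lineage arrivals):

E[freq after T cycles] = mu ((1+2s)^T - 1) / (2s) + (G/2) mu (1+2s)^T,

weighted by (1 - 2s) for the differentiation output. A Monte-Carlo
estimate of this expectation would be dominated by rare jackpot lineages;
the closed form is exact for the declared process.

**Age distribution.** The default (`study_donor_ages()`) evaluates the
expectation at the two donor ages (65 and 68, equal weight) — the ages at
which the model is constrained by data and at which the measured average
testis frequency is taken as the transmission-probability proxy. Because
clonal expansion is exponential in age, integrating instead over a
population distribution of fathers' ages (`population_paternal_ages()`,
mean 31, SD 6.5) yields rates one to two orders of magnitude lower; users
studying realized population incidence under the model should prefer the
population distribution and interpret the donor-age default as the
selection-driven ceiling anchored at the measured ages. This sensitivity is
the dominant uncertainty in the extrapolation and is deliberately exposed
as a parameter.

# What the synthetic generator does and does not emulate

`generator_config()`/`gen_piece_counts()`/`gen_reads()` reproduce the
study's *structure*: 3 donors x 192 pieces, ~64,000 UID families per piece,
type-specific backgrounds, clonal spikes confined to contiguous pieces, and
the exact read layout (barcode + UID + 127-nt amplicon) with Hamming-3
barcodes. They do not emulate: variable per-piece family counts (the real
study's depths vary several-fold and seven pieces fell below the missing
threshold; the generator defaults to constant depth, which slightly
understates MaxPF noise), PCR family-size biases, quality-score profiles,
or position-dependent error spectra beyond the six substitution classes.
Green tests on synthetic data therefore validate the pipeline's logic and
its statistical contracts, not the full messiness of the assay.

Reference bases of the packaged amplicon lookup are real only at the ~30
positions pinned by the curated variant table; the rest are fixed synthetic
filler (flagged in the file), sufficient for simulation and for classifying
consequences of unannotated substitutions but not for transcript-level
annotation, which is out of scope.

# Problem sizes

The shipped acceptance runs use: an envelope from ~207,000 neutral
replicates across four mutation rates (most at the genome-average rate,
fewer at elevated rates to populate high-frequency bins); 500 fresh neutral
testes x 381 candidates for the family-wise error; 1,500 replicates per age
per grid point for calibration (6 x 6 grid); and closed-form birth-rate
evaluation. These sizes give stable envelope thresholds in the densely
populated bins while keeping a full run in the tens of minutes on one CPU;
the envelope's extreme-quantile bins remain the dominant Monte-Carlo noise
source, and users wanting tighter thresholds should raise `reps_per_mu`.

# Known limitations

* The envelope conditions on average frequency alone; variants reaching a
  given average via background noise and via clones have different MaxPF
  nulls, and the bin mixture is only as representative as the simulation
  mix supplied.
* There is no canonical choice of Bonferroni divisor, percentile estimator
  or simulation size for envelopes of this kind; this package fixes
  defensible choices (K = 762, inverse-ECDF quantile) and tests the
  family-wise error contract directly.
* Calibration targets rest on a single reported worked-example cluster,
  and the (mu, s) fit is weakly identified along a ridge.
* The model cannot simultaneously reproduce the printed per-donor cluster
  counts (8 at 65 vs 17 at 68) — it has no donor heterogeneity — and the
  birth-rate extrapolation inherits whichever compromise the calibration
  makes.
* Duplex (two-strand) error correction, alignment, and quality-aware
  consensus are out of scope: inserts are fixed-length amplicons.
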