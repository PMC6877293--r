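---
title: "Fragment-size-resolved MNase-seq analysis of HU-organised archaeal chromatin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-size-resolved MNase-seq analysis of HU-organised archaeal chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htatools)
```

## The problem

*Thermoplasma acidophilum* packages its circular ~1.56 Mb chromosome with
HTa, a highly expressed HU-family protein, instead of histones. MNase
digestion of such chromatin leaves protein-protected DNA fragments whose
lengths fall into two classes — small fragments of 40–65 bp (a minimal
binding footprint) and large fragments of 70–100 bp (extended footprints,
consistent with a nucleation–extension mode of binding in which additional
protomers join an initial, sequence-favoured contact and grow the
footprint directionally). `htatools` turns mapped protected fragments into
normalized coverage tracks, called and oriented footprints, dyad-relative
nucleotide profiles, and a sequence model of occupancy, and it ships a
synthetic-data generator that reproduces the statistical structure of all
of these so that every stage can be validated against known ground truth.

Coordinates are 0-based half-open throughout, the genome is treated as
circular everywhere (windows, coverage and fragment sampling wrap), and
the dyad of a fragment or peak of even width is the left-of-centre base
(`floor((start + end) / 2)`), applied uniformly.

## Coverage and normalization

`compute_coverage()` counts, for every base pair, the retained fragments
overlapping it, restricted to a size class. Class bounds are inclusive on
both ends — small `[40, 65]`, large `[70, 100]` — so a 66–69 bp fragment
belongs to neither class; the bounds are recorded in the track metadata.

Two biases are handled explicitly:

* **Sequencing depth.** `rpgc_normalize()` rescales a raw track by
  `effective_genome_size / sum(values)` so that mean coverage over the
  effective genome size is 1 ("1× genome coverage"). For the
  *T. acidophilum* assembly the effective size is 1,564,906 bp
  (`genome_length_ta()`).
* **Replication.** Exponentially growing cells carry more copies of
  early-replicating, origin-proximal DNA. `normalize_by_input()` divides
  the MNase track by a 10 kb running-mean-smoothed copy of the matched
  sonicated input and converts the ratio to a Z-score (mean 0, sd 1).
  Smoothing the input is deliberate: the input's own sampling noise must
  not be injected into the signal. When no input exists,
  `self_normalize()` divides by a 250 kb smoothed copy of the track
  itself; with a window at or beyond the genome length this degenerates,
  by construction, to global-mean normalization. Zeros in the smoothed
  input raise an error rather than being patched silently — a pseudocount
  is available but must be requested (`pseudocount =`), because silent
  pseudocounts distort ratios where coverage is genuinely absent.

The Z-score is computed over all positions; masking of unmappable regions,
if wanted, belongs upstream. An optional `cap_coverage()` post-processor
thresholds raw tracks at an upper percentile (useful for duplicate-heavy
libraries); it is off by default.

## Peak calling

`fourier_filter()` takes the discrete Fourier transform of the (circular)
track and keeps the lowest-frequency fraction of components (default 2%,
the conventional scale for footprint-sized features; configurable per
run), preserving the mean exactly. `detect_peaks()` then takes local
maxima of the filtered track as candidate dyads (leftmost position on
plateaus), measures each peak's extent as the contiguous region above half
its centre height — a parameter-free definition that makes width testable
— and scores each candidate as

```
score = (filtered[center] - mean(raw)) / sd(raw)
```

i.e. the low-pass peak height as a standard score against the empirical
distribution of the unfiltered track, thresholded at 2.5. Scoring the
*filtered* height (rather than the raw value at the filtered maximum) is a
deliberate design choice: candidate maxima are already selected positions,
so raw values there are biased upward, and a raw-value score at threshold
2.5 would admit a steady trickle of false calls on pure noise. The
filtered height has no such selection inflation: on featureless tracks the
retained low-frequency components carry only ~2% of the variance, so no
candidate approaches the threshold, while a genuine footprint's height
passes the filter nearly intact. The package's validation checks both
sides: ≥ 95% of planted, well-separated footprints recovered within
±5 bp, and zero calls on pure noise in ≥ 99% of simulations. Because the
score is location/scale-free, calls are invariant under affine rescaling
of the track. Detection expects a mean-zero normalized track (the output
of the normalization step), for which the half-height extent is well
defined.

Extent widths ≤ 65 bp are classed narrow, ≥ 70 bp broad (mirroring the
fragment classes); 66–69 bp extents stay unclassified. `overlap_peaks()`
matches two peak sets greedily by reciprocal overlap (default 50% of both
extents). `decile_partition()` ranks broad peaks by
`mean(small) / (mean(small) + mean(large))` over the extent and splits
them into ten equal-count groups, lowest relative small-fragment coverage
first. `intergenic_enrichment()` calls a peak intergenic when its dyad
lies outside every gene interval and reports the enrichment ratio against
the genomic intergenic fraction plus an exact upper-tail hypergeometric
p-value (query drawn from a stated peak population).

## Orienting broad footprints

Nucleation–extension predicts that small fragments concentrate at one edge
of a broad footprint. `orient_peaks()` computes the mean small-fragment
coverage over `[dyad - h, dyad)` (a) and `[dyad, dyad + h)` (b) — h
defaults to half the peak extent, since the averaging span is a free
choice — and flags peaks with a/b < 1 as flipped. Ties are not flipped;
b = 0 with a > 0 counts as ratio +Inf (not flipped). Downstream,
`reoriented_aggregate()` reverses flipped windows before averaging, and
`length_position_matrix()` bins fragment dyads by length and signed,
orientation-aware offset, from non-normalized fragments so that cell
counts conserve the number of contributing fragments.

## Nucleotide profiles

`positional_class_profile()` reports, per dyad-relative offset, the
proportion of reads whose genomic dinucleotide at that offset belongs to a
class: SS = {CC, CG, GC, GG}, WW = {AA, AT, TA, TT}, the purine classes RR
and YY, their mixed complements, and the mononucleotide classes
mono_GC/mono_AT. Reads first pass `filter_reads()`: mean base quality
≥ 30, overlap with a called peak of at least 90% of the read's length, and
exact-coordinate deduplication (so profiles are not dominated by the most
occupied footprints). Merged MNase fragments are double-stranded and carry
no strand, so profiles are computed on the reference strand; this is what
makes an RR-versus-YY asymmetry across the dyad a meaningful,
bookkeeping-stable property rather than an artefact. The dyad base is
offset 0 and a dinucleotide at offset d spans `[d, d + 2)`; for
even-length reads the floor-dyad convention shifts mirrored profiles by
exactly one base, a property the test suite pins down explicitly.
`background_expectation()` estimates the chance proportion of a class from
25,000 uniformly placed regions of matching size.

## The k-mer LASSO occupancy model

Per-bp features are frequencies of all k-mers (k = 1–4) in 21 bp and
51 bp centred windows — the short window captures read-internal sequence
patterns that never overlap MNase cut sites, the long one spans a full
footprint. Windows containing N are excluded. Of the 680 candidate
features, the 80 with the highest absolute Pearson correlation with the
normalized coverage response over the first third of the genome are kept
(`select_features()`, computed one feature at a time so the full matrix is
never materialised), and `fit_lasso()` fits an L1-penalised linear model
on that training third. Cross-validation folds are *contiguous blocks*:
adjacent base pairs are near-duplicates, and randomly scattered folds
would leak training information into validation and undershoot the
penalty. The penalty grid is 100 log-spaced values down to
`1e-4 · lambda_max`; the minimum-CV-error penalty is the default
(`rule = "min"`), with the conservative one-standard-error rule available
(`rule = "1se"`) — under pure noise the min rule admits a handful of
spurious features in a minority of fits, which is exactly the situation
the 1-SE rule exists for, so the package's noise-robustness check
exercises that rule. Coefficients are returned on the original feature
scale; dinucleotide features print in XpY notation (the "GC" feature is
reported as GpC, the strongest single predictor of HTa occupancy).
Separate models are intended for small- and large-fragment responses.
`predict_coverage()` evaluates the linear model genome-wide and
`evaluate_prediction()` reports Spearman correlation on the trained third,
the untrained remainder, or everything. Position subsampling
(`step`) is supported for very large genomes and logged in the model;
the default is every base pair.

## EMSA band-sequencing quantification

The gel-shift library consists of 100 bp backbone oligos, each with eight
randomized dinucleotides at fixed, non-overlapping positions.
`assign_reads()` matches reads to backbones by exact identity at all
non-randomized positions — no mismatch tolerance, because the randomized
slots make edit-distance assignment ambiguous; erroneous reads are simply
dropped and counted. Ambiguous designs (two backbones identical at all
jointly fixed positions) are rejected at load time. `compute_pslow()`
groups assigned reads by integer-percent G+C content of the full oligo
(the full-oligo convention is the default and configurable) or by GpC
dinucleotide count, and reports `P_slow = n_slow / (n_slow + n_fast)` per
group, plus a per-backbone table. `weighted_correlation()` gives the
Pearson correlation of composition with P_slow, each group weighted by its
read count, with an optional bootstrap CI. An anomalously behaving
backbone (in practice, the most AT-rich one) can be excluded via
`exclude_backbones`.

## The synthetic-data generator

The generator exists so that every analysis stage can be checked against
planted truth; its defaults encode the study conditions the analysis
assumes.

* `generate_genome()`: i.i.d. bases within GC segments tiling a circular
  genome; per-segment realized GC lands within ±2% of target for ≥ 5 kb
  segments.
* `plant_occupancy()`: occupancy = intercept + Σ weight × windowed k-mer
  frequency, shifted to be non-negative — the exact functional form the
  LASSO module is supposed to recover.
* `sample_fragments()`: fragment centres drawn proportional to occupancy
  times an optional origin–terminus copy-number multiplier (linear decay
  with circular distance from the origin, 2:1 by default); lengths from a
  two-component discretised Gaussian mixture truncated to [20, 200] bp
  with modes 50 and 85 bp (the twin ~85 bp sub-modes seen in real data,
  separated by about one helical turn, are not modelled separately — they
  are analysed jointly downstream anyway); a configurable fraction of
  exact coordinate duplicates emulates PCR structure. Exactly
  `n_fragments` records are returned.
* `sample_broad_footprints()`: per nucleation site, large fragments centred
  on the site and small fragments centred on one footprint edge with
  probability `edge_bias`; the per-site preferred edge is recorded as
  ground truth for orientation checks.
* `generate_emsa_pool()`: backbone chosen uniformly per read, slots filled
  i.i.d. over the 16 dinucleotides, slow-band membership drawn from
  `plogis(Σ affinity × feature)` with features GpC count and G+C fraction;
  zero affinity gives P(slow) = 0.5 exactly.

Every generator is a pure function of its spec and seed; the pipeline
derives per-stage sub-seeds deterministically from one master seed, so a
full run is byte-reproducible. What the generator does *not* emulate:
sequencing errors and base-quality structure (a scalar mean quality per
fragment at most), mappability gaps, MNase cut-site sequence bias, and the
twin large-fragment sub-modes. Consequently, passing validation
demonstrates the correctness of the computations and the recoverability of
planted structure — not robustness to every artefact of real libraries.

## Numerical choices and degenerate inputs

* Spearman correlations resolve ties by average ranks (R's default).
* `normalize_by_input` returns all zeros when the ratio's sd is below
  1e-12 (identical signal and input), rather than dividing by ~0.
* Peak extent search is capped (default 1000 bp) to bound worst-case work
  on pathological tracks; the Z-scored inputs used in practice cross half
  height within tens of bp.
* The hypergeometric p-value is computed exactly (log-space internally via
  `phyper`), never by normal approximation.
* Zero-variance features get correlation 0 in selection; a zero-variance
  response is an error, not a silent constant fit.
* A lone selected feature is duplicated internally before the lasso fit
  (the solver requires two columns) and the pooled coefficient returned.

## Validation scale

The bundled checks run at desk scale, chosen to finish in minutes on one
CPU while keeping every estimate well-powered: 100 random 1 kb coverage
instances against a brute-force oracle; a 200 kb genome with 3 × 10^5
fragments (and three replicate datasets, mirroring the study's replicate
pooling) for gradient removal — a single dataset's residual rank
correlation has an effective sample size of only genome/fragment-length,
so the replicate mean is the meaningful measurement of systematic
residual; 50 planted footprints on 100 kb plus 100 pure-noise tracks for
peak calling; a five-k-mer planted model on 100 kb with noise at 25% of
the signal sd, evaluated held-out and on an independent second genome; 100
EMSA pools of 10^5 reads for affinity-sign recovery; and 25,000 sampled
background regions. The demo pipeline uses a 20 kb genome with 6 × 10^4
fragments and a reduced k-mer candidate set (k ≤ 2, top 10 features) so an
end-to-end run, twice for the determinism check, stays in seconds.

## Known limitations

* BAM input is not parsed directly; convert alignments to BED fragments
  upstream (the package is deliberately testable without an alignment
  library).
* Peak extents use the half-height definition; no dyad refinement by
  fragment-midpoint averaging is attempted.
* The LASSO uses plain L1 — no elastic net, interactions, or positional
  (phased) features.
* No statistical test accompanies the a/b asymmetry ratio; it is a
  descriptive re-orientation device.
* Multi-chromosome genomes are out of scope; one circular (or linear)
  sequence per analysis.
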