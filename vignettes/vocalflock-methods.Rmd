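---
title: "Measuring adult vocal learning and social integration in budgerigar flocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring adult vocal learning and social integration in budgerigar flocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vocalflock)
```

## The problem

Budgerigars are open-ended vocal learners: adults joining a new flock
develop contact-call types shared with their new flockmates within weeks.
Whether that ability ages — and how it relates to the animal's social
life — is studied with a repeated-measures design: four previously
unfamiliar males of one age class ("young", 6 months–1 year, or "old",
3+ years) form a flock; each bird's calls are recorded in one pre-flock
baseline block and four post-flock blocks, while affiliative and agonistic
interactions and inter-individual distances are scored from video.
`vocalflock` implements the full measurement chain for this design and a
generator of synthetic experiments with known ground truth, so that every
statistic the chain produces can be validated by parameter recovery rather
than by eye.

## The measurement chain

### Detection

Calls are found on the band-limited (0.5–8 kHz) amplitude envelope
(rectified signal, 5 ms moving average): contiguous runs above a threshold
expressed as a fraction of the envelope maximum, merged across gaps
shorter than a hold time and filtered to plausible call durations. The
threshold being relative makes detection invariant to recording gain. The
threshold, duration window and hold time are chosen by exhaustive grid
search against an annotated fixture, maximizing the F-score under a
50%-of-truth-duration overlap criterion — ties broken toward higher recall
and then lower threshold, since the downstream random-forest signal/noise
classifier can remove false positives but cannot recover missed calls.
Noise events detected in quiet recordings are expected and are the
classifier's job, not the detector's.

### Features

Audio is resampled to 19 kHz (anti-aliased, zero-phase bandpass) and each
call summarized by a 150-sample Hann spectrogram at 50% overlap
(frequency resolution ≈ 127 Hz). Seventeen features are computed:
duration; mean, sd, median and quartiles of the time-aggregated magnitude
spectrum restricted to the passband; standardized spectral skewness and
kurtosis; normalized spectral, temporal and overall entropies; spectral
flatness; and the per-frame dominant-frequency track's mean, min, max and
range with the modulation index `sum(|Δf|)/range` (1 for monotone sweeps
and, by convention, for flat tracks). The inter-quartile range is carried
in extracted tables for convenience but excluded from the canonical set,
being exactly `q75 − q25`. Features are z-scaled with the population-SD
convention; zero-variance columns are an error rather than silently
dropped.

### Trait space, areas and overlaps

All calls to be compared — every individual, every block — are embedded
**jointly** with exact (O(n²)) t-SNE into two dimensions. Joint embedding
is essential: coordinates from separate runs are not commensurable, and a
single trait space is what makes per-subset areas and overlaps comparable.
The implementation is compiled (RcppArmadillo), uses a fixed perplexity
(default 30), early exaggeration and adaptive gains, and draws its initial
layout in R under the caller's seed, so results are bit-reproducible.

Each (individual, block) subset, and each pooled three-flockmate subset,
gets a Gaussian-kernel density on one shared 200×200 grid spanning the
joint embedding padded by three global bandwidths. Bandwidths follow
Silverman's rule per subset (`min(sd, IQR/1.349) · n^(-1/6)` per axis).
The highest-density region (HDR) at level L = 0.95 is the smallest set of
cells whose cumulated mass reaches L; its area operationalizes repertoire
diversity. L is exposed as a parameter; 0.95 is the conventional choice,
and areas are monotone in L. On 50 000 standard-bivariate-normal samples
the estimated 95% HDR area falls within a few percent of the closed form
π·χ²₀.₉₅(2) ≈ 18.8.

Directional overlap is defined as
`O(A→B) = P_A(hdr A ∩ hdr B) / P_A(hdr A)`:
the share of A's own HDR mass that lies inside B's HDR. The measure
weights by A's density — agreement in A's high-density core counts more
than agreement in its sparse margins — and gives self-overlap exactly 1.
The two directions are genuinely different quantities; their arithmetic
mean is the single symmetric similarity used by the metrics. Both area and
overlap agree within 2% with an independent fine-grid numerical
integration of the same kernel density.

### Vocal metrics and models

Per individual and block: vocal output (call count), diversity change
(area minus baseline area; blocks 2–5), plasticity (mean overlap with the
own baseline space, stored as similarity so that lower values mean more
plasticity) and convergence (mean overlap with the pooled flockmate space
of the same block; the block-1 value is computed but flagged as
pre-exposure, since flockmates had not yet met). Pooling flockmates means
one KDE on their concatenated calls, not an average of three pairwise
overlaps. Subsets with fewer than 5 calls are skipped and reported;
individuals without a baseline space raise an error in the granular
functions and are skipped (reported as missing) by the table-level
assembler.

The model battery mirrors standard practice for these response types:
negative binomial (log link) for counts, Gaussian for area changes, beta
(logit) for overlap proportions — squeezed off the boundary by
`(y(n−1)+0.5)/n` when 0s or 1s occur, the beta support being open —
binomial for network density (6 possible dyads as trials) and Gamma
(inverse link) for proximity strength. Fixed effects are age class, block
(continuous) and optionally their interaction, dropped when
nonsignificant at α = 0.05 (at α ≥ 1 nothing counts as significant, so
the reduced model is always returned); random intercepts for individual
and flock. Gaussian mixed fits report Satterthwaite t statistics, all
other families Wald z, matching the conventional reporting layout.
Non-convergence and complete separation are flagged on the returned
object, never thrown. Calibration is checked by simulation: type-I error
of the age test within [0.03, 0.08] at α = 0.05 and planted effects
recovered within simulation confidence intervals for the Gaussian,
negative-binomial and beta batteries.

### Social networks

Proximity edges are proportions of *valid* snapshots at ≤ 10 cm
(inclusive — 10 cm is one body length); snapshots where either bird was
out of the measurable plane are excluded from the denominator, which
handles unequal observation counts across dyads. Interaction edges are
undirected counts, optionally split into first (blocks 1–2) and second
(blocks 3–4) halves of the observation period. Density uses binarized
edges; strength uses weights. Both are checked against brute-force
enumeration and the handshake identity.

## The synthetic generator

The generator emulates exactly the study design: same-age four-bird
flocks; five blocks of daily recording sessions (4 per block, 1 baseline
block); 8 video sessions with 88 proximity snapshots per flock. Calls are
harmonic stacks (1/k amplitude decay) under cubic-interpolated FM anchor
contours, placed in sessions with exponential gaps and rendered as 16-bit
mono WAV with ground-truth selection tables that tile sample positions
exactly. Repertoire dynamics are linear: from block 2 on, every contour
moves a fraction `convergence_rate` toward the flock-mean baseline
contour — a common target, so pairwise contour distances contract
geometrically and monotonically — plus Gaussian anchor drift. Each bird
carries an individual base-frequency signature (lognormal, sd 0.12)
making baseline repertoires distinct, as they are for birds drawn from
separate source populations.

Age presets encode the documented qualitative directions with free
magnitudes, since no quantitative effect sizes are available: old calls
are 0.8× as long, 1.15× as high, 0.6× as frequency-modulated; old birds
call somewhat more per session (58 vs 48, matching the reported per-block
collection averages) but prune half their call types after the baseline
block — the generator's mechanism for the observed loss of vocal
diversity with age. Interaction rates are calibrated so six flocks
observed for eight sessions have expected affiliative/agonistic totals of
316/202 (young) and 116/134 (old), the published cohort totals; counts
are negative binomial (dispersion 2), matching the count model fitted
downstream. Proximity affinities (0.35 young, 0.30 old) and the 15%
absence probability are realism choices, deliberately mild because the
published proximity contrasts were not significant.

What the generator does **not** emulate: warble song and other
non-contact-call vocalization classes, realistic budgerigar timbre,
reverberation or cage noise structure, diurnal rhythms, or directed
(asymmetric) social relationships. Passing tests therefore demonstrate
that the chain recovers planted effects under its own assumptions — not
that those assumptions exhaust real recordings.

## Validation by parameter recovery

The decisive check is end-to-end: simulate flocks with
`convergence_rate > 0` and zero drift, run audio → features → embedding →
spaces → convergence, and fit the block-slope of the convergence
statistic. Over 20 replicates the slope is positive in ≥ 90%; with
`convergence_rate = 0` the slopes are centered on zero. This recovery
experiment uses a benchmark flock with well-separated baseline
repertoires (`spaced_profiles()`): when baseline repertoires largely
coincide, the overlap statistic starts near its ceiling and the planted
contraction, though present in the generating contours, has little
headroom — a saturation property of overlap-based similarity worth
remembering when interpreting real data.

## Problem sizes and numerical choices

Default analysis sizes were chosen so a full synthetic run is comfortable
on a single CPU: recovery replicates use 4 birds × 5 blocks × 24 calls
(~480 calls, exact t-SNE in a couple of seconds), cohort checks three
replicate cohorts of 2 flocks per age × 16 calls per block, and KDE grids
120–200 cells per axis; the KDE calibration uses 50 000 points. Determinism is strict throughout:
every stochastic stage derives its seed from one master seed, reruns of
`run_pipeline()` with the same configuration are bit-identical, and the
RNG state of the caller is always restored. Tie-breaks and degenerate
inputs are fixed rather than left to chance: HDR cells are cumulated in
density order with the crossing cell included; a flat dominant-frequency
track has modulation index 1; dyads with no valid snapshots get weight 0
with a warning; single-class training sets, zero-variance features,
missing baseline blocks and Nyquist-violating prototypes are errors that
name the offender.

## Known limitations

t-SNE areas have no absolute acoustic meaning — only contrasts within one
joint embedding are interpretable, which is why diversity change, not raw
area, is the response. Exact t-SNE is O(n²) and is intended for the tens
of thousands of calls of one experiment, not millions. The 17-feature set
matches the named features of standard bioacoustic extraction tools, but
the exact historical feature list of any given study may differ; parity
is at the contract level (named statistics on a defined spectrogram). The
beta-family mapping assigns plasticity and convergence (overlap
proportions) to the beta battery and diversity change to the Gaussian
one; where published method descriptions are ambiguous between these, the
mapping here follows the data types.
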