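---
title: "Basecaller-guided nanopore signal alignment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Basecaller-guided nanopore signal alignment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(squigalign)
```

## The problem

A nanopore sequencer measures ionic current while a DNA or RNA strand
translocates through a pore. Basecallers turn that current ("squiggle") into
nucleotides, but many analyses — above all the detection of base
modifications such as 5mC and m6A — need the *inverse* map: which raw current
samples were produced while each reference position occupied the pore.
`squigalign` computes that map by dynamic time warping (DTW) between the
measured signal and the current *expected* from the reference sequence,
using the basecaller's own coarse signal-to-base "move" table to pre-place a
narrow alignment band.

## The k-mer pore model

The expected current is produced by a k-mer pore model: a table mapping each
of the $4^k$ length-$k$ words to a mean and standard deviation of the
current measured while that word occupies the pore (in normalized units;
`pa_mean`/`pa_sd` calibrate back to picoamps). Reference position $r$ is
assigned the k-mer starting at $r - \texttt{central\_pos}$, where the
*central base* is the k-mer position with the largest influence on current.
We estimate it from the model's substitution profile: entry $(b, p)$ of the
profile is the mean absolute current change caused by substituting base $b$
at position $p$, averaged over all k-mers; the central base is the position
with the highest column mean (ties toward the smaller index).
Self-substitutions contribute zeros and are included in the average — they
scale every column by the same factor 3/4 and cannot change the ranking.

`reduce_model()` averages k-mers sharing a window of positions (means by
arithmetic mean, sds by root mean square), and `expand_kmer()` is its
section: each longer k-mer inherits the value of the contained k-mer with
central positions aligned, so expanding and then reducing over the same
window is the identity.

## Signal preprocessing

**Event detection.** Raw samples are grouped into "events" (runs of
approximately constant current) by rolling Welch t-tests: for each of two
window lengths $w$, the statistic at sample $i$ compares the $w$ samples
before $i$ with the $w$ after; boundaries are local maxima above a
per-detector threshold, and an accepted boundary suppresses further
boundaries from the same detector for $w$ samples. Defaults are windows
(3, 6) with thresholds (1.4, 9.0) for DNA and (7, 14) / (2.5, 9.0) for the
slower direct-RNA chemistry. Two consequences matter downstream: the
detector deliberately over-segments (extra boundaries become "stays" and are
harmless), and dwells shorter than the short window are unresolvable — such
positions merge into a neighbor and surface as "skips".

**Normalization.** Per-read current is mapped to model units in up to two
iterations. Iteration 1 is method-of-moments: with event means $E$ and the
model means $K$ of the reference positions covered by the basecalled
alignment (each covered position contributing once),
$\mathrm{scale} = \sigma(K)/\sigma(E)$ and
$\mathrm{shift} = \mu(K) - \mathrm{scale}\cdot\mu(E)$, with population
(n-denominator) standard deviations throughout — the transformed events then
match $\mu(K), \sigma(K)$ exactly. Iteration 2 refits by ordinary least
squares of model means on the per-position observed means (all raw samples
aligned to a position averaged first, so each position counts once
regardless of dwell); slope and intercept compose with the iteration-1
transform and a second DTW pass follows. Whether a re-alignment should
follow the regression is not prescribed anywhere; re-aligning after the
rescale is the conservative choice here and is configurable
(`norm_iterations`). Only iteration 1 is used during model training, where
regression would chase the errors of an immature model.

## Basecaller-guided banded DTW

The move table marks, at a resolution of one stride (5 samples for DNA, 10
for RNA), the signal blocks where the basecaller emitted a base.
`project_moves()` pushes these intervals through the alignment cigar into
reference coordinates: insertions and soft clips merge their samples into
the preceding position's interval, deletions receive intervals interpolated
between their flanks, and introns always break the projection into blocks.
Indels longer than `del_max` (10 by default) are spliced out — insertion
samples are masked, deleted reference stretches are excised — because they
would otherwise put a discontinuity inside the band; reference k-mers
straddling an excised deletion spell sequence absent from the genome and are
masked unless `unmask_splice` is set.

The DTW band (width 25 events by default) is centered, per reference
position, on the event containing the midpoint of the projected interval,
then forced monotone. The recurrence over events $i$ and reference
positions $j$, with $\mathrm{cost}(i,j) = |e_i - m_j|$, is

$$D[i,j] = \min\big(\mathrm{cost} + D[i{-}1,j{-}1],\;
                    \mathrm{cost} + D[i{-}1,j],\;
                    \mathrm{skip}\cdot\mathrm{cost} + D[i,j{-}1]\big)$$

with `skip = 2` for standard alignment and 4 during training. The
multiplicative skip penalty applies to the *cost term of the skip step*.
The alternative reading — multiplying the accumulated prefix $D[i,j-1]$ —
was implemented and rejected during development: with several skips on a
multi-kilobase read the prefix is multiplied by $\mathrm{skip}^{\#skips}$,
which provably (and observably, against an exact brute-force oracle) makes a
globally mis-registered path that front-loads all skips cheaper than the
true path. Under the cost-term reading a skip over a perfectly matching
position is free and the penalty stays proportional to the local model
mismatch, which also preserves the documented behavior of the worked
examples. Traceback ties break diagonal > stay > skip.

Positions reached by a skip share the signal of the position that owns it;
by default they simply copy its current statistics (masking skips removes
useful signal around modifications, which themselves cause skips), with
`mask_skips = "all"` or `"keep_best"` available — training uses
`keep_best`, retaining the position whose model mean is closest to the
shared observed mean. Per-position current mean and sd are always
recomputed from the raw samples between the assigned event boundaries, not
from event summaries, so the stored `current_sd` is the true per-position
standard deviation.

## Storage

Alignments are stored per reference position ("layers": aligned sample
count, current mean, current sd, optional fractional event count) in BAM
auxiliary tags: `us` holds signal-order run lengths (positive = aligned
samples of consecutive positions, zero = skip, negative = masked signal;
magnitudes of 65535 or more chain the sentinel 65535 with the following
entry), `ur` the `[start, stop)` reference blocks, `uc`/`ud` currents as
16-bit fixed point over $[-5, 5]$ (quantum $10/65534 \approx 1.5\times
10^{-4}$; 65535 is the null used for masked positions), and `un` the final
scale/shift. Two invariants are checked on every encode and decode: the sum
of `|us|` equals the raw signal length, and the `ur` span equals the number
of non-negative `us` entries (zeros are reference skips, so they occupy
reference coordinates). In SAM/BAM, `us`/`ur` are written as 32-bit arrays
purely as a container concession — SAM's signed int16 subtype cannot hold
the 65535 sentinel, and reference coordinates exceed 16 bits on real
genomes — while the codec semantics above stay 16-bit. Text exports follow
the community eventalign dialect (one row per unmasked position;
`event_length` in raw samples) and a free-form layer TSV.

## Statistics

Per-position comparisons between two alignments of the same read use the
signal Jaccard distance $1 - |A \cap B| / |A \cup B|$ on the raw-sample
sets (the printed source formula, $1 - (A \cup B)/(A \cap B)$, contradicts
its own stated range and is treated as a typo), and the signal-to-reference
distance: the mean, over the samples one method assigns to a coordinate, of
the distance in bases to the coordinate the other method assigns the same
sample, averaged over both directions. Against the move projection the
distance is one-sided (`mvcmp.dist`) and doubles as the training filter
(positions with distance > 1 are excluded). Modification detection compares
per-read, per-position current means between two samples with the
two-sample Kolmogorov–Smirnov statistic (via `stats::ks.test`) or a Welch
z-score, at a minimum coverage of 20 reads; raw statistics are reported
without multiple-testing correction (a Benjamini–Hochberg helper is
provided but off by default). Read-level quality is summarized by the model
MAD — the median absolute difference between per-position currents and the
model. The positional dwell analysis groups positions by the m-mer at a
fixed coordinate offset and reports the standard deviation of per-group
median dwells, localizing where sequence modulates translocation speed.

## Pore model training

Training iterates: align all reads (in a seeded random order, stopping
early once every k-mer has `min_kmer_count` observations) with the training
parameter set (skip cost 4, keep-best skip masking, one normalization
iteration), keep unmasked positions with `mvcmp.dist <= 1`, pool
per-position current means by k-mer, and set the next model's mean/sd to
the pooled median/sd, re-normalized to mean 0 / sd 1. K-mers below
`min_kmer_count` inherit the previous model's values so iteration is total.
De novo initialization treats the move projections themselves as
alignments: per-position means (z-normalized per read) pooled over a short
k-mer, whose shortness averages out the projections' one-to-two-base
errors; the k-mer length then grows every `iters_per_k` iterations
(default 2) until the target, with any remaining iteration budget
(`max_iterations`) spent at the target length — in practice the final-k
stage needs a few extra iterations to converge, since each round's
alignments improve with the model.

## The simulator and what it does (not) show

All tests run on synthetic squiggles with complete ground truth
(`simulate_read()`): per covered position a shifted-geometric dwell with
mean 8 samples (minimum 4, which keeps dwells at or above the event
detector's resolution so the effective skip rate stays in the stated
few-percent regime), explicit skips at 2% by default, Gaussian current with
sd `noise_sd` (0.3 by default, in normalized units — the synthetic model's
per-k-mer sds are exactly 1) around the model mean, a per-read affine
scale/shift distortion (sd 5%), DAC quantization through standard
calibration constants, and a stride-5 move table with ±1 step jitter,
mirroring the observation that real moves are often a position or two off.
The synthetic truth model sums independent per-position base effects whose
magnitudes decay geometrically away from the central base (factor 0.3, the
shape real substitution profiles show) plus a small non-additive term
(sd 0.05), then normalizes. Reference-position randomness is drawn before
insertion randomness so that two reads simulated with the same seed and
differing only by an inserted segment share every per-position draw — this
is what makes splice-invariance testable exactly.

Training scenarios use a reference built from an order-5 de Bruijn core
(`debruijn_reference()`; every 5-mer present, 1028 nt) padded to 2 kb: a
random 2 kb reference omits roughly 14% of 5-mers entirely, which no
training procedure can recover and which practitioners avoid the same way.
The study-scale choices used throughout the validation suite — 2 kb
references, 100–200 reads, 50× tracks for detection — are the package's
test design; they exercise every code path at desk scale.

What the simulator does *not* emulate: adapter/stall signal, open-pore
current, homopolymer-specific dwell behavior, correlated (non-white) noise,
and base-call errors beyond explicit indel specs. Passing tests therefore
demonstrate algorithmic correctness and statistical behavior under the
stated signal model, not performance on any particular real chemistry.

## Numerical choices and known limitations

* Population (n-denominator) standard deviations are used in normalization
  and in per-position `current_sd`; `stats::sd` (unbiased) is used for
  pooled training sds and z-scores, where a sample estimator is standard.
* The Welch t-statistic denominator is floored at $10^{-10}$ so noiseless
  step signals segment exactly.
* Dwells shorter than the short t-test window merge into neighbors; the
  affected positions surface as skips and contaminate per-position means.
  This attenuates the end-to-end regression normalization by a few percent
  (the operation itself recovers planted distortions well within 2% when
  given per-position means over the true sample map).
* De novo training at desk scale (2 kb reference, 200 reads) converges to
  Pearson r ≈ 0.988 against the truth model rather than fully recovering
  it. The truth model is a stable fixed point of the iteration (r = 0.9999
  maintained when training starts from it), but the coarse 1→3→5
  initialization path lands in a nearby self-consistent solution: alignment
  errors induced by an imperfect model recur at the same positions across
  reads and the pooled medians confirm them. On a 2 kb reference each
  5-mer occurs in only ~2 sequence contexts, so these context-dependent
  registration biases cannot average out; with genome-scale training data
  (hundreds of contexts per k-mer) they do.
* Raw signal is integer DAC; "exact" recovery claims on noiseless data hold
  to the quantization step of the simulated digitizer.
* Reverse-strand and 3'→5' (direct RNA) traversal are implemented as mirror
  walks of the projection and expected signal; the simulator itself emits
  forward-strand reads, so reverse paths are exercised by constructed
  examples only.
* `eventalign` output reports `event_length` in raw samples, not seconds.
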