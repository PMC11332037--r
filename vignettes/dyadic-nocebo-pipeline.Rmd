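---
title: "Methods: dyadic synchrony and socially transmitted nocebo hyperalgesia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic synchrony and socially transmitted nocebo hyperalgesia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadsynch)
```

## The problem this package addresses

Nocebo hyperalgesia — heightened pain driven by negative treatment
expectancies rather than nociceptive input — can be acquired socially, by
watching another person in pain. `dyadsynch` implements an analysis pipeline
for transmission-chain experiments in which dyads of a demonstrator (who
receives calibrated thermal stimuli under a sham-treatment cue) and an
observer rotate roles down a chain of generations: G1 is directly
conditioned (54 °C on "treatment" Tx trials, 45 °C on no-treatment NT
trials), while G2 and G3 receive 45 °C on every trial, so any Tx−NT
difference they express is socially acquired. The analysis asks whether that
difference propagates down the chain and whether dyadic *interpersonal
synchrony* — physiological (electrodermal) and psychological (expectancy
tracking) — predicts how strongly it transmits.

The pipeline covers five stages, each usable on its own: phasic scoring of
continuous signals, cross-recurrence quantification of dyadic EDA,
trial-level psychological synchrony, permutation-based responder
classification, and the inference models (mixed ANCOVA, hierarchical
moderation regressions, simple slopes). A synthetic chain-session generator
with the statistical structure the analysis assumes makes every stage
testable without access to laboratory recordings.

## Phasic scoring

EDA is band-pass filtered 0.0159–5 Hz with a 2nd-order Butterworth applied
forward–backward. The protocol this models states only the band; the
zero-phase realisation is our choice, made so that filtering cannot shift
response onsets relative to event markers. Epochs run from −2 s to +6 s
around cue and heat onsets (closed endpoints; the sample at offset 0 is the
onset sample) and are decimated to 100 Hz by stride selection — the analysis
band ends at 5 Hz, far below the 50 Hz Nyquist of the target rate, so the
band-pass doubles as the anti-alias filter.

Extreme trials are excluded by a jack-knife rule: trial *t* is excluded when
any of its samples deviates from the leave-*t*-out mean by more than 4.89
leave-*t*-out SDs, with mean and SD pooled over all samples of the remaining
trials, separately per epoch type and participant. Leaving the assessed
trial out keeps an artefactual trial from inflating its own exclusion
threshold. Whether the original analysis pooled samples exactly this way is
not stated; pooling per epoch type is our reading, exposed as a parameter.

The peak-to-peak score is `max` over \[onset+3 s, onset+6 s\] minus the
minimum from that maximum back to the onset (closed windows, so the score is
non-negative by construction); values below the 0.02 µS device resolution
floor become 0, and the analysed value is `ln(1 + raw)` (natural log; the
base is not stated in the original analysis and the natural log is the analysis
convention). Facial action units are summarised per frame as the PSPI-style
composite `AU04 + max(AU06, AU07) + max(AU09, AU10) + AU12 + max(AU25,
AU26)`, and each epoch scored as the maximum over the 3 s following onset;
frames with failed face detection are skipped, and all-missing epochs are
excluded exactly like EDA outliers. For the repeated-measures models,
sequential trial pairs within cue are averaged (1–2, 3–4, 5–6), a pair with
one excluded member keeping the surviving value — this mirrors the
missing-data strategy of the design the pipeline reproduces.

## Cross-recurrence quantification (CRQA)

Physiological synchrony is measured on whole-block EDA of both dyad members:
band-pass 0.05–1 Hz, decimation to 8 Hz, z-scoring. Both series are
time-delay embedded, and the cross-recurrence plot marks pairs (i, j) with
Euclidean embedded distance ≤ radius. We report the recurrence rate RR, the
fraction of recurrent points on diagonal lines of length ≥ 2 (determinism,
DET — interconnection of the two trajectories) and on vertical lines of
length ≥ 2 (laminarity, LAM — shared stable periods). A minimum line length
of 2, the Euclidean norm, and no Theiler window (cross-recurrence between
two people has no trivial self-matches) follow the common defaults in the
recurrence literature; none are stated in the original analysis, so all are
parameters.

Parameters are selected per dyad: the delay is the first local minimum of
the average mutual information (capped at 40 samples, 5 s at 8 Hz); the
embedding dimension the smallest with a false-nearest-neighbour fraction
below 0.1 (Kennel criterion, relative tolerance 10, capped at 10); the
radius is then found by bisection so that RR lands in the 2–4% band, seeded
at the subsampled distance quantile matching the band centre. RR is monotone
non-decreasing in the radius, which makes the bisection sound; a failure to
bracket the band (degenerate series) raises an error with diagnostics rather
than returning a silent extrapolation.

Two numerical conventions are worth noting. First, DET on an all-recurrent
plot is (N²−2)/N², not exactly 1: the two corner cells lie on length-1
diagonals, below the minimum line length. Our implementation and the naive
enumeration oracle in the test suite agree exactly on this definition.
Second, the exponential transform applied to DET/LAM before z-scoring across
dyads (to correct their left skew) operates on proportions in \[0, 1\], not
percentages — the scale is unstated in the original analysis, and proportions keep
`exp` in a numerically benign range.

Series of unequal length are truncated to the shorter length after
preparation. The O(N²) scans (recurrence counting, diagonal and vertical
run-length collection, false nearest neighbours) are implemented in C++ over
flat row-major buffers; an R matrix implementation of the same definitions
is exported for inspection and serves as a cross-check in the tests.

## Psychological synchrony and responder classification

Psychological synchrony is the product-moment correlation between the
demonstrator's and observer's trial-level expectancy ratings, pairwise
deleting trials where either rating is missing. Dyads with fewer than 3
usable pairs or zero variance in either member get a missing score and are
excluded from all synchrony analyses, so every synchrony metric is compared
on an identical sample. Rank correlation is available as an option; the
product-moment choice matches the standardised-coefficient framing of the
regression stage.

Responders are classified per demonstrator from the observed nocebo response
— mean(Tx) − mean(NT) pain — against a permutation null that relabels the 12
ratings preserving the 6/6 cue split. The default draws 10,000 random
relabelings and uses the add-one estimator, `p = (1 + #{null ≥ obs}) / (1 +
n_perm)`, which is a valid Monte-Carlo p-value and never exactly zero; an
exact mode enumerates all C(12, 6) = 924 relabelings. Ties count toward the
null, and the comparison uses a tolerance of 10⁻⁹ times the rating scale so
that the observed labeling's own entry in the null set — computed through a
different floating-point path — cannot fall on the wrong side of the
comparison. `p_upper ≤ 0.05` marks a responder, the symmetric lower tail a
reverse-responder, everything else a non-responder. Responder proportions
across generations are compared with a continuity-uncorrected Pearson
chi-square and Cramér's V = √(χ²/N).

## Inference models

The primary model is a mixed ANCOVA on per-trial pain: Generation (G2, G3)
between subjects, Cue (Tx, NT) and per-cue Trial (1–6; or 3 averaged pairs
for phasic outcomes) within subjects, and the dyad's gender match as a
subject-constant covariate. It is fitted as a multivariate linear model on
the subject-by-cell matrix with Type III univariate repeated-measures tests
assuming sphericity — integer degrees of freedom, no correction, which is the
convention of the printed statistics this pipeline mirrors. Generation is
effect-coded (+1/−1) and the covariate centred, so the covariate-adjusted
marginal means are unweighted averages over groups at the covariate mean;
their standard errors come from the between-subject projection combined with
the residual covariance of the cell means. Partial eta-squared intervals
invert the noncentral-F distribution two-sided at 95%. The covariate enters
as the gender match of the dyad in which the demonstrator previously
*observed* — the dyad through which the social information arrived — which is
our reading of an underspecified choice.

Synchrony effects are tested with hierarchical regressions on the nocebo
magnitude (mean Tx − NT pain of the former observer when demonstrating):
stage 1 the synchrony z-score, stage 2 adds effect-coded Generation, stage 3
the Synchrony × Generation interaction. All stages are refit on the
identical complete-case sample, standardised coefficients are `B · sd(x) /
sd(y)` with product terms standardised as columns, and the interaction is
unpacked with simple slopes at the group codes, `B_focal + code ·
B_interaction`, with delta-method intervals. The effect coding G2 = +1,
G3 = −1 is the unique coding consistent with the printed conditional-effect
arithmetic of the original analysis (a main effect of 3.62 and interaction of
−4.65 giving slopes of −1.03 and 8.27).

## The synthetic chain generator

The generator exists so that every downstream stage runs, and is tested,
without the original recordings. It emulates: the three-block chain with the
45/54 °C schedule; 12-trial blocks drawn uniformly from the set of cue
sequences satisfying the pseudorandomisation rules (6/6 split, no more than
3 repeats, 2–4 occurrences per half, transitions from each cue split as
evenly as possible — 230 sequences survive these constraints out of 924
placements); trial timing matching the published procedure (2 s fixation,
6 s cue, 6 s expectancy window, 7–10 s ITI before heat, 5 s post-heat, a
rating period, 12 s ITI); 1 kHz EDA; 60 fps action-unit tables; and an 8.2%
missing-expectancy rate applied per rating cell.

Arousal is modelled with Ornstein–Uhlenbeck processes: each member's tonic
EDA is `level + amp · (κ·S + √(1−κ²)·I)`, where S is a shared slow process
(mean reversion 0.1 s⁻¹) and I an independent mixture of the same slow
dynamics with a faster component (3 s⁻¹, half the independent variance).
The timescale split is deliberate: shared arousal is slow co-adaptation,
idiosyncratic arousal contains faster fluctuation, so the coupling κ
expresses itself in the smoothness and interconnection of the joint
dynamics — which is precisely what DET measures. An early all-slow variant
produced DET values insensitive to κ (every recurrence of a smooth
band-limited series lies on a diagonal); the mixed-timescale model restores
the monotone DET–κ relationship the analysis presumes, with mean DET rising
from ≈0.72 to ≈0.85 across κ = 0.1…0.9 under the test conditions.

Phasic responses are Bateman bi-exponential SCR kernels (0.75 s rise, 2.0 s
decay, 1.0 s latency) at heat onsets, scaled by felt pain on top of a
per-temperature base amplitude, with log-normal jitter; smaller cue-locked
responses scaled by expectancy model anticipatory arousal (without them the
cue-epoch scores would measure pure noise). Felt pain is nociception (30 VAS
at 45 °C, 75 at 54 °C) plus an expectancy term times the responder type (+1
responder, 0 non-responder, −1 reverse-responder) plus Gaussian noise (SD 8),
clipped to \[0, 100\]. The expectancy term is anchored to the expectancies
the demonstrator brings *into* the block and saturates at ±½ once the
learned Tx/NT separation reaches 10 VAS, so a responder's expected Tx−NT
difference equals the configured effect size exactly when learning succeeded,
and shrinks proportionally when it did not. The default effect size is 15 VAS
*per responder*: under the 0.45/0.50/0.05 responder mixture this yields a
cohort-level adjusted Tx−NT difference in the region of the ~7 VAS points
that group-level analyses of such designs report — the printed group
difference averages over responders and non-responders and is not the
responder shift itself. Anchoring at block
entry avoids a feedback loop in which the demonstrator's own low felt pain
erodes the learned separation mid-block and silently shrinks the realised
effect.

Observers learn by a delta rule applied per cue, `e ← e + λ(expressed pain −
e)` with λ = 0.5, attenuated by half on the 50% of trials whose pain rating
is suppressed (face-only observation; the display pattern honours the
published constraints — first Tx and first NT always shown, three per half,
never three in a row). How strongly real observers weight ratings against
faces is unknown; both the learning rate and the attenuation are plain
configuration values, not inferred quantities. Expectancy-rating noise grows
with (1 − κ), linking measured psychological synchrony to the generator's
coupling, and the responder effect size can be modulated by κ
(`nocebo_coupling_slope`, default 0.5) so that synchrony–transmission
analyses have a recoverable signal. The responder mix defaults to
0.45/0.50/0.05 (responder/non/reverse), consistent with the roughly half
non-responder rates reported for this design and the existence of a small
reverse-responder group.

What the generator does **not** emulate: nonstationary drift and motion
artefacts in real EDA, electrode detachment, blinks and head pose in the AU
tables, serial dependence of ratings beyond the delta rule, and individual
differences in SCR shape. One emergent divergence from the human data is
worth flagging: because an observer can only learn from what their
demonstrator expresses, chains whose G2 is a non-responder transmit little
to G3, and under the default responder mixture the cohort-level Tx−NT
difference attenuates at G3 — more strongly than the sustained transmission
reported for human chains. Passing tests therefore demonstrate that the
pipeline measures what it claims on data with the assumed structure — they do
not validate the psychophysiology of real recordings, nor the persistence of
transmission in real chains.

## Problem sizes and numerical choices

The test suite and validation experiments use these sizes, chosen to give
stable Monte-Carlo estimates at interactive runtimes: 200 random instances
(N ≤ 40) for exact oracle agreement of the CRQA measures; 2,000 simulated
null subjects for classifier calibration (exact enumeration mode); 50
default-condition dyads for recurrence-rate targeting; 200 replicates of
n = 60 dyads for the synchrony-coefficient sign recovery; 500 replicates for
the 95% interval coverage of a 7-point injected cue effect; 50 dyads per κ
level for the DET monotonicity check (at a compressed trial timing that
preserves the epoch geometry). Root seeds are fixed in the tests;
`scripts/acceptance.R` derives all its randomness from the `--seed`
argument.

Degenerate inputs are handled explicitly: constant series are rejected
before CRQA preparation; an all-identical rating vector yields a permutation
p of 1 (non-responder); a within-subject contrast that is identically zero
reports F = 0 rather than 0/0; jack-knife exclusion requires at least 3
usable trials and otherwise warns and excludes nothing; zero recurrence
leaves DET and LAM undefined rather than zero.

## Known limitations

The ANCOVA covers the two-level between factor and fully crossed
within-factor designs used here, not general multi-factor layouts, and
offers no sphericity corrections by design. CRQA is whole-block; windowed or
diagonal-profile variants are out of scope. The permutation classifier
assumes the 6/6 cue balance (unbalanced inputs are tolerated with a
warning). External validity against the deposited human data requires that
download and a dialect map for its on-disk layout; nothing in this package
depends on it.
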