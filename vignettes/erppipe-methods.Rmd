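---
title: "Models and methods behind erppipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind erppipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`erppipe` implements a complete analysis chain for a four-condition
face-detection EEG experiment — self, fearful, happy and neutral faces — in
which the questions of interest are (i) whether late event-related
potentials (P3, late positive potential) are selectively enhanced for the
self-face, (ii) whether that difference is distributed across the scalp and
over time (spatio-temporal cluster-permutation testing with threshold-free
cluster enhancement), and (iii) whether the *pattern* of scalp activity for
the self-face resembles that of emotional faces (time-resolved
representational similarity analysis). Because raw data for such studies
are rarely shareable, the package pairs the analysis chain with a
generative model of the whole study, so that every stage can be validated
against data whose ground truth is known.

This vignette documents the models, the parameter choices and the
numerical conventions, including the places where a design decision was
genuinely open and what settled it.

## The generative model

Each subject's epoch for condition $c$ is

$$x_{c}(e,t) = \underbrace{v(e,t)}_{\text{shared visual complex}}
 + A^{P3}_{sc}\, w^{P3}_c(e)\, g(t)
 + A^{LPP}_{sc}\, w^{LPP}_c(e)\, \pi(t)
 + \text{noise}(e,t)$$

* **Shared visual complex** $v$: P1 (100 ms), N170 (170 ms) and a small P2
  (230 ms), identical across conditions, with posterior/lateral-occipital
  topographies. It exists so that condition-orthogonal electrode selection
  and the collapsed grand average have realistic structure to work on.
* **P3**: a Gaussian bump, latency 350 ms, width $\sigma = 60$ ms, spatial
  weights Gaussian (falloff 3.5 cm) around PZ/CPZ.
* **LPP**: a sustained plateau with raised-cosine onset at 600 ms and
  offset at 1250 ms (ramp 100 ms), weighted around FCZ. A plateau rather
  than a second bump matches the sustained character of the LPP.
* **Calibration**: the amplitude parameter of each component *is* the
  pooled window-mean the analysis reports (P3: PZ/CPZ/CP2/P2 at
  250–500 ms; LPP: FCZ/FC2/C2 at 650–900 ms). The component template is
  rescaled so this holds exactly, which makes planted values directly
  comparable to the pipeline's output.

**Amplitude structure across subjects.** Condition means default to the
group means the design emulates (P3 7.771/5.103/4.811/5.300 µV; LPP
16.789/9.078/9.010/8.759 µV). Each subject draws one common offset (s.d.
2.4 µV for P3, 7.4 µV for LPP) shared by all conditions, plus a
subject-by-condition jitter (1.31 µV and 3.0 µV). The common offset
reproduces the between-subject spread of the emulated amplitude tables; the
jitter reproduces the within-subject error variance implied by the group
$F$ statistics (for a one-way within design, $MS_{error}$ follows from $F$
and the condition means). These are the two variance components that govern,
respectively, descriptive spread and the power of paired comparisons.

**Noise.** Three parts: (i) spatially correlated $1/f$ background — eight
shared sources with Gaussian spatial mixing profiles, each a unit-variance
$1/f$ series generated by FFT spectral shaping, scaled to 4 µV per channel.
Spatial correlation matters because cluster statistics face correlated
neighbours in real EEG; independent channel noise would make the
permutation tests look better calibrated than they are. (ii) White sensor
noise, 1.5 µV. (iii) Posterior 10 Hz alpha, 1.5 µV with random phase and
amplitude per trial. Earlobe channels carry 10% of the mean scalp signal
plus their own (larger) sensor noise, so the linked-earlobe re-referencing
stage is exercised non-trivially.

**Artefacts.** A configurable fraction of trials (3% by default) receives
one of three injections — a one-sample voltage jump of 70–120 µV, a slow
half-sine of 230–320 µV, or a flattened channel — each built to violate
exactly the corresponding rejection threshold, so rejection can be
validated bidirectionally (injected trials are caught; clean trials are
not).

**Reaction times.** A shifted lognormal:
$rt = (m_c + u_s)\,e^{\sigma z}$ with condition medians $m_c$ from the
emulated design (244.9–249.3 ms), a subject shift $u_s$ with s.d. 24.5 ms
(which dominates the between-subject spread of medians) and trial-level
$\sigma = 0.1$ (≈ 25 ms spread, appropriate for a speeded simple-detection
task). With 72 trials per condition, the sampling error of a subject's
median is then ≈ 3.7 ms, which is what gives the omnibus test over medians
its realistic (moderate) power.

**Seeding.** Every subject derives an independent seed from the master
seed through an integer hash followed by a short burn-in of the generator.
The hash is deliberate: linearly related seeds fed to R's Mersenne–Twister
produce correlated *first* draws, which in an early version biased all
subject offsets of a study in the same direction — visible only as a
systematic shift of group means. Study-level reproducibility is exact:
the same configuration always yields byte-identical data.

### What the generator does and does not emulate

It emulates the *statistical* structure the analyses assume: planted
condition effects of known magnitude at known electrodes and times,
realistic between/within-subject variance components, spatially correlated
background noise, threshold-violating artefacts, and RT medians with the
observed dispersion. It does **not** emulate the covariance of real EEG
beyond these components: no eye blinks or muscle artefacts below the
rejection thresholds, no inter-electrode covariance structure beyond
Gaussian source mixing, no N170 condition effects, no trial-order or
fatigue effects. A passing validation therefore shows the pipeline is
correct and calibrated under the assumed data model — not that the pipeline
would produce identical numbers on any real recording.

## Preprocessing conventions

* Epochs span −200…1500 ms at 500 Hz with **inclusive endpoints**: 851
  samples. Sample mapping rounds half away from zero.
* Re-referencing subtracts the algebraic mean of the two earlobes;
  filtering is a second-order Butterworth band-pass (0.01–30 Hz) plus a
  second-order band-stop notch at 50 Hz (2 Hz wide; the width is a
  package choice). Filters run forward–backward (zero phase) with
  odd-reflection padding so component latencies are undistorted. The
  stage order is re-reference → notch → band-pass.
* Artefact rule (c) — "lowest permitted activity within a 100-ms
  interval" — is read as the minimum peak-to-peak amplitude over every
  sliding 100-ms window (step one sample), the standard reading of that
  criterion; rules are evaluated on every channel and a trial is rejected
  if any rule fires anywhere.
* Ocular ICA correction is a manual, visually guided step and is not
  implemented; a history entry records its absence.

## ERP analysis

Electrode pools are selectable from the condition-collapsed grand-average
topography (largest window means, ties broken by label), which is
orthogonal to condition differences by construction; the default pools are
PZ/CPZ/CP2/P2 (P3) and FCZ/FC2/C2 (LPP). The P3 window defaults to
250–500 ms; 200–500 ms remains available as an argument because both
appear in the emulated design's description and the discrepancy is
unresolved there — the window actually used for results is taken to be
250–500 ms.

## Univariate statistics

* Routing: Shapiro–Wilk per condition; any deviation (p < .05, or a
  degenerate constant column) routes the omnibus test to Friedman,
  otherwise to repeated-measures ANOVA.
* The Greenhouse–Geisser correction is applied whenever the numerator df
  exceeds one — unconditionally, not gated on Mauchly's test. Effect size
  is partial $\eta^2$, which for a one-way within design equals the
  classical $\eta^2$.
* Wilcoxon signed-rank post hocs use the exact distribution for n ≤ 25
  without ties and a continuity- and tie-corrected normal approximation
  otherwise; the Bonferroni-adjusted threshold (family α / number of
  comparisons) is reported with each pair.
* The JZS Bayes factor uses the default Cauchy(0, 0.707) prior on the
  standardized effect size, computed by adaptive quadrature of the
  noncentral-t likelihood against the prior. The same t-based BF is
  reported next to nonparametric comparisons — a caveat worth making
  explicit: it is the Bayes factor of the corresponding t contrast, not of
  a rank test, matching common practice in the software this emulates.
* RT outlier rule: a subject is excluded only when its median exceeds the
  group mean + 3 s.d. in *every* condition.

## Cluster-based permutation testing

The paired contrast is implemented as a one-sample test on within-subject
difference maps, whose exchangeability under the null justifies random
sign flips. For each permutation the maximum absolute enhanced statistic
over all (channel, time) points is recorded; the Monte Carlo p-value is
$(1 + \#\{\text{perm max} \ge \text{observed}\})/(n_{perm} + 1)$, so the
smallest attainable p is $1/(n_{perm}+1)$ and p = 0 is impossible. When
$2^n \le n_{perm}$ the full set of sign assignments is enumerated instead.

TFCE uses the standard parameterization $E = 0.5$, $H = 2$, with Riemann
step $dh = \max|t|/100$; extent counts (channel, sample) points without
physical-area weighting. Testing is two-tailed via signed enhancement of
the positive and negated maps against a max-|statistic| null. Spatial
adjacency is 3D electrode distance below 4 cm on the spherical montage
(~6.5 neighbours per channel for the full cap); connectivity in the
spatio-temporal grid is spatial neighbours at the same sample plus
temporal neighbours on the same channel. The implementation activates
points in descending height order under a union–find, which is
algebraically identical to the naive per-threshold labelling (tested
against an independent flood-fill sweep to machine precision). A classical
fixed-threshold cluster-mass mode is retained; with a single threshold it
reduces to the textbook cluster-mass test.

## Representational similarity analysis

Trials of each condition are randomly split into two pools and averaged,
giving 8 spatial patterns per time point; their pairwise Euclidean
distances form an 851 × 8 × 8 distance series per subject. One random
(seeded) split is the default; averaging over several splits is available.
Three binary templates code the hypotheses (self+fear, self+happy,
self-only), with same-condition cross-pool pairs coded similar — any other
coding would contradict the two pools acting as replicates — and polarity
1 = dissimilar so a positive β means the model's structure is expressed in
the distances.

**Vectorization.** The regression runs on the 56 off-diagonal cells with a
constant intercept, templates z-scored over those cells. An alternative
reading — all 64 cells with the 8 × 8 identity as the intercept — is
implemented (`vectorization = "full64"`) but is not the default, for a
structural reason: Euclidean distance matrices computed from noisy
patterns have a positive off-diagonal noise floor, and under the 64-cell
coding that floor is not representable by the identity intercept, so it
leaks into the template coefficients (solving the type-level least-squares
problem gives β proportional to the floor, positive for *all three*
templates even for data with no representational structure at all). The
self+fear and self+happy models would then be constant positive
predictors, which contradicts both the intended null behaviour and the
directional findings this analysis is meant to express. With off-diagonal
vectorization and a free intercept, data with no structure yield exactly
zero template coefficients in expectation.

β series are smoothed with a unit-mass Gaussian kernel of 32 ms width,
interpreted as the FWHM (σ ≈ 13.6 ms); reflective padding keeps constants
invariant. The "width" convention is not fixed by the emulated design, so
it is an argument. Group inference on a template's β uses the same
sign-flip TFCE machinery with temporal-only adjacency, since β has no
spatial dimension.

A directional note on the self+fear / self+happy models: a planted
geometry in which the self pattern is simply displaced from a common
topography yields β ≈ 0 for these models (not negative). They become
*negative* predictors exactly when the self pattern is farther from the
emotional patterns than from the neutral one. The self-distinct validation
configuration therefore displaces the emotional topographies slightly
opposite to the self displacement, which reproduces that direction.

## Validation studies and problem sizes

The test suite and `scripts/acceptance.R` validate the chain end to end
with replicate simulated studies at desk scale, chosen so the full suite
runs in minutes while leaving each property's power intact:

* **Geometry**: 29 subjects, full 851-sample epochs, 12-channel subset.
* **Null calibration**: 200 replicate null studies (20 subjects, equal
  amplitudes, no condition jitter, 12 channels, −100…200 ms epochs),
  family-wise error of the TFCE contrast and of the RSA group test checked
  against the binomial 95% band around 0.05. Error control comes from
  sign-flip exchangeability and is geometry-free, which is what licenses
  the reduced geometry.
* **ERP recovery**: 20 replicate studies of 30 subjects, 16 trials per
  condition, the 21-channel subset, full epochs, planted at the default
  amplitude maps.
* **RSA recovery**: 20 replicate self-distinct studies (20 subjects,
  16 trials, displacement 2 cm / 0.7 cm).
* **Behavioural recovery**: 20 replicate RT tables at the default design.
* **Oracles**: TFCE against a brute-force threshold sweep at
  $dh = \max|t|/1000$; template regression against the pseudo-inverse
  normal equations; Friedman/Wilcoxon against definitional/enumerated
  statistics; the JZS Bayes factor against an independent quadrature of
  the g-mixture integral form.

## Numerical choices and degenerate inputs

* Zero-variance points in permutation t maps are set to t = 0 (they carry
  no evidence); an all-zero observed map short-circuits to "no clusters".
* A beta series with zero between-subject variance and nonzero mean is an
  error (duplicated subjects), not a test result.
* Constant columns route to the nonparametric branch; an all-tied Friedman
  matrix yields statistic 0, p 1 rather than NaN.
* Filters are designed per call with `signal::butter`; the inner
  forward–backward loop is compiled, with odd-reflection padding of up to
  250 samples.
* The epoch container is a flat little-endian float64 binary plus a JSON
  sidecar; it exists because the analysis needs a stable, text-adjacent
  interchange format, and it round-trips bit-exactly.

## Known limitations

* The generator's evoked templates are smooth and low-dimensional; real
  single-trial EEG has richer spectro-spatial structure, so real-data
  artefact rates and split-half noise floors will differ from simulated
  ones.
* The BF-next-to-Wilcoxon caveat above.
* No peak-latency measures, no N170 analysis, no ICA, no channel
  interpolation, no resampling, and no correction across the three
  cluster contrasts (each contrast controls its own family-wise error,
  matching the emulated design).
* BrainVision support is read-only and limited to multiplexed binary
  IEEE_FLOAT_32 / INT_16 layouts.
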