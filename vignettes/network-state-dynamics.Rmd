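---
title: "Transient network states from amplitude envelopes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient network states from amplitude envelopes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(envstates)
```

## The problem

Resting electrophysiological activity is not stationary: band-limited
oscillatory power waxes and wanes in coordinated bursts across large-scale
brain networks on timescales of one to a few hundred milliseconds. A
productive way to describe these dynamics is to segment the recording into
a small number of recurring **network states**: periods during which a
particular set of regions shows elevated (or suppressed) oscillatory
amplitude. The occupancy, visit rate, and dwell time of such states differ
between clinical groups — for example, states resembling the default-mode
and dorsal-attention networks are visited about half as often, and for
shorter periods, in Alzheimer-type dementia than in matched controls.

`envstates` implements the full analysis chain for this kind of study —
amplitude-envelope preprocessing, hidden Markov segmentation, temporal
metrics, spatial mapping, and group inference — together with a
ground-truthed synthetic-cohort generator, so that every stage can be
validated against planted parameters without access to patient recordings
(which are typically not shareable).

## The observation model

The segmentation operates on **amplitude envelopes**. Each subject's
multichannel recording (M = 38 channels by default, at 200 Hz) is:

1. band-pass filtered into the wide 4–30 Hz band (zero-phase Butterworth,
   order 5 per pass; narrow-band variants use theta 4–7, alpha 8–12,
   beta 15–30 Hz);
2. leakage-corrected by **symmetric orthogonalization** (below);
3. converted to instantaneous amplitude via the modulus of the analytic
   (Hilbert) signal;
4. downsampled to 20 Hz by block averaging (an anti-aliasing mean over
   consecutive 10-sample windows rather than decimation);
5. trimmed by 1 s at each end (filter and Hilbert edge transients),
   demeaned per channel, scaled by the subject's global standard
   deviation, and concatenated across subjects.

The concatenated envelope matrix is modeled by a K-state hidden Markov
model in which state \(k\) emits
\(x_t \sim \mathcal N(\mu_k, \Sigma_k)\) with a full \(M \times M\)
covariance, and the latent state follows a first-order chain with
row-stochastic transition matrix \(A\). K = 10 by default. Parameters are
estimated by Baum–Welch expectation-maximization; the state sequence is
decoded with the Viterbi algorithm, computed in the log domain so that
sequences of 10^5–10^6 samples cannot underflow. Ties in the Viterbi
recursion break toward the lowest state index, making decoding fully
deterministic.

### Likelihood maximization versus variational inference

The reference analyses in this literature use a variational-Bayes HMM and
select the realization with the lowest free energy. The quantities this
package is validated on — the decoded segmentation and everything computed
from it — depend on the state parameters, not on the Bayesian treatment of
their uncertainty, so `fit_hmm()` uses maximum-likelihood EM and selects
the restart with the highest log-likelihood. This choice is fully
specifiable (no prior hyperparameters to guess) and reproducible. Each of
the `n_restarts = 10` restarts initializes by assigning time points to
states uniformly at random (seeded) and taking means and covariances from
that assignment. Convergence is declared when the relative log-likelihood
change falls below 1e-6, with a cap of 500 iterations. Covariances are
kept well-conditioned by a ridge of 1e-6 times the mean diagonal plus an
eigenvalue floor of 1e-10; when the floor activates, the fit is flagged
`regularized`.

The EM core is compiled (RcppArmadillo) because the default study
conditions fit a 10-state, 38-channel model with full covariances on
roughly 10^5 concatenated samples, ten times over.

### Decoding across subjects

The model is fitted once on the concatenated cohort (per-group fits are
the same operation on subsets). Decoding restarts at each subject
boundary, with the chain initialized from the stationary distribution of
the fitted \(A\) — subjects are independent recordings, so the decoder
must not carry state across the concatenation seam.

## Symmetric orthogonalization

Source-reconstructed channel time-courses contaminate one another at zero
lag (signal leakage), which inflates zero-lag envelope correlations.
`symmetric_orthogonalize()` removes all zero-lag correlations at once by
finding the matrix with mutually orthogonal columns closest to the input
in the least-squares (Frobenius) sense, over matrices of the form
\(L\,\mathrm{diag}(\rho)\) with orthonormal \(L\). The solver alternates
the closest-orthonormal-matrix step (SVD polar factor, computed in the
\(M \times M\) coefficient space of a thin QR factorization) with the
optimal per-column magnitudes \(\rho_m = \langle x_m, l_m\rangle\), until
the relative objective change falls below 1e-10 (cap 1000 iterations).
Unlike sequential Gram–Schmidt, the result does not depend on channel
ordering, and the test suite verifies it beats every Gram–Schmidt ordering
in displacement. Rank-deficient input has no orthogonal counterpart and is
rejected, naming the offending columns.

Orthogonalization is applied to the band-limited time-courses *before*
envelope computation (leakage is a property of the raw signal, not of its
envelope). Channel-level maps, by contrast, are computed against
non-orthogonalized envelopes: mapping asks where raw amplitude co-varies
with a state, and orthogonalization would remove exactly the shared
variance being mapped.

## Temporal metrics

From a decoded path at rate `fs` (20 Hz):

- **Fractional occupancy** `FO_k`: fraction of samples spent in state
  \(k\); sums to 1.
- **Fractional count** `FC_k`: number of visits (maximal runs) to state
  \(k\) divided by the total number of visits across states. The total
  *visit* count is used as the denominator (rather than the transition
  count, which is one smaller) so that `FC` sums to exactly 1 and is
  comparable across subjects; boundary runs count as full visits.
- **Mean lifetime** `LT_k`: mean run length times `1000/fs`, in ms. A
  state never visited has an undefined (NA) lifetime, not zero.
- **Empirical transition matrix**: row-normalized one-step counts, with
  the self-transitions retained by default (`mode = "exclude_self"`
  zeroes the diagonal first, describing where the path goes when it
  leaves each state).

For a geometric dwell process with self-transition probability \(p\),
\(LT = 1000/(fs\,(1-p))\) ms; the suite checks this closed form and its
consistency with the empirical transition diagonal.

The **occurrence-rate time-course** is the proportion of time in a state
inside a sliding 5 s window (100 samples at 20 Hz — half a cycle of a
0.1 Hz oscillation), the representation used to relate fast state
dynamics to ultra-slow (< 0.1 Hz) potentials.

## Spatial maps as GLM partial correlations

State maps answer: where is oscillatory amplitude elevated during state
\(k\), relative to what happens on average? For each subject, each
channel's z-scored envelope is regressed on the z-scored state design
(the T × K indicator expansion of the decoded path), and the coefficient
reported for state \(k\) is the partial correlation between the state's
time-course and the envelope, controlling for all other states.

One numerical subtlety deserves a record. The complete one-hot design is
*exactly* collinear after centering: the raw indicator columns sum to one
at every time point, so the z-scored columns obey a perfect linear
dependence and the correlation matrix of the full design is singular. The
package therefore computes partial correlations from the Moore–Penrose
generalized precision of `cor(cbind(design, channel))`. For any full-rank
design this equals the exact precision — so the estimates coincide with
residualization-based partial correlations, which the test suite verifies
— while for complete state designs it yields the minimum-norm GLM
solution. A masked or collapsed design whose columns become constant
(a state absent from the masked rows) is rejected instead.

Variants all reuse the same machinery:

- **Collapsed designs** (`build_design(ind, collapse = ...)`): several
  state columns are OR-combined into one regressor before z-scoring
  (z-scoring happens after the combination — the merged column is a
  single regressor), probing regions engaged across several states.
- **Narrow-band maps**: the wide-band decoded design against theta-,
  alpha-, or beta-band envelopes; states are never refit per band.
- **High-occurrence-rate masks**: rows restricted to the top quartile of
  a state's 5 s sliding-window rate before (re-)standardization. The
  quartile is a documented default; the literature leaves "high
  occurrence rate" undefined.
- **Ultra-slow maps**: partial correlations between the < 0.1 Hz signal
  at each channel and the per-state occurrence-rate design. Because the
  coupling phase is ambiguous across subjects, group averaging of these
  maps uses absolute coefficients (`average_maps(use_absolute = TRUE)`).

## Group inference

Metric and map differences between two cohorts use Welch's t statistic
(safer than pooled-variance t at n = 10 per group) with permutation
inference: the group labels are exchanged, exhaustively when the number
of distinct splits does not exceed `n_perm` (then the p-value is the
exact proportion of splits at least as extreme, the observed split
included), otherwise by `n_perm` random draws with the add-one estimator
\((1 + \#\{|t^\ast| \ge |t|\})/(1 + n)\). All inference is two-sided.
Between-subject variance differences use the classical Bartlett test
(`stats::bartlett.test`; the suite re-derives the closed form by hand).

Channel-wise map comparisons control the family-wise error rate with
**threshold-free cluster enhancement** (TFCE): the t-map is enhanced by
\(\sum_h e(h)^{E} h^{H} \, dh\) over thresholds \(h\), where \(e(h)\) is
the extent of the suprathreshold connected component containing the
channel (E = 0.5, H = 2, dh = max|t|/100 — the standard defaults;
negative values are enhanced separately on the flipped map). Corrected
p-values come from the permutation distribution of the maximum absolute
enhanced statistic, and are floored at the uncorrected permutation p so
the usual dominance relation holds exactly. Channel adjacency is supplied
by the caller; `block_adjacency()` builds the block-neighborhood graph
matching the synthetic topographies, since no voxel grid exists in this
setting.

## The synthetic-cohort generator

`simulate_cohort()` plants exactly the statistical structure the analysis
assumes, so recovery can be checked quantitatively:

- a latent K-state chain generated at the 20 Hz envelope rate and
  sample-held to 200 Hz, keeping ground truth aligned with decoded paths;
- per-channel carriers of zero-phase band-limited (4–30 Hz) Gaussian
  noise, unit variance;
- amplitude modulation `1 + depth * state_depth[k] * topography[k, m]`
  while state \(k\) is active (default topographies give each state a
  block of 3 channels); modulation depth 1 by default — active channels
  double their amplitude;
- optional zero-lag leakage mixing, and an optional ultra-slow sinusoidal
  modulator (0.05 Hz default) that both scales the probability of
  *entering* a coupled state by `1 + gain * modulator(t)` and adds a slow
  potential to that state's channels. Only genuine entries are scaled:
  scaling the self-transition would conflate occurrence rate with dwell
  time (and can exceed probability one for persistent states).

`transition_from_occupancy()` turns stationary-occupancy targets plus
per-state self-transition probabilities into a transition matrix whose
stationary distribution matches the targets exactly (off-diagonal mass
proportional to calibrated jump weights, fixed-point refined), so both
occupancy and dwell time are planted without interaction.

Two presets encode the contrast the package validates against. The
CH-like (healthy-control-like) preset plants DMN-like occupancy 6% with a
250 ms dwell, DAN-like occupancy 14% with 200 ms, and the remaining eight
states sharing the rest at 150 ms. The AD-like preset halves the two
salient occupancies (3% / 7%), shortens all dwells to 150 ms, and
attenuates the DMN-like modulation depth by 30%. Cohorts default to 10
subjects at 9 minutes each (three 3-minute recordings concatenated, as in
the acquisition protocol these studies use).

**Surrogates.** `simulate_surrogate()` produces stationary Gaussian
datasets matched to a reference in per-channel spectra and zero-lag
cross-correlations: white noise is colored by the reference's smoothed
amplitude spectrum, then the reference correlation is imposed through the
symmetric square root of its correlation matrix, then channel means/SDs
are restored. The order — color first, then correlate — is one admissible
reading of "matched in spectra and correlations"; imposing correlations
second slightly mixes spectra across channels, which is immaterial when
channels share a band. Surrogates carry the reference's static structure
but no state dynamics, so they serve as the null for "is there switching
structure beyond stationary correlation?".

### What the generator does *not* emulate

Real source-space MEG has 1/f background, inter-subject topography
variability, non-Gaussian and non-geometric dwell distributions, artifact
residuals, and head-geometry-driven leakage patterns. Passing recovery
tests on these cohorts therefore demonstrates the *correctness of the
pipeline's computations* under its own model assumptions — not that the
model is adequate for any particular real dataset.

## Problem sizes and determinism

The validation suite fits the full study conditions — two cohorts of 10
subjects × 9 min, K = 10, 10 restarts — once each; smaller unit fixtures
(2–3 subjects, a few minutes, K ≤ 5) exercise every other property. These
sizes are the package's validation choices and keep a complete run in the
tens of minutes on a single core. Every stochastic stage takes an explicit
integer seed; sub-seeds for subjects, restarts, and surrogates derive from
the master seed, so identical configurations reproduce outputs bitwise.
The RNG state of the caller is never disturbed.

## Known limitations

- Maximum-likelihood EM can in principle select a different local optimum
  than variational free energy would; `fit_hmm()` exposes the
  per-restart log-likelihoods (`restart_logliks`) so the spread across
  initializations can be inspected on any given fit.
- Free energies of the reference variational implementation are not
  reproducible here (prior hyperparameters unpublished) and are not
  validation surfaces.
- The Viterbi hard assignment discards state uncertainty; metrics from
  posterior probabilities would differ slightly near transitions.
- Group-level maps assume subject-level maps are exchangeable across
  subjects within group; no hierarchical shrinkage is applied.
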