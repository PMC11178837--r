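---
title: "Methods: directed connectivity from multisite LFP with state-space Granger causality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directed connectivity from multisite LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varconn)
```

# The analysis in one paragraph

`varconn` estimates directed functional connectivity between
simultaneously recorded brain regions from resting-state local field
potentials (LFP).  Continuous multichannel recordings are down-sampled,
notch-filtered, z-scored and cut into short epochs; a vector
autoregression (VAR) is fitted across epochs; spectral
pairwise-conditional Granger causality (GC) is computed from the fitted
VAR through its innovations state-space form; GC is reduced to
band-limited scalars over canonical frequency bands; and the resulting
per-animal edge values are compared between groups (e.g. wildtype vs
heterozygous knockout) with scaled Wilcoxon rank-sum statistics under
false-discovery-rate (FDR) control.  A parallel branch summarises
operant biconditional-discrimination behaviour, including the
discrimination-ratio statistic.  A synthetic-data module generates both
kinds of data from known ground truth so that every stage has a
parameter-recovery oracle.

# The model

## VAR and Granger causality

For an $n$-channel signal $y_t$ the VAR($p$) model is
$$y_t = \sum_{k=1}^{p} A_k\, y_{t-k} + \varepsilon_t,
  \qquad \operatorname{Cov}(\varepsilon_t) = \Sigma .$$
Granger causality from channel $j$ to channel $i$, conditional on all
remaining channels, is the log ratio of the residual variance of $y_i$
when the model omits channel $j$ to the residual variance under the full
model, in nats.  For a VAR this conditional quantity is exactly zero
iff $A_k[i,j] = 0$ for all lags.

## State-space computation

Fitting the reduced (source-omitted) model directly is awkward because
the reduced process is generically VARMA, not VAR.  `varconn` instead
recasts the fitted VAR in innovations state-space form
($z_t$ = stacked lags; $z_{t+1} = A z_t + K\varepsilon_t$,
$y_t = C z_t + \varepsilon_t$) and obtains the reduced model *exactly*
by solving a discrete algebraic Riccati equation (DARE) for the
subsystem that observes all channels except the source.  The solver is
a structure-preserving doubling iteration (quadratically convergent;
tolerance $10^{-12}$); the plain Kalman covariance recursion is kept as
an independent cross-check in the test suite.  The conditional spectral
GC at angular frequency $\lambda$ is
$$f_{j \to i \mid \text{rest}}(\lambda) =
  \log V^R_{ii} -
  \log\!\bigl(V^R_{ii} - |G_{ij}(\lambda)|^2\, \sigma_{j\mid r}\bigr),$$
where $V^R$ is the reduced model's innovation covariance, $G(\lambda)$
the transfer function from the full innovations to the reduced
innovations, and $\sigma_{j|r}$ the partial variance of the source
innovation given the others.  Values below $10^{-12}$ are clipped to
zero to absorb round-off.  The reduced-innovation spectrum
$G V G^{*}$ reproduces $V^R$ at every frequency to machine precision,
which the test suite uses as an internal consistency check.

## A caution on the spectral integral

For *unconditional* (bivariate) GC the average of the spectral measure
over the frequency circle equals the time-domain value (the Geweke
identity); `varconn` reproduces this to machine precision.  For the
*conditional* measure the identity is not a theorem: on random stable
VARs the circle mean can sit several percent (occasionally tens of
percent on weak edges) below the time-domain value.  The package's test
suite measures this deviation against an independent long-simulation
regression oracle and against a brute-force Geweke-style partialization
construction; both agree with the spectral measure, confirming the gap
is a property of the conditional decomposition itself rather than an
implementation artefact.  Band-limited comparisons between groups are
unaffected (both groups are reduced with the same measure), but
absolute band values should not be read as exact partitions of the
time-domain GC.

# Preprocessing choices

* **Down-sampling** (default 1017 Hz to 200 Hz): zero-phase windowed-sinc
  FIR low-pass with cutoff at the new Nyquist, then cubic-spline
  resampling to exactly `floor(duration * target_fs)` samples.  A
  zero-phase FIR was chosen over forward-backward IIR because it
  preserves DC exactly and has no start-up transient under reflection
  padding.
* **Notch** (default 50 Hz, 2 Hz bandwidth): second-order IIR notch
  applied forward-backward.  The narrow stopband protects the flanking
  gamma bands (35–45 and 55–75 Hz).
* **Normalisation**: each channel is z-scored within animal (default),
  so every site enters the VAR with unit variance; cross-animal pooling
  happens only at the group-statistics stage.  A `scope = "global"`
  switch standardises each site by statistics pooled across animals
  instead, preserving relative amplitudes.  Moment-based (mean/SD)
  statistics are used, not median/MAD.
* **Epoching**: contiguous non-overlapping 5 s epochs from the start of
  the recording; a trailing remainder is dropped.  Ten minutes at the
  default settings gives 120 epochs.
* **Artifact rejection**: an epoch is removed if any sample of any
  channel exceeds 6 SD in normalised units.  Six SD makes false
  rejection of clean Gaussian epochs (1000 samples x 6 channels)
  essentially impossible while catching the boxcar artifacts the
  generator injects.  Rejections are logged per epoch and channel;
  rejecting *all* epochs is an error, never a silent empty result.
  Sleep-epoch exclusion by slow-wave/spindle detection is deliberately
  **not** implemented; amplitude rejection is the only exclusion.

# VAR fitting and adequacy

Coefficients are estimated by least squares pooled across epochs; no
regression crosses an epoch boundary, and no intercept is fitted (the
signals are z-scored).  The residual covariance uses an
$N/(N - np)$ degrees-of-freedom correction.  Order selection minimises
the multivariate Gaussian AIC, $N \log\det\hat\Sigma_{ML} + 2pn^2$,
with the first `max_order` samples of each epoch dropped for *all*
candidates so likelihoods are comparable; the default search bound of
30 comfortably covers the orders selected for 200 Hz LFP.  Three
adequacy diagnostics gate each animal:

* multivariate $R^2 = 1 - \operatorname{tr}\hat\Sigma_{ML} /
  \operatorname{tr}\hat\Sigma_{y}$, gated at 30%;
* per-channel Durbin–Watson statistics with normal-approximation
  p-values.  Whiteness *passes* when no channel rejects at
  $\alpha = 0.05$ — i.e. a small p-value is evidence against the model.
  (The criterion is sometimes quoted the other way round; the
  non-rejection reading is the only one under which "white residuals"
  is the passing state, so that is what the gate implements.)
* model consistency,
  $100\,(1 - \lVert R_{\text{data}} - R_{\text{model}}\rVert /
  \lVert R_{\text{data}}\rVert)$ over the stacked lag-$0..p$
  autocovariances (model autocovariances computed analytically via the
  companion-form Lyapunov equation), gated at 80% — fitted models on
  well-behaved resting-state LFP sit in the mid-80s or above.

Gated animals are excluded with the reason recorded in the cohort QC
table (`qc_action = "warn"`/`"none"` relax the gating for simulation
studies); nothing is dropped silently.

# Band reduction and group comparison

Spectral GC is evaluated on a 0.25 Hz grid over (0, 100] Hz (fine
enough to put at least eight points inside the narrow 2–4 Hz band) and
reduced to six canonical bands: delta 2–4, theta 6–10, beta 15–25, low
gamma 35–45, mid gamma 55–75, high gamma 70–90 Hz.  The mid/high gamma
overlap is honoured as defined; bands are integrated independently.
The default reduction is the trapezoidal *integral* in Hz (nats·Hz); a
`reduce = "mean"` switch divides by bandwidth, since either convention
is found in practice.

Groups are compared per directed edge with the two-sided Wilcoxon
rank-sum test (exact enumeration for tie-free samples of at most 8 per
group, normal approximation with continuity and tie corrections
otherwise) and the effect direction is reported as the rank-biserial
*scaled W*: $2U/(n_a n_b) - 1 \in [-1, 1]$, where $U$ counts
comparison-group-higher pairs with half-credit for ties; negative
values mean the comparison group (HET) is lower.  FDR control is
Benjamini–Hochberg by default (Benjamini–Yekutieli available).  The
family is always *all* tests of the chosen mode — 180 edge-by-band
cells in `per_band` mode, 30 edges in `broadband` mode — and the family
size is recorded in the result; narrower families would need a
substantive argument the data do not supply.

Two pooling conventions exist for the broadband mode.
`pool = "band_samples"` treats each animal-by-band value as a sample
(pool sizes $14 \times 6 = 84$ and $11 \times 6 = 66$ at the reference
cohort sizes), which mirrors how broadband n is often reported.  Band
values within an animal are statistically dependent, however — they
derive from one fitted model — so the rank-sum independence assumption
fails and the test is anti-conservative under that pooling: in a null
simulation with identical generative truths for both groups the package
measures an order-of-magnitude excess of flagged edges.
`pool = "animal_mean"` (one broadband value per animal) is
exchangeable under the null and is the configuration under which the
package's calibration and power claims are made; the test suite
verifies FDR calibration (flagged proportion well below the nominal
0.05 across 200 null label draws) and power (a halving of one true
coupling is flagged with negative scaled W in every draw at 14 vs 11
animals) under it.

# The synthetic-data module

The generator exists to give every stage a known truth, not to imitate
real LFP in detail.  It emulates:

* stationary multichannel VAR signals with a known directed coefficient
  graph.  The default six-region truth (PRL, IL, NAcC, NAcS, dCA1,
  vCA1) is a VAR(2) whose diagonal dynamics have real poles at 0.9 and
  0.8 — strongly autocorrelated, low-frequency-dominated signals whose
  persistence survives 5x down-sampling, so fitted models clear the
  adequacy gates the way resting-state LFP does — and five directed
  lag-1 couplings with the accumbens core as the dominant source
  (NAcC->NAcS 0.25, NAcC->IL 0.20, PRL->dCA1 0.20, dCA1->NAcS 0.15,
  vCA1->dCA1 0.20).  Null edges have exactly zero conditional GC by
  construction;
* 50 Hz line contamination (pure sinusoid, amplitude in channel-SD
  units) and high-amplitude movement artifacts (boxcar offsets of
  `artifact_amp` SD lasting `artifact_dur` s, Poisson-placed) — the
  simplest event model that exercises the notch and rejection logic.
  No amplitude criterion for artifacts is published for the reference
  analysis, so the simulator's artifact parameters are free knobs, not
  calibrated to data;
* behavioural cohorts of biconditional sessions: 24 trials (12 per
  cue), per-trial correct/incorrect lever presses Poisson with
  genotype-, cue- and session-dependent means ramping linearly from a
  common chance level to final-session rates (wildtype: correct on both
  cues; heterozygous: a "one-cue learner"), inter-trial intervals drawn
  from a Beta distribution rescaled to 45–180 s with mean 120 s, and
  counterbalancing alternated within genotype.  Poisson counts are a
  reasonable trial-timescale approximation to random-interval
  responding; operant microstructure is out of scope.

It does **not** emulate 1/f broadband spectra, oscillatory rhythms,
volume conduction, non-stationarity, sleep states, or realistic
artifact morphology.  Passing tests therefore certify the *analysis
machinery* — recovery of a known graph, calibration of the statistics —
not robustness to every pathology of in-vivo data.

Determinism: every generator is bit-reproducible for a fixed seed, and
the pipeline fans a single global seed into per-stage, per-animal
substreams, so adding an animal never reshuffles the others.

# Behavioural statistics

With $S^+$ the per-trial correct-lever counts and $S^-$ the
incorrect-lever counts pooled across both cues of one session, the
discrimination ratio is
$$\text{ratio} = P(S^+ > \text{all } S^-) \times
                 P(S^- < \text{all } S^+),$$
the proportion of correct-lever trials strictly above every
incorrect-lever count times the proportion of incorrect-lever trials
strictly below every correct-lever count.  Strict inequalities make
ties count against discrimination, which pins both endpoints exactly:
a perfect responder (every correct count positive, every incorrect
count zero) scores 1, and uniform responding (equal counts) scores 0.
Because both factors range over all trials of *both* cues, a one-cue
learner — perfect on one cue, at chance on the other — scores strictly
below a two-cue learner with the same total presses, which is exactly
the contrast the statistic exists to expose.  A per-cue-then-average
variant is available (`per_cue = TRUE`) for sensitivity analyses.
Session-level acquisition curves and final-session per-cue breakdowns
are exported as tidy tables (mean, SEM, n) so that mixed ANOVA can be
run in any standard package; those routine fits are intentionally not
re-implemented here.

# Numerical choices and degenerate inputs

* VAR simulation discards a burn-in of `10 * order` samples (at least
  0.5 s); the long-simulation GC oracle uses $10^6$ samples and
  20-lag regressions, placing its Monte-Carlo error well below the
  differences it is used to resolve.
* Non-stationary truths (companion spectral radius $\ge 1$) are
  rejected with the radius reported; unstable *fitted* models are
  flagged and refuse spectral analysis rather than returning garbage.
* Rank-deficient VAR regressors raise an explicit singularity error;
  zero-variance channels are rejected by name during normalisation.
* DARE non-convergence names the failing source channel.
* Band integrals interpolate band endpoints linearly when they fall
  between grid points and refuse grids coarser than 0.5 Hz inside a
  band.

# Study conditions used by the test suite

Simulation studies are sized for a desk-scale machine: cohort
calibration and power studies use 40 five-second epochs per animal at
200 Hz, the VAR fitted at the generative order, a 0.5 Hz frequency
grid, pools of 28 + 22 animals resampled into 14-vs-11 group draws (200
null draws, 25 alternative draws); oracle comparisons use $10^6$-sample
realisations.  Full-scale settings (ten-minute recordings at 1017 Hz,
0.25 Hz grid, AIC search to order 30) are exercised once end-to-end in
the preprocessing and epoching tests.

# Known limitations

* The conditional spectral integral identity is approximate (see
  above); band values are comparable across groups but are not an exact
  additive decomposition of time-domain GC.
* Whiteness gating tests each channel at $\alpha = 0.05$ without
  multiplicity adjustment; with six channels a correctly specified
  model fails the gate for a predictable minority of animals.
  Simulation studies therefore relax gating (`qc_action`), and cohort
  QC tables always record why an animal was excluded.
* The broadband `band_samples` pooling is anti-conservative (dependent
  within-animal samples); it is provided for descriptive comparability
  and its pool sizes are verified, but inferential claims should use
  `pool = "animal_mean"`.
* Sleep staging, channel interpolation, re-referencing, time-varying
  GC and nonparametric (factorisation-based) GC are out of scope.
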