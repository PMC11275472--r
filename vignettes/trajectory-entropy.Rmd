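---
title: "Trajectory complexity of dynamic functional network connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory complexity of dynamic functional network connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Resting-state fMRI yields, after spatial decomposition, a time course for
each of $N$ intrinsic connectivity networks. Windowed correlation turns a
scan into a trajectory through *connectivity space*: at window $t$ the
subject occupies the point $y_t \in [-1,1]^l$, the vectorized upper
triangle ($l = N(N-1)/2$) of the tapered Pearson correlation matrix of
the $N$ channels. This package quantifies how *complex* those
trajectories are, and whether complexity differs between groups.

The state space is modeled as a linear mixture of $m$ recurring
connectivity patterns: $y_t \approx \mu + \sum_j s_j(t)\, v_j$, with the
$v_j$ (the temporally independent FNC profiles, tFNCPs) fixed across
subjects and the source time courses $s_j$ maximally statistically
independent. Independence is what makes the complexity measure tractable:
the differential entropy of the trajectory decomposes into the sum of the
per-source entropies, so each dimension can be estimated separately with
a one-dimensional estimator and the joint entropy obtained by summation.
This additivity fails under dependence, which is why the basis is
estimated with ICA rather than PCA alone.

The pipeline is therefore: tapered sliding-window correlation per subject
→ concatenation of all subjects' records into one $l \times K$ matrix →
PCA whitening to $m$ dimensions → InfoMax ICA repeated $R$ times and
consolidated ICASSO-style → per-subject source isolation → per-source
Kozachenko–Leonenko entropy → group statistics.

## Estimators and conventions

**Tapered window.** The window is a 40-TR rectangle convolved with a
Gaussian of sd 3 TR, truncated at $\pm 4\sigma$ and renormalized, giving
an effective length of 64 TR. Windows are fully interior (no padding) and
slide in steps of 1 TR by default; both choices avoid edge bias and
maximize the number of window samples available to the entropy
estimator. The step is configurable; a window that long means adjacent
windows are heavily correlated, so a larger step loses little
information. The Fisher z-transform is *not* applied to windowed
correlations by default (a flag enables it for sensitivity analysis).

**Vectorization.** One canonical ordering — row-major strictly upper
triangle — is used for every conversion between matrices and vectors, so
patterns can never be silently scrambled relative to the data.

**Decomposition.** PCA retains exactly $m$ components before square ICA.
InfoMax maximizes entropy of a logistic squashing of the unmixed signals,
equivalent to maximum likelihood under a super-Gaussian source prior;
that matches the heavy-tailed sources the generator produces and those
reported for connectivity dynamics. The natural-gradient update is
applied on mini-batches (size 256) with an initial learning rate
$10^{-2}/\ln m$ for the batch-*averaged* gradient (the classical
batch-summed heuristic divided by the batch size is far too small),
annealing by 0.9 whenever successive updates turn by more than 60°, and
halving on divergence with up to 5 restarts. After convergence the
unmixing matrix is symmetrically decorrelated (projected to orthonormal
rows), so group-level sources have exactly unit variance and exactly zero
mutual correlation; InfoMax on whitened data converges to a near-rotation
anyway, and the projection removes the residual.

**ICASSO consolidation.** $R$ runs (default 150; the validation studies
use 10–20 for speed) differ only in seeded initialization and batch
order. Components are pooled, similarity is the absolute correlation of
source time courses, clusters come from average-linkage agglomeration cut
at $m$, each cluster is represented by its centrotype, and the stability
index is mean within-cluster similarity minus mean similarity to
everything outside. Identical runs give indices of exactly 1; indices
below ~0.9 signal that runs disagree (local optima or over-splitting).

**Scale and sign.** Differential entropy is scale-dependent
($H(aX) = H(X) + \ln a$), so between-subject comparisons are only
well-posed under a fixed scale convention: sources are normalized to unit
variance at the *group* level, and subject-level variance — the signal of
interest — is left untouched. Signs are fixed by making each pattern's
largest-magnitude entry positive; entropy is sign-invariant, so this is
cosmetic. Components are ordered by decreasing pattern norm.

**Entropy.** For each subject and source, the $T$ window samples are
treated as draws from the source's marginal and fed to the
Kozachenko–Leonenko k-nearest-neighbor estimator
$$\hat H = m_v \ln \bar\rho_k + \ln(N_s-1) - \psi(k) + \ln c_1(m_v),$$
with $\bar\rho_k$ the geometric mean of the $k$-th neighbor distances,
$\psi$ the digamma function and $c_1$ the Euclidean unit-ball volume
($c_1(1)=2$). Everything is in nats. The estimator is exactly
scale-equivariant, which the tests exploit. $k$ defaults to 3 — the
usual small-bias choice for kNN entropy estimators; it is exposed in the
configuration. "Entropy rate" here means exactly this marginal
differential entropy per window sample: the estimator contains no
temporal-embedding term, so no block or embedding machinery is added.
Exact ties (impossible for continuous data, possible after rounding) are
broken by a seeded Gaussian jitter of sd $10^{-10}\times$ the sample sd,
applied only when duplicates exist; the geometric mean requires strictly
positive distances.

**Statistics.** For each profile and for the joint entropy:
group means and variances; an OLS regression of entropy on diagnosis
(0 = control, 1 = patient) adjusted for site (dummy-coded), age and
gender; Student's equal-variance t-test, reported only when both groups
pass the Jarque–Bera normality test (NA otherwise); the two-sample
Kolmogorov–Smirnov test; and a pooled-label difference-of-means
permutation test ($B = 10{,}000$ by default, p-value floor $1/(B+1)$)
with Hedges' g as effect size — the bias-corrected standardized mean
difference (sometimes misprinted as "Hodges' G"). BH-FDR is applied to
the $m$ per-profile KS p-values; the joint entropy is a single
pre-specified test reported with its raw p outside that family. PANSS
regressions use patients only (controls have no symptom scores); the
cognition regression uses all subjects with scores.

## The synthetic cohort generator

No suitable public dataset ships with the package (the motivating data
are access-restricted), so validation rests on a generator whose ground
truth is analytic:

* **Patterns** are symmetric, unit-diagonal, block-structured matrices
  (domain blocks of correlated/anticorrelated networks plus within-block
  heterogeneity), redrawn until all pairwise vectorized correlations are
  below 0.5. An optional spectral-spread floor rejects near-low-rank
  draws for BOLD-level recovery studies (below).
* **Sources** are i.i.d. Laplace by default (configurable to Gaussian or
  generalized-Gaussian). Group differences are induced purely through
  scale: patients' scale on the affected sources is multiplied by a
  designed ratio, so the true entropy difference is exactly
  $\ln(\text{ratio})$ nats — no simulation is needed to know the truth.
  Per-subject log-scale deviations (sd 0.15) and per-site offsets
  (sd 0.05) add realistic between-subject and between-site structure.
* **Covariates**: balanced-ish site and gender, ages 18–65, PANSS scores
  for patients only, and a cognition score linearly coupled to the
  subject's log-scale deviation on one designed source, which makes the
  population slope of the entropy-on-cognition regression available in
  closed form.
* **Two generation levels.** *dFNC-level* records emit the trajectory
  directly ($y_t = \sum_j s_j(t) v_j + \text{noise}$) and are the fast
  path for validating decomposition, entropy and statistics. *BOLD-level*
  scans sample each volume from a time-varying covariance
  $\Sigma_t = \text{shrink}\cdot I + (1-\text{shrink})(I + \sum_j
  \tilde s_j(t) P_j)$ via its Cholesky factor plus white noise, and are
  used to validate the windowing stage end to end.

**Positive definiteness by construction.** At the BOLD level the
patterns are rescaled to unit spectral radius and source excursions are
clipped at 0.45, which bounds the modulation's most negative eigenvalue
above $-(1-\text{shrink})\,m\,c > -1$ at the defaults. Both operations
are identical across subjects and groups, so the distributional scale
ratios — and hence the entropy ground truth — are unchanged.

**Source persistence.** BOLD-level sources are renewal processes that
redraw every 40 TR (the rectangle length) rather than every TR. An
i.i.d.-per-TR covariance modulation is invisible to a 64-TR window: the
taper attenuates its variance by roughly the effective sample size
(~1/43), far below the windowed-correlation sampling noise (sd ~0.15 per
entry), so nothing could be recovered from it even in principle. Dwell
times on the order of the window match how connectivity states are
described in practice and let the modulation pass through the window.
dFNC-level cohorts keep i.i.d. sources (`dwell = 1`).

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: no hemodynamic response function, no
physiological or scanner artifacts, no head motion, no spatial stage at
all (network time courses are the starting point), linear mixing with
temporally constant patterns, and sources that are exactly independent
and exactly within a named scale family. Passing the validation battery
demonstrates that the estimators recover what they are defined to
recover; it does not certify the neuroscientific model.

## The validation study and its problem sizes

The reference detection study uses 60 subjects (30 per group), 20
networks, 4 sources with a designed $\ln 2$ reduction in two of them,
trajectories of 97 windows (the bookkeeping of a 160-volume scan under
the 64-TR taper), $R = 20$ consolidated runs and $B = 2000$
permutations, replicated over 10 cohorts. These sizes keep the full
battery at a few minutes on a single core while leaving all effects
comfortably detectable; they are the package's choices, scaled down from
the motivating study's dimensions (151 patients, 160 controls, 53
networks, 8 sources, $R = 150$, $B = 10{,}000$).

The study runs on dFNC-level records. This is deliberate: at a 160-volume
scan length the BOLD route carries almost no usable information — the
windowed-correlation noise dominates the PD-bounded modulation, and with
sources persisting about one window there are only ~2.4 independent
source values per subject for an entropy estimate. The windowing stage is
validated separately: an exact oracle (uniform taper ≡ plain Pearson) and
a BOLD-level recovery study in the regime where recovery is genuinely
possible (16 subjects × 6000 volumes, 2 sources, dwell 160 TR, low
noise). Even there, individual pattern draws vary in how much modulation
energy survives spectral normalization — near-low-rank draws lose most of
it — so that study constrains the *median* matched correlation across
replicate cohorts (> 0.9) rather than every draw, and draws its patterns
with a spectral-spread floor of 0.9. This is a property of the generative
geometry, not of the estimators.

One calibration note: the regression-recovery check asks for coverage of
±2 SE intervals in at least 95 of 100 cohorts, while the nominal coverage
of a ±2 SE interval is 95.45%; the binomial fluctuation of that bar is of
the same order as its margin, so occasional dips below 95 at particular
seeds are expected behavior of a correctly calibrated model, not a
defect.

## Numerical choices and degenerate inputs

* Taper kernels are truncated at $\pm4\sigma$ and renormalized; weights
  are peak-normalized (the raw convolution preserves the rectangle's
  mass, which the tests assert).
* Windows in which a channel has (numerically) zero weighted variance
  yield NA entries and a warning; more than 5% such windows is an error.
* PCA refuses a model order above the numerical rank (threshold
  $10^{-10}$ relative to the top eigenvalue) and reports the rank.
* `model_order_scan` provides the order-selection harness: mean/min
  stability per candidate order, plus FDR-significant group-difference
  counts when covariates are supplied.
* Constant covariates and single-level factors are dropped from
  regressions; genuine rank deficiency is an error naming the aliased
  terms. Missing covariate rows are deleted listwise and counted.
* All randomness is seeded and every seeded function restores the
  caller's RNG state. Pipeline stage seeds derive from the master seed by
  fixed offsets (ICA run $i$: `+1000+i`; entropy jitter: `+2000`;
  permutations: `+3000`), so the whole run is reproducible from one
  integer and the stages draw from effectively independent streams.

## Limitations

Joint entropy by summation is exactly valid only under exact
independence; ICA minimizes but does not abolish dependence, so the
joint value is best read as a tight upper bound. The marginal-entropy
reading of "entropy rate" ignores temporal dependence within a source's
window samples; with step-1 windows the samples are strongly
autocorrelated, which inflates estimator variance (not bias) relative to
the i.i.d. case. Model order $m$ is a user choice; the scan harness
summarizes stability but does not decide. And the BOLD-level generator is
a test harness for the windowing stage, not a claim about how real scans
arise.
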