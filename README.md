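# dfncentropy

Trajectory complexity of dynamic functional network connectivity (dFNC)
in resting-state fMRI, for neuroimaging researchers comparing clinical
groups.

A scan is turned into a trajectory through connectivity space: at each
position of a tapered sliding window (a 40-TR rectangle convolved with a
Gaussian of sd 3 TR), the Pearson correlation matrix of the N network
time courses is vectorized to its upper triangle, giving a T × N(N−1)/2
record per subject. All subjects' records are concatenated, PCA-whitened
to m dimensions, and decomposed by InfoMax ICA run R times and
consolidated ICASSO-style into m temporally independent FNC profiles
(tFNCPs) with stability indices. Each subject's complexity along profile
j is the Kozachenko–Leonenko k-nearest-neighbor estimate of the
differential entropy of its source time course,

    H(k, N) = m ln ρ̄_k + ln(N − 1) − ψ(k) + ln c₁(m)    [nats]

with ρ̄_k the geometric mean of k-th neighbor distances, ψ the digamma
function and c₁(m) the unit-ball volume; the joint entropy is the sum
over profiles, valid because ICA maximizes their independence. Groups
are compared per profile and jointly with a covariate-adjusted OLS
regression (diagnosis contrast 0 = control, 1 = patient), a
Jarque–Bera-gated Student's t-test, the Kolmogorov–Smirnov two-sample
test, and a difference-of-means permutation test with Hedges' g,
BH-FDR-corrected across the profile family.

Because the motivating clinical data are access-restricted, the package
includes a seeded two-group cohort generator with analytic ground truth:
group entropy differences are induced through source scale, so the true
difference is exactly ln(scale ratio) nats, and a cognition score is
coupled to one source with a closed-form regression slope. Every stage
is validated against this generator.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(simulate → window → decompose → entropy → stats → replicates); each
script writes its tables under `results/`. Running
`Rscript analysis/01_simulate.R` through `05_stats.R` on the reference
cohort (60 subjects, 20 networks, 4 sources, designed ln 2 ≈ 0.693-nat
reduction in sources 3–4 of the patient group) prints:

```
ICASSO stability indices: 0.996, 0.974, 0.997, 0.975.
Matched |correlation| with the designed patterns: 1, 1, 0.998, 0.999

Control-minus-patient entropy differences (designed vs estimated):
  true_source designed_diff_nats estimated_diff_nats
1           1             -0.041              -0.050
2           2             -0.022               0.010
3           3              0.721               0.747
4           4              0.683               0.682

variable mean+-var (pat)   mean+-var (con)   beta+-SE           p(KS)      q(FDR)     flagged
tfncp_1  1.301+-0.050      1.311+-0.030      -0.027+-0.058      0.808      0.808
tfncp_2  1.330+-0.044      1.279+-0.035      0.006+-0.053       0.0709     0.0945
tfncp_3  0.835+-0.049      1.517+-0.046      -0.705+-0.061      1.01e-15   4.06e-15   yes
tfncp_4  0.790+-0.045      1.537+-0.044      -0.772+-0.059      2.99e-14   5.99e-14   yes
joint    4.256+-0.248      5.644+-0.179      -1.498+-0.122      2.99e-14   -

CMINDS regression on tfncp_2 ...: beta = 0.1321 +- 0.0284, p = 2.51e-05.
```

Reading: the decomposition recovers the four designed connectivity
patterns essentially exactly (matched |correlation| ≥ 0.998); the
per-subject entropy differences match the designed ±ln 2 within
estimator error; exactly the two affected profiles are flagged at
FDR < 0.05 with negative regression and effect signs (patients lower);
joint entropy is reduced in patients; and the cognition coupling is
recovered near its closed-form population slope (0.12).
`analysis/06_replicates.R` repeats the study over 10 independent cohorts
(10/10 flag exactly the designed sources).

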