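---
title: "Stepwise functional connectivity: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise functional connectivity: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind **stepconn**, the
choices made where the methodology is genuinely open, the design and
calibration of the synthetic-cohort generator, and what the validation
suite does and does not establish.

## The analysis model

The pipeline takes per-subject region-by-time matrices (a parcellation
with 7 cortical communities — visual, somatomotor, dorsal attention,
ventral attention, limbic, frontoparietal, default mode — plus 7
subcortical structures), a phenotype table (age, sex, BMI in kg/m²,
waist-to-hip ratio, TFEQ eating-behavior scores), and proceeds in five
stages.

**Connectivity.** Columns are z-scored and the sample covariance $S$ is
ridge-regularized before inversion: $P = (S + \rho I)^{-1}$, partial
correlation $r_{ij} = -P_{ij}/\sqrt{P_{ii}P_{jj}}$. The ridge keeps the
estimate well-conditioned when the region count approaches the timepoint
count; $\rho = 0.5$ is the conventional default for parcellated
resting-state data and is scale-free because the columns are standardized
first. An alternative dialect $S + \rho\,\overline{\mathrm{diag}(S)}\,I$
is available (`ridge = "scaled"`); the two coincide on z-scored data.

**Degree and seed selection.** Degree centrality is the total connection
strength $d_i = \sum_{j \ne i} |r_{ij}|$. Whether negative partial
correlations should count toward "total strength" is ambiguous in the
field; both conventions are implemented (`degree_mode`), with
`absolute` the default because discarding negative edges makes degree
depend discontinuously on estimation noise near zero. Per region, degree
is correlated with WHR across subjects; two-sided p-values use the exact
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ transform (two-sided because both positive
and negative phenotype effects are expected and observed), and
Benjamini–Hochberg FDR at $q < 0.05$ defines the seed set. Seeds are
selected on the pooled cohort, as is standard for a dimensional phenotype
analysis; a covariate-adjusted variant is available through
`sensitivity = "age_sex"` / `"tfeq"`, which residualizes degrees by
ordinary least squares before selection.

**Stepwise connectivity.** Each subject's connectivity matrix is
thresholded at the 95th percentile of its own edge distribution and
binarized; walk counts from the seed set are computed by iterated matrix
multiplication, $C_{k+1} = C_k A$, which counts *walks* (revisits
allowed). Counting simple paths instead is NP-hard and is not what the
stepwise-connectivity literature computes. Three choices deserve note:

* *Signed thresholding.* Edges are ranked by signed weight, so the top 5%
  are the most-positive partial correlations. Ranking by magnitude would
  admit strong negative partial correlations as "connections", which is
  hard to justify on a binarized graph; `edge_rank = "absolute"` exists
  for sensitivity analyses.
* *Per-subject thresholds.* The percentile is applied to each subject's
  own matrix, so all subjects have identical edge counts (density is
  controlled, not the cutoff weight).
* *Per-step z-normalization.* Counts grow combinatorially with $k$;
  z-normalizing across regions within each step (population
  $1/N$ standard-deviation convention, fixed) makes steps and subjects
  comparable. A consequence worth remembering: step degrees are
  *relative* quantities — raising one network's connectivity necessarily
  lowers the z-degrees of the rest.

**Hubs.** The hub rule "degree above 1.5× the mean degree" is ill-posed
on z-scores whose mean is zero, so degrees are min-shifted to be
non-negative before the rule is applied (`shift = "min"`, the default;
`"none"` reproduces the plain rule on raw counts). This is an
implementation decision, flagged here rather than silently assumed.

**Group contrasts and behavior.** Subjects are assigned to groups by the
joint BMI/WHR rule (healthy weight: $18.5 \le \mathrm{BMI} < 25$ and WHR
$\le$ 0.85 female / 0.90 male; overweight: $\mathrm{BMI} \ge 25$ and WHR
above the cutoff; everyone else unassigned) or WHO WHR risk bands (low:
< 0.80/0.95; high: > 0.86/1.00). A t-test needs per-subject values, so
contrasts are two-sample t-tests across subjects' step degrees — Welch by
default, since the groups differ in size and variance; pooled variance is
available. FDR families are regions-within-step and networks-within-step,
and the family sizes are recorded in the output so they can be asserted.
For unequal groups, `balanced_bootstrap_compare()` repeatedly subsamples
the larger group to the smaller group's size (without replacement) and
collects the t-distribution. Network step degrees at the largest step are
correlated with the five TFEQ score combinations (restraint,
disinhibition, hunger, restraint+disinhibition, total — composites always
recomputed from subscales) using permutation tests: scores are shuffled
(statistically equivalent to shuffling degrees under exchangeability),
and the two-sided p uses the add-one convention
$p = (1 + \#\{|r^\ast| \ge |r|\})/(n_{\mathrm{perm}} + 1)$, which is a
valid p-value and never zero; the plain proportion is available for
comparability with the "exceeds 95% of the null" phrasing.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `rho` | 0.5 | ridge added to the standardized covariance (dimensionless) |
| `alpha` | 0.05 | FDR level for seed selection and downstream tests |
| `n_boot`, `boot_frac` | 1000, 0.9 | bootstrap iterations and resample fraction (with replacement) |
| `percentile` | 95 | edge-retention percentile of the edge-weight distribution |
| `max_step` | 5 | largest step distance; step degrees stabilize beyond this |
| `hub_multiplier` | 1.5 | hub rule: degree > multiplier × mean |
| `n_perm` | 5000 | permutations for behavior associations |
| `t_variant` | welch | two-sample test variant |

## The synthetic-cohort generator

Real cohorts of this kind live in access-restricted databases, so the
generator is a first-class component: it produces cohorts whose planted
structure the pipeline should recover, with the ground truth stored
alongside.

Time series are zero-mean multivariate normal with a block covariance:
within-community covariance `w = 0.3`, between-community 0, unit
variances. Three effects are planted by modulating covariance entries per
subject:

* **Phenotype effect.** The `n_true_seeds` true seed regions are chosen
  round-robin across all 14 labels; signs follow a fixed community map
  (sensory/subcortical-thalamic negative, transmodal positive). Same-sign
  seeds are grouped into cliques of at most 5, and every clique edge gets
  covariance $0.2 + s\,\beta_e z_i$, where $z_i$ is subject $i$'s
  standardized WHR, $s$ the sign, and the per-edge amplitude $\beta_e$
  divides a total budget $\beta(r) = K \cdot r/\sqrt{1-r^2}$ among each
  seed's clique edges. Because modulated edges join true seeds only,
  no other region receives planted signal — false-positive rates
  downstream are interpretable. The clique design (rather than modulating
  one edge harder) keeps every modulated covariance far from zero:
  $|r_{ij}|$ is V-shaped in the underlying covariance, so an edge crossing
  zero *rectifies* and destroys a planted negative effect.
* **Group effect.** Overweight subjects' within-network covariance in
  `group_effect_networks` (default visual + somatomotor) is shifted by
  `.group_amp_per_d × group_effect_magnitude` with the configured sign
  (default: overweight lower).
* **Behavior effect.** A standard-normal latent $b_i$ modulates the
  behavior network's covariance (amplitude 0.10); the targeted TFEQ
  subscale loads on $b_i$ with loading $r_{\mathrm{target}}/\hat\rho$,
  where $\hat\rho$ is the measured correlation between the latent and the
  network's step-5 z-degree.

Phenotypes are drawn with sex-specific WHR distributions (female lower,
so the sex-specific group cutoffs are genuinely exercised),
status-conditional BMI bands coupled to the within-status WHR residual
(`bmi_whr_coupling`, a free knob — the marginals do not identify the
joint model), ages truncated to 18–85, and integer, zero-truncated TFEQ
scores. Subjects drawn as "intermediate" violate one conjunct of each
group rule, so configured group fractions translate into assignment
counts. Overweight subjects receive small TFEQ shifts (higher restraint
and disinhibition) *except* on subscales carrying a planted behavior
effect: group status correlates with WHR, WHR modulates the seed cliques,
and that pathway would contaminate the planted score–degree correlation
with a confound of order −0.06.

**Calibration.** The mapping from planted targets to covariance
amplitudes cannot be derived in closed form (it depends on the partial
correlation estimator's noise at finite `T`, the absolute-value degree,
thresholding, and walk-count nonlinearities). The three constants —
`K = 0.55`, `0.0256` covariance shift per unit Cohen's d, and
`rho_hat = 0.626` — were measured once with pilot simulations at the
default estimation conditions (`T = 200`, `R = 60`, `rho = 0.5`,
`w = 0.3`) and then frozen. At those conditions the realized values match
their targets well (degree–WHR correlation 0.31 at target 0.30; behavior
correlation −0.28 at target −0.25). Away from those conditions —
different `T`, `R`, seed counts, or threshold — the realized effects
drift, and the group-effect mapping is the most condition-sensitive of
the three; treat `group_effect_magnitude` as approximate outside the
calibration conditions.

**What the generator does not emulate.** No hemodynamics, autocorrelated
noise, head motion, scanner artifacts, site effects, or spatially
heterogeneous community structure; time points are i.i.d. draws, so
estimation noise is optimistic relative to autocorrelated fMRI; the
between-community baseline covariance is exactly zero. Passing
parameter-recovery tests on these cohorts therefore demonstrates the
*statistical machinery* is correct and calibrated, not that effects of
this size are detectable in real resting-state data.

## Validation design and problem sizes

The suite asserts, among others: exact agreement of the walk counter with
a depth-first exhaustive enumerator on random graphs (≤ 8 regions, ≤ 5
steps); exact agreement of the FDR adjustment with a hand-coded step-up
on random p-vectors; empirical size of the permutation test within
Monte-Carlo bounds of 0.05; seed recovery on planted cohorts (300
subjects, 60 regions, 26 true seeds: sensitivity ≈ 1.0, false-discovery
proportion ≈ 0.05); network group-test power at planted d = 0.8 with
100/75 subjects (≈ 1.0) and null family-wise discovery ≈ 0.05; and
byte-identical reproducibility of the full pipeline and of individual
stages re-run from their logged seeds. Simulation sizes (60 regions, 200
timepoints, tens of replicate cohorts) are the package's chosen
desk-scale study conditions: large enough for calibrated estimation
noise, small enough to re-run routinely.

Two honest caveats the suite itself surfaces:

* **Bootstrap stability has a null baseline.** A 90% resample *with
  replacement* shares roughly 63% of its subjects with the full sample,
  so bootstrap effect maps correlate about 0.65 with the full-sample map
  even when there is no signal at all. Stability values should be read
  against that baseline, not against zero.
* **Behavior-association power at small planted effects.** With a planted
  score–degree correlation of −0.25 at 180 subjects and FDR over the
  5 × 5 network-score grid, detection effectively requires the rank-1
  Benjamini–Hochberg hurdle $p \le 0.05/25$, i.e. $|\hat r| \gtrsim
  0.23$; since $\mathrm{sd}(\hat r) \approx 0.07$, the achievable
  detection rate is ≈ 0.7, not the ≥ 0.8 one might hope for. The
  recovery *accuracy* (mean $\hat r$ within ±0.1 of the target) holds;
  the detection-rate shortfall is a property of the design size, and the
  suite reports it rather than enlarging the planted effect.

## Known limitations

* Step degrees are relative (z-normalized) quantities; a planted increase
  in one network induces compensatory decreases elsewhere, so "which
  networks differ" should be interpreted jointly, not cell-by-cell.
* Walk counts weight revisiting walks heavily at high steps; they are the
  standard stepwise-connectivity quantity but not a shortest-path or
  communicability measure.
* The generator's calibration constants are tied to the default
  estimation conditions, as described above.
* No NIfTI/CIFTI ingestion, no surface rendering, no atlas-based
  functional decoding of seed regions; users supply parcellated time
  series and, where needed, seed-subset lists.
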