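# stepconn

Stepwise functional connectivity (SFC) analysis of phenotype-associated
brain networks, for researchers studying how anthropometric phenotypes such
as the waist-to-hip ratio (WHR) relate to the organization of the
resting-state functional connectome.

Conventional seed-based connectivity looks one edge away from a seed
region. SFC generalizes this to *indirect* connectivity: on a thresholded,
binarized connectome `A`, the step-`k` connectivity of region `j` to a seed
set `S` is the number of length-`k` walks

```
C_k(j) = sum over s in S of (A^k)_{sj},      k = 1, ..., 5
```

so step 1 is ordinary seed connectivity, and increasing `k` traces how
signal from the seeds spreads through progressively more indirect routes,
typically converging onto transmodal hub systems. Per step, the walk counts
are z-normalized across regions ("step degrees") and summarized per
subject, group, and functional network.

The package implements the full analysis pipeline:

1. **Connectivity** — per-subject ridge-regularized partial correlation of
   parcellated time series (`partial_correlation()`, precision matrix of
   `S + rho I` with `rho = 0.5`), and weighted degree centrality
   (`degree_centrality()`).
2. **Seed selection** — per-region Pearson correlation of degree centrality
   with WHR across subjects, Benjamini–Hochberg FDR at `q < 0.05`
   (`phenotype_association()`), with 1000× bootstrap stability of the
   whole-brain effect map (`bootstrap_stability()`) and community
   stratification (`stratify_by_network()`).
3. **SFC core** — 95% edge-retention threshold and binarization
   (`threshold_binarize()`), exact walk counts at steps 1–5
   (`sfc_walk_counts()`), per-step z-normalization, and hub detection at
   1.5× the mean degree (`detect_hubs()`).
4. **Group statistics** — healthy-weight vs overweight assignment from BMI
   and sex-specific WHR cutoffs, or WHO risk bands (`assign_groups()`);
   regional- and network-level Welch t-tests with per-step FDR
   (`compare_groups()`); balanced bootstrap for unequal groups
   (`balanced_bootstrap_compare()`).
5. **Behavior** — permutation tests (5000 shuffles, two-sided) linking
   network step degrees to Three-Factor Eating Questionnaire scores,
   FDR-corrected across the network × score grid (`associate_behavior()`).
6. **Synthetic cohorts** — `simulate_cohort()` generates cohorts with
   recoverable ground truth: planted degree–WHR correlations, group
   differences in chosen networks, and behavior–degree correlations, so
   every stage of the pipeline can be validated by parameter recovery.

Results are tibbles throughout; fitted objects have `tidy()` / `glance()`
methods and `autoplot()` visualizations.

## Worked example

```r
library(stepconn)

cohort <- simulate_cohort(sim_config(
  n_subjects = 150, n_regions = 42, n_timepoints = 150, n_true_seeds = 12,
  rng_seed = 2024))
cohort
#> <sfc_cohort> 150 subjects, 42 regions x 150 timepoints, 12 true seed region(s)

config <- pipeline_config(n_boot = 200, n_perm = 1000, rng_seed = 7)
result <- run_pipeline(cohort, config)
result
#> <sfc_pipeline> 12 seed region(s) at q < 0.05; stability 0.94 +/- 0.02
#> <sfc_contrast> overweight (n=38) vs healthy_weight (n=52), welch t
#>   regional discoveries (q<0.05): 152 of 210 tests
#>   network discoveries (q<0.05): 60 of 70 tests

glance(result$effect_map)
#> # A tibble: 1 × 6
#>   phenotype n_subjects n_regions alpha n_selected    min_q
#>   <chr>          <int>     <int> <dbl>      <int>    <dbl>
#> 1 whr              150        42  0.05         12 1.57e-10

intersect(result$seeds, cohort$ground_truth$seed_regions_true)
#>  [1]  1  4  7 10 13 16 19 22 25 28 31 34
```

The 12 regions selected at `q < 0.05` are exactly the 12 with planted
WHR effects. `stability 0.94` is the mean spatial correlation between the
full-sample degree–WHR map and 200 bootstrap maps (90% resamples with
replacement). The contrast block reports where overweight subjects'
z-normalized step degrees differ from healthy-weight subjects'
(at all five step distances, regionally and per network), and
`result$behavior` holds the network × TFEQ permutation correlations at the
largest step. `autoplot(result$effect_map)`, `autoplot(result$contrast)`
and `autoplot(result$behavior)` draw the standard summary figures.

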