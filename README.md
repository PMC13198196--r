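# herdsync

Activity-synchrony analysis for scan-sampled social ungulate groups.

## The scientific problem

Group-living ungulates coordinate their activity: at any moment most of a
herd is often lying, foraging or walking together. How much of that
coordination exceeds chance, and whether it is biased towards particular
partners — nearest neighbours, same-sex pairs, affiliated or similarly
ranked animals — is a central question in collective-behavior research and
in the study of sexual segregation. `herdsync` implements a complete,
tested pipeline for answering it from instantaneous scan-sampling data on a
mixed-sex herd with fluctuating attendance, of the kind produced by
ZooMonitor-style field protocols: repeated short sessions with one focal
animal, every visible animal's behavior recorded in four categories
(lying, standing, walking, foraging), nearest-neighbour ranks NN1–NN3 and
categorical distances (within 1 body length, within 3 BL, over 3 BL)
referenced to the focal.

## The statistics at its core

* **Group synchrony degree** per scan: `100 · max_b n_b / n`, the
  percentage of animals performing the modal behavior, summarised with
  cumulative threshold proportions (≥70%, ≥90%, 100%).
* **Fleiss' multi-rater kappa** on the subset of scans where the whole
  roster is present (raters = animals, subjects = complete scans,
  categories = 4): `K = (P̄ − P̄_e)/(1 − P̄_e)` with
  `P_i = (Σ_j n_ij² − m)/(m(m−1))` and `P̄_e = Σ_j p_j²`.
* **Dyadic observed synchrony**: the proportion of co-presence scans in
  which a pair matches behaviors, compared against the **independence
  null** `E[sync] = Σ_x P_A(x)·P_B(x)` built from each animal's activity
  budget, with a paired t-test across dyads.
* **Foraging-threshold filtering**: scans with ≥ 80% of animals foraging
  (strict `<` retains) are excluded — at scan level for dyadic analyses,
  whole-session for session-level analyses — to separate social coupling
  from mass-grazing bouts.
* **Nearest-neighbour vs random-conspecific synchrony**: per session, the
  proportion of scans each neighbour type (NN1, NN2, NN3, and a seeded
  uniform draw among non-neighbours) matches the focal.
* **Randomized Elo dominance**: winner–loser displacement events are
  shuffled 10,000 times; sequential Elo updates
  (`E_w = 1/(1 + 10^((R_l − R_w)/400))`, K = 200, start 1000) are averaged
  and converted to ordinal ranks 1..N.
* **Regression contracts**: a beta GLM (logit) of foraging proportion on
  sex + rank; a binomial GLMM of session synchrony by neighbour type with
  hour and focal-identity random intercepts; a binomial GLMM of scan-level
  focal–NN1 synchrony on sex combination + affiliation + rank difference
  with distance, both identities and hour as random intercepts; and
  Gaussian LMMs of dyadic synchrony / proximity likelihood with crossed
  member-identity random effects and Satterthwaite single-term deletions.

A seeded agent-based simulator (`simulate_herd()`) generates a full herd —
spatial movement, socially coupled behavior dynamics with proximity-, sex-
and affiliation-weighted copying, rank-dependent foraging, grooming and
displacement streams, and the scan-sampling observation layer — so every
stage is testable without field data, including null calibration and
effect-recovery checks against the simulated truth.

## Worked example

```r
library(herdsync)

sim <- simulate_herd(sim_config(seed = 1))       # 17 animals, 128 sessions
bundle <- run_analysis(sim$data, sim$interactions,
                       seed_conspecific = 1, seed_elo = 1, n_rand = 2000)
print(bundle)
#> <herd_bundle> 17 individuals, 128 sessions, 512 scans, 136 dyads
#> group synchrony: mean 64.75%; thresholds >=70: 38.3%, >=90: 10.0%, >=100: 3.3%
#> Fleiss kappa: 0.149 on 9 complete scans
#> dyadic synchrony: observed 50.05% vs expected 42.02% (t = 41.91, df = 135)

truth_report(sim$truth, bundle)
#>               check       value pass                                              note
#> 1 elo_rank_recovery 0.990196078 TRUE                                    threshold 0.90
#> 2       nn_gradient 0.189453125 TRUE NN1>=NN2>=NN3>=random within MC error, NN1>random
#> 3   sex_effect_sign 0.015021934 TRUE                                         w_sex > 0
#> 4  rank_effect_sign 0.037906981 TRUE                                     beta_rank > 0
```

Reading the output: the simulated herd synchronizes well above the
independence expectation (50.1% observed vs 42.0% expected dyadic
synchrony, paired t₁₃₅ = 41.9); the Elo ranking recovers the latent
dominance order (Spearman ρ = 0.99); focal animals are 18.9 percentage
points more synchronized with their nearest neighbour than with a random
conspecific; and the configured sex and rank effects come back with the
right sign. Fleiss' kappa is computed on the 9 scans (this seed) where all
17 animals happened to be present.

Real data enter through `read_scans()` (one CSV row per animal per scan)
and `read_interactions()`; a small synthetic example export is included:

```r
x <- read_scans(system.file("extdata", "synthetic_scans.csv", package = "herdsync"))
group_size_summary(x)$mean
behavior_budget(x)
```

A command-line front end is installed at `inst/cli/herdsync`
(`simulate`, `analyze`, `check` subcommands).

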