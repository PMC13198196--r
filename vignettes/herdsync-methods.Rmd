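---
title: "Measuring behavioral synchrony in scan-sampled herds: models, nulls and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring behavioral synchrony in scan-sampled herds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(herdsync)
```

## The data model and its assumptions

`herdsync` analyses instantaneous scan samples of a closed roster of
individually known animals. The unit of observation is the scan: at one
time point, every visible animal's behavior is recorded in exactly four
mutually exclusive categories — lying, standing, walking, foraging. Scans
come in sessions of up to four at 5-minute intervals, each session with one
focal animal to whom two further measurements are referenced: categorical
distance (within 1 body length, within 3 BL, over 3 BL — *nested*, so
"within 3 BL" includes "within 1 BL") and the identities of the three
nearest neighbours (NN1–NN3). Attendance fluctuates: an animal absent from
a scan is simply not a row in it.

Assumptions this encodes: sex is a roster attribute (carried once, not per
row, so rows cannot contradict each other); timestamps matter only to the
minute, and the integer hour 9–17 is the temporal random-effect unit;
sessions whose scans miss any present animal's behavior are unusable as
sessions and are dropped whole (`drop_incomplete_sessions()`), mirroring
field practice. Nearest-neighbour ties in the field record are stored as
recorded; the package does not re-break them.

## Synchrony statistics and the independence null

The group synchrony degree of a scan is the percentage of animals in the
modal behavior; with four categories and group size `n` it is bounded below
by `100·ceil(n/4)/n`, which is why threshold summaries (the proportion of
scans at or above 70 / 90 / 100 percent, cumulative by construction) are
reported alongside the mean.

Because synchrony measures are sensitive to group size and the number of
categories, the chance-corrected agreement of choice is Fleiss' kappa with
animals as raters and scans as subjects. Kappa requires a constant rater
panel, which fluctuating attendance breaks; the package therefore computes
it only on *complete* scans (every roster individual present). There is
deliberately no padding mode for incomplete scans — imputing absent
animals' behavior would manufacture agreement. With 17 animals at 0.8
attendance, complete scans are rare (a few percent), so single-dataset
kappa estimates carry sampling noise of a few hundredths; the null
calibration tests average kappa over 20 simulated herds for that reason.

Dyad-level synchrony is the proportion of co-presence scans a pair spends
in the same behavior. Its null is the independence expectation
`Σ_x P_A(x)·P_B(x)`, with each profile `P` computed from **all** scans
where that animal is present, not only co-presence scans — the literal
activity-budget reading, and the one that keeps the null a property of the
individuals rather than of the pairing. A paired t-test across dyads
compares observed with expected; the t statistic is scale-invariant, so
proportions versus percentages do not change it.

One property worth stating precisely, because it shapes what the tests can
claim: permuting behavior labels across animals *within* a scan preserves
the scan's behavior composition. For animals behaving independently, the
permuted pair-match probability `E[n_b(n_b−1)/(k(k−1))]` equals `p_b²`, so
permutation reproduces the independence null exactly — that is the
permutation oracle the tests use. For coupled herds, however, the
composition itself is overdispersed, and no within-scan permutation can
remove group-level synchrony. The test suite verifies both facts; a green
permutation test therefore establishes the null machinery, not that all
synchrony is dyadic.

## Foraging-threshold filtering

Synchrony can be inflated by a common attractor — a grazing bout that
recruits everyone is synchrony, but not social facilitation. The filter
excludes scans where the fraction of animals foraging is at or above a
threshold (default 0.80; inclusion is strict `<`, so boundary scans are
excluded), and for session-level analyses removes whole sessions containing
any such scan. The threshold is a parameter, not an estimate:
`suggest_threshold()` reports the moments of per-scan foraging fractions
and a `mean + k·sd` offset together with histogram counts, but applies
nothing, because the field rule combined a histogram inspection with a
moment rule whose printed arithmetic is ambiguous (a "half standard
deviation" that does not reconstruct from the printed mean and offset —
both the half-sd and full-sd readings are reachable via `k`).

## Dominance and affiliation

Affiliation is deliberately binary and direction-free: a pair has either
exchanged allogrooming at least once or it has not. Dominance comes from
non-contact displacements via randomized Elo: the event order in a pooled
observation period is arbitrary, so sequential Elo scores are averaged over
10,000 uniform shuffles of the event list. The update uses the classical
logistic curve with base 10 and scale 400, K-factor 200 and initial score
1000; all three constants are exposed because different published
implementations differ and *ordinal ranks*, not raw scores, are the
downstream contract (ranks enter the models as integers 1..N, 1 = most
dominant; ties on mean score are broken lexicographically and flagged).
Total score is conserved by construction — a useful invariant the tests
check after every update sequence.

## The regression contracts

Four model structures are fit (the fifth being the same dyadic LMM on a
second response):

* **Foraging ~ sex + rank**, beta family, logit link, on per-individual
  foraging proportions. Proportions exactly 0 or 1 are outside the beta
  support; the standard compression `(y(n−1)+0.5)/n` is available but
  opt-in (`compress = TRUE`), so silent transformation cannot happen.
  Single-term deletions are likelihood-ratio chi-squares. A caveat the
  package's own calibration quantifies: with only ~17 animals the
  asymptotic chi-square reference is slightly anticonservative (nominal 5%
  rejects somewhat more often under the null); the acceptance calibration
  therefore runs at n = 40, where the reference holds, and small-herd
  p-values near 0.05 should be read with that in mind.
* **Session synchrony ~ neighbour type**, binomial GLMM as successes out
  of valid scans (binomial weights of 4 for complete sessions), logit
  link, random intercepts for hour and focal identity, with the random
  conspecific as the reference level so the NN1–NN3 contrasts are directly
  the facilitation effects. The random conspecific is drawn per scan,
  uniformly among attendees excluding the focal and NN1–NN3, from a seeded
  generator recorded in the run manifest.
* **Scan-level focal–NN1 synchrony ~ sex combination + affiliation + rank
  difference**, binary GLMM with random intercepts for the neighbour's
  distance category, both identities and hour.
* **Dyadic synchrony (or proximity likelihood) ~ sex combination +
  affiliation + rank difference**, Gaussian LMM with *crossed* random
  intercepts for both members' identities. Member 1 is the
  lexicographically smaller id; the tests assert the fit is invariant to
  relabelling, which is what makes that convention harmless. Each fixed
  term has one degree of freedom, so the Satterthwaite t-test *is* the
  single-term deletion.

Satterthwaite degrees of freedom are computed in-package on top of lme4:
the REML deviance is rebuilt as a function of the variance parameters
(θ, σ), the asymptotic covariance of their estimates is `2H⁻¹` from a
numerical Hessian, and `df = 2·Var(β̂_j)²/(g'·2H⁻¹·g)` with `g` the
gradient of `Var(β̂_j)` in (θ, σ). Two independent checks pin this down:
the rebuilt deviance equals `-2·logLik` at the optimum, and a balanced
one-way design with a group-level covariate returns the textbook
`n_groups − 2` degrees of freedom. When the Hessian is singular (boundary
fits) the residual degrees of freedom are used and the fit is flagged.
Convergence warnings and singular-fit flags are carried on every model
object rather than silenced; diagnostics beyond that (residual and
random-effect summaries) are intentionally basic.

## What the simulator emulates — and what it does not

`sim_config()` defaults state the observation regime of the study system
the package was built around: 17 animals (13 females, 4 males), 128
sessions of 4 scans at 5-minute intervals between 09:00 and 17:00 over ~10
days, per-scan visibility 0.8 per non-focal animal — group membership
fluctuates between scans, which is exactly what forces kappa onto complete
scans — giving mean scan group size ≈ 13.8 with the full range reachable,
focal rotation excluding the previous focal, and a
stationary activity budget of roughly 62% foraging, 15% standing, 11.5%
lying, 11.5% walking.

Dynamics, per simulated minute: positions follow a noisy
centroid-attraction walk (cohesion 0.02, step sd 1 BL, giving a stationary
herd spread of about 5 BL per axis — local neighbourhoods are meaningful
at the protocol's 1/3-BL distance categories); behavior either copies an
influencer drawn with weight `exp(−d/λ)·(1 + w_sex·same-sex)·(1 +
w_aff·affiliated)` (copy probability 0.35, λ = 1.5 BL so influence
concentrates within the 3-BL zone) or follows a persistence-0.85 Markov
chain whose stationary law is the configured budget, with the foraging
logit shifted by `β_rank·(rank − mean rank)` (default 0.08 per rank unit,
spreading foraging proportions over roughly 0.45–0.75 across 17 ranks —
subordinates forage more). Same-sex influence weight 2× (w_sex = 1) and
affiliated weight 1.5× (w_aff = 0.5) are the default, deliberately modest,
social biases: the corresponding dyadic effects are then of the same small
order as field effects, which is why single-run sign checks in
`truth_report()` fail only on a *confidently* wrong sign, while the
100-replicate recovery tests isolate one mechanism at a time at clearly
recoverable strength (e.g. sex-dominated copying with flat proximity).
Copying uses previous-step behaviors (synchronous update), so the result
does not depend on animal order. A single extra scalar, `w_env`, adds a
shared sinusoidal foraging-logit pulse: with copying off it generates
common-attractor synchrony, the confound the foraging filter exists to
address.

Grooming events are emitted for every affiliated dyad (so analysis-side
affiliation is exactly recoverable) and displacement winners follow a
logistic on latent scores spaced one rank apart (τ = 1, adjacent-rank win
probability ≈ 0.73).

What it does not emulate: habitat structure and forage distribution,
persistent spatial sex segregation (positions are socially unstructured),
observation error, weather or day-to-day regime changes, and any attempt
to fit the generator to the original field data. A green test on simulated
data therefore establishes that the *estimators and tests* behave as
claimed under a known generative model — not that the generator is a
calibrated model of any real herd.

## Numerical and design decisions

* Strict `<` at the foraging threshold; boundary scans excluded.
* Threshold proportions are cumulative (≥70 includes ≥90 and 100).
* Behavior profiles for the expected-synchrony null use all scans where
  the animal is present (not co-presence subsets).
* No minimum co-presence count is imposed on dyads; pairs never co-present
  are reported and excluded.
* "Within three body lengths" includes the within-1-BL category.
* With fewer than four valid scans in a session, neighbour-synchrony
  denominators use the valid count, not 4.
* Two independent RNG streams (random-conspecific sampling; Elo
  randomization) with separately logged seeds, so one can be varied
  without disturbing the other.
* Hour of observation enters models as a factor over integer hours 9–17.
* Elo constants (K = 200, init = 1000, logistic base 10/400) are config
  parameters; ordinal ranks are the contract.
* Kappa refuses datasets with fewer than two complete scans, and reports
  an explicit error state when chance agreement is 1 (kappa undefined).
* Zero-variance difference vectors make the paired t-test an error, not a
  silent `t = 0`.

## Known limitations

Exact reproduction of the original study's printed statistics requires its
deposited field data, which the package cannot redistribute; the
acceptance test for that criterion fails with an explanatory message
unless a copy is supplied locally. The Satterthwaite implementation
matches lmerTest's approach but is not the same code; degrees of freedom
can differ in the last decimals for ill-conditioned fits. The binomial
GLMMs use Laplace approximation (lme4 default); with very sparse responses
the single-term-deletion p-values inherit its known biases, which the
calibration tests bound but do not remove.
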