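---
title: "Estimating adverse-event risk under competing events and varying follow-up"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating adverse-event risk under competing events and varying follow-up}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerisk)
```

## The estimation problem

Safety reporting in randomized trials asks a deceptively simple question: what
is the probability that a patient experiences a given adverse event (AE)
within a time window $[0, \tau]$? Three features of real trial data make the
naive answers biased. Patients enter the study at different calendar times and
are observed for different durations (*varying follow-up*); some observations
end before any event (*censoring*); and some clinical events — death before
the AE being the canonical example — preclude the AE from ever being observed
(*competing events*, CEs). `aerisk` analyzes time-to-*first*-event data coded
per subject as censored (0), AE of interest (1), or competing event (2), one
dataset per AE type, with time measured from randomization (strictly positive
by construction, since onset at the randomization instant is not recordable).

## The five absolute-risk estimators

Write $\hat S$ for the all-cause product-limit survival, $n_i$ for the risk
set at the $i$-th ordered event time, $d_{AE,i}$, $d_{CE,i}$ for event counts,
and $PT(\tau) = \sum_i \min(t_i, \tau)$ for person-time.

* **Incidence proportion (IP)** — $d_{AE}(\tau)/n$. Ignores censoring (it
  estimates the probability that an AE occurs *and is observed*), accounts for
  CEs. Binomial variance.
* **Probability transform of the incidence density (ID)** —
  $1 - \exp(-\hat\lambda_{AE}\tau)$ with
  $\hat\lambda_{AE} = d_{AE}(\tau)/PT(\tau)$. Handles varying follow-up but is
  fully parametric (constant hazard) and ignores CEs.
* **CE-aware transform (ID-CE)** — with $a = \hat\lambda_{AE}$,
  $b = \hat\lambda_{CE}$: $\frac{a}{a+b}\left(1 - e^{-(a+b)\tau}\right)$,
  defined as 0 when $a + b = 0$. Still parametric, but targets the correct
  cumulative incidence.
* **One minus Kaplan–Meier (1−KM)** — product-limit for time-to-AE with CEs
  and censorings both treated as censored. Handles censoring and follow-up,
  but estimates a distribution function that tends to one, so under CEs it
  is biased upward for the AE probability. Greenwood variance.
* **Aalen–Johansen (AJE)** — the nonparametric cumulative incidence
  $\hat F_{AE}(\tau) = \sum_{t_i \le \tau} \hat S(t_i-)\, d_{AE,i}/n_i$. It
  accounts for censoring, varying follow-up and CEs simultaneously with no
  parametric assumption, and is the package's gold standard throughout.

The identities the estimators must satisfy are tested exactly: conservation
$\hat F_{AE} + \hat F_{CE} + \hat S \equiv 1$ at every jump time; AJE $\equiv$
1−KM whenever no CEs are present; IP $=$ AJE at the maximal time without
censoring; ID-CE collapses to ID when $b = 0$; and the sample-wise orderings
$1{-}\mathrm{KM} \ge \mathrm{AJE}$ (pointwise) and
$\mathrm{AJE}(\tau_{\max}) \ge \mathrm{IP}(\tau_{\max})$.

## Relative effects

Between-arm comparisons use the risk ratio
$\widehat{RR} = \hat q_E/\hat q_C$ at a stated evaluation time, computed over
any of the five bases, with the delta-rule variance
$\mathrm{Var}(\log \widehat{RR}) = \mathrm{Var}(\hat q_E)/\hat q_E^2 +
\mathrm{Var}(\hat q_C)/\hat q_C^2$; the incidence-density ratio with Poisson
log-variance $1/D_E + 1/D_C$; and, as the hazard-scale gold standard, the
cause-specific Cox hazard ratio from a two-group fit in which the other event
type and censoring are treated as censored. Hazard ratios use the full
follow-up and carry no $\tau$; risk ratios always do.

AEs for which either arm-wise probability estimate is zero are flagged
`defined = FALSE` rather than raising errors, so that batch analyses can
tabulate exclusions; the same flag marks Cox fits with a monotone partial
likelihood (all events in one arm).

Because a comparator effect and its gold standard are computed on the same
subjects, their ratio has no closed-form variance; `ratio_to_gold()` uses
whole-subject bootstrap resampling stratified by arm. The scheme — percentile
intervals with a default of $B = 999$ resamples — is this package's own
choice, as is flagging (and counting) resamples on which an effect is
undefined rather than failing.

## Regulatory categorization

Absolute risks map to the SmPC/CIOMS frequency classes (very rare < 0.01%,
rare < 0.1%, uncommon < 1%, common < 10%, very common ≥ 10%), with strict
"<" at each upper edge. Relative effects map to four evidence classes from
the CI: *no effect* when 1 is inside; otherwise, for effects above one, by
the lower bound (≤ 1.11 minor, ≤ 1.33 considerable, > 1.33 major), and
symmetrically below one by the upper bound (≥ 0.9 minor, ≥ 0.75 considerable,
< 0.75 major), applied identically to harms and benefits and to RRs and HRs.
The published interval notation overlaps at the cut points 0.75, 0.9, 1.11
and 1.33; this package resolves every boundary toward the **less severe**
class, centralized in one constants table and pinned by explicit boundary
tests. `switch_table()` cross-tabulates comparator categories against the
gold standard's; off-diagonal mass is the practical cost of estimator choice.

## The simulator and what it does (not) emulate

`simulate_trial()` generates constant-hazard competing-risks data: a latent
first-event time exponential with rate $\alpha + \beta$, type AE with
probability $\alpha/(\alpha+\beta)$ — exactly equivalent to latent competing
exponentials, but cheaper — plus random exponential censoring ($\gamma$) and
an administrative horizon reduced by a uniform staggered-entry offset, which
is the mechanism producing varying follow-up. Time is in years and hazards
per year by convention. Closed forms accompany every scenario:
$F_{AE}(t) = \frac{\alpha}{\alpha+\beta}(1 - e^{-(\alpha+\beta)t})$, the
1−KM estimand $1 - e^{-\alpha t}$ (which dominates $F_{AE}$ strictly whenever
$\beta t > 0$, tending to the ratio $(\alpha+\beta)/\alpha$), the true RR at
any time, and the true HR $\alpha_E/\alpha_C$.

The generator emulates the *structure* that drives estimator bias — the mix
of censoring, CEs, and follow-up — not real trials: hazards are constant, so
it cannot probe bias from non-proportional or time-varying hazards, there is
no covariate structure, no recurrent events, and censoring is independent by
construction. Passing tests therefore demonstrate correctness of the
estimators and the direction/magnitude of bias *under this model*, not the
empirical bias in any particular trial.

## Numerical choices

* **Ties.** Events are processed before censorings at the same time; AE and
  CE ties share one risk set, decremented after both. The Cox partial
  likelihood uses Breslow tie handling — simple and adequate for a two-group
  comparison with modest ties, and stated so results are reproducible.
* **Newton–Raphson.** Tolerance $10^{-8}$ on the step, at most 50 iterations,
  with step halving; a zero-information or monotone likelihood returns a
  flagged, non-iterated result. The fit is verified against a grid search of
  the partial likelihood on small fixtures and against an independent
  implementation on larger ones.
* **Variances.** AJE pointwise variance uses the standard counting-process
  (Aalen-type) estimator, cross-validated against the patient-level
  bootstrap; Greenwood for 1−KM; Poisson-based delta method for the density
  transforms. When a product-limit curve hits zero its Greenwood factor is
  degenerate and the variance is set to zero at that point.
* **Evaluation time.** The default $\tau$ is the *maximal evaluation time*:
  the latest observation (event or censored) in the dataset, pooled over
  arms; arm-wise variants are obtained by filtering first. Estimates
  requested beyond the last observation carry the last value forward and are
  flagged, not refused.
* **Probability CIs** are Wald on the complementary log-log scale, clipped to
  $[0,1]$ — range-respecting and standard for cumulative incidences.

## Verification at scale

The test suite anchors the package to analytic truth with simulations sized
to be decisive yet quick: consistency of AJE and ID-CE at $n$ = 200 vs 2000;
parameter recovery of HR = IDR = 2 and the true RR with two arms of 5000
subjects over 20 replicates, with CI coverage pooled across the three
interval types (60 intervals) — pooling chosen because per-measure coverage
over 20 replicates has resolution of only 0.05; the headline upward bias of
1−KM under $\beta = 3\alpha$, whose estimand ratio
$(1-e^{-\alpha t})/F_{AE}(t)$ approaches $(\alpha+\beta)/\alpha = 4$; and
directional medians (1−KM above, IP below the AJE benchmark) across batches
of simulated trials. A caveat worth stating: at the largest observation time
the realized 1−KM is itself random — it jumps to exactly 1 when the last
observation happens to be an AE (probability $\alpha/(\alpha+\beta)$ under
constant hazards) and otherwise sits near the KM estimand at that time — so
the simulated inflation ratio fluctuates around 3.4–4.0 at $n = 5000$ while
the analytic anchor is deterministic.

## Limitations

First events only (no recurrence), two-arm or single-arm designs, no
covariate adjustment or stratification, no subdistribution-hazard (Fine–Gray)
modelling, and no meta-analytic machinery: the aggregated-summary schema
deliberately exposes exactly the per-trial, per-AE rows such a meta-analysis
would consume, and nothing subject-level.
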