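# aerisk

Adverse-event (AE) risk estimation for clinical trials with **varying
follow-up times, censoring, and competing events (CEs)** — and quantification
of how badly the usual shortcuts go wrong.

Routine safety reporting mostly uses the incidence proportion or one minus
Kaplan–Meier to estimate the probability of an AE in a window $[0,\tau]$.
Neither is generally valid when patients are followed for different lengths
of time and when events such as death preclude the AE from being observed.
`aerisk` is for trial statisticians and methodologists who want to

* estimate the absolute AE probability with five estimators side by side —
  incidence proportion (IP), the probability transforms of the incidence
  density with and without CE hazards (ID, ID-CE), one minus Kaplan–Meier
  (1−KM), and the nonparametric gold standard, the **Aalen–Johansen
  estimator** $\hat F_{AE}(\tau) = \sum_{t_i\le\tau}\hat S(t_i-)\,d_{AE,i}/n_i$;
* compare arms via risk ratios $\hat q_E/\hat q_C$ (delta-rule variance),
  incidence-density ratios, and cause-specific Cox hazard ratios (Breslow
  ties, Newton–Raphson on the partial likelihood), with bootstrap comparison
  of any estimator against its gold standard;
* map results into regulatory categories — SmPC/CIOMS frequency classes
  (very rare < 0.01% … very common ≥ 10%) and CI-based evidence classes
  (no effect / minor / considerable / major) — and cross-tabulate category
  switches induced by estimator choice;
* simulate constant-hazards competing-risks trials with closed-form truths
  and benchmark every estimator's bias against truth or against the
  Aalen–Johansen reference.

All user-facing functions take a data frame first and return tibbles, so
everything composes with the pipe; `autoplot()`, `tidy()` and `glance()`
methods are provided for the result types.

## Worked example

Subject-level data are tibbles with `subject_id`, `arm`, `time` (from
randomization), and `event_code` (0 censored, 1 AE, 2 competing event); CSVs
load via `read_trial()`. A four-subject toy — AE at 1, CE at 2, censored at
3, AE at 4 — shows the estimators disagreeing sharply:

```r
library(aerisk)
toy <- trial_data(data.frame(
  subject_id = paste0("s", 1:4), arm = "experimental",
  time = c(1, 2, 3, 4), event_code = c(1, 2, 0, 1)
))
estimate_ae_risk(toy, tau = 4)
#> # A tibble: 5 × 11
#>   estimator    arm            tau estimate variance     n  d_ae  d_ce n_cens
#> 1 ip           experimental     4    0.5     0.0625     4     2     1      1
#> 2 id           experimental     4    0.551   0.0646     4     2     1      1
#> 3 id_ce        experimental     4    0.466   0.0555     4     2     1      1
#> 4 one_minus_km experimental     4    1       0          4     2     1      1
#> 5 aje          experimental     4    0.75    0.0469     4     2     1      1
```

The incidence proportion (0.50) misses the censored subject's unobserved
risk; 1−KM (1.00) treats the competing event as censoring and runs off to
one; the Aalen–Johansen value 0.75 is the correct nonparametric estimate
(and 0.75 + 0.25 + 0 sums to one with the CE incidence and the survivors).

On a simulated two-arm trial with true hazard ratio 2 (AE hazards 0.2 vs 0.1
/year, CE hazard 0.3, censoring 0.1, 2000 patients/arm):

```r
cfg <- scenario_config(n_per_arm = 2000, alpha_e = 0.2, alpha_c = 0.1,
                       beta_e = 0.3, beta_c = 0.3, gamma = 0.1, seed = 2026)
trial <- simulate_trial(cfg)
risk_ratio(trial, basis = "aje")   # RR of AE probabilities at the maximal time
#>   measure basis   tau estimate lower upper ...
#> 1 rr      aje    15.6     1.48  1.33  1.65
cox_hr(trial, "ae")                # cause-specific hazard ratio, truth = 2
#>   measure basis   tau estimate lower upper ...
#> 1 hr_ae   cox      NA     1.87  1.65  2.12
frequency_category(c(0.092, 0.004, 0.2))
#> [1] common      uncommon    very_common
```

The RR (1.48) and HR (1.87) differ because they answer different questions —
a probability contrast at $\tau$ versus a hazard contrast — even with the
same data; the true RR at that $\tau$ is 1.60 and 2.0 is inside the HR's CI.

A thin command-line front end ships in `inst/cli/aerisk`
(`estimate`, `compare`, `categorize`, `simulate`, `benchmark`).

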