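# stetrials

Design, interim monitoring and simulation for single-arm two-stage phase II
trials with a **nested discrete-time survival endpoint** — the typical
oncology setting where progression-free survival is scanned every 3 months
and the primary endpoint is the survival rate at a 12-month landmark.

## The problem

Simon-type two-stage designs stop for futility after `n1` patients, but when
the endpoint is 12-month survival the trial must sit idle for a year of
follow-up before the interim can be run. Using a *short-term* endpoint
(3-month survival, threshold `s1`) at the interim removes most of that pause,
but ties the design's power to a planning guess about the short-term survival
rate: if the true 3-month rate is lower than assumed, the trial stops far too
often even when the treatment works at 12 months.

`stetrials` implements two interim rules that use *every* assessment
available at the interim look instead of a fixed short-term threshold:

* **CP rule** — conditional power. The conditional survival chain
  `p_{k|k-1} = P(alive at k | alive at k-1)` is estimated by the discrete
  Kaplan–Meier MLE `x_k / n_k`; each patient pending at assessment `k'`
  survives to the landmark with probability
  `p_{k*|k'} = prod_{k > k'} p_hat_{k|k-1}`, pending-group survivors are
  drawn as `y_{k'} ~ Binomial(m_{k'}, p_hat_{k*|k'})`, and the CP is
  `P(known survivors + sum y > r)` — available both by Monte Carlo and as an
  exact binomial convolution.
* **PoS rule** — Bayesian posterior predictive probability of success. Each
  transition gets a negative log-Gamma prior
  (`-log p_{k|k-1} ~ Gamma(1/k*, rate)`), chosen because the landmark product
  of the transition probabilities then follows a Beta distribution; the
  factorized posteriors are computed on a deterministic grid (no MCMC) and
  the prediction averages over joint posterior draws, which shrinks extreme
  CP values towards the prior.

Both cutoffs are **calibrated by simulation** so that the binding-rule type I
error stays below the nominal level (0.10 in the reference scenario), using a
patient-level simulator with Weibull event times solved through the
hypothesized discrete rates and Poisson accrual. Exact operating
characteristics and an exhaustive design search for the classic designs
(binomial formulas, nested short/long-term joint law) are included as
references.

## Worked example

An 18-patient interim look (month 28 of a 38-patient trial, reject at the end
iff more than `r = 6` of 38 are 12-month survivors):

```r
library(stetrials)
print(run_worked_example(n_mc = 100000, seed = 1))
```

```
== Worked example: interim look at month 28 (scenario-1 design) ==

Interim snapshot at month 28 (18 of 38 patients recruited)
  survivors/evaluable:  12/18  6/11  3/5  3/3
  pending m_k' (k' = 0..3): 20, 1, 1, 0; confirmed landmark survivors: 3; observed deaths: 13

Conditional survival MLEs p_{k|k-1}: 0.6667  0.5455  0.6  1
Conditional-to-landmark p_{k*|k'}, k' = 0..k*: 0.2182  0.3273  0.6  1  1
Posterior means E(p_{k|k-1} | data): 0.6811  0.5828  0.6584  0.9457

Fixed short-term rule: 12 survivors at the first assessment vs s1 = 13 -> stop for futility
CP rule:  conditional power = 0.8156 (cutoff 0.728) -> continue to stage 2
  exact value by convolution: 0.8170
PoS rule: posterior predictive PoS = 0.7751 (cutoff 0.734) -> continue to stage 2
```

Reading it: 12/18 patients survived their 3-month scan, one short of the
fixed threshold `s1 = 13`, so the classic short-term rule kills the trial.
But the interim also contains 6/11 survivors at 6 months, 3/5 at 9 months and
3/3 confirmed 12-month survivors; chaining those transitions, a newly
enrolled patient reaches the landmark with estimated probability 0.218, and
the predicted probability that the *finished* trial clears `x > 6` is 0.82
(CP) or 0.78 (PoS) — both clearly above their calibrated futility cutoffs, so
both assessment-based rules continue. The trial only needs 4 more landmark
survivors among 22 outstanding patients and is in fact in good shape.

Reproducing the surrounding design and calibration from scratch:

```r
# the reference design: s1 = 13, r = 6, n1 = 18, n = 38
spec <- design_search_spec(p_lte_null = 0.127, p_lte_alt = 0.317,
                           p_ste_null = 0.7, p_ste_alt = 0.9)
attr(search_kunz_design(spec), "oc")

# CP cutoff calibration under the null (~0.728)
null_scen <- scenario_spec(0.7, 0.127, accrual_rate = 0.5, design = scenario1_design())
calibrate_cutoff(null_scen, "ste_cp", alpha_target = 0.10,
                 n_replicates = 20000, seed = 1)

# power when the short-term assumption is wrong (true 3-month rate 0.7):
# the fixed-threshold design collapses to ~0.33, the CP rule keeps ~0.77
mis <- scenario_spec(0.7, 0.317, accrual_rate = 1, design = scenario1_design())
kunz_power(scenario1_design(), 0.7, 0.317)
estimate_oc(mis, "ste_cp", n_replicates = 5000, seed = 1, cutoff_override = 0.728)
```

## Command line

```sh
Rscript inst/cli/stetrials.R design-search --config design.json --out design.csv
Rscript inst/cli/stetrials.R interim-cp --config interim.json --patients patients.csv --seed 1
Rscript inst/cli/stetrials.R calibrate --config scenario.json --seed 1
Rscript inst/cli/stetrials.R simulate-oc --config scenario.json --out oc.csv --seed 1
Rscript inst/cli/stetrials.R fixture
```

Configs are JSON; patient tables are CSV with columns
`id, recruit_time, event_time` (empty = no event) and optional
`lost_to_followup`. Exit codes: 0 success, 2 validation error, 3 infeasible
design search.

See `vignettes/interim-monitoring.Rmd` for the statistical model, the
numerical choices and the known limitations.
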