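# rtscan

**Information-theoretic scan scheduling for fractionated radiotherapy.**

During a six-week radiotherapy course (2 Gy per fraction, Monday–Friday),
tumor scans are costly, so only a few can be collected — yet they are the
only way to learn how radiosensitive a particular tumor is while there is
still time to adapt the treatment. `rtscan` implements a sequential
Bayesian optimal-experimental-design loop that decides *when to scan*
(and, when tumor composition is measurable, *which metric to record*) so
that a fixed scan budget constrains the radiosensitivity parameter as
tightly as possible.

The radiobiology is the linear-quadratic (LQ) model: a fraction
`SF(d) = exp(−αd − βd²)` of cells survives each dose `d`. With `α` fixed
at 0.14/Gy, the target of inference is `β` (equivalently the `α/β`
ratio). The machinery is a high-to-low-fidelity calibration study:

* **High-fidelity data** come from a hybrid cellular automaton of a tumor
  spheroid cross-section: oxygen diffuses from the boundary and is
  consumed by living cells; its local level drives
  proliferating/quiescent/necrotic transitions; cells divide with
  adhesion chain-shifts and contact inhibition, necrotic cells lyse, and
  each dose kills each living cell with probability `1 − SF`.
  Daily measurements convert cross-section extents to an ellipsoid
  volume `V = 0.5·h·v²` (mm³).
* **Low-fidelity surrogates** are calibrated against the accumulated
  scans: a one-compartment logistic ODE
  `dV/dt = A·V(1 − (B/A)V)` with impulsive kill `V(t⁺) = SF·V(t⁻)`, and
  a two-compartment viable/necrotic system in which the killed fraction
  moves into the necrotic compartment and decays at rate `ζ`.
* **Calibration** of `β` is by delayed-rejection adaptive Metropolis
  (DRAM) under a Uniform(0, 0.5) prior, with residual variances
  Gibbs-sampled from their conjugate full conditionals.
* **Scan selection** maximizes a k-nearest-neighbor (Kraskov) estimate of
  the mutual information between the `β` posterior and the model
  prediction at each candidate scan, normalized to a relative MI
  `R ∈ [0,1]` and optionally penalized for skipped days:
  `S_k(i,r) = R(i,r) − k·Σ_{j<i} R(j,r) / Σ_l R(l,r)`.
  The penalty weight `k ∈ [0,1]` trades a late, informative scan against
  the information forfeited on the days skipped to reach it.

Three reference tumors ("high", "medium", "low" radiosensitivity:
`β` = 0.14, 0.0467, 0.0156 at `α/β` = 1, 3, 9) span the clinically
relevant range.

## Worked example

One scan per treatment week: generate high-fidelity data for the
high-radiosensitivity tumor, then let the design loop pick the scan day
for each of weeks 2–6 and recalibrate after each scan.

```r
library(rtscan)

traj <- run_scenario("high", seed = 1, params = ca_params())
fit  <- weekly_design(traj, n_iter = 5000, n_mi = 500, seed = 2)
tidy(fit)
#> # A tibble: 5 × 8
#>    week   day cycle_day    mi beta_median beta_q25 beta_q75 rel_error
#>   <int> <dbl>     <dbl> <dbl>       <dbl>    <dbl>    <dbl>     <dbl>
#> 1     2    22         1  3.64       0.212    0.199    0.230     0.128
#> 2     3    29         1  2.83       0.211    0.198    0.224     0.129
#> 3     4    36         1  3.07       0.211    0.200    0.223     0.129
#> 4     5    43         1  1.49       0.210    0.200    0.222     0.129
#> 5     6    50         1  2.51       0.211    0.201    0.222     0.129

glance(fit)
#> # A tibble: 1 × 8
#>   beta_hat beta_q25 beta_q75 rel_error n_scans     k model design
#>      <dbl>    <dbl>    <dbl>     <dbl>   <int> <dbl> <chr> <chr>
#> 1    0.211    0.201    0.222     0.129       8 0     one   weekly
```

Reading the output: in every week the first day of the weekly treatment
cycle (simulation days 22, 29, 36, 43, 50; `cycle_day = 1`) carries the
most mutual information, so a clinician limited to one scan per week
should scan on Mondays for this rapidly responding tumor. `beta_median`
and the quartiles track the posterior of `β` as scans accumulate — the
interquartile range narrows from eight scans' worth of information — and
`rel_error` is the whole-horizon relative L2 error of the calibrated
model against the daily high-fidelity series. The final estimate
`β ≈ 0.21` sits above the generating value 0.14: in the automaton,
radiation-killed cells lyse and leave the measured volume within about a
day — a removal channel the one-compartment surrogate lacks — so the
calibrated `β` absorbs that model discrepancy by over-responding. This
bias between the high-fidelity data and its calibrated surrogate is
itself a central feature of high-to-low-fidelity calibration studies.

Unconstrained budgeted designs, the two-compartment variants, penalty
sweeps and plotting:

```r
h <- sequential_design(traj, model = "one", budget = 12, k = 0.5, seed = 3)
autoplot(h, ca_data = traj)   # chosen scans over the trajectory
plot_iqr_trace(h)             # posterior shrinkage per step
plot_score_table(h, step = 1) # MI and score across candidate days

rep <- run_experiment(list(scenarios = "high", k = c(0, 0.5, 1),
                           budget = 12, seeds = 1))
rep$summary
```

A thin command-line front end (subcommands `simulate-ca`, `calibrate`,
`design`, `evaluate`, `report`) is installed at
`system.file("cli", "rtscan.R", package = "rtscan")`.

## Vignette

`vignettes/scan-scheduling.Rmd` documents the models and their
assumptions, the generator's conditions and how its free constants were
fixed, the estimator details (KSG variant, jitter, marginal
standardization), the numerical choices, and what the synthetic study
does and does not say about clinical data.
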