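# prostasim

Individual-level microsimulation of the harms, benefits and
cost-effectiveness of PSA-based prostate cancer screening strategies.

Population screening for prostate cancer averts deaths but overdiagnoses —
it detects cancers that would never have surfaced clinically — and the
balance between the two shifts with the start age, stop age and interval of
the screening programme. This package is for modellers and health
economists who want to explore that balance with a transparent, fully
reproducible simulation: it generates no-screening life histories for a
cohort of men, overlays a grid of 230 screening strategies (starts 50–55,
intervals 1/2/3/4/8 years plus single tests, last test by 69) on the *same*
histories, and prices the differences.

## The model in brief

* **Natural history.** Onset follows a piecewise-constant age hazard;
  cancers then progress through 18 preclinical states — T stage (T1–T3) ×
  Gleason (<7, 7, >7) × extent (local-regional, distant) — as a semi-Markov
  process in which progression competes with clinical detection, all
  exponential. Other-cause death comes from a life table.
* **Screening.** At each test age: attendance (0.80) → test positivity
  given the preclinical state (PSA ≥ 3 ng/mL represented as state-specific
  episode sensitivity) → biopsy compliance (0.90) → biopsy sensitivity
  (0.90). Overdiagnosis = screen detection of a cancer whose counterfactual
  clinical diagnosis never precedes the man's death. Biopsies are
  back-calculated from detections via PPVs of 22.7% (screen) and 35.8%
  (clinical).
* **Mortality benefit.** Screen-detected relevant cancers are cured with a
  lead-time-dependent probability c(L) = c_max·(1 − e^(−βL)); cured men die
  of other causes, non-cured men die at their counterfactual clinical-
  pathway age (treated with HR 0.56 for local disease; distant disease
  gains nothing).
* **Economics.** QALY losses Σ(1−uᵢ)·dᵢ·nᵢ over health states (including
  the 9-year postrecovery state at utility 0.95), discounted costs by phase,
  everything at 3.5% from cohort entry at age 50. Strategies become points
  (QALYs gained, net cost) per 1000 men; strong and extended dominance
  prune them to an efficient frontier with strictly increasing ICERs, and
  the optimum is the largest ICER at or below a willingness-to-pay of
  €20,000/QALY.

All inputs are synthetic, generated fixtures (life table, natural-history
parameters, utilities, costs) so the whole pipeline runs offline; see the
methods vignette (`vignettes/prostasim-methods.Rmd`) for every assumption
and what the synthetic world does *not* claim about any real population.

## Worked example

```r
library(prostasim)

cfg  <- default_run_config(cohort_size = 2e4, master_seed = 1)
grid <- run_grid(cfg)          # 230 strategies on one shared cohort
summarize_grid(grid)
```

```
<ce_result> 230 strategies; 7 efficient, 223 dominated
  optimum at WTP 20 000 EUR/QALY: 53-69@2
# A tibble: 8 × 4
  strategy_id   net_cost qalys_gained   icer
  <chr>            <dbl>        <dbl>  <dbl>
1 .no_screening       0          0       NA
2 64@once         18551.         5.96  3111.
3 53-69@8         64522.        14.4   5444.
4 53-69@4        105984.        19.7   7797.
5 53-68@3        128284.        21.3  14417.
6 53-69@2        190613.        25.4  15040.
7 53-67@1        306009.        30.5  22735.
8 53-69@1        345714.        32.2  23240.
optimum 53-69@2: PCM reduction 16.6%, 89.4 LYG/1000,
  14.2% of screen-detected overdiagnosed, net cost 190613 EUR/1000
```

Reading this: each surviving row is an efficient strategy
(`"{start}-{last}@{interval}"`, singles `"{age}@once"`); `net_cost` and
`qalys_gained` are per 1000 men versus no screening, discounted at 3.5%;
`icer` is the incremental cost per QALY against the previous efficient row.
At this willingness-to-pay, biennial screening 53–69 is optimal in the
bundled synthetic world: a 16.6% prostate-cancer mortality reduction and
89.4 (undiscounted) life-years gained per 1000 men, with 14.2% of
screen-detected cancers overdiagnosed. Any single strategy row is
available too:

```r
grid$results |> dplyr::filter(strategy_id == "55-64@3")
#   invitations tests biopsies screen_detected overdiagnosed pcm_reduction_pct
#        3785.2 3024.2   320.7            13.8           1.7               8.6
#   life_years_gained qalys_gained net_cost
#                50.6         15.1  84072.4
```

`run_sensitivity(grid)` re-prices the same histories under high/low utility
variants and ±20% unit costs (counts and deaths cannot change, only the
frontier), `autoplot(grid)` draws the cost-effectiveness plane, and
`calibrate_incidence()` fits onset parameters to age-group incidence
targets. Because every random draw is a pure function of
`(master_seed, person_id, purpose)`, two runs with the same seed are
bit-identical, and a man's history can be regenerated alone.

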