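---
title: "Models and methods behind prostasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prostasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

prostasim is an individual-level (micro)simulation of prostate cancer
natural history with a PSA screening overlay and a cost-effectiveness layer.
This vignette is the package's account of its models: what is simulated, the
assumptions behind each component, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic inputs do and do
not represent.

## The natural-history model

Each simulated man enters the cohort alive and cancer-free at exact age 50
and is followed to death. Four processes unfold on a continuous age axis:

1. **Other-cause death.** A death age is drawn from a single-year life
   table, conditional on survival to 50, with uniform placement within the
   year of death. The bundled life table is a Gompertz–Makeham fixture
   (`make_life_table()`, hazard $a + b e^{ct}$ with defaults
   $a = 5\times10^{-4}$, $b = 3\times10^{-5}$, $c = 0.09$), chosen because
   three parameters give smooth, realistic adult mortality; it is synthetic
   and clearly labelled so.
2. **Onset.** A piecewise-constant hazard on 5-year age bands over
   [50, 90) — the same granularity as the calibration targets — with rate
   $\text{scale} \cdot r_k \cdot e^{\text{shape}(m_k - 60)}$ in the band with
   midpoint $m_k$. `scale` and `shape` are the calibration-facing free
   parameters. With the defaults the lifetime risk of a *clinical* diagnosis
   is near 10%.
3. **Preclinical progression.** Eighteen screen-detectable states — T stage
   (T1 < T2 < T3) × Gleason category (<7 < 7 < >7) × extent
   (local-regional < distant) — form an acyclic graph whose edges raise
   exactly one severity component at a time. The process is semi-Markov with
   exponential holding times: in each state, progression along each outgoing
   edge competes with clinical (symptomatic) detection, both
   exponential. Cancers begin mostly in (T1, <7, local-regional)
   (probability 0.8 by default; where cancers begin is not observable, so
   the onset-state distribution is fully configurable). A man can therefore
   visit at most six states; visited severity never decreases.
4. **Clinical pathway.** At clinical diagnosis a treatment (radical
   prostatectomy, radiation therapy, active surveillance, or none) is drawn
   from an age-band × stage × Gleason × extent policy table. Baseline
   time to prostate-cancer death is exponential by (Gleason, extent) —
   a deliberately closed-form choice so treatment and cure effects have
   exact oracles. Curative treatment of local-regional disease scales the
   hazard by 0.56; distant disease never benefits. Active-surveillance
   men switch to curative treatment with an exponential switch time
   calibrated so 30% switch within 7 years; switchers get the hazard ratio
   from the switch time onward. Realised death is the earlier of the
   prostate-cancer and other-cause death ages, with exactly one cause
   recorded.

Disease progression is simulated *latently*, past other-cause death: the
counterfactual clinical-diagnosis age is exactly what the overdiagnosis
definition needs, so it is kept alongside the censored, observed history.

### Common random numbers

Every draw is a pure function of `(master_seed, person_id, slot)` through a
counter-based generator (murmur3 finalizer). Consequences worth spelling
out:

* a person is bit-identical whether generated alone or inside any cohort;
* the screening overlay uses dedicated slots, so base histories are
  untouched and all 230 strategies are overlaid on the *same* men (paired
  design, large variance reduction on differences);
* screening draws are keyed by *age*, not by test sequence number, so a
  strategy whose test ages contain another's detects a superset of men —
  the monotonicity property the tests assert.

## The screening overlay

A strategy is a set of integer test ages (starts 50–55, intervals 1, 2, 3,
4, 8 years, last test by 69, plus single tests at 50–69; 230 strategies in
all). At each test age before the man's clinical diagnosis or death (strict
inequality: a test at exactly that age does not happen), four Bernoulli
gates apply in order: attendance (default 0.80, drawn independently per
invitation; a "never-attender" mode is available in which a fixed 20% of
men never attend), test positivity given the current preclinical state,
biopsy compliance (0.90) and biopsy sensitivity (0.90). The PSA cutoff of
3 ng/mL is represented through the state-specific positivity vector
(episode-sensitivity style) rather than a simulated PSA level, because no
PSA growth model is part of the design; the default positivity rises with
stage and extent (0.55 for T1 up to ~0.99 for distant T3). Screening stops
at the first detection.

A screen detection is **overdiagnosed** if the latent clinical diagnosis is
absent or falls at or after the man's other-cause death age. **Lead time**
is the latent clinical-diagnosis age minus the screen-detection age.
Relevant (non-overdiagnosed) cases are cured with probability
$c(L) = c_{\max}(1 - e^{-\beta L})$ of their lead time $L$ (defaults
$c_{\max} = 0.8$, $\beta = 0.2$); the functional form is a package design
choice — smooth, monotone, $c(0)=0$, two interpretable parameters — behind
a pluggable parameter list. Cured men die of other causes; non-cured men
die at their counterfactual clinical-pathway death age, so lead time in
itself buys no survival — its harms (overtreatment, quality of life,
costs) are what the economics layer prices. This also makes the mortality
reduction of any strategy nonnegative by construction.

Biopsy volumes are back-calculated, not simulated: screen detections divided
by a PPV of 0.227 and clinical detections divided by 0.358.

## Economics

QALY losses follow $\sum_i (1-u_i)\, d_i\, n_i$ over health states
(screening attendance, biopsy, diagnosis, treatment periods, post-treatment
periods, the 9-year postrecovery state at utility 0.95, palliative and
terminal illness). Conventions the formula itself does not fix:

* a state's duration is truncated at death (no loss beyond life);
* states overlapping in time add their losses (the formula is a sum);
* each state entry is discounted as a lump sum at its entry age, with the
  annual-compound factor $(1+r)^{-(a-50)}$, $r = 0.035$, reference age 50
  (cohort entry); life-years gained are discounted exactly, as the integral
  of the discount factor between the paired death ages;
* active-surveillance switchers are modelled as receiving radical
  prostatectomy (its cost and health states) at the switch time;
* palliative/advanced-disease costs and states attach to prostate-cancer
  deaths, ending at the death age.

Unit costs (invitation, PSA test, biopsy, RP, RT, AS, staging, follow-up,
advanced care) are discounted at the event age; costs after death are not
incurred. Every utility, duration and unit cost is a configurable table;
the bundled values are synthetic placeholders on realistic scales, except
where noted above.

The engine stores, per strategy and arm, the discounted truncated duration
sum per utility state and the discounted count per cost item. QALY losses
and costs are then *linear* in the utility and cost tables, which is what
makes the univariate sensitivity analysis (every utility at its high/low
variant, every unit cost ±20%) an exact re-pricing of the same simulated
histories — counts, detections and deaths provably cannot change.

## Cost-effectiveness analysis

Strategies are points (QALYs gained, net cost) per 1000 men relative to no
screening, anchored at (0, 0). Strongly dominated points (at least as
expensive and less effective, with one strict) are removed; then weakly
(extended-) dominated points are removed until ICERs strictly increase
along the cost-ordered list — equivalently, the upper-left convex hull.
Ties on identical points keep the lexicographically smallest strategy id;
collinear middle points are removed (strict monotonicity). The optimum is
the efficient strategy with the largest ICER at or below the
willingness-to-pay threshold (≤, which matters only when an ICER equals the
threshold exactly); if all ICERs exceed it, the answer is "no screening".
The test suite certifies the frontier against an independent
support-function oracle (a point is efficient iff it uniquely maximises
$\lambda\,\text{QALY} - \text{cost}$ for some $\lambda > 0$) on hundreds of
random instances.

## Calibration

`predict_incidence()` tabulates clinical incidence per 100,000 person-years
in 5-year bands 50–75 from an unscreened cohort (person-years are years
lived, to death from any cause). `calibrate_incidence()` minimises the
weighted squared relative error to target bands over up to three free
parameters (`onset_scale`, `onset_shape`, `clin_scale`), Nelder-Mead with a
logistic box transform (golden-section search when only one parameter is
free). Every objective evaluation simulates with the *same* seed, so the
objective is a deterministic function of the parameters and the whole fit
replays exactly. The loss is relative (scale-free across bands); for
parameter-recovery experiments the package weights bands by their
case-proportional share, the inverse-variance choice — a band's relative
sampling error scales as $1/\sqrt{\text{cases}}$, and equal weights let the
sparse youngest band dominate the noise in the age-slope parameter.

`validate_mortality()` lays predicted prostate-cancer mortality alongside
targets without fitting, as a validation-only comparison.

## What the synthetic inputs are — and are not

The synthetic_data layer (`make_life_table()`, `make_nh_fixture()`,
`make_calibration_targets()`, the default utility/cost/policy tables)
exists so that every pipeline stage runs and is testable with no downloads.
The fixtures are *internally consistent* and on realistic scales, but they
are not calibrated to any registry or trial: passing tests demonstrate that
the machinery is correct (oracles, identities, invariants, recovery of
known parameters), not that the headline numbers describe any real
population. Published microsimulation analyses of organised PSA screening
rest on parameter sets calibrated to registry incidence and trial data;
reproducing any such calibrated model's headline mortality-reduction or
overdiagnosis figures is deliberately out of scope here. Calibration targets carry a single
synthetic period — secular trends (changing background incidence over
calendar time) are out of scope, as is risk-stratified or MRI-based
screening, opportunistic testing outside the programme, and indirect costs.

Other simplifications worth knowing: no prevalent preclinical pool exists
at exactly age 50 (onset starts at cohort entry), so a test at 50 finds
little; treatment allocation probabilities and survival rates are shared by
RP and RT (one hazard ratio); and active-surveillance pre-switch survival
equals untreated baseline survival.

## Problem sizes and determinism

The package's own experiments use a 200,000-man default cohort
(`default_run_config()`), which keeps per-1000 outcome noise small while a
full 230-strategy run completes in a few minutes on one CPU; unit tests use
2,000–100,000 men depending on what they measure, and the calibration
recovery experiment uses a 50,000-man evaluation cohort against targets
simulated at 400,000. Two runs with the same `master_seed` are bit-identical
down to the stored economic components, on any machine, because no draw
depends on global RNG state, cohort size or iteration order.

```{r example}
library(prostasim)
cfg <- default_run_config(cohort_size = 2e4, master_seed = 1)
grid <- run_grid(cfg)
summarize_grid(grid)
autoplot(grid)
sens <- run_sensitivity(grid)
```
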