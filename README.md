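# safetysd

Deterministic system-dynamics simulation of how an enterprise safety
system drives (un)safe acts in coal mines, for safety-science researchers
and safety managers studying organisational behaviour control.

The model couples three layers — **safety culture** (SC), the **safety
management system** (SM: policy, organisational structure, procedures)
and individual **safety ability** (SA: knowledge, awareness, habits,
psychology) — into eleven stocks in [0, 1] whose flows are saturating
uptakes, first-order material delays (DELAY1) and a negative behavioural
feedback from the safe-acts level UA:

- element uptake: (1 − 2^(−S/80)) · 2^(−t/6), with S = Σ wᵢ·AVᵢ the
  weighted construction standard (AV ∈ [0, 100]) of the feeding elements;
- layer uptake: 1.5 · (1 − 2^(−up/2)) · (1 − 2^(−W/n)) · 2^(−self),
  delayed by 0.25 months;
- behavioural feedback: 1 − 2^(−UA/4), delayed by 1 / 0.5 / 0.25 months
  into SC / SM / SA;
- acts uptake: (1 − 2^(−SA/2)) · 2^(−UA).

Integration is explicit Euler (default 96 steps of 0.25 months over a
24-month horizon) with per-step clamping to [0, 1]. Layer weights are the
cause proportions of an 84-accident coal-and-gas-outburst analysis; a
seeded Poisson–multinomial generator emulates such cause tallies and
`estimate_weights()` recovers proportions from them. Scenario tools run
new-mine (HV = 0) and production-mine (HV = 0.25–0.75) experiments over
AV/HV grids and rank layer and element influence. The methods vignette
(`vignettes/safety-system-dynamics.Rmd`) documents the model, how
ambiguities in the published equation list are resolved (option flags
`sm1`, `sa_damping`, `ua_outflow`, `delay_init`), and which published
orderings the reconstruction does and does not reproduce.

## Worked example

```r
library(safetysd)

# a newly opened mine (HV = 0) built to standard AV = 80
traj <- run_model(model_parameters(av = 80, hv = 0))
summarize_trajectory(traj)[c(1, 2, 6, 11), ]
#>    stock peak_value peak_time trough_time final_value
#> 1     SC  1.0000000      2.25        24.0   0.9244413
#> 2     SM  0.7030292     17.25        24.0   0.6738010
#> 6     SA  0.1161958     12.25        19.5   0.0000000
#> 11    UA  0.3470711     19.50          NA   0.3470711

all(diff(traj$UA) >= 0)   # safe acts keep rising in a new mine
#> [1] TRUE

# which ability element matters most in a production mine (HV = 25%),
# raising its construction standard from 60 to 80?
element_influence_experiment("h", hv = 0.25, baseline_av = 60,
                             raised_av = 80)
#>              factor       effect rank
#> 1  safety knowledge 1.603305e-04    1
#> 2     safety habits 5.819503e-05    2
#> 3 safety psychology 5.819503e-05    3
#> 4  safety awareness 2.912039e-05    4
```

The summary says: culture saturates within ~2 months and stays near its
ceiling, the management system peaks at month 17.25, ability peaks at
month 12.25 and is then eroded by the behavioural feedback, and the
safe-acts level rises monotonically to 0.347. The ranking says raising
knowledge standards moves the ability level most (habits and psychology
tie exactly; awareness is weakest).

A command-line wrapper is installed at `inst/cli/safetysd.R`:

```sh
Rscript inst/cli/safetysd.R simulate --hv 0 --av 80 --out out/
Rscript inst/cli/safetysd.R synth --n 84 --seed 1 --out out/
```

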