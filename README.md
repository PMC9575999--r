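# wbvitals

Demographic inference for a seasonally migratory ungulate population —
an individual-based blue wildebeest study system — from three observation
streams: known-fate survival of radio-collared adult cows, herd-composition
counts, and imperfect calf-detection histories.

## The model

Mortality risk at age *a* follows the five-parameter Siler
competing-hazard curve,

    h0(a) = a1·exp(−b1·a) + a2 + a3·exp(b3·a),

modified proportionally by season, location along the migratory axis, and
year:

    h(a, t) = h0(a) · exp(βS·I_wet(t) + βL·x(t) + β_Y(t)).

Three likelihoods share this hazard: an interval-censored, left-truncated
known-fate likelihood for collared cows; a binomial likelihood for the
calf fraction among classified animals in herd counts, with expected
fraction r/(1+r), r = f·S_c(t); and a hidden-state forward recursion for
calf detections over {no-calf, present, dead, dissociated} with detection
probabilities p (true) and q (false) and a dissociation hazard
γ_D·(a − 0.75) past age 0.75. Parameters are estimated by adaptive
random-walk Metropolis in a sequence of stages whose posteriors become
the priors of later stages. Derived outputs are longevity (age reached by
0.1% of females), life expectancy (the integral of survivorship),
evidence ratios ER = Pr/(1−Pr) with LER = log10(ER), interannual hazard
ratios maxR = exp(range(ln h)) and meanR = exp(MAD(ln h)), and a biannual
51-class female Leslie projection whose annual growth rate λ checks
vital-rate self-consistency.

A synthetic-data generator (`sim_scenario()`, `simulate_observation_set()`)
reproduces the study's observation structure with known true parameters,
so every stage is testable without field data. The package ships as an
analysis workflow: numbered scripts under `analysis/` drive the package
functions and write tables under `results/`.

## Worked example

Simulate an 8-year study at the default conditions (45 collared cows plus
annual top-ups, ~60 herd counts/yr, biweekly sightings; fecundity 0.68,
wet-season hazard ratio 1.27, detection p = 0.89 / q = 0.02, baseline
curve through annual survival 0.91 at age 2 and 0.57 at age 10 with
first-year survivorship 0.56), then fit and project:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit.R
Rscript analysis/03_project.R
Rscript analysis/04_summarize.R
```

The run used for this example printed (seed 20260926):

```
== calf-detection model ==
  parameter      ev   lower   upper
          f  0.6946  0.6203  0.7585
          p  0.9008  0.8879  0.9107
          q  0.0183  0.0137  0.0239

== estimates vs generating values ==
            quantity    ev lower upper truth covered
           fecundity 0.690 0.532 0.951 0.680    TRUE
 first_year_survival 0.557 0.392 0.699 0.518    TRUE
    recruitment_to_1 0.369 0.344 0.396 0.352    TRUE
    recruitment_to_2 0.308 0.244 0.372 0.311    TRUE

point-rate projection: lambda = 0.970
posterior lambda: EV 0.943, 90.9% HPD (0.901, 0.985)
```

Reading it: the calf-detection stage recovers fecundity and both
detection probabilities tightly (it observes cows right after the birth
pulse); the herd-count stage pins the *product* f·S₁ (recruitment, 0.369
against a generating 0.352) far more tightly than either factor — counts
near calving are excluded, so fecundity and early calf survival are only
weakly separable there and their intervals are honestly wide; and the
Leslie projection built from the estimated rates yields a near-stable
growth rate, as it should when the rates are internally consistent.
Intervals are 90.9% (= 10/11) highest-posterior-density intervals, the
level at which the evidence ratio is 10.

The quick one-liner versions of the core quantities:

```r
library(wbvitals)
p <- siler_from_anchors()        # curve through the survival anchors
life_expectancy(p)               # 3.667 yr
longevity(p)                     # 13.93 yr (age reached by 0.1%)
project(build_transition(p, f = 0.68, S1 = 0.56))$lambda   # 0.970
```

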