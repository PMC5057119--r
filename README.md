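# nephrogrowth

Growth estimation for Norway lobster (*Nephrops norvegicus*) — and stepped
growers like it — from tag-recapture increments and catch length
frequencies.

*N. norvegicus* supports one of the most valuable demersal fisheries in the
Northeast Atlantic, but individuals cannot be aged and grow only at moult,
so the von Bertalanffy growth function (VBGF) parameters that assessments
need, the asymptotic carapace length `L∞` and growth constant `k`, have to
be pieced together indirectly. This package implements the two-source
workflow used for inshore tagging studies, keeping the two parameters
deliberately decoupled:

* **Powell–Wetherall plot** for `L∞`: regress `(mean length above cutoff −
  cutoff)` on the cutoff over fully recruited sizes; under steady state
  with constant recruitment and exponential mortality `Z`, the
  Beverton–Holt relation `L̄ = (Z·L′ + k·L∞)/(Z + k)` makes the plot
  linear, with `L∞ = −a/b` and `Z/k = −(1 + b)/b`.
* **Forced Gulland–Holt plot** for `k`: each recaptured tag gives an
  annualised rate `ΔL/(Δt/365.25)` at mean length `L̄ = (L1 + L2)/2`; with
  `L∞` fixed from the previous step, `k̂ = Σ rᵢ(L∞ − L̄ᵢ) / Σ (L∞ − L̄ᵢ)²`
  (least squares through the point `(L∞, 0)`), optionally pooling
  recapture years.

Around the estimators: audited filtering of unusable recaptures,
size-class increment and weight tables, moult-frequency classification of
increment distributions (single vs double moulters), captive moult
detection (sustained > 0.5 mm rule), wild/captive and size-vs-growth
comparisons, CL→TL and CL→weight conversions, CSV/YAML I/O, and an
individual-based simulator of stepped (moult-wise) growth with seasonal
moult timing and steady-state catch sampling, so the whole pipeline is
testable end to end without field data. See the methods vignette
(`vignettes/nephrops-growth.Rmd`) for the model, the generator's design
and its limits.

## Worked example

Simulate a tagging campaign under the default study conditions, filter it,
and estimate both parameters for females:

```r
library(nephrogrowth)

cfg   <- sim_config(seed = 42)              # defaults = the study conditions
tags  <- simulate_tag_recapture(cfg, 500)
flt   <- filter_increments(increment_records(tags))
flt
#> Increment filter: 473 kept, 27 dropped
#>   non-positive growth    27

catch <- simulate_catch_sample(cfg, 20000)
pw    <- powell_wetherall(catch$cl_mm[catch$sex == "F"], recruit_length = 38)
pw
#> Powell-Wetherall fit
#>   points: 9 (cutoffs 38.0-54.0 mm)
#>   a = 22.493 mm, b = -0.4074, R^2 = 1.000
#>   L_inf = 55.22 mm, Z/k = 1.455

forced_gulland_holt(flt$kept[flt$kept$sex == "F", ], pw$l_inf_hat)
#> Forced Gulland-Holt fit
#>   L_inf fixed at 55.2 mm;  n = 208
#>   k = 0.0605 per year;  residual sd 0.447 mm/yr
```

Reading the numbers: the 27 dropped records are animals recaptured before
their first moult (the zero-growth class the method excludes); the catch
sample reproduces its generative `L∞` of 55.2 mm essentially exactly; and
the `k` estimate of 0.0605/yr sits below the generative 0.077/yr because
under realistic seasonal moulting the last moult precedes recapture, a
structural bias of the forced Gulland–Holt method on stepped growers that
the vignette quantifies. `recovery_sim_config()` gives the
moult-synchronised regime in which the estimator is consistent and both
parameters are recovered within a few percent.

The reference size-class tables from the tagging study ship with the
package:

```r
t1 <- nephrops_increment_table(1)                    # year-1 liberty (~344 d)
m  <- t1[t1$sex == "M", ]
overall_mean_from_classes(m$n, m$mean_dcl)           # 5.053535 -> prints 5.1
sum(t1$n * t1$mean_dw) / 1000                        # 2.0922 kg total gain
```

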