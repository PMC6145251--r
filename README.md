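# kinextract

Empirical kinetic modelling of solid–liquid extraction. The motivating
system is the extraction of anthocyanin pigment from dried jambolan
(*Syzygium cumini*) fruit granules into acidified ethanol at 35 °C, run at
four agitation frequencies (0, 50, 100, 150 rpm) of an orbital shaker —
but the machinery applies to any time–concentration extraction series.

## What it computes

The solvent-phase concentration is modelled as
`X(t) = X_eq · [1 − f(t, a, b)]`, where `f` is one of five empirical decay
functions for the dimensionless concentration
`X* = (X − X_eq)/(X_i − X_eq)`:

| model | `f(t, a, b)` |
|---|---|
| Lewis | `exp(−a t)` |
| Henderson–Pabis | `a · exp(−b t)` |
| Peleg | `1 − t/(a + b t)` |
| Page | `exp(−a t^b)` |
| Silva | `exp(−a t − b √t)` |

Every model has closed-form forward, derivative and inverse-time
expressions, so a fitted curve directly yields:

* the **extraction rate** `dX/dt = −X_eq · df/dt` (analytic, no numerical
  differentiation);
* the **process time** to reach a target fraction of equilibrium, e.g. the
  Page inverse `t = (−ln X*/a)^(1/b)` at `X* = 0.03` for 97% of
  equilibrium;
* the **percent extracted** at any comparison time, `100 · (1 − f(t))`.

Models are fitted by bounded Levenberg–Marquardt least squares in
concentration space (`minpack.lm`), with the equilibrium concentration
estimated from the tail of the fastest experiment, and ranked by
chi-square (unweighted residual sum of squares) with R² and parsimony
tie-breaks.

## Worked example

```r
library(kinextract)

# four-condition synthetic panel: Page-model truth with the bundled
# reference parameters, shared X_eq = 13.1 mg/100 g, sigma = 0.3
panel <- jambolan_panel(seed = 1)
res <- run_pipeline(run_config(panel, x_eq_mode = "tail"), quiet = TRUE)
res$ranking[res$ranking$rank == 1, c("condition", "model", "r_squared", "chi_square")]
```

```
 condition model r_squared chi_square
     0 rpm peleg    0.9962      1.282
   100 rpm  page    0.9959      1.186
   150 rpm  page    0.9924      1.673
    50 rpm  page    0.9942      2.152
```

At realistic noise the Page truth wins three of four conditions outright
(Peleg edges it narrowly at 0 rpm — the two families are hard to separate
on a still-rising series). The equilibrium recovered from the 150 rpm tail
is 13.26 mg/100 g against a true 13.1.

The headline predictions from the bundled reference Page parameters:

```r
reference_report()
```

```
                quantity condition    value value_rounded reference pass
       time_to_97pct_min     0 rpm 158.9842         159.0     159.0 TRUE
       time_to_97pct_min    50 rpm  87.9877          88.0      88.0 TRUE
       time_to_97pct_min   100 rpm  66.2606          66.0      66.0 TRUE
       time_to_97pct_min   150 rpm  27.9450          28.0      28.0 TRUE
 percent_extracted_28min     0 rpm  56.2607          56.3      56.3 TRUE
 percent_extracted_28min    50 rpm  71.2745          71.3      71.3 TRUE
 percent_extracted_28min   100 rpm  83.9881          84.0      84.0 TRUE
 percent_extracted_28min   150 rpm  97.0151          97.0      97.0 TRUE
all comparisons pass
```

Reading: without agitation the process takes ~159 min to reach 97% of
equilibrium; at 150 rpm it takes ~28 min — roughly six times faster — and
at that 28-min mark the slower conditions have only extracted 56–84% of
the equilibrium concentration.

A thin command-line wrapper with `fit`, `simulate`, `predict` and
`reference` subcommands lives at `inst/cli/kinextract.R`.

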