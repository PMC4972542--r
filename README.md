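# adlisim

Firing-rate simulations of the olfactory bulb's two parallel output
pathways — mitral cells (MCs) and tufted cells (TCs) — under
**activity-dependent lateral inhibition (ADLI)**, with everything needed to
ask the question the package exists for: *which pathway discriminates
similar odors better, and at which odor concentrations?*

The package is for computational neuroscientists and olfaction researchers
who want a fully synthetic, fully reproducible version of this analysis:
no recordings or deposited data are required; odor panels, network
responses, and the companion electrophysiology/morphology fixtures are all
generated in code from a single seed.

## The model in brief

Odors are activation patterns on a 15 × 10 grid of glomeruli. Each unit
(one MC or TC per glomerulus) follows

    tau dv/dt = f(I_trial) - g_l (v - E_l) - inhib(v, u)

where `f` is a logistic input sigmoid saturating at 100 Hz (TC: slope
0.01, midpoint 350; MC: 0.007, 500) and lateral inhibition from the
randomly connected presynaptic pool `u = sum of connected rates` is gated
by the postsynaptic rate:

    inhib_adli = g_i * u * exp(-(v - mu)^2 / sigma)

with the TC gate at `mu = 10 Hz` (`sigma = 350 Hz^2`) and the MC gate at
`mu = 50 Hz` (`sigma = 500 Hz^2`) — inhibition hits TCs firing at low
rates and MCs at intermediate rates. Subtractive (`g_i u`), divisive
(`g_i v`) and no-inhibition controls are built in, as are dual-output
networks with two cells per glomerulus (MC-MC, TC-TC, MC-TC). Odor
identity is decoded from steady-state population rates with a linear
classifier on a stratified half split; panel-level accuracies feed a
one-way ANOVA (Bonferroni-corrected over concentrations) with Welch
post-hoc t-tests.

Companion modules implement the associated measurement statistics on
synthetic fixtures with known ground truth: IPSC detection (3 s.d. for
>10 ms within 500 ms post-stimulus), early/late charge transfer, the
effective activity range of lateral inhibition from paired FI curves
(>10% decrease on ≥2 consecutive steps), and granule-cell morphology
clustering (Ward linkage on normalized gemmule depth histograms, gap
statistic for the cluster count, plus the superficial/deep EPL depth
rule).

## Worked example

An 8-odor discrimination experiment at 30% and 60% of maximum
concentration, four panels per cell, comparing TC, MC and uninhibited
populations:

```r
library(adlisim)

spec <- sweep_spec(
  n_odors = 8, concentrations = c(30, 60), n_panels = 4, n_trials = 500,
  configurations = c("TC", "MC", "none"), seed = 7,
  sigmoid_mode = "type", classifier = "lda"
)
result <- run_sweep(spec)
summary(result)
#>   configuration concentration n mean_accuracy        sem frac_converged
#> 1            MC            30 4     0.8234127 0.04721778              1
#> 2            MC            60 4     0.9424603 0.03569591              1
#> 3          none            30 4     0.8363095 0.04102795              1
#> 4          none            60 4     0.9484127 0.02676734              1
#> 5            TC            30 4     0.8293651 0.04427761              1
#> 6            TC            60 4     0.9503968 0.02501889              1
significance(result)
#>   concentration   p_anova p_adj significant best best_significant max_p_posthoc note
#> 1            30 0.9789926     1       FALSE none            FALSE            NA
#> 2            60 0.9806729     1       FALSE   TC            FALSE            NA
```

Each row of `summary(result)` is one (configuration × concentration) cell:
the mean half-split decoding accuracy over panels, its s.e.m., and the
fraction of trial blocks whose integration converged. With only 8 odors
the task is easy and the three configurations are statistically
indistinguishable (`significant = FALSE` at both concentrations) — the
pathway differences only emerge on harder, 32-odor panels, where the TC
network wins at low concentration and the MC network at high
concentration, and mixed MC-TC populations beat either homogeneous
network on average. Those are the headline experiments reproduced by the
acceptance script and by `tests/testthat/test-acceptance.R`.

A command-line front end wraps the same machinery:

```sh
exec/adlisim sweep --odors 32 --concentrations 30,60 --panels 20 \
    --configs TC,MC,none --classifier lda --seed 1 --outdir results/
```

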