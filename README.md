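# cavistress

Tools for linking xylem cavitation to lethal leaf dehydration during
drought. The package re-implements, as a tested and reusable pipeline, an
analysis of whole-plant drydown experiments on *Eucalyptus viminalis*
saplings in which time-lapse optical imaging of leaves (the optical
vulnerability technique, OVT), psychrometer water-potential records,
chlorophyll fluorescence (Fv/Fm) and leaf-width shrinkage are combined to
ask *what kills the leaf*: turgor loss, stem cavitation, cavitation of the
high-order veins (HOV), or runaway hydraulic failure.

It is aimed at plant hydraulics researchers who want to (a) compute
runaway-cavitation thresholds from vulnerability-curve parameters, (b)
quantify cavitation events by vein order in OVT image stacks, (c) estimate
breakpoints, P-levels, turgor loss points, minimum conductance and
rehydration-kinetics conductance from bench data, and (d) test the whole
chain end to end on synthetic data with known ground truth.

## The model at the core

Leaf hydraulic conductance declines sigmoidally with water potential
&Psi;:

    K(psi) = Kmax / (1 + exp((P50 - psi) / alpha)),   alpha > 0

so that `K(P50) = Kmax/2`. With cuticular transpiration
`Ec = gmin * VPD / Patm` as the demand after stomatal closure, the
steady-state supply through the cavitating pathway,
`S(psi_leaf) = K(psi_leaf) * (psi_source - psi_leaf)`, has a peak; runaway
cavitation begins when that peak falls below `Ec`, which happens at the
closed-form leaf water potential

    psi_runaway = P50 - alpha * ln(alpha * Kmax / Ec)

with percent loss of conductance `PLC = 100 x / (1 + x)`,
`x = alpha * Kmax / Ec`. The package provides this closed form, an
independent numerical supply-demand oracle, and a capacitance-based ODE
drydown simulator that exhibits the runaway feedback dynamically.

Around this core sit the OVT quantification (difference imaging,
connected-component event detection, vein-order assignment, cumulative
cavitation curves, per-segment event counts, leaf-width measurement,
functional-HOV-area mapping), the estimators (two-segment Muggeo-style
breakpoint regression, cumulative-sigmoid fitting and P-level extraction,
4-parameter K_leaf rehydration sigmoid, gmin from mass traces, PV-curve
turgor loss point), and a seeded synthetic-data generator for every input.

## Worked example

```r
library(cavistress)

vc <- vuln_curve(kmax = 5.77, p50 = -3.73, alpha = 0.09)
ec <- cuticular_transpiration(gmin = 10.02, vpd_kpa = 1.94,
                              patm_kpa = 101.3)
round(ec, 2)
#> [1] 0.19

runaway_point(vc, ec = 0.19)
#> Runaway cavitation point (closed-form)
#>   psi_runaway: -3.8205 MPa
#>   PLC at runaway: 73.21 %
#>   K at runaway: 1.5456 mmol s-1 m-2 MPa-1
```

A leaf at these parameters loses its steady state at -3.82 MPa: beyond
that, cuticular demand exceeds the best the cavitating xylem can supply
and dehydration becomes self-amplifying. The dynamic simulator reaches
the same point:

```r
sim <- simulate_drydown_ode(vc, ec = 0.19)   # -0.5 to -6 MPa over 5 days
sim$psi_leaf_onset
#> [1] -3.803196
```

A full synthetic experiment — 13 leaves with procedural vein networks,
per-order cavitation schedules, fluorescence and width series, stem event
streams, gmin/PV/rehydration traces — runs through every estimator with:

```r
run <- run_pipeline(pipeline_config(seed = 1))
run$comparison$thresholds_mpa
#>  BP_width   BP_fvfm   P20_hov       TLP   runaway  P88_stem
#> -3.818906 -3.820030 -3.798532 -2.053118 -3.821442 -5.444241
```

The three damage thresholds (width breakpoint, Fv/Fm breakpoint, 20% HOV
cavitation) coincide within ~0.03 MPa on bundles generated with coupled
thresholds — the signature the analysis is built to detect — while turgor
loss (-2.05) and 88% stem cavitation (-5.44) fall far from the damage
point.

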