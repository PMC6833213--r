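# coursense

Biomass concentration is the central state variable of a fed-batch
cultivation, but it cannot be measured online: dry cell weight (DCW) comes
from sparse manual sampling, hours apart. What *is* available continuously —
from any ordinary off-gas analyzer — is the oxygen uptake rate (OUR).
`coursense` implements a culture-invariant soft sensor that estimates the
full biomass trajectory of aerobic fed-batch cultures (demonstrated for
recombinant *E. coli* and *S. cerevisiae*) from the **cumulative** oxygen
uptake rate (cOUR) alone, with no bioreactor-specific parameters, no feed
profile, and no iterative numerical optimisation.

## The model

Oxygen consumption follows a Luedeking–Piret balance,

    OUR(t) = α·X′(t) + β·X(t)

where `α` (g O₂ per g DCW) is the specific oxygen yield for growth and `β`
(1/h-scale) the maintenance coefficient, which also absorbs product
formation after induction. Integrating from inoculation gives the working
form `cOUR(t) = α·(X(t) − X₀) + ∫ β X dt`.

**Stage A (offline, once per strain).** During fitting, `β` is modelled as
time-linear with an activation time `tᵢ`: `β(t) = k₁·(t − tᵢ)` and zero
before `tᵢ` (IPTG injection for *E. coli*; inferred for yeast). Parameters
are found by maximising the entropy criterion

    S = − Σₘ wₘ · (cOURₘ − predₘ)² ,   wₘ = (K_exp·Xₘ² + 1 − K_exp) / Xₘ²

over the offline samples, with Monod-form uncertainty weighting: `K_exp = 1`
is ordinary least squares, `K_exp = 0` weights squared percentage errors
(default `K_exp = 0.4`). `S` is quadratic in `(α, k₁)`, so the maximiser is
a closed-form 2×2 linear solve; `tᵢ` is found by exhaustive criterion search
over a candidate grid. The recovered maintenance values
`β(tₘ) = k₁·(tₘ − tᵢ)` are then regressed against biomass,
`β(X) = k_β₂X² + k_β₁X + k_β₀`, and the activation threshold `X_specific`
(the biomass above which maintenance matters) is the root of `β(X) = 0`.
For the published strains: `X_specific = 6.29` g/l (*S. cerevisiae*, linear)
and `20.6` g/l (*E. coli*, quadratic, stationary-point fallback).

**Stage B (online).** Below `X_specific` the estimator is the affine map
`Xₘ = cOURₘ/α + X₀`; above it the accumulated maintenance oxygen
`Σ β(Xₗ)·Xₗ·Δt` (previous-point rule, each point computed once) is
subtracted from cOUR first. Each update costs O(1) — suitable for 1-min
online data.

A synthetic fed-batch simulator (two-phase growth with post-induction
deceleration, multiplicative observation noise) makes every stage testable
without experimental data, and MAE/MAPE/RMSE report accuracy over the
windows since inoculation and since feed start.

## Worked example

```r
library(coursense)

# a synthetic E. coli-type culture: alpha = 1.01, k1 = 4e-3, induction 10 h,
# 2% cOUR noise, 5% DCW noise
cfg <- simulationConfig(betaMode = "time", ourNoiseCv = 0.02,
                        dcwNoiseCv = 0.05, seed = 11)
ex  <- addNoise(simulateStageAExperiment(cfg), seed = 11)
ds  <- ex@offlineDataset
ds@inductionTime <- 10          # known IPTG injection time

fitStrain(list(offline = ds, our = ex@observedOurSeries), kExp = 0.4,
          strainLabel = "synthetic E. coli-type")
#> StageAFit over 1 experiment(s)
#> StrainParameters 'synthetic E. coli-type': alpha = 1.008 g O2/g DCW,
#>   k1 = 0.003944, tI = 10 h, kExp = 0.4
#> MaintenanceModel (degree 1): beta(X) = 0 X^2 + 0.0010731 X + -0.0045797
#>   X_specific = 4.268 g/l
#>   flags: degree-2 beta(X) fit concave or without positive activation root;
#>   downgraded to degree 1
```

The growth yield comes back within 0.2% of the generating value and the
maintenance slope within 1.5%, from 20 noisy offline samples. Online
estimation then needs only the cOUR stream:

```r
ex2  <- addNoise(simulateCulture(simulationConfig(seed = 11)), seed = 11)
traj <- estimateTrajectory(strainPreset("ecoli"), ex2@observedOurSeries,
                           x0 = 0.2)
traj
#> BiomassTrajectory: 1201 points, X = 0.2 -> 41.02 g/l, 341 in maintenance regime
evaluateEstimation(traj, ex2@offlineDataset, feedStart = 5)[c(1, 3)]
#> $maeSinceInoculation
#> [1] 0.5674043
#> $mapeSinceInoculation
#> [1] 4.270846
```

0.57 g/l mean absolute error against the (noisy) offline samples over a
culture growing to 41 g/l — comparable accuracy to dedicated hybrid-model
estimators, from a single off-gas signal.

The same pipeline is scriptable from a shell via
`inst/scripts/coursense {simulate|fit|estimate|evaluate}`.

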