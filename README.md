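# signoise

Exact stochastic simulation of the reversible-binding reactions at the
heart of cellular signaling, and information-theoretic analysis of what
those reactions can tell a cell about its environment.

## The problem

A signaling pathway detects a stimulus through reversible binding: a
ligand `S` to a receptor `R`, a receptor–ligand complex to DNA, a
transcription factor to a promoter driving gene expression.  Binding and
unbinding are single-molecule events, so the pathway's response to a
fixed stimulus is a *distribution* of output counts, not a number.  For
`n` equiprobable signal levels and an output species `O`, this package
quantifies:

* **information** — the mutual information
  `I(S;O) = H(Pr(S)) − H(Pr(S|O))` in bits, bounded by `log2 n`;
* **noise** — the Fano factor `σ²/μ` of each conditional response
  distribution `Pr(N_O | S = N_S)`, averaged over the `n` levels;
* **output range** — the spread `max_s μ(O|s) − min_s μ(O|s)` of the
  conditional means.

Sweeping the equilibrium constant `K_eq = k_d/k_a` (molar; smaller =
stronger affinity) shows the three-regime structure these quantities
share: at weak affinity the output is empty and noisy, at strong
affinity it is saturated and quiet, and only in between — where
occupancy *fluctuates*, i.e. where the dynamics is noisy — does the
output range open up and information flow.  Noise is not merely
tolerated at the information optimum; the kinetics that produce a
usable output range necessarily produce non-minimal noise.

The package implements five model variants (reversible binding; a
two-step binding cascade onto DNA; TF-regulated gene expression; gene
expression with an explicit polymerase whose copy number is redrawn per
replicate — extrinsic noise; and a complete linear pathway), an exact
Gillespie (direct-method) simulator with a compiled inner loop, the
metric estimators, sweep orchestration, and a closed-form stationary
distribution of the binding birth–death chain that serves as an
analytic oracle for the simulator.

## A worked example

Ten receptors (`1e-8` M), signal up to 1000 molecules (`1e-6` M), eight
signal levels, 500 replicate simulations per level, affinity swept one
point per decade:

```r
library(signoise)
sw <- affinitySweep(bindingModel(), keqGrid = 10^-(5:9), nLevels = 8,
                    replicates = 500, seed = 1)
sweepTable(sw)[, c("Keq", "information", "noise", "outputRange",
                   "informationNorm", "noiseNorm")]
#>     Keq information  noise outputRange informationNorm noiseNorm
#> 1 1e-05     0.10862 0.9655       0.764          0.2516   1.00000
#> 2 1e-06     0.43168 0.6467       3.852          1.0000   0.66978
#> 3 1e-07     0.40605 0.1975       3.566          0.9406   0.20451
#> 4 1e-08     0.11718 0.0253       0.754          0.2715   0.02625
#> 5 1e-09     0.00712 0.0024       0.044          0.0165   0.00249

findOptimum(sw)  # optimum: Keq = 1e-06 M, I = 0.432 bits, noiseNorm = 0.67
```

Reading the table: at `1e-5` M the receptors are almost always empty —
noise (Fano ≈ 0.97) is maximal but the output range (0.76 complexes) is
negligible, so information ≈ 0.1 bits.  At `1e-9` M the receptors are
saturated — noise and range both collapse and information vanishes.
Information peaks in between (0.43 bits at `1e-6` M), where the
normalized noise sits at 0.67 — near half its maximum, not near zero.
The same structure can be computed without any sampling from the exact
stationary distributions via `exactBindingMetrics()`.

Sweeps can also be driven from a YAML configuration, from R
(`runSweepConfig("config.yaml", outDir = "out")`) or from a shell via
the wrapper in `inst/scripts/run_sweep.R`; see
`inst/extdata/binding_sweep.yaml` for an example.

## Package layout

* `R/` — S4 classes (`ReactionSystem`, `PathwayModel`,
  `ResponseEnsemble`, `SweepResult`), model constructors, simulator
  front end, metric estimators, sweep orchestration, analytic oracle.
* `src/ssa.cpp` — the Gillespie direct-method inner loop (uses R's RNG,
  so `set.seed()` governs everything).
* `vignettes/noise-and-information.Rmd` — the methods vignette: model
  definitions, propensity forms, unit conventions and volumes, default
  parameters and their rationale, estimator choices, limitations.
* `tests/testthat/` — unit, property and end-to-end tests, including
  simulator-vs-oracle convergence.
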