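# opvar

Ordinal-pattern analysis of univariate signals in which the entropy of the
pattern sequence is complemented by the magnitude information the ordinal
encoding normally throws away.

## The problem

Bandt–Pompe ordinal-pattern (OP) analysis turns a signal
`{x_t}, t = 1..T` into a sequence of symbols: the signal is split into
quasi-non-overlapping windows of `D` samples spaced `τ` apart (consecutive
windows share exactly one sample), and each window is mapped to one of the
`D!` possible orderings of its components. The entropy of the resulting
symbol distribution `P(α)` is a robust, nearly assumption-free measure of
signal unpredictability — but it discards the magnitudes entirely, so
signals with very different amplitude structure can look identical.

`opvar` computes, alongside the permutation entropy

    H = − Σ_α P(α) log₂ P(α)          (bits)

and the Rényi min-entropy

    H∞ = − log₂ max_α P(α)            (bits),

the **pattern-averaged magnitude variability**

    ⟨log₂ σ_j⟩ = Σ_α P(α) log₂ σ_j(α),
    avg_j{⟨log₂ σ_j⟩} = (1/D) Σ_j ⟨log₂ σ_j⟩,

where `σ_j(α)` is the standard deviation (optionally the inter-quartile
range) of the signal magnitudes at the `j`-th window component over all
windows carrying symbol `α`. The pair `(avg_j{⟨log₂ σ_j⟩}, H∞)` places a
signal in an entropy–variability plane where dynamical regimes that share
one coordinate often separate cleanly along the other — chaotic map
regimes with nearly equal entropies, or sleep–wake EEG states with
similar spectral content.

The package also ships the validation tooling for this statistic on known
dynamics: simulators for coupled identical logistic maps
(`x_{t+1} = (1−ε) f(x_t) + ε f(y_t)`, `f(z) = r z (1−z)`) and the Hénon
map (`x_{t+1} = 1 − a x_t² + y_t`, `y_{t+1} = b x_t`), observational
(additive Gaussian) noise, maximum-Lyapunov-exponent estimation by both
the analytic-Jacobian (Benettin) iteration and Wolf's nearest-neighbour
divergence tracking, and a scaling sweep of `avg_j{⟨log₂ σ_j⟩}` over
embedding dimensions whose fitted power-law slope separates
deterministic-like from noise-like signals (reference slopes ≈ −2 and
−1/2 respectively).

## Worked example

```r
library(opvar)

tr <- simulate_coupled_logistic(r = 3.8, eps = 0.01)  # T = 1e6, transient 1e3
s  <- op_summary(tr$x, D = 4)
s
#> ordinal-pattern summary (T = 1000000, D = 4, tau = 1, m = 333333)
#>   H      = 2.7467 bits (max 4.5850)
#>   H_inf  = 2.0531 bits
#>   avg_j{<log2 sigma_j>} = -4.2289 (sd estimator)

mle_wolf(tr)
#> maximum Lyapunov exponent: 0.4323 nats/iteration (wolf method, 999990 steps)
```

The 10⁶-sample trajectory yields 333,333 windows of 4 samples. Its
min-entropy, 2.05 of the attainable log₂ 4! ≈ 4.58 bits, says the most
common ordering still appears in about 2⁻²·⁰⁵ ≈ 24% of windows — strongly
structured chaos — and the magnitude variability says the typical
amplitude spread inside a given pattern is 2⁻⁴·²³ ≈ 0.05 in the map's
[0, 1] units. The positive Lyapunov exponent (≈ 0.43 nats/iteration,
matching the Benettin value from the exact Jacobian) confirms the regime
is chaotic.

Noise discrimination via the variability scaling:

```r
x <- simulate_henon(1.15, 0.3)$x
curves <- scaling_sweep(x, D_values = 3:8, noise_sd = c(0, 1), seed = 7)
curves[["0"]]
#> variability scaling curve (noise sd 0): slope -1.724 over D in {3, 4, 5, 6, 7, 8}
curves[["1"]]
#> variability scaling curve (noise sd 1): slope -0.512 over D in {3, 4, 5, 6, 7, 8}
classify_regime(curves[["1"]])$regime
#> [1] "noise-like"
```

The noiseless chaotic map decays steeply (slope −1.72, toward the −2
reference); once unit-variance observational noise dominates, the decay
flattens to the −1/2 order-statistics reference.

A command-line wrapper over these functions is installed at
`system.file("cli", "opvar.R", package = "opvar")`, with subcommands
`simulate`, `analyze`, `lyapunov`, and `scaling`; see the header of that
file for usage.

## Acceptance script

`scripts/acceptance.R` re-derives the package's benchmark quantities from
scratch — it simulates the coupled logistic and Hénon maps at the
standard configuration (x₀ = 0.65, y₀ = 0.44, transient 10³, T = 10⁶),
encodes the x-coordinate with D = 4, τ = 1, and evaluates the Rényi
min-entropies, magnitude variabilities, and maximum Lyapunov exponents
for the benchmark parameter sets:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The JSON output maps each benchmark id to the freshly computed value and
the trajectory length used. All benchmark configurations are
deterministic; the seed only anchors incidental randomness.

## Scope notes

EEG and power-grid recordings analysed with this method are not
redistributable, so no real-world data ships with the package; the
dithering rule for quantised recordings (`dither_signal()`, amplitude =
signal range × 2⁻¹⁶) and generic single-column CSV ingestion
(`read_signal()`) cover that workflow. The methods vignette
(`vignettes/ordinal-magnitude-variability.Rmd`) documents the estimator
conventions, degenerate-case rules, and known limitations.
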