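# primingdose

Modelling and calibration of the radiation **priming-dose effect** (the
Yonezawa or Raper–Yonezawa effect): a small conditioning dose of ionizing
radiation, given hours before a large challenging dose, can leave fewer
DNA lesions or mutations than the challenging dose alone. The package is
aimed at radiation biophysicists and radiobiologists who want to quantify
this adaptive response in two-dose experiments, predict it for planned
dose schedules, or re-estimate its parameters from their own count data.

## The model

The probability rate of a successful adaptive-response repair event after
a pulse of dose *D* received *t* hours ago is

    p_AR(D, t) = α₀ D² t² exp(−α₁ D − α₂ t)

with three positive parameters: amplitude α₀ (Gy⁻² h⁻³), dose decay α₁
(Gy⁻¹) and time decay α₂ (h⁻¹). Lesions decay as dN = −N p_AR dt, which
integrates in closed form; the protective effect of priming dose D₁ given
Δt hours before challenge D₂ is the fractional reduction

    δ = 1 − N₁₊₂ / N₂

with closed-form expressions for the lesion endpoint (finite observation
time T) and the mutation endpoint (T → ∞):

    δ_mut = 1 − exp(−f(D₁, Δt)) − (D₁/D₂) exp(−ξ_D₁)

where f is the repair antiderivative and ξ_D = f(D, 0) the lifetime
repair integral of one pulse. Negative δ (no protection) is returned,
flagged, and kept — it is informative for calibration. Schemes with two
or *n* identical priming doses are included, as are the published
estimation procedures: deterministic multistart bounded quasi-Newton
least squares and a simplified genetic algorithm, plus worst-case Poisson
uncertainty bounds.

## Worked example

```r
library(primingdose)

# the illustrative parameter set in abstract dose/time units
p <- ar_params(1, 1, 0.7)
delta_mutations(p, d1 = 1, d2 = 5, dt = 3)
#> delta (mutations scheme): 0.728384
#> Yonezawa effect present (delta > 0): TRUE
```

A priming dose of 1 unit given 3 time units before a 5-unit challenge
removes 73% of the mutations the challenge alone would have left.

Refitting the bundled human-lymphocyte chromatid-break records (23
two-dose experiments, 200–300 scored cells per arm):

```r
les <- load_bundled("shadley_lesions")
fit_lbfgsb(les, "lesions")
#> Adaptive-response fit (lbfgsb, lesions variant, 23 records)
#>   alpha0 = 22.9482 Gy^-2 h^-3
#>   alpha1 = 79.4562 Gy^-1
#>   alpha2 = 0.0832385 h^-1
#>   SSR = 0.20771586  (fitness 4.81427)
#>   runs: 113 kept / 125 total
```

So in these lymphocytes the repair signal peaks for priming doses near
2/α₁ ≈ 25 mGy and about 2/α₂ ≈ 24 h after them, and the protective
effect fades with the priming-to-challenge gap roughly as

```r
linear_trend(les$records[les$records$study == "Shadley et al.", ])
#> slope -0.0052 /h, intercept 0.484, R2 0.61
```

i.e. about half a percentage point of δ lost per hour of gap, vanishing
beyond roughly 100 h.

A command-line interface covering the same operations (`delta`, `fit`,
`simulate`, `predict`, `datasets`) is installed under the package's
`exec/` directory; see `?cli_main`.

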