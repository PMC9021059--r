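---
title: "Modelling the priming-dose (Raper-Yonezawa) effect"
author: "primingdose package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the priming-dose (Raper-Yonezawa) effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primingdose)
```

## The phenomenon and the model

A small *priming* (conditioning) dose of ionizing radiation, given hours
before a large *challenging* dose, can leave fewer chromosomal lesions or
mutations than the challenging dose alone — the priming-dose, Yonezawa, or
Raper–Yonezawa effect, a special case of the radiation adaptive response.
This package implements a three-parameter biophysical model of that effect
and its calibration against published two-dose experiments.

The core object is the probability rate of a successful adaptive-response
repair event triggered by a pulse of dose $D$ received $t$ hours ago:

$$p_{\mathrm{AR}}(D, t) = \alpha_0\, D^2 t^2\, e^{-\alpha_1 D - \alpha_2 t},$$

with $\alpha_0 > 0$ (rate amplitude, Gy$^{-2}$h$^{-3}$), $\alpha_1 > 0$
(dose decay, Gy$^{-1}$) and $\alpha_2 > 0$ (time decay, h$^{-1}$). The
"hunchbacked" kernel rises and falls in both variables: the repair signal
peaks at dose $2/\alpha_1$ and at time $2/\alpha_2$ after exposure, so both
very small and very large doses (or very short and very long delays) prime
poorly. Signals from separate pulses add; simultaneous pulses merge into a
single pulse of the summed dose.

Unrepaired lesions decay under this signal, $\mathrm{d}N = -N\,
p_{\mathrm{AR}}\,\mathrm{d}t$, which integrates in closed form through the
antiderivative

$$f(D, t) = \frac{\alpha_0}{\alpha_2^3} D^2
  e^{-\alpha_1 D - \alpha_2 t}\left[(\alpha_2 t)^2 + 2\alpha_2 t +
  2\right], \qquad N(T) = N_0\, e^{f(D,T) - f(D,0)}.$$

$f$ decreases monotonically from the lifetime repair integral
$\xi_D = f(D, 0) = 2(\alpha_0/\alpha_2^3) D^2 e^{-\alpha_1 D}$ to
$f(D,\infty) = 0$, so the lesion count never falls below
$N_0 e^{-\xi_D}$: repair saturates because the signal dies away.

## The delta statistic

The effect is quantified by the fractional reduction
$\delta = 1 - N_{1+2}/N_2$, comparing the primed arm ($D_1$, then $D_2$
after a gap $\Delta t$) with the challenge-only arm. Working through the
two-pulse kinetics and cancelling the challenge's own repair factor gives
the $\mu$-free forms used throughout:

* lesions, observed at finite time $T$:
  $\delta = 1 - e^{f(D_1,T) - f(D_1,\Delta t)} -
  (D_1/D_2)\, e^{f(D_1,T) - \xi_{D_1}}$;
* mutations (all repair finished, $T \to \infty$):
  $\delta = 1 - e^{-f(D_1,\Delta t)} - (D_1/D_2)\, e^{-\xi_{D_1}}$.

Negative values are meaningful — they say the primed arm ended up slightly
*worse* — and are returned as-is with a `yonezawa_effect = FALSE` flag,
because the published calibration deliberately keeps such rows. As the gap
grows, $\delta$ falls to the asymptote
$\delta_{\min} = -(D_1/D_2) e^{-\xi_{D_1}}$. `dt_threshold_ok()` locates
the largest protective gap by a bracketed root search on the sign
condition; the condition is evaluated through differences of $f$ inside a
single exponential, which stays exact in regimes where the textbook
rearrangement (a logarithm of a difference of separate exponentials)
underflows.

Two generalisations are provided. `delta_two_priming()` implements the
closed three-term formula for two priming pulses. `delta_multi_priming()`
handles $n$ identical priming pulses by per-dose survival bookkeeping: the
pooled surviving lesions are propagated from pulse to pulse under all
signals already switched on. The published nested expression for general
$n$ is ambiguous as printed beyond $n = 3$; we committed to the recursion
that reproduces the one- and two-primer closed forms exactly at $n = 1, 2$
(both identities are property-tested across random parameter draws). The
recursion's $\Delta t \to 0$, $n \to \infty$ limit is *not* a model of
chronic exposure — that regime saturates at `chronic_saturation()`
($P_c = \xi_{\dot D}$), the long-age limit of the continuous-irradiation
integral `p_ar_continuous()`.

## Bundled data and units

`load_bundled()` returns the transcribed published calibration tables:

* `shadley_lesions` — 23 chromatid-break records in human lymphocytes
  ($D_2 = 1.5$ Gy, gaps 10–84 h, 200–300 cells per arm), including three
  negative-$\delta$ rows at priming doses of 0.3–0.5 Gy;
* `shadley_aberrations` — 10 chromosome-aberration records
  ($D_1 = 50$ mGy, $D_2$ of 2 or 4 Gy);
* `day_inversions` — 8 chromosomal-inversion frequency records in mouse
  prostate and spleen (priming doses of 0.001–10 mGy, stored in Gy).

Internal canonical units are Gy and hours everywhere; the CSV reader and
the CLI accept mGy through an explicit flag and convert on entry. Each
printed $\delta$ is revalidated against its own counts at the printed
3-decimal precision (`validate_printed_deltas()`, tolerance 5e-4, half-up
rounding as in the tables).

## Parameter estimation

Both published estimation routes minimise the same objective, the sum of
squared residuals between observed and model $\delta$ (`ssr_objective()`),
on log-transformed parameters inside the box $\alpha_0 \in [10^{-6},
10^6]$, $\alpha_1 \in [10^{-3}, 10^4]$, $\alpha_2 \in [10^{-8}, 10]$ —
two-plus orders of magnitude around every published estimate:

* `fit_lbfgsb()` — bounded quasi-Newton (L-BFGS-B) started from every node
  of a log-spaced $5^3$ grid; deterministic.
* `fit_sga()` — a simplified genetic algorithm: fitness-proportional
  selection on $1/\mathrm{SSR}$, no crossover, multiplicative log-normal
  mutations whose scale anneals geometrically from 0.6 to 0.01, and
  elitism. The published budget (population 99, millions of generations,
  $\ge 50$ restarts) is far beyond what the algorithm needs on these
  datasets; the defaults keep the published population of 99 but run 600
  generations and 12 restarts, which lands every restart within the 1%
  fitness filter on the lesion data, and the full budget remains available
  through `fit_config()`. Surviving runs bound a box that is optionally
  re-scanned by brute force.

The mutation operator and its annealing schedule are our concrete choices;
the source describes the mutation step only qualitatively (small direct
parameter changes, with flavours of particle-swarm and simulated-annealing
methods).

For the pooled 33-record analysis the three lymphocyte studies are fitted
jointly with the finite-time lesion formula, using each row's own
observation time — the aberration rows are treated as lesion-like, which
is how the source pools them; this is an assumption, not a derivation.

Worst-case Poisson uncertainty (`poisson_worstcase_uncertainty()`) refits
two extreme datasets in which every count is shifted by one standard
deviation ($\sqrt{k}$) in the directions that jointly push $\delta$ up
(challenge arm up, primed arm down) and down (reversed). The exact recipe
(how many standard deviations, which counts move) is not stated in the
source, so only order-of-magnitude comparability with the published
asymmetric ranges is claimed or tested. Frequency-only records carry no
counts to perturb and are rejected explicitly.

The spleen subset has two records for three parameters; the fit is
exercised (with an explicit underdetminedness warning) but its printed
parameters are treated as one point on a zero-residual manifold, not a
unique optimum — only SSR-equivalence is checked.

## Synthetic experiments and what they show

`generate_dataset()` emulates the calibration experiments: the design
(doses, gaps, observation times, denominators of 200–300 scored cells,
challenge-arm baseline frequencies of 0.34–0.42) defaults to the 23-row
lesion design verbatim (`table2_lesion_design()`), the model $\delta$ at
the true parameters sets the primed arm's expected frequency, and both
arms' counts are drawn Poisson. Noise enters through counts only — doses
and times are exact, mirroring how the published uncertainty analysis
treats the data. What the generator does *not* emulate: donor-to-donor
variability, shared challenge-arm controls across rows (each synthetic row
draws its own), cell-cycle-phase structure, or any over-dispersion beyond
Poisson. Passing recovery tests therefore demonstrate estimator
correctness under the model's own assumptions, not robustness to real
biological heterogeneity.

`recovery_experiment()` repeats generate-and-fit over a seeded stream and
summarises per-parameter bias, RMSE, the componentwise median estimate
with its relative deviation from truth (`rel_err_of_median` — the robust
statistic we report, appropriate because the sampling distribution of
$\hat\alpha_0$ is heavy-tailed), and the median of per-replicate relative
errors. At published-scale noise the time-decay $\alpha_2$ recovers to a
few percent and $\alpha_1$ to better than ten percent, but $\alpha_0$ is
only weakly identified: rows with priming doses $\ge 0.2$ Gy have
$\xi \approx 0$ at realistic $\alpha_1$ and bound it only from below, so
the likelihood has a ridge along $\alpha_0 e^{-\alpha_1 D_1}$ on which
occasional noisy replicates wander orders of magnitude upward. This is a
property of the design plus the model, not of the optimiser; the test
suite documents it by asserting a 15% recovery bound that $\alpha_0$
does not meet.

## Numerical choices

* $t = \infty$ is a first-class input: $f$ returns exactly 0 there,
  because the mutation endpoint uses that limit structurally.
* Every $e^{f - f'}$ factor exponentiates a *difference* of $f$ values
  (never a ratio of exponentials); $f$ itself cannot overflow since its
  exponent is $\le 0$.
* Quadrature (the continuous-irradiation path and all test oracles) is
  adaptive with absolute tolerance $10^{-10}$; closed forms carry all
  production computation.
* The discrete-schedule signal takes a caller-supplied hours-per-step
  scale (default 1 h), since the step duration is abstract in the model.
* A non-fatal warning is emitted when $\alpha_1 D_2 > 10$: the model is
  built for challenging doses that are not too large, and the threshold is
  our documented heuristic for "too large".
* Problem sizes in the test suite (restart counts, replicate counts,
  generations) are chosen so the whole suite runs in well under a minute
  apart from the recovery experiment, which fits 20 replicated datasets.

## Known limitations

The model assumes the same repair-probability function for priming and
challenging doses, which biologically caps the challenging dose's
validity; $\delta \to 1$ is an unreachable perfect-repair limit; the
lesion and mutation forms differ negligibly at long observation times, and
the pooled fit exploits that. Cell-cycle-phase-specific parameter sets and
organism-level mortality endpoints are out of scope.
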