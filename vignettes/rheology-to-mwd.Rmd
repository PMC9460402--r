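---
title: "From oscillatory rheometry to molecular-weight distributions"
author: "rheomwd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From oscillatory rheometry to molecular-weight distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rheomwd)
```

## The problem

High-molecular-weight biopolymer gels — native (non-hydrolyzed) collagen is
the motivating case — cannot be characterized by GPC or electrophoresis:
the chains are too large, too entangled and too cross-linked to enter a
column or a gel. Melt rheometry offers an alternative: the way a sample
stores and dissipates energy under small oscillatory shear encodes the
distribution of chain relaxation times, and relaxation times map onto chain
masses. `rheomwd` implements that route end to end, from raw sweep tables
to a weight-based molecular-weight distribution $w(M)$ with its moments
$M_w$, $M_n$ and polydispersity index $\mathrm{PDI} = M_w/M_n$.

The chain of models is:

1. **Generalized Maxwell model.** The relaxation modulus is
   $G(t) = \sum_i G_i e^{-t/\lambda_i}$, and the dynamic moduli of one mode
   are the standard Lorentzian kernels
   $G'(\omega)=\sum_i G_i \frac{(\omega\lambda_i)^2}{1+(\omega\lambda_i)^2}$,
   $G''(\omega)=\sum_i G_i \frac{\omega\lambda_i}{1+(\omega\lambda_i)^2}$.
2. **Continuous relaxation spectrum.** Letting the mode count grow,
   $G(t) = \int_0^\infty H(\lambda) e^{-t/\lambda}\, d\ln\lambda$, with the
   analogous kernels for $G'$ and $G''$. $H(\lambda)$ is the pivot between
   rheology and molecular structure.
3. **Double reptation.** The reptation modulus of a polydisperse entangled
   melt follows the mixing rule
   $G_r(t) = G_N \left( \int_{M_e}^{\infty} F(M,t)^{1/\beta} w(M)\,
   \frac{dM}{M} \right)^{\beta}$
   with plateau modulus $G_N$, entanglement mass $M_e = M_c/2$, mixing
   exponent $\beta$ (2 for double reptation), and a monodisperse kernel
   taken as essentially exponential, $F(M,t) = e^{-t/\lambda_d(M)}$ with
   $\lambda_d(M) = K M^\alpha$.

Around that chain sit the quality-control stages any practitioner runs
first: the linear viscoelastic (LVE) region from amplitude sweeps, the
denaturation temperature $T_d$ from temperature sweeps, robust repair of
inhomogeneous frequency sweeps, and time–temperature superposition (TTS)
to widen the frequency window.

## Pipeline and parameters

```{r pipeline, eval = FALSE}
gen <- generate_frequency_sweeps(synthetic_scenario(noise_sigma = 0.02))
res <- analyze_sweeps(gen$sweeps,
                      config = run_config(tts = list(reference_temperature = 28,
                                                     vertical = FALSE)))
res$summary   # Mw, Mn (2 significant figures), PDI (1 decimal)
```

The tunables that matter, their units and defaults:

* `lve_tolerance` (fraction, 0.05). The LVE plateau is the longest
  contiguous run of amplitude-sweep points whose $G'$ all lie within
  ±5% of the run's median. 5% is the conventional criterion; the plateau
  value reported is the run median, which is robust to single outliers.
* `td_drop_fraction` (fraction, 0.5). $T_d$ by the viscosity route is the
  temperature where complex viscosity falls to half its initial value. The
  "initial value" is the mean of the first three samples rather than the
  single first point, to resist noise; the threshold crossing is located
  by linear interpolation. The tan δ route takes the maximum of
  $G''/G'$ after a fixed 3-point moving average, refined by parabolic
  interpolation; a maximum at either sweep boundary is rejected because an
  unbracketed peak cannot be distinguished from drift.
* `anomaly_k` (robust scale units, 4) in `fit_modulus_curves()`. Sweep
  points are admitted low-frequency-first into a trusted set; a candidate
  is flagged when its extrapolation residual exceeds `anomaly_k` times a
  robust scale built from the one-step-ahead residuals of previously
  accepted points. Basing the scale on *extrapolation* residuals (not fit
  residuals) makes smooth model inadequacy — a dense spectrum approximated
  by few modes — part of the baseline, so only abrupt departures such as
  collapsing near-$T_d$ tails are flagged. The scale has a floor of
  5×10⁻³ log₁₀ units (~1% in modulus) so noiseless data cannot produce a
  degenerate threshold.
* `max_complexity` (modes or degree, 6). Model complexity is chosen by the
  small-sample-corrected Akaike criterion; candidates whose parameter
  count exceeds the number of points are infeasible. Mode relaxation
  times are constrained to (slightly beyond) the reciprocal data window:
  modes outside it are unidentifiable and, left free, extrapolate
  erratically.
* `search_decades_beyond_data` (decades, 1) in `find_crossover()`. The
  $G' = G''$ crossover is searched inside the data window and up to one
  decade above it; extrapolated crossovers are always flagged. The search
  deliberately does not extend below the window: data with $G' > G''$
  throughout are gel-like, and a model-implied crossover beneath the
  measured range would be an artifact of terminal-zone extrapolation.
* `reptation_params()`: $G_N$ (Pa), $M_e$ (g/mol), $\beta$ (2), $\alpha$
  (3.4, the standard reptation scaling), and $K$ (s·(g/mol)$^{-\alpha}$).
  $G_N$ and $M_e$ for collagen gels are not established constants; both
  are required configuration inputs. Defaults are $G_N = 1000$ Pa (a
  typical gel plateau) and $M_e = 5\times10^4$ g/mol (well below the
  collagen monomer at ~3×10⁵ g/mol, so monomers are entangled). $K$ fixes
  the absolute time scale and is *degenerate with it*: by default it is
  anchored so a 6.8×10⁵ g/mol chain has terminal time 1 s
  ($K = \lambda_\mathrm{ref}/M_\mathrm{ref}^\alpha$). **Absolute $M_w$
  accuracy depends entirely on this anchor**; without an independent
  calibration point the recovered distribution is known only up to the
  mass scale implied by $K$.
* `tts`: horizontal shifts only by default; vertical shifts are an opt-in
  flag (`vertical = TRUE`), estimated analytically for each candidate
  horizontal shift. Registration operates on fitted curves, not raw
  points, so overlap windows need not share abscissae. No WLF or
  Arrhenius form is imposed on $a_T(T)$ — three or four temperatures
  cannot constrain one.

## Spectrum inversion

Recovering $H(\lambda)$ from $G'(\omega), G''(\omega)$ is a classic
ill-posed problem. The implementation:

* discretizes $H$ on a log-spaced grid (10 points/decade by default)
  spanning the reciprocal frequency window extended one decade each side,
  to absorb edge effects; spectrum mass outside the data window is
  reported as unreliable in the diagnostics;
* solves a nonnegative least-squares problem whose residual rows are
  scaled by $1/G$, so that relative errors — approximately log-moduli
  errors — are weighted equally across the decades;
* penalizes the second difference (curvature) of $H$ along the grid. The
  penalty is applied to $H$ itself rather than $\log H$: a log-domain
  penalty cannot be expressed inside a single nonnegative least-squares
  solve, and with row scaling by $1/G$ the linear-curvature variant
  yields the same smoothness behavior in practice;
* selects the penalty strength by the L-curve corner (maximum Menger
  curvature of the residual–seminorm trade-off in log–log coordinates),
  with a guard: if the corner's residual exceeds 1.5× the best achievable
  residual over the candidate strengths, the smoothest solution within
  that factor is taken instead. The guard matters because the L-curve
  corner is ill-defined as noise → 0 and otherwise over-smooths clean
  data.

## The molecular-weight inversion

Free-form inversion of the mixing rule is unidentifiable at the data
quality of gel rheometry, so $w(M)$ is parameterized as a mixture of at
most three log-normal components — Gaussians in $\ln M$, matching the
"molecular-weight Gaussians" output style of commercial rheometry
software. Whether such reported Gaussians live in $M$ or $\ln M$ is
rarely stated; Gaussian-in-$\ln M$ is the physically standard choice and
is assumed here. The fit minimizes least squares in $\log G_r$ between
the target and the forward model, restricted to the reptation window
($G_r/G_N \in [10^{-4}, 0.99]$), with a deterministic multistart grid of
initializations (centers offset around the characteristic mass implied by
the target's terminal time; widths 0.3–1.1 in $\ln M$) — no random
numbers, so inversion is reproducible without seeds. Times below
$\tau_e = K M_e^\alpha$ are discarded before fitting: sub-entanglement
(Rouse-like) dynamics depend only weakly on $w(M)$ and are outside the
mixing rule's domain.

Moments are computed analytically from the fitted components
($M_w = \sum_i \pi_i e^{\mu_i + \sigma_i^2/2}$,
$M_n^{-1} = \sum_i \pi_i e^{-\mu_i + \sigma_i^2/2}$) and reported rounded
to 2 significant figures ($M_w$, $M_n$) and 1 decimal (PDI), the
convention of tabulated collagen results. β-sensitivity is real and
documented rather than hidden: monodisperse results are exactly
β-invariant (the mixing rule collapses algebraically), polydisperse
moments shift with β.

## What the synthetic generator emulates — and what it does not

The generator is the package's stand-in for unavailable rheometer data;
its defaults are the study conditions asserted throughout the test suite:

* truth $w(M)$: one log-normal with $M_w = 6.8\times10^5$ g/mol and
  PDI = 2 (σ² = ln 2) — the scale reported for native collagen;
* temperatures 23, 28, 32 °C with planted shifts
  $\log_{10} a_T = +0.5, 0, -0.5$ about the 28 °C reference;
* $T_d$ = 38.1 °C (the value measured for 4–5% wt collagen masses),
  planted simultaneously as a viscosity-sigmoid midpoint and a tan δ
  Gaussian peak so the two estimators can be cross-validated;
* LVE boundary at strain 0.1; frequency window 10⁻²–10² rad/s at
  5 points/decade; multiplicative log-normal noise, σ = 0.02 by default,
  independent per point on both moduli (the simplest model consistent
  with positive moduli and decade-spanning data — correlated noise is
  deferred);
* corruption modes: `near_td_tail` (the last 3 points collapse away from
  the last valid level, emulating softening/sliding near denaturation)
  and `gel_like` (a frequency-independent elastic floor added to $G'$, so
  $G'\parallel G''$ with $G' > G''$ and no crossover — the low- and
  high-concentration failure phenotype).

The forward chain runs truth → mixing rule → dense Maxwell re-expression
→ dynamic moduli on shifted windows, i.e. the same physics the inverse
pipeline assumes. Passing tests therefore demonstrate *internal
consistency and correct inversion of the stated model*, not that real
collagen obeys single-exponential kernels, thermorheological simplicity,
or uncorrelated noise. Real data can violate all three; the QC stages
(LVE, $T_d$, monotone crossover check, overlap rms) exist to catch the
violations, not to repair them.

## Numerical choices

* All quadrature is trapezoidal on log grids ($d\ln\lambda$, $d\ln M$,
  the mixing rule's $dM/M$), 10 points/decade by default; tests pin the
  refinement error of smooth integrands below 0.1%.
* All curve fitting operates on $\log_{10}$ moduli so every decade counts
  equally; robust scales are MAD-based.
* Degenerate inputs are handled explicitly: zero moduli invert to the
  zero spectrum; identical ANOVA groups with zero variance return the
  $p = 1$ convention with a `degenerate` flag; fully-relaxed tails
  ($G < 10^{-8} G_{\max}$) are dropped before spectra are fitted to
  relaxation curves; near-monodisperse mixture grids are widened to a
  minimum usable span.
* Master curves retain coincident shifted abscissae rather than merging
  them, so the point count is exactly the retained-point total and the
  result is invariant under permuting input sweeps.
* Problem sizes used by the default test and acceptance runs: 21-point
  sweeps at three temperatures, 50-seed noise ensembles for recovery
  statistics, 100-seed ensembles for false-flag rates, and 10⁴ null
  simulations for the ANOVA type-I calibration.

## Known limitations

* $K$, $G_N$ and $M_e$ are external calibration inputs for collagen;
  absolute mass scales inherit their uncertainty directly.
* The kernel is single-exponential: no constraint release beyond the
  mixing exponent, no contour-length fluctuations, no Rouse modes.
* TTS assumes thermorheological simplicity; the only diagnostic offered
  is the overlap rms.
* The mixture inversion cannot resolve components narrower than the
  reptation window allows, and reported widths near zero mean "below
  resolution", not literal monodispersity.
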