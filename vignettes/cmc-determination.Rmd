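---
title: "Determining the cmc and transition width with a concentration model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining the cmc and transition width with a concentration model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmcfit)
```

## The model

Micellization is not a sharp phase transition: micelles appear over a finite
concentration interval around the critical micelle concentration. `cmcfit`
models this directly on the surfactant concentration. The curvature of the
monomer concentration $[S_1]$ with respect to the total concentration
$[S]_0$ is taken to be Gaussian,

$$\frac{d^2[S_1]}{d[S]_0^2}
  = -\frac{A}{\sqrt{2\pi}\,\sigma}
    \exp\!\left(-\frac{([S]_0-\mathrm{cmc})^2}{2\sigma^2}\right),$$

which encodes two things: the cmc is the point of maximum change in the
gradient of the monomer concentration (the classical Phillips condition,
applied to the concentration rather than to a measured property), and the
degree of micellization around it follows a normal distribution, as a
central-limit description of many molecules distributing between free and
micellized states. Integrating twice with $[S_1](0)=0$ and
$[S_1]\to\mathrm{cmc}$ gives the closed form implemented in
`monomer_concentration()`; the amplitude $A(r)$ (`amplitude()`) is exactly
the constant enforcing the zero-concentration boundary condition and is
always derived from $r$, never fitted. The width is reported as the
relative transition width $r=\sigma/\mathrm{cmc}$ so that surfactants with
different cmc values can be compared.

Assumptions worth keeping in mind:

* the aggregation number $n$ is constant, also at the onset of
  micellization; $[M]=[S_m]/n$;
* the model is empirical — it is a fitting function with interpretable
  parameters, not a thermodynamic theory of micellization;
* units are whatever the data use (mM, mol kg$^{-1}$, nM, ...); the model is
  scale invariant in $(\mathrm{cmc},\sigma)$ and no conversion is ever done
  internally.

Property equations (conductivity, Szyszkowski surface tension, NMR shift,
dye-binding fluorescence, pyrene band ratio, absorbance and absorbance
ratio, FCS mean diffusion, aggregated fraction) plug $[S_1]$, $[S_m]$ and
$[M]$ into standard expressions; all live in the model registry behind
`forward_model()` and are fitted by `fit_curve()` / `global_fit()`.

The three different $\gamma$s of this field are kept apart deliberately:
surface tension (`surface_tension()`), the differential degree of
micellization (`degree_of_micellization(mode = "differential")`) and the
aggregated fraction (`aggregated_fraction()`) never share an identifier.

## Parameters that matter

| parameter | meaning | default / typical | notes |
|---|---|---|---|
| `cmc` (`cac`) | critical concentration, data units | fitted; initialized from the smoothed second derivative | log-scale fit keeps it positive |
| `r` | relative transition width $\sigma/\mathrm{cmc}$ | init 0.1; typical 0.05–0.2, up to ~1 for weak amphiphiles | log-scale fit; values > 1 trigger a warning |
| `a`, `b`, `kappa_s` | conductivity slopes below/above the cmc, solvent term | from end-segment regression lines | natural scale |
| `k` (`c`) | composite binding constant $K/n$ per micellized surfactant | init $2/\mathrm{cmc_0}$ | see identifiability below |
| `gamma0`, `st_coeff`, `k_ad` | Szyszkowski solvent tension, $RT/\omega$, adsorption constant | from curve plateaus | `k_ad`, `st_coeff` positive |

Identifiability: in the dye equations only the product $K[M]=(K/n)[S_m]$
enters, so $K$ and $n$ cannot be separated from one titration curve. The
fit parameter is therefore the composite per-surfactant constant; the typed
interfaces (`dye_binding_params()`, `diffusion_params()`,
`pyrene_ratio_params()`) accept a per-micelle constant only together with
$n$. Likewise, the pyrene constant `c` lumps binding, quenching and
brightness factors; its decomposition is not implemented because the
printed definition in the source literature is corrupted, and committing to
a guessed formula would be worse than reporting the lumped constant.

## Fitting: numerical choices

* **Optimizer.** Damped least squares (Levenberg–Marquardt via
  `minpack.lm::nls.lm`), relative SSR tolerance $10^{-10}$, gradient
  tolerance $10^{-8}$, at most 500 iterations. Non-convergence is returned
  as a flagged result with the optimizer's message, never as a silent
  answer.
* **Positivity.** cmc, $r$, $\Delta$, binding constants and `k_ad` are
  fitted as logarithms; estimates and delta-method standard errors are
  back-transformed. This prevents negative-width pathologies on sparse
  data.
* **Weights and errors.** With per-point uncertainties the weights are
  $1/y_{err}^2$ and the covariance is the inverse weighted normal matrix,
  unscaled; without them, the covariance is scaled by the reduced $\chi^2$
  (the convention most commercial fitting software uses, hence comparable
  to published ± values). A singular normal matrix — e.g. when $r$ is
  smaller than the grid spacing and therefore carries no information — is
  flagged and standard errors are reported as unavailable.
* **Initialization.** The cmc starts at the extremum of a local-quadratic
  smoothed second derivative of the data (window 20% of points, minimum 5),
  clipped to the interior 10–90% of the concentration range so that
  featureless curves still start inside the data; $r$ starts at 0.1; slopes
  and plateaus come from end-segment regressions and means.
* **Degenerate inputs.** $r<10^{-6}$ switches to the exact
  piecewise-linear limit $[S_1]=\min(s_0,\mathrm{cmc})$, avoiding
  $0\cdot\infty$; the exponential underflow at small $r$ is accepted as an
  exact zero; the integrated Boltzmann model is evaluated with a
  log-sum-exp so sharp transitions do not overflow.
* **Tie-breaks.** `derivative_cmc()` refines the discrete extremum by a
  quadratic through the three surrounding points and resolves exact ties to
  the smallest concentration.
* **Masks.** Concentration-range masks (for, e.g., surface-tension curves
  with a cac and a cmc) are explicit user inputs, never auto-detected.

Global fits concatenate the residual blocks of all curves into one
least-squares problem; each share group occupies a single free slot, so the
shared estimate pools the information of every curve. Model comparison is
descriptive only: reduced $\chi^2$ values are reported side by side, no
tests are performed.

## The two conductivity width parameters

The integrated Boltzmann (Carpena-type) conductivity model is included as a
fitting alternative and a cross-check. Its width $\Delta[S]_0$ is not the
Gaussian $\sigma$: equating the curvatures of the two differential
sigmoids at the cmc gives $\sigma/\Delta[S]_0 = 4/\sqrt{2\pi} \approx 1.60$
(`equal_slope_width_ratio()`), while least-squares matching of the full
integrated curves gives ratios near 1.75 (`best_fit_width_ratio()`);
fits of the two models to the same data land between roughly 1.5 and 1.8
(`compare_carpena()`). The package fixes the integrated-curve
interpretation for `best_fit_width_ratio()`; matching the derivative
sigmoids instead would give the 1.60 figure, and both are exposed so the
distinction stays visible.

## What the synthetic data do and do not emulate

`simulate_curve()` adds independent Gaussian noise (absolute or relative)
to an exact forward model on a linear or logarithmic grid — exactly the
statistical structure weighted least squares assumes. The temperature-series
generator reproduces the structure of published conductivity series of
surface-active drugs: a second-order polynomial cmc(T), a
temperature-independent $r$, and linear slopes with $b/a$ rising in
temperature; its default shape (19 concentrations × 31 temperatures) mirrors
that design. Sparse-data studies mirror the published pattern of a
332-point conductivity curve reduced to 10 points with $r$ fixed at 0.1 or
0.001.

Real titrations additionally contain what the generator deliberately omits:
correlated drifts, impurity minima near the cmc (classic in surface
tension), heteroscedasticity beyond the simple relative model, temperature
fluctuations and concentration errors on the x-axis. Passing the test suite
therefore demonstrates correctness of the estimator under its own
assumptions — consistency, calibrated uncertainties, reproduction of the
known estimator biases — not robustness to every experimental artifact.

Test problem sizes were chosen to be representative yet quick: coverage is
checked on 100 replicate curves of 30 points at 0.5% relative noise
(weighted fits; ±2 SE intervals for the cmc), the double-integration
equivalence on grids of a few hundred thousand points, and the sparse-data
protocol on a 332-point parent curve.

## Known limitations

* No mass-action or thermodynamic micellization model; the aggregation
  number is constant and never inferred.
* No counterion (ion-selective electrode) model; no ITC model; no
  micelle–water partition-coefficient workflow; no mixture rule for
  $r$(composition).
* The pyrene ratio equation is a simplification valid for $r < 0.4$;
  detailed photophysics (excimer kinetics, time-resolved intensities) are
  out of scope.
* Graphical and derivative estimators are provided for comparison, and
  inherit their known biases by design.
* The ± values reported by unweighted fits follow the reduced-$\chi^2$
  scaling convention stated above; other software may define them
  differently, so error conventions should be checked before comparing.
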