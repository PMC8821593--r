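---
title: "A morphogen-gradient and temperature-scaling model of zebrafish somitogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A morphogen-gradient and temperature-scaling model of zebrafish somitogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somitempo)
library(dplyr)
```

## The model

Somites form when a genetic oscillator (the segmentation clock, period
$\tau_s$) interacts with a posteriorly moving determination wavefront. This
package implements a quantitative version of that clock-and-wavefront
picture in which the wavefront is set by the Fgf8 mRNA field

$$u(x, t) = F_0 \, e^{-x/\lambda - t/\tau},$$

where $x$ is the distance from the tail end in µm (increasing anteriorly),
$\lambda$ is the spatial decay length of the transcript (cells stop
transcribing *fgf* genes as they exit the posterior progenitor domain, so
the mRNA decays over a characteristic length as cells move anteriorly), and
$\tau$ is the temporal decay constant of the source amplitude. The field is
closed-form by construction; there is deliberately no reaction–diffusion
solver here, because the model's content is precisely that this
two-exponential form suffices.

A boundary forms where the *spatial gradient* of the (possibly transformed)
signal falls to a threshold $\eta_t$ at each clock tick $t_n = n \tau_s$.
For a monotone transfer function with local slope $G'$ at threshold this
gives

$$x_n = x_0 - n \tau_s \frac{\lambda}{\tau}, \qquad
  x_0 = \lambda \ln\!\left(\frac{G' F_0}{\eta_t \lambda}\right),$$

an arithmetic series: the PSM shrinks at the constant velocity
$\lambda/\tau$ fixed entirely by the Fgf8 dynamics, and every somite has the
same tail-frame size $\tau_s \lambda / \tau$. Two perturbation operations
probe the structure of this prediction:

* a **spatially uniform exogenous source** (any time course) adds nothing to
  the spatial gradient, so every boundary is unchanged — `apply_perturbation()`
  with `uniform_source()` returns the baseline series identically;
* a **persistent threshold change** by a factor $k$ from stage $n_p$ shifts
  all later boundaries rigidly by $-\lambda \ln k$, so exactly one somite
  size differs from baseline (`threshold_change()`).

`boundary_series_general()` relaxes the exponential time dependence to an
arbitrary positive source profile $F(t)$, giving
$x_n = \lambda \ln(G' F(t_n) / \eta_t \lambda)$; the exponential case is an
exact reduction, and a constant source yields a non-shrinking PSM.

### Sign and coordinate conventions

The kymograph convention follows the kinematic identity between lab-frame
rates: the front velocity is the sum of the tail elongation rate and the
PSM shrinkage rate. Because published fits quote the PSM slope as negative,
the package stores the shrinkage *magnitude* `v_psm_shrink >= 0` and defines
`v_front = v_tail + v_psm_shrink`; traces satisfy
`front_position = tail_position - psm_length` on every row. Positions $x$
are distances from the tail end; lab-frame positions are obtained as
`tail_position - x`.

Two notions of "somite size" coexist and are both reported: the tail-frame
boundary spacing $\tau_s \lambda/\tau$ (≈ 24 µm with the default constants)
and the lab-frame size $(V_\mathrm{tail} + V_\mathrm{PSM}) \tau_s$
(≈ 52 µm). The literature does not always disambiguate them; the package
never conflates the two.

## Temperature scaling

Every rate in the system — the clock frequency, the Fgf8 decay rate, tail
growth, PSM shrinkage — empirically scales as $a \, (T - T_c)$ with a common
critical temperature $T_c = 14.4$ °C. This is the signature of critical
slowing down: all characteristic times diverge as $1/(T - T_c)$. No
nonlinear critical exponent is fitted anywhere (the exponent is 1
throughout), and temperatures stay in °C because the law is affine in them.
The registry `somite_constants()` holds the fitted constants; everything
downstream recomputes derived numbers from it.

```{r constants}
k <- somite_constants()
segmentation_period(27)                  # hours per somite at 27 degrees C
segmentation_period(20) / segmentation_period(32)  # the "factor three"
```

A consequence worth singling out: the lab-frame somite size
$(\beta_\mathrm{tail} + \beta_\mathrm{PSM})(T - T_c) \cdot \tau_s(T)$ is
temperature-independent because $(T - T_c)$ cancels against the period law
— the model's explanation for why somite size does not change while the
period varies three-fold.

Two decay-time conventions circulate for converting a fitted per-stage
slope into a time constant: $\tau = 1/a$ (reading the slope on the natural-log
concentration scale) and $\tau = 1/(a \ln 2)$ (reading it as a log2 δCt
slope). They differ by $\ln 2$ (≈ 11 vs ≈ 15 periods for the default
slope). `decay_time_from_slope()` exposes both and has **no default**: the
caller must name the convention, because the source conventions are
genuinely inconsistent and silently picking one would hide a 40%
difference.

## The δCt pipeline

RT-qPCR measures the threshold-cycle difference
$\delta Ct = Ct_\mathrm{GOI} - Ct_\mathrm{REF}$, i.e.
$\log_2$ of the reference-to-target concentration ratio; one unit is a
two-fold change. `delta_ct_table()` averages the PCR replicates
arithmetically per (sample, gene) before differencing and propagates the
replicate standard errors in quadrature. Amplification efficiency is
assumed to be exactly 2 per cycle (no efficiency correction), and no
outlier rejection is applied — both documented simplifications. A sample
with a single replicate cannot yield an sd, so a configurable floor
(default 0.2 cycles) is substituted; the same floor protects weighted fits
from zero sds produced by degenerate (noise-free) replicates.

Straight lines are fitted by minimising
$\chi^2 = \sum_i \left((y_i - a x_i - b)/\sigma_i\right)^2$ in closed form
(`fit_weighted_line()`), with errors from the inverse normal matrix. With
no sds supplied, unit weights are used, the reported $\chi^2$ is a plain
residual sum of squares (flagged), and standard errors are scaled by
$\sqrt{\mathrm{RSS}/\mathrm{df}}$ in the ordinary-least-squares manner.

Because δCt series taken at different temperatures share one per-stage law,
plotting them against somite stage $s = t/\tau_s(T)$ collapses them onto a
single line with slope $a' = a / a_s$; `pooled_collapse_fit()` performs the
rescaled pooled fit and `collapse_test()` tests the collapse with a nested-model
F ratio (pooled single line vs independent per-temperature lines).

**A numerical choice that matters:** the F statistic defaults to unweighted
residual sums of squares rather than per-point-σ-weighted χ². Per-point sds
estimated from three replicates are extremely noisy, and weighting by them
distorts the statistic's null distribution badly enough to invalidate its
nominal size; with homoscedastic Gaussian noise (which the generator
produces and real replicate noise approximates) the unweighted version is
exactly F-distributed. `use_sd = TRUE` restores the literal weighted form
for data with externally known uncertainties.

Gene classification (`classify_gene()`) is a two-sided $|a|/\mathrm{se} \ge 2$
rule — the threshold is a package decision, configurable, since no published
criterion exists. `reference_stability()` implements a simplified
BestKeeper-style score (Ct standard deviation across samples, then mean
pairwise correlation), not the full geometric-mean index.

## The synthetic-data generators

Real replicate tables for this system are not redistributable, so the
package carries seeded generators that emulate the study design:

* `gen_ct_table()` — samples at the five incubator temperatures
  23/26/27/29/31 °C, somite stages 5–21, three PCR replicates, reference
  gene at baseline Ct 16, gene-of-interest mean Ct following
  $a' s + b$ (defaults $a' = 0.122$, $b = 3.955$) with Gaussian noise of
  0.3 cycles on every replicate. Gaussian noise on Ct is multiplicative
  log-normal noise on concentration — the natural scale for qPCR. The
  0.3-cycle default produces reduced χ² of order one in the weighted fits.
  Both the stage and the equivalent time $t = s\,\tau_s(T)$ are emitted so
  the same table feeds stage-axis fits and the time-axis collapse.
* `gen_kymograph()` — rates $\beta (T - T_c)$ with the default
  $\beta_\mathrm{tail} = 4.79$ and $\beta_\mathrm{PSM} = 5.08$ µm h⁻¹ °C⁻¹,
  starting PSM length 800 µm (a realistic early-somitogenesis length that
  keeps 6 h of shrinkage positive at all default temperatures), 0.25 h
  sampling, 5 µm position noise.
* `gen_rate_table()` — four observables at the published temperature
  slopes with 5% fractional Gaussian noise and an sd column equal to 5% of
  the true rate (NA when noise is zero, so downstream fits fall back to
  unit weights).

Every generator requires an explicit seed and is a pure function of
(config, seed). What the generators deliberately do **not** model: PCR
amplification kinetics and chip effects, embryo-to-embryo variance as a
separate component from replicate noise (samples pool many embryos), and
the extra stage-heterogeneity of fixed-time sampling. Passing parameter-recovery
tests on these generators therefore demonstrates the estimators'
correctness and calibration under the assumed noise model, not robustness
to those unmodelled effects in real data.

## Numerical choices and degenerate inputs

* Boundary series and kymographs **truncate with a warning and a
  `truncated` attribute** (never silently) where $x_n$ or the PSM length
  would go negative; a negative anchor $x_0$ is returned as-is with a
  warning.
* The shared-$T_c$ fit profiles the total χ² over $T_c$ (per-observable
  slopes re-solved in closed form at each candidate), then polishes the
  golden-section optimum with parabolic steps so that noise-free data are
  recovered to ~1e−10 relative; its standard error comes from the profile
  curvature ($\Delta\chi^2 = 1$).
* $T_c$ is estimated as the common x-intercept of straight lines, matching
  how the scaling is presented; evaluating any law at $T \le T_c$ is an
  error, not an extrapolation.
* `fit_critical_law()` accepts two points per observable (an exact fit
  with zero degrees of freedom), which keeps df bookkeeping testable.
* All stochastic operations error when called without a seed.

## Problem sizes used in the test-suite simulations

Monte-Carlo checks run at 300 seeds for the coverage studies (pooled
per-stage slope and shared-$T_c$), 200 seeds for the collapse-test type-I
rate, 200 seeds for kymograph velocity coverage, and 100 seeds for
power/median-error checks — sizes chosen so the whole suite completes in a
couple of minutes while leaving the binomial uncertainty of each rate well
inside its asserted band.

## Known limitations

* The clock is a bare period; no oscillator network, phase model or
  cell-level simulation.
* No absolute quantification, standard curves, melt-curve QC or multi-plate
  calibration in the qPCR pipeline.
* The thresholding wavefront uses a single scalar $G'$; a full transfer
  function would only enter through this one number anyway, but strongly
  non-monotone signal processing is out of scope.
* No Arrhenius/Q10 modelling and no mechanistic account of why $T_c$ takes
  the value it does.
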