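---
title: "Modeling circadian core-clock and clock-controlled genes with constant-delay DDEs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling circadian core-clock and clock-controlled genes with constant-delay DDEs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`clockdde` models the mammalian core circadian clock as five coupled delay
differential equations, one per gene: *Bmal1*, *Rev-Erba*, *Per2*, *Cry1*
and *Dbp*. Each equation has the form

$$\frac{dX}{dt} \;=\; \prod_k \mathrm{reg}_k\big(Y_k(t - \tau_{Y_k})\big)
\;-\; d_X\, X,$$

where each regulatory term is a statistical-mechanics promoter-occupancy
factor — activation $\left(\frac{1 + b\,Y/K}{1 + Y/K}\right)$ for
CLOCK:BMAL1 on Ebox elements and DBP on Dbox elements, inhibition
$\left(\frac{1}{1 + Y/K}\right)$ for PER2/CRY1 on Ebox-mediated
transcription and REV-ERBa on RRE elements — raised to the integer number
of functional elements on that promoter (fixed exponents: RRE² on *Bmal1*;
Ebox³ and Dbox¹ on *Rev-Erba*; Ebox² and Dbox¹ on *Per2*; Ebox², RRE² and
Dbox¹ on *Cry1*; Ebox³ on *Dbp*). The delay $\tau_Y$ lumps translation,
nuclear entry, complex formation and DNA binding of regulator $Y$; light
entrainment is not modeled explicitly and is absorbed by the fitted
parameters.

A clock-controlled gene (CCG) is a single additional equation of the same
form, forced one-way by the core trajectory, with exponents $(n_1, n_2,
n_3)$ equal to the number of Ebox, RRE and Dbox elements found by scanning
its promoter (`pwm_scan()`, `count_elements()`). A zero count makes the
corresponding term identically 1.

## The integrator

No constant-delay DDE solver ships with the pre-installed stack, and the
integrator is a core deliverable here, so `dde_integrate()` implements the
method of steps directly (in C++): an embedded Dormand–Prince 5(4) pair
with the step size capped at the smallest positive delay, so that every
delayed lookup lands on an already-committed solution segment, evaluated
by cubic Hermite interpolation of the stored `(t, y, y')` nodes.

Numerical choices:

* Default tolerances `rel_tol = 1e-6`, `abs_tol = 1e-9`; default
  `hmax = 0.1` for the generic engine. The Hermite dense output is locally
  $O(h^4)$, so `hmax` — not the RK error control — bounds the
  between-node interpolation error; 0.1 keeps it near 1e-7 for smooth
  right-hand sides. Clock-model simulation uses `hmax = 0.25` (0.5 during
  fitting), always additionally capped at the smallest delay.
* Derivative discontinuities propagating from $t_0$ are absorbed by the
  step cap rather than located explicitly; every analysis here runs after
  a burn-in on the smooth limit cycle, where they have decayed.
* The pre-initial history is a constant vector, default all states at 1
  (the data are normalized around 1). The history before $t=0$ is not
  observable; any positive constant reaches the same limit cycle, only
  the transient differs — hence the default burn-in of 240 h with a
  subsequent analysis window (120 h for simulation, 72 h during fitting).

## Normalization and alignment

Microarray expression is normalized per gene so profiles oscillate around
1. Correspondingly, simulated profiles are divided by their mean over one
period (`model_profile()`) before any comparison with data; this scaling
never enters the dynamics. The model is free-running (period ≈ 24.2 h at
the published parameters) while data times are hours after lights-on, so
every fit carries one global time-offset parameter (bounded to ±12 h)
aligning the limit cycle to clock time. The offset is a nuisance
parameter and is excluded from the reported confidence intervals.

## Parameter estimation

`fit_core_clock()` estimates the five transcriptional delays and five
degradation rates (per tissue, or jointly across tissues — the consensus
fit) by box-constrained least squares; residuals are model minus data,
stacked over tissues, genes, times and replicates with equal weight.
Bounds follow physiological ranges: delays in [0.1, 8] h, degradation
rates in [0.05, 1.5] h⁻¹. Parameter sets that fail to oscillate return a
constant penalty residual (10 per point) so the optimizer can retreat.

The sum-of-squares landscape is severely multimodal: wrong assignments of
gene peaks to data peaks form deep local minima. The solver therefore
layers standard global-search practice over a Levenberg–Marquardt core:

1. a seeded Latin-hypercube candidate pool (default 150; rate-like
   parameters sampled log-uniformly) is screened with one residual
   evaluation each, after setting each candidate's offset so its simulated
   *Bmal1* peak matches the data's replicate-mean *Bmal1* peak;
2. the best `n_starts` candidates get full local searches — bounded
   Levenberg–Marquardt with a forward-difference Jacobian (relative step
   1e-3, well above the integrator's discretization noise; `nlminb`'s
   internal ~1e-8 steps drown in that noise and converge falsely);
3. each converged search is refined by seeded basin hopping (perturb,
   short refit, keep improvements), and the overall winner receives a
   coordinate-wise polish.

Accepted Levenberg–Marquardt iterations decrease the objective by
construction; the trace is stored on the fit object.

Wald 95% confidence intervals follow the standard normal-theory recipe:
$\hat p \pm t_{0.975,\,df}\sqrt{\mathrm{diag}\,(J^\top J)^{-1}\sigma^2}$
with $df = n - k$ and $\sigma^2 = \|r\|^2/df$. The source literature
prints the residual variance with an unsquared norm ($\|r\|/df$); since
the interval routine it cites uses the standard estimator, the standard
form is the default and the literal form is available as
`wald_ci(..., sigma_mode = "literal")` for reproduction experiments.
Two details matter for calibrated intervals on DDE fits. First, the
Jacobian spans *all* fitted parameters including the alignment offset —
the offset is dropped from the report, but its variance is marginalized
over, not conditioned on (conditioning understates delay variances badly;
measured coverage collapsed below 50% in early versions). Second, the CI
Jacobian uses a forward difference with relative step 1e-3, well above
the integrator's discretization noise (noise-dominated Jacobians are
inflated and give spuriously narrow intervals; the generic `ls_fit()`
keeps 1e-6 for analytically smooth residuals).

CCG fitting (`fit_ccg()`) holds the consensus core trajectory and the
scanned element counts fixed and estimates the CCG's fold changes,
dissociation constants and degradation rate per tissue; parameters whose
element count is zero are structurally unidentifiable and held fixed.

## Phases, sensitivity, regulation factors

A gene's phase is its peak time relative to lights-on times $2\pi$ over
its period, in $[0, 2\pi)$. Peaks are located by local-maximum bracketing
on the dense output with quadratic refinement; data phases use the
replicate-mean profile (the alternative — phase of a fitted curve — is
available by fitting first and taking the model phase). Circular
differences are reported in $(-\pi, \pi]$ with exact antiphase mapped to
$+\pi$ by convention. Flat profiles (amplitude below `flat_eps`) yield an
undefined-phase flag rather than a number.

`phase_sensitivities()` perturbs one parameter at a time by +10% (central
differences optional), re-simulates, and reports raw coefficients
$\Delta\phi_i/\Delta p_j$ with phase changes unwrapped to $(-\pi,\pi]$,
plus dimensionless normalized coefficients
$|(\Delta\phi_i/\phi_i)/(\Delta p_j/p_j)|$ — the source does not define
its normalization, and this is the standard choice matching the
"normalized sensitivity coefficient" phrasing. Phases are compared at
each perturbed system's own period (phase is period-scaled by
definition). A perturbation that destroys the oscillation flags the
column as non-computable instead of zeroing it.

Regulation factors are the five multiplicative terms of the CCG
production rate evaluated over one cycle with the same delayed arguments
and exponents as the dynamics. Their coefficient of variation is the
population SD over mean on a uniform 0.05 h grid — the source does not
specify the sampling, and a dense uniform grid removes any dependence on
solver steps. ΔCV% between two tissues is $(\max-\min)/\max \cdot 100$,
defined as 0 when both CVs are 0; it is specified pairwise only, and no
extension to more than two tissues is attempted. Factor series are
divided by their cycle mean for plotting/export only.

## Promoter scanning

`pwm_scan()` scores every offset of a promoter window (convention:
−10 kb/+5 kb around the TSS, 15 kb total) on both strands with a log2-odds
matrix built from counts with a total pseudocount of 0.8 distributed by a
uniform background, and reports hits with relative score
$(S - S_{\min})/(S_{\max} - S_{\min}) \ge 0.85$. Windows containing N are
skipped; overlapping hits all count ("absolute numbers" of elements feed
the exponents); coordinates are reported 1-based inclusive, BED export is
0-based half-open. Scanning both strands, the pseudocount and the uniform
background are this package's choices — the original analysis does not
state its scoring scheme, which is why published per-gene counts are not
bit-reproducible here and are not acceptance material. The bundled
Ebox/RRE/Dbox matrices are synthetic stand-ins (the originals are only
published as images) and are named accordingly.

## Synthetic data: what it does and does not establish

`generate_timecourse()` emulates the study design: 18 sampling times per
24 h cycle (0.25, 1, 2, 4, 6, 8, 10, 11, 11.75 | 12.25, 13, 14, 16, 18,
20, 22, 23, 23.75 h after lights-on; 12:12 light:dark), three replicates
(the design's three successive days collapsed to one cycle), values
normalized to cycle mean 1. Noise is multiplicative lognormal with
$\sigma = \sqrt{\log(1 + \mathrm{CV}^2)}$ and mean 1 — expression data
are positive and normalized, and the default CV of 10% is a realistic
microarray replicate noise level; additive Gaussian noise is available
behind a flag. The default inter-tissue scenario shares one core-clock
truth across tissues (the consensus assumption) while CCG dissociation
constants differ — the hypothesized mechanism for inter-tissue phase
variability.

Every generator returns a truth manifest sufficient to regenerate its
output bit-exactly. What a green test on synthetic data establishes is
that the pipeline recovers parameters *under the model's own assumptions*
(correct structure, lognormal noise, rhythmicity by construction). It
does not establish robustness to probe-level microarray artifacts,
normalization distortions, non-stationary rhythms, or model
misspecification — none of which the generator emulates.

## Known limitations

* Degradation rates and delays are only weakly identified by one cycle of
  normalized data; the fit landscape has near-degenerate valleys, and
  confidence intervals inherit that sloppiness.
* The offset/phase landscape is multimodal; the screened multi-start with
  basin hopping is a practical remedy, not a guarantee of the global
  optimum.
* Very large element counts make the CCG equation numerically stiff;
  counts are used as-is (an optional cap exists but is off by default).
* State-dependent or distributed delays, stochastic transcription,
  explicit light forcing and protein states are out of scope.
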