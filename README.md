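# clockdde

Delay-differential-equation modeling of circadian core-clock and
clock-controlled gene expression across tissues.

## What this is for

Peripheral tissues (liver, muscle, adipose, lung) express the same
core-clock genes — *Bmal1*, *Rev-Erba*, *Per2*, *Cry1*, *Dbp* — in near
synchrony, yet many clock-controlled genes (CCGs) peak at very different
times in different tissues. `clockdde` is a toolkit for asking whether
Ebox/RRE/Dbox-mediated transcription can account for that variability.
It is aimed at systems-biology work with circadian time-course expression
data: simulate the clock network, fit its delays and degradation rates to
replicate time courses, quantify which parameters set the phases, scan
promoters for regulatory elements, and attribute CCG rhythms to specific
transcription factors.

## The model

Five constant-delay DDEs, one per core-clock gene. Each gene's
transcription is a product of promoter-occupancy terms — activation
`(1 + b·X/K)/(1 + X/K)`, inhibition `1/(1 + X/K)` — with each regulator
`X` evaluated at `t − τ_X` (the transcriptional delay: translation,
nuclear entry, complex formation, DNA binding) and raised to the integer
number of functional promoter elements, minus first-order degradation
`d·X`. A clock-controlled gene is one more equation of the same form,
forced by the core trajectory, with exponents `(n1, n2, n3)` = the number
of Ebox, RRE, Dbox elements found by PWM promoter scanning at an 85%
relative-score threshold.

On top of the dynamics: bounded least-squares estimation (per-tissue or
all-tissue consensus) with Wald 95% confidence intervals
`p̂ ± t(0.975, df)·sqrt(diag((JᵀJ)⁻¹σ²))`; local sensitivity of gene
phases `s_ij = ∂φ_i/∂p_j` under 10% parameter perturbations; regulation
factors (the five occupancy terms over one cycle) with their CV and the
inter-tissue ΔCV% = (max−min)/max·100; and seeded generators emulating
the 18-time-point, 3-replicate, 12:12 light:dark microarray design.

## Worked example

```r
library(clockdde)

# 1. simulate the published consensus clock
core <- simulate_core_clock(clock_params("All-tissues"))
estimate_period(core)
#> [1] 24.19756
phase_report(core)[, c("gene", "peak_time_h", "amplitude")]
#>      gene peak_time_h amplitude
#> 1   Bmal1   22.385640  1.463844
#> 2 RevErba    7.295318  5.222118
#> 3    Per2   14.108967  4.422939
#> 4    Cry1   18.588308  1.372949
#> 5     Dbp    9.462904 26.019643
```

The free-running period is ≈24.2 h; within a cycle *Rev-Erba* and *Dbp*
peak first, *Per2* follows roughly 5–7 h later, then *Cry1*, then *Bmal1*
— the canonical ordering of the mammalian clock (absolute peak times are
defined up to the alignment offset fitted against data).

```r
# 2. which parameters set the phases?
sens <- phase_sensitivities(clock_params("All-tissues"))
round(sens$normalized["Bmal1", ], 2)
#> tau_Bmal1 tau_RevErba  tau_Per2  tau_Cry1   tau_Dbp   d_Bmal1 d_RevErba
#>      1.03        0.52      2.22      1.98      0.49      0.19      1.55
#>    d_Per2    d_Cry1     d_Dbp
#>      0.04      1.55      0.60
```

*Per2* and *Cry1* transcriptional delays and *Rev-Erba*/*Cry1*
degradation rates carry the largest normalized phase sensitivities — the
same pattern holds for all five output genes.

```r
# 3. recover parameters from synthetic four-tissue data (truth = consensus)
truth <- clock_params("All-tissues")
gen <- generate_timecourse(setNames(rep(list(truth), 4), paste0("T", 1:4)),
                           noise_cv = 0.1, seed = 23)
fit <- fit_consensus(gen$data, clock_fit_spec(n_starts = 3), seed = 23)
fit$objective            # ~14.4: the noise floor for 1080 points at CV 10%
wald_ci(fit)             # delays/degradations with 95% CIs

# 4. promoter scan -> CCG exponents -> regulation factors
pwms <- example_pwms()   # bundled synthetic stand-in matrices
prom <- generate_promoters(data.frame(gene = "ccgA", k_ebox = 2,
                                      k_rre = 1, k_dbox = 1), seed = 1)
ec <- count_elements(promoter_region("ccgA", prom$sequences[[1]]),
                     pwms$ebox, pwms$rre, pwms$dbox)
ccg <- ccg_parameters(b = 3, ba = 1, cr = 2, gr = 1, ar = 1.5, f = 4,
                      fa = 0.5, d = 0.3, n1 = ec$n1, n2 = ec$n2,
                      n3 = ec$n3, gene = "ccgA")
rf <- regulation_factors(core, ccg)
round(rf$cv, 3)   # which factor varies most over the cycle
```

A command-line interface mirrors the pipeline stages
(`simulate`, `synth`, `fit`, `fit-ccg`, `sensitivity`, `regfac`, `scan`,
`report`); see `inst/cli/clockdde` and `clock_cli("--help")`.

## Layout

* `R/`, `src/` — implementation (method-of-steps RK5(4) DDE integrator in
  C++; models, estimation, sensitivity, regulation factors, PWM scanning,
  generators, IO, CLI)
* `vignettes/clockdde-methods.Rmd` — the methods notes: model,
  assumptions, numerical choices, what the synthetic data does and does
  not establish
* `inst/extdata/` — synthetic stand-in PFMs (JASPAR text format)
* `tests/testthat/` — unit, property and acceptance suites
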