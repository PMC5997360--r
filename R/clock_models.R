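# The five-gene core-clock network and its clock-controlled gene extension.
#
# Interlocked loops: BMAL1 activates Ebox genes (Rev-Erba, Per2, Cry1, Dbp);
# PER2/CRY1 repress Ebox transcription; REV-ERBa represses RRE genes (Bmal1,
# Cry1); DBP activates Dbox genes (Rev-Erba, Per2, Cry1).  Light entrainment
# is not modeled explicitly; it is absorbed in the fitted parameters.

# occupancy terms (statistical-mechanics promoter model)
act_term <- function(x, b, K) (1 + b * x / K) / (1 + x / K)
inh_term <- function(x, K) 1 / (1 + x / K)

#' Right-hand side of the core-clock DDE system (R closure)
#'
#' Returns a function `(t, y, ylag)` suitable for [dde_integrate()], where
#' `ylag[, k]` is the state at `t - tau_k` in gene order (Bmal1, RevErba,
#' Per2, Cry1, Dbp).  This R-level route mirrors the compiled route used by
#' [simulate_core_clock()]; the two are cross-checked in the test suite.
#'
#' @param params `core_clock_params`.
#' @return rhs closure.
#' @export
core_clock_rhs <- function(params) {
  p <- as.list(param_vector(params))
  force(p)
  function(t, y, ylag) {
    B <- ylag[1, 1]; R <- ylag[2, 2]; P <- ylag[3, 3]
    C <- ylag[4, 4]; D <- ylag[5, 5]
    c(inh_term(R, p$ar1)^2 - p$d_Bmal1 * y[1],
      act_term(B, p$b2, p$ba2)^3 * inh_term(P, p$cr2)^3 *
        inh_term(C, p$gr2)^3 * act_term(D, p$f2, p$fa2) -
        p$d_RevErba * y[2],
      act_term(B, p$b3, p$ba3)^2 * inh_term(P, p$cr3)^2 *
        inh_term(C, p$gr3)^2 * act_term(D, p$f3, p$fa3) - p$d_Per2 * y[3],
      act_term(B, p$b4, p$ba4)^2 * inh_term(P, p$cr4)^2 *
        inh_term(C, p$gr4)^2 * inh_term(R, p$ar4)^2 *
        act_term(D, p$f4, p$fa4) - p$d_Cry1 * y[4],
      act_term(B, p$b5, p$ba5)^3 * inh_term(P, p$cr5)^3 *
        inh_term(C, p$gr5)^3 - p$d_Dbp * y[5])
  }
}

#' Simulate the core-clock network
#'
#' Integrates the five-gene system from a constant history (default: all
#' states at 1, matching data normalized around 1) for `burn_in + duration`
#' hours.  The returned trajectory keeps the burn-in segment (needed for
#' delayed lookups by downstream CCG integration) and marks the analysis
#' window via `window_start`.
#'
#' @param model a `tissue_model`, or a `core_clock_params` set.
#' @param duration analysis window length (hours) after burn-in.
#' @param burn_in transient discarded before analysis (hours); default 240.
#' @param history constant pre-initial state (length 5).
#' @param rel_tol,abs_tol,hmax integrator controls; `hmax` is additionally
#'   capped at the smallest transcriptional delay.
#' @return `dde_traj` with variables named after the clock genes and an
#'   `oscillation` element: peak-to-trough ratios of the last two cycles.
#' @export
simulate_core_clock <- function(model, duration = 120, burn_in = 240,
                                history = rep(1, 5), rel_tol = 1e-6,
                                abs_tol = 1e-9, hmax = 0.25) {
  params <- if (inherits(model, "tissue_model")) model$params else model
  tissue <- if (inherits(model, "tissue_model")) model$tissue else NA_character_
  if (!(duration > 0) || burn_in < 0 || duration <= 0)
    stop("need duration > 0 and burn_in >= 0")
  if (length(history) != 5 || any(!is.finite(history)) || any(history < 0))
    stop("history must be 5 finite non-negative values")
  v <- param_vector(params)
  res <- tryCatch(
    core_clock_integrate_cpp(v, as.numeric(history), 0,
                             burn_in + duration, rel_tol, abs_tol, hmax),
    error = function(e) stop("core-clock integration failed",
                             if (!is.na(tissue)) paste0(" [", tissue, "]"),
                             ": ", conditionMessage(e), call. = FALSE))
  traj <- new_dde_traj(res, varnames = CLOCK_GENES, window_start = burn_in)
  traj$tissue <- tissue
  traj$params <- params
  traj$oscillation <- oscillation_diagnostics(traj)
  traj
}

# peak-to-trough ratio per gene over the last two ~24 h spans of the window
oscillation_diagnostics <- function(traj, cycle = 24) {
  t1 <- traj$t_end
  t0 <- max(traj$window_start, t1 - 2 * cycle)
  times <- seq(t0, t1, by = 0.1)
  m <- dde_evaluate(traj, times)
  ratio <- apply(m, 2, function(v) {
    lo <- min(v)
    if (lo <= 0) return(Inf)
    max(v) / lo
  })
  list(peak_trough_ratio = ratio, sustained = all(ratio > 1.2))
}

#' Right-hand side of a clock-controlled gene (R closure)
#'
#' One-way coupling: the CCG is a scalar equation forced by delayed
#' evaluations of a committed core-clock trajectory.  Delays are the five
#' transcriptional delays stored in the core trajectory's parameters.
#'
#' @param ccg `ccg_params`.
#' @param core core-clock `dde_traj` (from [simulate_core_clock()]).
#' @return function `(t, x)` returning dCCG/dt.
#' @export
ccg_rhs <- function(ccg, core) {
  stopifnot(inherits(ccg, "ccg_params"), inherits(core, "dde_traj"))
  taus <- param_vector(core$params)[1:5]
  force(ccg)
  function(t, x) {
    prod <- 1
    if (ccg$n1 > 0) {
      B <- dde_evaluate(core, t - taus[1])[, "Bmal1"]
      P <- dde_evaluate(core, t - taus[3])[, "Per2"]
      C <- dde_evaluate(core, t - taus[4])[, "Cry1"]
      prod <- prod * act_term(B, ccg$b, ccg$ba)^ccg$n1 *
        inh_term(P, ccg$cr)^ccg$n1 * inh_term(C, ccg$gr)^ccg$n1
    }
    if (ccg$n2 > 0) {
      R <- dde_evaluate(core, t - taus[2])[, "RevErba"]
      prod <- prod * inh_term(R, ccg$ar)^ccg$n2
    }
    if (ccg$n3 > 0) {
      D <- dde_evaluate(core, t - taus[5])[, "Dbp"]
      prod <- prod * act_term(D, ccg$f, ccg$fa)^ccg$n3
    }
    prod - ccg$d * x
  }
}

#' Simulate a clock-controlled gene over a core-clock trajectory
#'
#' Integrates the scalar CCG equation forced by the core trajectory.  By
#' default the CCG runs over the core's full span (sharing its burn-in and
#' analysis window); requesting a window beyond the core's end is an error
#' naming the required extension.
#'
#' @param ccg `ccg_params`.
#' @param core core-clock `dde_traj`.
#' @param t_end end of integration; default the core's `t_end`.
#' @param history constant CCG level before t0 (default 1).
#' @param rel_tol,abs_tol,hmax integrator controls.
#' @return one-variable `dde_traj` (variable named after `ccg$gene`).
#' @export
simulate_ccg <- function(ccg, core, t_end = core$t_end, history = 1,
                         rel_tol = 1e-6, abs_tol = 1e-9, hmax = 0.25) {
  stopifnot(inherits(ccg, "ccg_params"), inherits(core, "dde_traj"))
  if (t_end > core$t_end + 1e-9)
    stop(sprintf(
      "core trajectory ends at %g h but CCG integration needs %g h; extend the core simulation by %g h",
      core$t_end, t_end, t_end - core$t_end))
  v <- param_vector(core$params)
  q <- c(ccg$b, ccg$ba, ccg$cr, ccg$gr, ccg$ar, ccg$f, ccg$fa, ccg$d)
  res <- ccg_integrate_cpp(q, c(ccg$n1, ccg$n2, ccg$n3), v[1:5],
                           unclass(core), history, core$t0, t_end,
                           rel_tol, abs_tol, hmax)
  traj <- new_dde_traj(res, varnames = ccg$gene,
                       window_start = core$window_start)
  traj$ccg <- ccg
  traj
}
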