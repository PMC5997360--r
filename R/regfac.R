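# Regulation factors: the instantaneous value of each multiplicative
# regulatory term of the CCG equation, used to attribute a CCG's rhythm to
# a specific transcription factor, plus their coefficient-of-variation
# statistics across tissues.

REGFAC_NAMES <- c("BMAL1", "PER2", "CRY1", "REVERBA", "DBP")

#' Compute regulation-factor time series over one cycle
#'
#' Evaluates the five multiplicative terms of the CCG production rate
#' (BMAL1 activation, PER2 inhibition, CRY1 inhibition via Ebox; REV-ERBa
#' inhibition via RRE; DBP activation via Dbox) on a uniform grid over one
#' period, using the same delayed core-clock arguments and exponents as the
#' dynamics.  A zero element count makes the factor identically 1 with
#' CV = 0.
#'
#' @param core core-clock `dde_traj`.
#' @param ccg `ccg_params`.
#' @param period cycle length (hours); default [estimate_period()] of the
#'   core's first gene.
#' @param t_start start of the cycle; default the core analysis window.
#' @param dt grid spacing (hours), default 0.05 (the CV is computed as the
#'   population SD / mean on this grid, making it independent of solver
#'   steps).
#' @return object of class `regfac_series`: `time_h`, `factors` (matrix,
#'   one column per factor), `cv` (named vector), `tissue`, `gene`.
#' @export
regulation_factors <- function(core, ccg, period = NULL,
                               t_start = core$window_start, dt = 0.05) {
  stopifnot(inherits(core, "dde_traj"), inherits(ccg, "ccg_params"))
  if (!all(CLOCK_GENES %in% core$varnames))
    stop("core trajectory must contain all five clock genes")
  if (is.null(period)) period <- estimate_period(core)
  taus <- param_vector(core$params)[1:5]
  times <- seq(t_start, t_start + period, by = dt)
  times <- times[times < t_start + period]  # half-open cycle
  B <- dde_evaluate(core, times - taus[1])[, "Bmal1"]
  R <- dde_evaluate(core, times - taus[2])[, "RevErba"]
  P <- dde_evaluate(core, times - taus[3])[, "Per2"]
  C <- dde_evaluate(core, times - taus[4])[, "Cry1"]
  D <- dde_evaluate(core, times - taus[5])[, "Dbp"]
  fac <- cbind(
    BMAL1 = if (ccg$n1 > 0) act_term(B, ccg$b, ccg$ba)^ccg$n1 else
      rep(1, length(times)),
    PER2 = if (ccg$n1 > 0) inh_term(P, ccg$cr)^ccg$n1 else
      rep(1, length(times)),
    CRY1 = if (ccg$n1 > 0) inh_term(C, ccg$gr)^ccg$n1 else
      rep(1, length(times)),
    REVERBA = if (ccg$n2 > 0) inh_term(R, ccg$ar)^ccg$n2 else
      rep(1, length(times)),
    DBP = if (ccg$n3 > 0) act_term(D, ccg$f, ccg$fa)^ccg$n3 else
      rep(1, length(times)))
  cv <- apply(fac, 2, pop_cv)
  cv[c(if (ccg$n1 == 0) c("BMAL1", "PER2", "CRY1"),
       if (ccg$n2 == 0) "REVERBA", if (ccg$n3 == 0) "DBP")] <- 0
  structure(list(time_h = times, factors = fac, cv = cv,
                 tissue = core$tissue, gene = ccg$gene, period = period),
            class = "regfac_series")
}

# population coefficient of variation (SD with denominator n)
pop_cv <- function(v) {
  m <- mean(v)
  if (m == 0) return(0)
  sqrt(mean((v - m)^2)) / m
}

#' Percent difference of two coefficients of variation
#'
#' `(max - min) / max * 100`; by convention 0 when both CVs are 0.
#'
#' @param cv_i,cv_j non-negative coefficients of variation.
#' @return percent in `[0, 100]`.
#' @export
delta_cv_percent <- function(cv_i, cv_j) {
  if (any(c(cv_i, cv_j) < 0)) stop("CV must be >= 0")
  hi <- pmax(cv_i, cv_j)
  lo <- pmin(cv_i, cv_j)
  ifelse(hi == 0, 0, (hi - lo) / hi * 100)
}

#' @export
print.regfac_series <- function(x, ...) {
  cat(sprintf("regulation factors [%s%s]: one cycle of %.3g h, CVs:\n",
              x$gene, if (!is.null(x$tissue) && !is.na(x$tissue))
                paste0(" in ", x$tissue) else "", x$period))
  print(round(x$cv, 4))
  invisible(x)
}

#' Tidy export of a regulation-factor series
#'
#' @param x `regfac_series`.
#' @param normalize divide each factor by its own cycle mean (plotting
#'   convention); the dynamics always use the unnormalized factors.
#' @param ... unused.
#' @return data.frame: tissue, gene, factor, time_h, value.
#' @export
as.data.frame.regfac_series <- function(x, ..., normalize = FALSE) {
  fac <- x$factors
  if (normalize) fac <- sweep(fac, 2, colMeans(fac), "/")
  data.frame(tissue = if (is.null(x$tissue)) NA_character_ else x$tissue,
             gene = x$gene,
             factor = rep(colnames(fac), each = length(x$time_h)),
             time_h = rep(x$time_h, ncol(fac)),
             value = as.vector(fac), stringsAsFactors = FALSE)
}

#' Phase lag versus regulation-factor variability for tissue pairs
#'
#' For each entry (one gene observed in two tissues, with per-tissue CCG
#' parameters and core trajectories), simulates the CCG in both tissues,
#' estimates its phase in each, and tabulates the circular phase difference
#' together with the five ΔCV% statistics of the regulation factors.
#' Undefined phases are flagged, not dropped.
#'
#' @param entries list; each element a list with fields `gene`, `tissues`
#'   (character pair), `ccg` (list of two `ccg_params`), `core` (list of two
#'   core `dde_traj`).
#' @return data.frame: gene, tissue_i, tissue_j, phase_diff_rad,
#'   dcv_bmal1..dcv_dbp (percent), flag.
#' @export
phase_vs_regfac_table <- function(entries) {
  rows <- lapply(entries, function(e) {
    stopifnot(length(e$tissues) == 2, length(e$ccg) == 2,
              length(e$core) == 2)
    ph <- numeric(2)
    flag <- "ok"
    cvs <- matrix(0, 2, 5, dimnames = list(NULL, REGFAC_NAMES))
    for (k in 1:2) {
      core <- e$core[[k]]
      ccg <- e$ccg[[k]]
      period <- estimate_period(core)
      rf <- regulation_factors(core, ccg, period = period)
      cvs[k, ] <- rf$cv[REGFAC_NAMES]
      traj <- simulate_ccg(ccg, core)
      pe <- withCallingHandlers(
        estimate_phase(traj, 1, period = period),
        warning = function(w) invokeRestart("muffleWarning"))
      if (pe$flag != "ok") flag <- "undefined_phase"
      ph[k] <- pe$phase
    }
    dcv <- vapply(REGFAC_NAMES, function(f)
      delta_cv_percent(cvs[1, f], cvs[2, f]), numeric(1))
    data.frame(gene = e$gene, tissue_i = e$tissues[1],
               tissue_j = e$tissues[2],
               phase_diff_rad = if (flag == "ok")
                 phase_difference(ph[1], ph[2]) else NA_real_,
               dcv_bmal1 = dcv["BMAL1"], dcv_per2 = dcv["PER2"],
               dcv_cry1 = dcv["CRY1"], dcv_reverba = dcv["REVERBA"],
               dcv_dbp = dcv["DBP"], flag = flag,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Rank correlation between |phase difference| and each ΔCV%
#'
#' Reported without thresholding; use to ask whether regulation-factor
#' variability tracks inter-tissue phase lags.
#'
#' @param tbl output of [phase_vs_regfac_table()].
#' @param method correlation method (default Spearman).
#' @return data.frame: factor, rho, n.
#' @export
regfac_phase_correlation <- function(tbl, method = "spearman") {
  ok <- tbl$flag == "ok" & is.finite(tbl$phase_diff_rad)
  x <- abs(tbl$phase_diff_rad[ok])
  cols <- c(BMAL1 = "dcv_bmal1", PER2 = "dcv_per2", CRY1 = "dcv_cry1",
            REVERBA = "dcv_reverba", DBP = "dcv_dbp")
  rows <- lapply(names(cols), function(f) {
    y <- tbl[[cols[f]]][ok]
    rho <- if (length(x) >= 3 && sd(x) > 0 && sd(y) > 0)
      cor(x, y, method = method) else NA_real_
    data.frame(factor = f, rho = rho, n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
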