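# Bounded nonlinear least squares for clock parameters, with Wald CIs.
#
# The model is free-running while the data clock is lights-on-referenced,
# so every fit carries one global time-offset parameter (bounded, excluded
# from the reported CI set) that aligns the limit cycle to clock time.
# Simulated profiles are divided by their cycle mean before residuals are
# formed (the data oscillate around 1).

#' Fit specification for clock model estimation
#'
#' Bounds follow literature ranges: transcriptional delays up to 8 h, mRNA
#' degradation rates spanning reported decay ranges (e.g. Per2 between 0.24
#' and 0.8 per hour; the default box is deliberately wider and shared by
#' all genes).
#'
#' @param free names of free parameters (default: the five delays and five
#'   degradation rates).
#' @param lower,upper named bounds for the free parameters.
#' @param fixed full parameter set supplying everything not fitted.
#' @param offset_bounds bounds (hours) of the global time-offset alignment
#'   parameter.
#' @param burn_in,sim_window simulation burn-in and analysis window (hours)
#'   used when computing residuals.
#' @param rel_tol,abs_tol,hmax integrator controls during fitting.
#' @param fd_rel_step relative forward-difference step for the Wald-CI
#'   Jacobian.  The default 1e-3 sits well above the integrator's
#'   discretization noise (smaller steps yield noise-inflated Jacobians
#'   and spuriously narrow intervals); 1e-6 is appropriate for
#'   analytically smooth residual functions.
#' @param penalty residual value substituted (per data point) when a
#'   parameter set fails to oscillate or integrate, so optimizers can
#'   retreat from pathological regions.
#' @param n_starts multi-start count: number of local searches run from
#'   the best screened candidates.
#' @param n_screen size of the seeded Latin-hypercube candidate pool the
#'   starts are screened from (one residual evaluation each).
#' @param n_hops basin-hopping refinements around each converged local
#'   search (perturb, short re-fit, keep improvements).
#' @param grad_rel_step relative forward-difference step for the
#'   optimizer's Jacobian.
#' @return list of class `clock_fit_spec`.
#' @export
clock_fit_spec <- function(free = names(default_clock_bounds()$lower),
                           lower = default_clock_bounds()$lower[free],
                           upper = default_clock_bounds()$upper[free],
                           fixed = clock_params("All-tissues"),
                           offset_bounds = c(-12, 12),
                           burn_in = 240, sim_window = 72,
                           rel_tol = 1e-5, abs_tol = 1e-8, hmax = 0.5,
                           fd_rel_step = 1e-3, penalty = 10,
                           n_starts = 5, n_screen = 150, n_hops = 4,
                           grad_rel_step = 1e-3) {
  lower <- unlist(lower)[free]
  upper <- unlist(upper)[free]
  if (any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper))
    stop("bounds must be finite with lower < upper for every free parameter")
  structure(list(free = free, lower = lower, upper = upper, fixed = fixed,
                 offset_bounds = offset_bounds, burn_in = burn_in,
                 sim_window = sim_window, rel_tol = rel_tol,
                 abs_tol = abs_tol, hmax = hmax, fd_rel_step = fd_rel_step,
                 penalty = penalty, n_starts = n_starts,
                 n_screen = n_screen, n_hops = n_hops,
                 grad_rel_step = grad_rel_step),
            class = "clock_fit_spec")
}

#' Default box constraints for core-clock delays and degradation rates
#' @return list with named vectors `lower` and `upper`.
#' @export
default_clock_bounds <- function() {
  taus <- paste0("tau_", CLOCK_GENES)
  ds <- paste0("d_", CLOCK_GENES)
  list(lower = setNames(c(rep(0.1, 5), rep(0.05, 5)), c(taus, ds)),
       upper = setNames(c(rep(8, 5), rep(1.5, 5)), c(taus, ds)))
}

# canonical residual ordering: tissue, gene, time, replicate
canonical_order <- function(df) {
  df[order(df$tissue, df$gene, df$time_h, df$replicate), , drop = FALSE]
}

#' Normalized model profile at observation times
#'
#' Divides each simulated gene by its mean over one period starting at the
#' analysis window, then evaluates at `window_start + offset + times`.
#' Shared by the synthetic-data generator and the residual function.
#'
#' @param traj `dde_traj`.
#' @param times observation times (hours after lights-on).
#' @param period cycle length; estimated from the first variable if NULL.
#' @param offset global alignment offset (hours).
#' @param dt grid spacing for the cycle-mean quadrature.
#' @return matrix `length(times)` x variables, oscillating around 1.
#' @export
model_profile <- function(traj, times, period = NULL, offset = 0,
                          dt = 0.05) {
  if (is.null(period)) period <- estimate_period(traj)
  ws <- traj$window_start
  grid <- seq(ws, ws + period, by = dt)
  grid <- grid[grid < ws + period]
  means <- colMeans(dde_evaluate(traj, grid))
  m <- dde_evaluate(traj, ws + offset + times)
  sweep(m, 2, means, "/")
}

#' Residuals of the core-clock model against time-course data
#'
#' Simulates once with the candidate parameters (shared across tissues:
#' the consensus structure), normalizes each gene to cycle mean 1, and
#' subtracts the observations (residual = model - data), stacked in
#' canonical order (tissue, gene, time, replicate).  Non-oscillatory or
#' non-integrable parameter sets yield a constant penalty residual.
#'
#' @param par named vector of free parameters, plus `offset` if present.
#' @param data time-course data.frame (tissue, gene, time_h, replicate,
#'   value).
#' @param spec `clock_fit_spec`.
#' @return numeric residual vector with attribute `"penalized"`.
#' @export
clock_residuals <- function(par, data, spec) {
  make_clock_residfun(data, spec)(par)
}

# build the residual closure once: data sorted canonically, observation
# indices precomputed, so each evaluation is one simulation plus lookups
make_clock_residfun <- function(data, spec) {
  data <- canonical_order(data)
  ut <- sort(unique(data$time_h))
  row_i <- match(data$time_h, ut)
  col_i <- match(data$gene, CLOCK_GENES)
  if (anyNA(col_i)) stop("unknown gene in data: ",
                         paste(unique(data$gene[is.na(col_i)]),
                               collapse = ", "))
  obs <- data$value
  npt <- length(obs)
  function(par) {
    offset <- if ("offset" %in% names(par)) par[["offset"]] else 0
    params <- spec$fixed
    free <- setdiff(names(par), "offset")
    params[free] <- as.list(par[free])
    r <- tryCatch({
      traj <- simulate_core_clock(core_clock_parameters(base = params),
                                  duration = spec$sim_window,
                                  burn_in = spec$burn_in,
                                  rel_tol = spec$rel_tol,
                                  abs_tol = spec$abs_tol, hmax = spec$hmax)
      period <- estimate_period(traj, dt = 0.1)
      prof <- model_profile(traj, ut, period = period, offset = offset,
                            dt = 0.1)
      # flat (non-oscillatory) profiles normalize to ~1 everywhere;
      # treat them as non-oscillatory rather than fitting noise
      if (max(abs(prof - 1)) < 0.02) NULL else
        prof[cbind(row_i, col_i)] - obs
    }, error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) {
      r <- rep(spec$penalty, npt)
      attr(r, "penalized") <- TRUE
    } else {
      attr(r, "penalized") <- FALSE
    }
    r
  }
}

# choose a starting alignment offset for a candidate parameter set by
# matching the simulated Bmal1 peak to the data's replicate-mean Bmal1 peak
init_offset <- function(par, data, spec) {
  off <- tryCatch({
    params <- spec$fixed
    free <- setdiff(names(par), "offset")
    params[free] <- as.list(par[free])
    traj <- simulate_core_clock(core_clock_parameters(base = params),
                                duration = spec$sim_window,
                                burn_in = spec$burn_in,
                                rel_tol = spec$rel_tol,
                                abs_tol = spec$abs_tol, hmax = spec$hmax)
    period <- estimate_period(traj, dt = 0.1)
    pm <- estimate_phase(traj, "Bmal1", period = period)$peak_time
    pd <- estimate_phase(data[data$gene == "Bmal1", , drop = FALSE],
                         period = 24)$peak_time
    d <- (pm - pd) %% period
    if (d > period / 2) d <- d - period
    d
  }, error = function(e) 0)
  min(max(off, spec$offset_bounds[1]), spec$offset_bounds[2])
}

# ------------------------------------------------------------- generic LS core

#' Bounded least-squares fit of a residual function
#'
#' Minimizes `sum(resid_fn(par)^2)` with box constraints via
#' `stats::nlminb`, recording an iteration trace.  This generic core backs
#' all clock fits and is also usable directly (e.g. for linear-regression
#' oracles).
#'
#' @param resid_fn function of a named parameter vector returning residuals
#'   (model minus data).
#' @param start named start vector.
#' @param lower,upper bounds (same names/order as `start`).
#' @param fd_rel_step relative step used later for the Wald-CI Jacobian.
#' @param grad_rel_step relative forward-difference step for the
#'   optimizer's Jacobian.  Chosen well above the integrator's
#'   discretization noise (steps near sqrt(machine eps) would drown in it).
#' @param max_iter iteration cap for the Levenberg-Marquardt loop.
#' @param ci_exclude parameter names excluded from CI reporting (e.g. the
#'   alignment offset).
#' @return object of class `clock_fit`: estimates, objective, residuals,
#'   convergence info (including the monotone accepted-iteration `trace`),
#'   and everything [wald_ci()] needs.
#' @export
ls_fit <- function(resid_fn, start, lower = -Inf, upper = Inf,
                   fd_rel_step = 1e-6, grad_rel_step = 1e-3,
                   max_iter = 200, ci_exclude = character(0)) {
  stopifnot(!is.null(names(start)))
  res <- lm_bounded(resid_fn, start,
                    rep_len(lower, length(start)),
                    rep_len(upper, length(start)),
                    max_iter = max_iter, fd_rel_step = grad_rel_step)
  par <- setNames(res$par, names(start))
  r <- resid_fn(par)
  structure(list(par = par, objective = res$objective, residuals = r,
                 convergence = res$convergence, message = res$message,
                 iterations = res$iterations,
                 lower = rep_len(lower, length(par)),
                 upper = rep_len(upper, length(par)),
                 resid_fn = resid_fn, fd_rel_step = fd_rel_step,
                 ci_exclude = ci_exclude, trace = res$trace,
                 n_obs = length(r)),
            class = "clock_fit")
}

# Box-constrained Levenberg-Marquardt with a forward-difference Jacobian.
# Steps are clipped to the box; the damping factor adapts on rejection.
# The returned trace holds the objective after each ACCEPTED iteration and
# is non-increasing by construction.
lm_bounded <- function(resid_fn, start, lower, upper, max_iter = 200,
                       fd_rel_step = 1e-3, ftol = 1e-8) {
  p <- pmin(pmax(start, lower), upper)
  names(p) <- names(start)
  r <- resid_fn(p)
  obj <- sum(r^2)
  trace <- obj
  lambda <- 1e-3
  msg <- "iteration limit reached"
  conv <- 1L
  it <- 0L
  n_small <- 0L
  while (it < max_iter) {
    it <- it + 1L
    J <- matrix(0, length(r), length(p))
    for (j in seq_along(p)) {
      h <- fd_rel_step * max(abs(p[j]), 1e-2)
      pj <- p
      pj[j] <- pj[j] + h
      J[, j] <- (resid_fn(pj) - r) / h
    }
    g <- crossprod(J, r)
    JtJ <- crossprod(J)
    dd <- diag(JtJ) + 1e-10
    improved <- FALSE
    for (tries in 1:10) {
      step <- tryCatch(solve(JtJ + lambda * diag(dd, length(dd)), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        pn <- pmin(pmax(p + as.numeric(step), lower), upper)
        rn <- resid_fn(pn)
        on <- sum(rn^2)
        if (is.finite(on) && on < obj) {
          n_small <- if ((obj - on) < ftol * (obj + 1e-12))
            n_small + 1L else 0L
          p <- pn; r <- rn; obj <- on
          trace <- c(trace, obj)
          lambda <- max(lambda / 3, 1e-12)
          improved <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved) {
      msg <- "no improving step found"
      conv <- 0L
      break
    }
    if (n_small >= 2L) {  # two consecutive negligible decreases
      msg <- "relative objective decrease below ftol"
      conv <- 0L
      break
    }
  }
  list(par = p, objective = obj, trace = trace, iterations = it,
       convergence = conv, message = msg)
}

#' @export
print.clock_fit <- function(x, ...) {
  cat(sprintf("least-squares fit: %d parameters, %d residuals, SSR = %.4g\n",
              length(x$par), x$n_obs, x$objective))
  print(signif(x$par, 4))
  invisible(x)
}

# Latin hypercube starts within bounds (start 1 = box midpoint; rate-like
# parameters, i.e. names starting with "d" or all-positive boxes spanning
# more than a decade, are sampled log-uniformly as is standard for rates)
lhs_starts <- function(n, lower, upper, seed) {
  k <- length(lower)
  loggish <- lower > 0 & upper / lower > 10
  mid <- (lower + upper) / 2
  mid[loggish] <- sqrt(lower[loggish] * upper[loggish])
  starts <- list(setNames(mid, names(lower)))
  if (n > 1) {
    set.seed(seed)
    for (i in seq_len(n - 1)) {
      u <- (sample(n - 1, k, replace = TRUE) - runif(k)) / (n - 1)
      s <- lower + u * (upper - lower)
      s[loggish] <- exp(log(lower[loggish]) +
                          u[loggish] * (log(upper[loggish]) -
                                          log(lower[loggish])))
      starts[[i + 1]] <- setNames(s, names(lower))
    }
  }
  starts
}

# basin-hopping refinement around a converged fit: perturb, re-run a short
# LM, keep improvements (seeded by the caller's RNG state).  `realign`
# optionally re-derives alignment-type parameters for a proposal (e.g. the
# time offset), which lets hops escape phase-misassignment minima.
hop_refine <- function(resid_fn, fit, lower, upper, hops = 8,
                       grad_rel_step = 1e-3, realign = NULL) {
  best <- fit
  k <- length(best$par)
  for (h in seq_len(hops)) {
    p <- best$par
    pick <- runif(k) < 0.5
    if (!any(pick)) pick[sample.int(k, 1)] <- TRUE
    scale <- (upper - lower)
    p[pick] <- p[pick] + rnorm(sum(pick), 0, 0.15 * scale[pick])
    p <- pmin(pmax(p, lower), upper)
    if (!is.null(realign) && h %% 2 == 0) p <- realign(p)
    cand <- lm_bounded(resid_fn, p, lower, upper, max_iter = 20,
                       fd_rel_step = grad_rel_step)
    if (cand$objective < best$objective)
      best[c("par", "objective", "trace", "iterations", "convergence",
             "message")] <- cand[c("par", "objective", "trace",
                                   "iterations", "convergence", "message")]
  }
  best
}

#' Fit core-clock delays and degradation rates to time-course data
#'
#' Box-constrained least squares with seeded Latin-hypercube multi-start;
#' the best objective wins (ties broken by first index).  A single
#' parameter vector is shared by all tissues present in `data`, so passing
#' one tissue gives a per-tissue fit and passing several gives the
#' consensus fit.
#'
#' @param data time-course data.frame (tissue, gene, time_h, replicate,
#'   value), values normalized around 1.
#' @param spec `clock_fit_spec`.
#' @param start optional named start vector (free parameters, optionally
#'   `offset`); used as the first start.
#' @param seed seed for the multi-start draw.
#' @return `clock_fit` with elements `starts` (per-start diagnostics) and
#'   `spec`.
#' @export
fit_core_clock <- function(data, spec = clock_fit_spec(), start = NULL,
                           seed = 1) {
  data <- validate_timecourse(data)
  lower <- c(spec$lower, offset = spec$offset_bounds[1])
  upper <- c(spec$upper, offset = spec$offset_bounds[2])
  resid_fn <- make_clock_residfun(data, spec)
  # seeded candidate pool; each local search starts from one of the best
  # screened candidates (standard sample-and-select multi-start)
  cands <- lhs_starts(max(spec$n_screen, spec$n_starts), lower, upper, seed)
  if (!is.null(start)) {
    s0 <- cands[[1]]
    s0[names(start)] <- start
    cands[[1]] <- s0
  }
  # phase-align every candidate: the offset landscape is multimodal, so
  # start the alignment offset where the simulated Bmal1 peak matches the
  # data's replicate-mean Bmal1 peak
  cands <- lapply(cands, function(s) {
    s["offset"] <- init_offset(s, data, spec)
    s
  })
  screen <- vapply(cands, function(s) sum(resid_fn(s)^2), numeric(1))
  picked <- order(screen)[seq_len(spec$n_starts)]
  realign <- function(p) {
    p["offset"] <- init_offset(p, data, spec)
    p
  }
  fits <- lapply(picked, function(i)
    tryCatch({
      f <- lm_bounded(resid_fn, cands[[i]], lower, upper,
                      max_iter = 100, fd_rel_step = spec$grad_rel_step)
      hop_refine(resid_fn, f, lower, upper, hops = spec$n_hops,
                 grad_rel_step = spec$grad_rel_step, realign = realign)
    }, error = function(e) e))
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) {
    msgs <- vapply(fits, conditionMessage, character(1))
    stop("all starts failed:\n", paste(" -", msgs, collapse = "\n"))
  }
  objs <- vapply(fits, function(f) if (!inherits(f, "error"))
    f$objective else Inf, numeric(1))
  res <- fits[[which.min(objs)]]
  # final coordinate polish on the winner: one-at-a-time perturbations
  # followed by short refits resolve near-degenerate single-parameter
  # misassignments left by the joint search
  for (j in seq_along(res$par)) {
    for (fac in c(0.7, 1.4)) {
      p <- res$par
      p[j] <- p[j] * fac
      p <- pmin(pmax(p, lower), upper)
      cand <- lm_bounded(resid_fn, p, lower, upper, max_iter = 10,
                         fd_rel_step = spec$grad_rel_step)
      if (cand$objective < res$objective) res <- cand
    }
  }
  par <- setNames(res$par, names(lower))
  best <- structure(list(par = par, objective = res$objective,
                         residuals = resid_fn(par),
                         convergence = res$convergence,
                         message = res$message,
                         iterations = res$iterations,
                         lower = lower, upper = upper,
                         resid_fn = resid_fn,
                         fd_rel_step = spec$fd_rel_step,
                         ci_exclude = "offset", trace = res$trace,
                         n_obs = nrow(data)),
                    class = "clock_fit")
  best$starts <- data.frame(start = seq_along(picked),
                            candidate = picked,
                            objective = objs, ok = ok)
  best$screen_objectives <- screen
  best$spec <- spec
  best$seed <- seed
  best
}

#' Consensus fit across tissues
#'
#' Convenience wrapper around [fit_core_clock()] emphasizing that residuals
#' from all tissues are stacked against a single shared parameter vector.
#'
#' @inheritParams fit_core_clock
#' @export
fit_consensus <- function(data, spec = clock_fit_spec(), start = NULL,
                          seed = 1) {
  fit_core_clock(data, spec, start = start, seed = seed)
}

#' Fit CCG parameters to time-course data over a fixed core trajectory
#'
#' Estimates the CCG fold changes (b, f), dissociation constants (ba, cr,
#' gr, ar, fa) and degradation rate (d) for one gene in one tissue, with
#' the Ebox/RRE/Dbox exponents fixed from the promoter scan and the core
#' trajectory fixed from the consensus fit.  Parameters whose element count
#' is zero are structurally unidentifiable and held fixed.
#'
#' @param data time-course rows for this gene/tissue (tissue, gene, time_h,
#'   replicate, value).
#' @param core core-clock `dde_traj` (consensus model).
#' @param counts integer vector `c(n1, n2, n3)`.
#' @param lower,upper named bounds for the 8 CCG parameters.
#' @param offset fixed alignment offset (hours), typically the core fit's.
#' @param start optional named start; default geometric mid-box.
#' @param n_starts multi-start count.
#' @param seed seed for multi-start.
#' @param fd_rel_step Jacobian step for [wald_ci()].
#' @return `clock_fit`; element `predicted` holds predicted-vs-observed
#'   pairs for identity-line evaluation.
#' @export
fit_ccg <- function(data, core, counts,
                    lower = c(b = 1.01, ba = 0.01, cr = 0.01, gr = 0.01,
                              ar = 0.01, f = 1.01, fa = 0.01, d = 0.05),
                    upper = c(b = 40, ba = 50, cr = 50, gr = 50, ar = 50,
                              f = 40, fa = 50, d = 1.5),
                    offset = 0, start = NULL, n_starts = 5, seed = 1,
                    fd_rel_step = 1e-3) {
  data <- validate_timecourse(data)
  gene <- as.character(data$gene[1])
  counts <- as.integer(counts)
  if (all(counts == 0) && sd(data$value) > 0.05)
    warning("structurally flat model: n1 = n2 = n3 = 0 but data appear rhythmic")
  active <- c(if (counts[1] > 0) c("b", "ba", "cr", "gr"),
              if (counts[2] > 0) "ar",
              if (counts[3] > 0) c("f", "fa"), "d")
  period <- estimate_period(core)
  resid_fn <- function(p) {
    full <- c(b = 2, ba = 1, cr = 1, gr = 1, ar = 1, f = 2, fa = 1, d = 0.3)
    full[names(p)] <- p
    r <- tryCatch({
      ccg <- ccg_parameters(b = full["b"], ba = full["ba"], cr = full["cr"],
                            gr = full["gr"], ar = full["ar"], f = full["f"],
                            fa = full["fa"], d = full["d"],
                            n1 = counts[1], n2 = counts[2], n3 = counts[3],
                            gene = gene)
      traj <- simulate_ccg(ccg, core)
      ut <- sort(unique(data$time_h))
      prof <- model_profile(traj, ut, period = period, offset = offset)
      pred <- prof[match(data$time_h, ut), 1]
      pred - data$value
    }, error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) r <- rep(10, nrow(data))
    r
  }
  lo <- lower[active]
  up <- upper[active]
  starts <- lhs_starts(n_starts, lo, up, seed)
  if (!is.null(start)) {
    s0 <- starts[[1]]
    s0[intersect(names(start), active)] <-
      start[intersect(names(start), active)]
    starts[[1]] <- s0
  }
  fits <- lapply(starts, function(s)
    tryCatch(ls_fit(resid_fn, s, lo, up, fd_rel_step = fd_rel_step),
             error = function(e) e))
  ok <- !vapply(fits, inherits, logical(1), "error")
  if (!any(ok)) stop("all CCG starts failed for ", gene)
  objs <- vapply(fits, function(f) if (inherits(f, "clock_fit"))
    f$objective else Inf, numeric(1))
  best <- fits[[which.min(objs)]]
  best$starts <- data.frame(start = seq_along(starts), objective = objs,
                            ok = ok)
  best$gene <- gene
  best$counts <- counts
  best$predicted <- data.frame(
    tissue = data$tissue, gene = gene, time_h = data$time_h,
    replicate = data$replicate, observed = data$value,
    predicted = data$value + resid_fn(best$par))
  best
}

# ------------------------------------------------------------------- Wald CIs

# forward finite-difference Jacobian of a residual function
fd_jacobian <- function(resid_fn, par, rel_step = 1e-6) {
  r0 <- resid_fn(par)
  J <- matrix(0, length(r0), length(par),
              dimnames = list(NULL, names(par)))
  for (j in seq_along(par)) {
    h <- rel_step * max(abs(par[j]), 1e-8)
    pj <- par
    pj[j] <- pj[j] + h
    J[, j] <- (resid_fn(pj) - r0) / h
  }
  J
}

#' Wald (normal) confidence intervals for a least-squares fit
#'
#' Interval `p_hat +/- t(0.975, df) * sqrt(diag(v))` with covariance
#' `v = (J'J)^{-1} sigma^2`, `J` the residual Jacobian and `df = n - k`.
#' The residual variance defaults to the standard estimator
#' `sigma^2 = sum(r^2) / df`; `sigma_mode = "literal"` instead uses
#' `sqrt(sum(r^2)) / df` (the unsquared-norm variant) for reproduction
#' experiments.
#'
#' @param fit `clock_fit`.
#' @param level confidence level (default 0.95).
#' @param sigma_mode `"standard"` or `"literal"` (see above).
#' @return data.frame: parameter, estimate, se, ci_lo, ci_hi, df, plus
#'   attribute `"singular"` if `J'J` needed a pseudo-inverse.
#' @export
wald_ci <- function(fit, level = 0.95, sigma_mode = c("standard", "literal")) {
  stopifnot(inherits(fit, "clock_fit"))
  sigma_mode <- match.arg(sigma_mode)
  par <- fit$par
  # the Jacobian spans ALL fitted parameters, nuisance ones (e.g. the
  # alignment offset) included: excluded parameters are marginalized over,
  # not conditioned on, so the reported variances are the full ones
  keep <- setdiff(names(par), fit$ci_exclude)
  J <- fd_jacobian(fit$resid_fn, par, rel_step = fit$fd_rel_step)
  r <- fit$residuals
  df <- length(r) - length(par)
  if (df <= 0) stop("degrees of freedom must be positive for Wald CIs")
  ssr <- sum(r^2)
  sigma2 <- if (sigma_mode == "standard") ssr / df else sqrt(ssr) / df
  JtJ <- crossprod(J)
  singular <- FALSE
  vmat <- tryCatch(solve(JtJ) * sigma2, error = function(e) NULL)
  if (is.null(vmat)) {
    singular <- TRUE
    warning("J'J is singular; using pseudo-inverse (non-identifiable ",
            "parameters flagged)")
    sv <- svd(JtJ)
    pos <- sv$d > max(sv$d) * 1e-12
    vmat <- (sv$v[, pos, drop = FALSE] %*%
               (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])) * sigma2
  }
  se_all <- setNames(sqrt(pmax(diag(vmat), 0)), names(par))
  se <- se_all[keep]
  tq <- qt(1 - (1 - level) / 2, df)
  out <- data.frame(parameter = keep, estimate = unname(par[keep]),
                    se = unname(se), ci_lo = unname(par[keep] - tq * se),
                    ci_hi = unname(par[keep] + tq * se), df = df,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "singular") <- singular
  attr(out, "sigma2") <- sigma2
  out
}
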