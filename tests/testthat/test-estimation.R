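# Least-squares machinery and Wald confidence intervals.

test_that("wald_ci matches the closed-form simple-regression oracle", {
  # y = p * x with x = (1, 2), y = (2, 4.3): p_hat = 10.6/5 = 2.12,
  # SSR = 0.018, df = 1, var = sigma^2 / sum(x^2), half-width
  # = qt(0.975, 1) * sqrt(0.018/5)
  fit <- ls_fit(function(p) p[["p"]] * c(1, 2) - c(2, 4.3), c(p = 1))
  expect_equal(unname(fit$par), 2.12, tolerance = 1e-8)
  ci <- wald_ci(fit)
  half_oracle <- qt(0.975, 1) * sqrt((0.018 / 1) / 5)
  expect_equal((ci$ci_hi - ci$ci_lo) / 2, half_oracle, tolerance = 1e-10)
  expect_equal(ci$estimate, 2.12, tolerance = 1e-8)
  # general linear model: wald_ci equals lm()'s confint
  set.seed(1)
  X <- cbind(1, rnorm(20), runif(20))
  beta <- c(0.5, -1.2, 2)
  y <- X %*% beta + rnorm(20, sd = 0.3)
  fitl <- ls_fit(function(p) as.numeric(X %*% p) - as.numeric(y),
                 c(b0 = 0, b1 = 0, b2 = 0))
  cil <- wald_ci(fitl)
  ref <- confint(lm(y ~ X - 1))
  expect_equal(cil$ci_lo, unname(ref[, 1]), tolerance = 1e-6)
  expect_equal(cil$ci_hi, unname(ref[, 2]), tolerance = 1e-6)
})

test_that("zero residuals give zero-width intervals at the estimate", {
  fit <- ls_fit(function(p) p[["a"]] * c(1, 2, 3) - c(2, 4, 6), c(a = 1))
  ci <- wald_ci(fit)
  expect_equal(ci$estimate, 2, tolerance = 1e-8)
  expect_equal(ci$ci_hi - ci$ci_lo, 0, tolerance = 1e-6)
})

test_that("literal sigma mode uses the unsquared residual norm", {
  fit <- ls_fit(function(p) p[["p"]] * c(1, 2) - c(2, 4.3), c(p = 1))
  s_std <- attr(wald_ci(fit), "sigma2")
  s_lit <- attr(wald_ci(fit, sigma_mode = "literal"), "sigma2")
  expect_equal(s_std, 0.018, tolerance = 1e-8)
  expect_equal(s_lit, sqrt(0.018) / 1, tolerance = 1e-8)
})

test_that("singular designs fall back to a flagged pseudo-inverse", {
  # two perfectly collinear parameters
  fit <- ls_fit(function(p) (p[["a"]] + p[["b"]]) * c(1, 2, 3) - c(2, 4, 6.3),
                c(a = 1, b = 1))
  expect_warning(ci <- wald_ci(fit), "singular|pseudo")
  expect_true(attr(ci, "singular"))
})

test_that("df must be positive for intervals", {
  fit <- ls_fit(function(p) p[["a"]] - 3, c(a = 0))
  expect_error(wald_ci(fit), "degrees of freedom")
})

test_that("residual stacking matches an independent implementation", {
  truth <- clock_params("All-tissues")
  gen <- generate_timecourse(list(A = truth, B = truth), noise_cv = 0.1,
                             seed = 3)
  spec <- clock_fit_spec()
  par <- c(unlist(truth[spec$free]), offset = 0)
  r <- clock_residuals(par, gen$data, spec)
  expect_false(attr(r, "penalized"))
  # independent stacking: loop over tissues/genes/times/replicates in
  # canonical order and subtract the shared normalized profile
  traj <- simulate_core_clock(truth, duration = spec$sim_window,
                              burn_in = spec$burn_in,
                              rel_tol = spec$rel_tol,
                              abs_tol = spec$abs_tol, hmax = spec$hmax)
  prof <- model_profile(traj, CIRCADIAN_GRID,
                        period = estimate_period(traj, dt = 0.1), dt = 0.1)
  d <- gen$data[order(gen$data$tissue, gen$data$gene, gen$data$time_h,
                      gen$data$replicate), ]
  r2 <- numeric(0)
  for (i in seq_len(nrow(d)))
    r2 <- c(r2, prof[match(d$time_h[i], CIRCADIAN_GRID),
                     match(d$gene[i], CLOCK_GENES)] - d$value[i])
  expect_equal(sum(r^2), sum(r2^2), tolerance = 1e-12)
})

test_that("noise-free residuals at truth are essentially zero", {
  truth <- clock_params("All-tissues")
  gen <- generate_timecourse(list(A = truth), noise_cv = 0, seed = 1)
  # fit spec at the generator's integration accuracy (the default fitting
  # spec trades ~1e-3 of dense-output accuracy for speed)
  spec <- clock_fit_spec(rel_tol = 1e-6, abs_tol = 1e-9, hmax = 0.25)
  r <- clock_residuals(c(unlist(truth[spec$free]), offset = 0),
                       gen$data, spec)
  expect_lt(max(abs(r)), 1e-3)
  # a single displaced observation shows up as exactly one residual
  d2 <- gen$data
  i <- which(d2$gene == "Per2" & d2$time_h == 6 & d2$replicate == 2)
  d2$value[i] <- d2$value[i] + 0.5
  r2 <- clock_residuals(c(unlist(truth[spec$free]), offset = 0), d2, spec)
  expect_equal(sort(abs(r2 - r), decreasing = TRUE)[1], 0.5,
               tolerance = 1e-9)
  expect_lt(sort(abs(r2 - r), decreasing = TRUE)[2], 1e-12)
  expect_equal(r2[which.max(abs(r2 - r))], r[which.max(abs(r2 - r))] - 0.5,
               tolerance = 1e-9)
})

test_that("non-oscillatory parameters give the penalty residual", {
  spec <- clock_fit_spec()
  # near-zero delays with fast degradation: stable fixed point
  par <- c(setNames(rep(0.2, 5), paste0("tau_", CLOCK_GENES)),
           setNames(rep(1.5, 5), paste0("d_", CLOCK_GENES)),
           offset = 0)
  gen <- generate_timecourse(list(A = clock_params()), noise_cv = 0,
                             seed = 1)
  r <- clock_residuals(par, gen$data, spec)
  expect_true(attr(r, "penalized"))
  expect_true(all(r == spec$penalty))
  expect_true(all(is.finite(r)))
})

test_that("fit from truth stays at truth on noise-free data", {
  truth <- clock_params("All-tissues")
  gen <- generate_timecourse(list(A = truth), noise_cv = 0, seed = 1)
  spec <- clock_fit_spec(n_starts = 1, n_screen = 1, n_hops = 0)
  tv <- unlist(truth[spec$free])
  # make the data exactly self-consistent with the fitting path, so the
  # optimum is at truth with zero residuals (tests optimizer
  # stationarity, not quadrature mismatch between generator and fitter)
  r0 <- clock_residuals(c(tv, offset = 0), gen$data, spec)
  gen$data$value <- gen$data$value + r0
  fit <- fit_core_clock(gen$data, spec, start = c(tv, offset = 0),
                        seed = 1)
  expect_lt(fit$objective, 1e-4)
  expect_equal(unname(fit$par[spec$free]), unname(tv), tolerance = 1e-3)
  # bounds respected
  expect_true(all(fit$par >= fit$lower - 1e-12 &
                    fit$par <= fit$upper + 1e-12))
  # accepted-iteration trace is monotone non-increasing
  expect_true(all(diff(fit$trace) <= 0))
})

test_that("consensus on identical tissues equals the single-tissue fit", {
  truth <- clock_params("All-tissues")
  one <- generate_timecourse(list(A = truth), noise_cv = 0, seed = 1)
  spec <- clock_fit_spec(n_starts = 1, n_screen = 1, n_hops = 0)
  tv <- unlist(truth[spec$free])
  # self-consistent data: optimum exactly at truth in both problems
  r0 <- clock_residuals(c(tv, offset = 0), one$data, spec)
  one$data$value <- one$data$value + r0
  f1 <- fit_core_clock(one$data, spec, start = c(tv, offset = 0), seed = 1)
  both <- rbind(one$data,
                transform(one$data, tissue = "B"))
  f2 <- fit_consensus(both, spec, start = c(tv, offset = 0), seed = 1)
  # duplicated residuals leave the normal equations unchanged: same
  # optimum, twice the objective
  expect_equal(unname(f2$par), unname(f1$par), tolerance = 1e-6)
  expect_lt(f2$objective, 1e-4)
})

test_that("CCG fit recovers parameters from noise-free data at truth start", {
  core <- make_core()
  ccg <- ccg_parameters(b = 3, ba = 1, cr = 2, gr = 1, ar = 1.5, f = 4,
                        fa = 0.5, d = 0.3, n1 = 2, n2 = 1, n3 = 1,
                        gene = "ccgA")
  gen <- generate_ccg_timecourse(list(T1 = ccg), core, noise_cv = 0,
                                 seed = 1)
  tv <- c(b = 3, ba = 1, cr = 2, gr = 1, ar = 1.5, f = 4, fa = 0.5,
          d = 0.3)
  fit <- fit_ccg(gen$data, core, counts = c(2, 1, 1), start = tv,
                 n_starts = 1, seed = 1)
  expect_lt(fit$objective, 1e-4)
  expect_equal(unname(fit$par[names(tv)]), unname(tv), tolerance = 1e-2)
  # predicted-vs-observed pairs on the identity line
  expect_gt(cor(fit$predicted$predicted, fit$predicted$observed)^2, 0.999)
})

test_that("all-zero counts reduce the CCG fit to the flat profile", {
  core <- make_core()
  flat_data <- data.frame(tissue = "T", gene = "flat",
                          time_h = rep(CIRCADIAN_GRID, each = 2),
                          replicate = rep(1:2, 18), value = 1)
  fit <- fit_ccg(flat_data, core, counts = c(0, 0, 0), n_starts = 1,
                 seed = 1)
  # structurally the model is x -> 1/d normalized to 1: perfect fit
  expect_lt(fit$objective, 1e-6)
  # rhythmic data with zero counts is flagged
  gen <- generate_ccg_timecourse(
    list(T = ccg_parameters(b = 3, ba = 1, n1 = 2, gene = "g")), core,
    noise_cv = 0, seed = 1)
  expect_warning(fit_ccg(gen$data, core, counts = c(0, 0, 0),
                         n_starts = 1, seed = 1),
                 "structurally flat")
})
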