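# Core-clock network and CCG extension.

test_that("saturating dissociation constants decouple the system", {
  # every K -> 1e12 makes all regulatory terms 1; each gene relaxes to 1/d
  ks <- c("ar1", "ar4", "cr2", "cr3", "cr4", "cr5", "gr2", "gr3", "gr4",
          "gr5", "ba2", "ba3", "ba4", "ba5", "fa2", "fa3", "fa4")
  over <- setNames(rep(1e12, length(ks)), ks)
  p <- core_clock_parameters(base = c(unlist(clock_params()[
    c(paste0("tau_", CLOCK_GENES), paste0("d_", CLOCK_GENES))]), over))
  p$d_Bmal1 <- 0.5
  tr <- simulate_core_clock(core_clock_parameters(base = p),
                            duration = 24, burn_in = 120)
  final <- dde_evaluate(tr, tr$t_end)
  ds <- unlist(p[paste0("d_", CLOCK_GENES)])
  expect_equal(as.numeric(final), as.numeric(1 / ds), tolerance = 1e-4)
  expect_equal(unname(final[1, "Bmal1"]), 2.0, tolerance = 1e-4)
})

test_that("production term of Bmal1 at Rev-Erba = ar1 is 0.25", {
  p <- clock_params()
  rhs <- core_clock_rhs(p)
  state <- rep(1, 5)
  ylag <- matrix(1, 5, 5)
  ylag[2, 2] <- p$ar1  # delayed Rev-Erba equals its dissociation constant
  d <- rhs(0, state, ylag)
  expect_equal(d[1] + p$d_Bmal1 * 1, (1 / (1 + 1))^2)
})

test_that("compiled rhs route equals the R closure route", {
  params <- clock_params("Muscle")
  tr_cpp <- simulate_core_clock(params, duration = 24, burn_in = 48)
  tr_r <- dde_integrate(core_clock_rhs(params),
                        delays = clockdde:::param_vector(params)[1:5],
                        history = setNames(rep(1, 5), CLOCK_GENES),
                        t_span = c(0, 72), hmax = 0.25)
  tt <- seq(48, 72, by = 0.5)
  expect_equal(dde_evaluate(tr_cpp, tt), dde_evaluate(tr_r, tt),
               tolerance = 1e-6)
})

test_that("published parameter columns oscillate with the expected pattern", {
  for (tis in clock_tissues()) {
    tr <- make_core(tis)
    expect_true(tr$oscillation$sustained, label = paste(tis, "sustained"))
    per <- vapply(CLOCK_GENES, function(g) estimate_period(tr, g),
                  numeric(1))
    expect_true(all(per > 20 & per < 28), label = paste(tis, "period"))
    # shared limit cycle: all five genes agree on the period within 0.5%
    expect_lt(diff(range(per)) / mean(per), 0.005)
  }
  # Liver peak order within one cycle: Rev-Erba and Dbp before Per2 before
  # Cry1 (dark-period peaking)
  tr <- make_core("Liver")
  pk <- vapply(CLOCK_GENES, function(g) estimate_phase(tr, g)$peak_time,
               numeric(1))
  expect_lt(pk["RevErba"], pk["Per2"])
  expect_lt(pk["Dbp"], pk["Per2"])
  expect_lt(pk["Per2"], pk["Cry1"])
})

test_that("positivity and boundedness hold along the limit cycle", {
  tr <- make_core()
  tt <- seq(0, tr$t_end, by = 0.25)
  m <- dde_evaluate(tr, tt)
  expect_true(all(m > 0))
  # crude production bound: max fold^power / d
  p <- clock_params()
  caps <- c(1 / p$d_Bmal1,
            p$b2^3 * p$f2 / p$d_RevErba,
            p$b3^2 * p$f3 / p$d_Per2,
            p$b4^2 * p$f4 / p$d_Cry1,
            p$b5^3 / p$d_Dbp)
  expect_true(all(t(m) <= caps * (1 + 1e-6)))
})

test_that("period is stable cycle to cycle after burn-in", {
  tr <- make_core()
  times <- seq(tr$window_start, tr$t_end, by = 0.05)
  v <- dde_evaluate(tr, times)[, "Bmal1"]
  peaks <- clockdde:::refine_peaks(times, v)
  gaps <- diff(peaks)
  expect_gte(length(gaps), 3)
  expect_lt(max(abs(diff(gaps))) / mean(gaps), 0.01)
})

test_that("CCG with zero counts reduces to first-order relaxation", {
  core <- make_core()
  ccg <- ccg_parameters(d = 0.5, n1 = 0, n2 = 0, n3 = 0)
  tr <- simulate_ccg(ccg, core)
  # closed form from history 1: x(t) = 2 + (1 - 2) exp(-0.5 t)
  tt <- seq(0, 30, by = 1)
  expect_equal(dde_evaluate(tr, tt)[, 1], 2 + (1 - 2) * exp(-0.5 * tt),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("CCG constant-core steady state matches direct evaluation", {
  # constant core at Bmal1 = ba, Per2/cr = Cry1/gr = 0 effective via huge
  # cr, gr: production = ((1+3)/2) * 1 * 1 = 2, steady state 2/d
  flat <- core_clock_parameters(base = c(
    setNames(rep(1, 5), paste0("tau_", CLOCK_GENES)),
    setNames(rep(0.4, 5), paste0("d_", CLOCK_GENES)),
    ar1 = 1e12, ar4 = 1e12, cr2 = 1e12, cr3 = 1e12, cr4 = 1e12,
    cr5 = 1e12, gr2 = 1e12, gr3 = 1e12, gr4 = 1e12, gr5 = 1e12,
    ba2 = 1e12, ba3 = 1e12, ba4 = 1e12, ba5 = 1e12,
    fa2 = 1e12, fa3 = 1e12, fa4 = 1e12))
  core <- simulate_core_clock(flat, duration = 120, burn_in = 240)
  lvl <- dde_evaluate(core, core$t_end)[1, "Bmal1"]  # = 1/0.4 = 2.5
  ccg <- ccg_parameters(b = 3, ba = lvl, cr = 1e12, gr = 1e12, d = 0.4,
                        n1 = 1, n2 = 0, n3 = 0)
  tr <- simulate_ccg(ccg, core)
  expect_equal(unname(dde_evaluate(tr, tr$t_end)[1, 1]), 2 / 0.4,
               tolerance = 1e-3)
})

test_that("a periodic core forces the CCG onto an orbit of the same period", {
  core <- make_core()
  ccg <- ccg_parameters(b = 3, ba = 1, cr = 2, gr = 1, ar = 1.5, f = 4,
                        fa = 0.5, d = 0.3, n1 = 2, n2 = 1, n3 = 1)
  tr <- simulate_ccg(ccg, core)
  p_core <- estimate_period(core)
  p_ccg <- estimate_period(tr)
  expect_equal(p_ccg, p_core, tolerance = 1e-3)
  # two-cycle comparison: last cycle overlays the one before
  t1 <- seq(tr$t_end - p_ccg, tr$t_end, by = 0.1)
  expect_equal(dde_evaluate(tr, t1)[, 1],
               dde_evaluate(tr, t1 - p_ccg)[, 1], tolerance = 1e-3)
})

test_that("CCG integration past the core trajectory end is refused", {
  core <- make_core()
  expect_error(simulate_ccg(ccg_parameters(), core,
                            t_end = core$t_end + 24),
               "extend the core simulation by 24")
})

test_that("parameter validation rejects bad values", {
  expect_error(core_clock_parameters(tau_Bmal1 = -1,
                                     base = clock_params()), "positive")
  expect_error(core_clock_parameters(d_Per2 = NaN, base = clock_params()),
               "finite")
  expect_error(ccg_parameters(n1 = -1), "non-negative")
  expect_error(ccg_parameters(n1 = 1.5), "non-negative")
  expect_error(ccg_parameters(b = 0), "> 0")
})

test_that("ccg_rhs closure is the derivative of the simulated CCG", {
  core <- make_core()
  ccg <- ccg_parameters(b = 2.5, ba = 1.2, cr = 1.8, gr = 0.7, ar = 2,
                        f = 3, fa = 0.6, d = 0.4, n1 = 2, n2 = 1, n3 = 1)
  tr <- simulate_ccg(ccg, core)
  rhs <- ccg_rhs(ccg, core)
  for (t in c(250, 300, 341.5)) {
    x <- unname(dde_evaluate(tr, t)[1, 1])
    # central difference of the dense output
    h <- 1e-3
    dnum <- (dde_evaluate(tr, t + h)[1, 1] -
               dde_evaluate(tr, t - h)[1, 1]) / (2 * h)
    expect_equal(unname(rhs(t, x)), unname(dnum), tolerance = 1e-4)
  }
})
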