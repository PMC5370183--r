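# Independent oracle for the dark-phase level: c0 * exp(-integral of the
# instantaneous coefficient), with the integral done by adaptive quadrature.
# Shares no code with the closed form or the ODE path.
quadrature_level <- function(t, c0, k1, k2, k3, extra = 0) {
  sapply(t, function(tt) {
    if (tt == 0) return(c0)
    I <- stats::integrate(function(s) (k1 - k2) * exp(-k3 * s) + k2 + extra,
                          0, tt, rel.tol = 1e-12)$value
    c0 * exp(-I)
  })
}

test_that("light-state fraction is the dusk-clock exponential", {
  expect_identical(light_state_fraction(0, 0.7), 1)
  expect_equal(light_state_fraction(1, 0.7), exp(-0.7))
  expect_equal(light_state_fraction(1e6, 0.7), 0, tolerance = 1e-12)
  expect_true(all(diff(light_state_fraction(0:10, 0.5)) < 0))
  # k3 = Inf: instantaneous reversion
  expect_identical(light_state_fraction(c(0, 0.1, 5), Inf), c(1, 0, 0))
  expect_error(light_state_fraction(-1, 0.7), "non-negative")
  expect_error(light_state_fraction(1, -0.1), "non-negative")
})

test_that("effective degradation coefficient relaxes from k1 to k2", {
  p <- degradation_params(0.2, 0.8, 0.7)
  expect_equal(effective_degradation_coefficient(0, p), 0.2)
  expect_equal(effective_degradation_coefficient(1e4, p), 0.8)
  p2 <- degradation_params(0.14, 0.8, 0.15)
  expect_equal(effective_degradation_coefficient(1, p2),
               0.8 + (0.14 - 0.8) * exp(-0.15), tolerance = 1e-12)
})

test_that("closed-form PRR5 level matches an independent quadrature oracle", {
  p <- degradation_params(0.2, 0.8, 0.7)
  expect_equal(prr5_analytic(0, 2.5, p), 2.5)
  # frozen from quadrature_level(12, 1, 0.2, 0.8, 0.7) at rel.tol 1e-12
  expect_equal(prr5_analytic(12, 1, p), 1.595665e-4, tolerance = 1e-6)
  expect_equal(prr5_analytic(12, 1, p),
               quadrature_level(12, 1, 0.2, 0.8, 0.7), tolerance = 1e-10)
  # k1 = k2 collapses to a single exponential
  pk <- degradation_params(0.5, 0.5, 0.3)
  tt <- seq(0, 24, by = 2)
  expect_equal(prr5_analytic(tt, 1, pk), exp(-0.5 * tt), tolerance = 1e-12)
  # k3 = 0 limit branch with warning
  p0 <- degradation_params(0.2, 0.8, 0)
  expect_warning(v <- prr5_analytic(3, 1, p0), "k3 = 0")
  expect_equal(v, exp(-0.2 * 3))
})

test_that("TOC1 closed form factorises the m8 channel", {
  p <- degradation_params(0.2, 0.8, 0.7, m8 = 0.1)
  p_no_m8 <- degradation_params(0.2, 0.8, 0.7)
  tt <- c(0, 1, 6, 12)
  # m8 = 0 reduces to the PRR5 solution
  expect_equal(toc1_analytic(tt, 1, p_no_m8), prr5_analytic(tt, 1, p_no_m8))
  # constant channel factorises as exp(-m8 t)
  expect_equal(toc1_analytic(tt, 1, p),
               prr5_analytic(tt, 1, p_no_m8) * exp(-0.1 * tt),
               tolerance = 1e-12)
  expect_equal(toc1_analytic(12, 1, p),
               quadrature_level(12, 1, 0.2, 0.8, 0.7, extra = 0.1),
               tolerance = 1e-10)
  # k1 = k2 with m8: single exponential at k + m8
  pk <- degradation_params(0.4, 0.4, 0.3, m8 = 0.1)
  expect_equal(toc1_analytic(tt, 1, pk), exp(-0.5 * tt), tolerance = 1e-12)
})

test_that("numerical integration agrees with the analytic solution", {
  grid <- seq(0, 12, by = 0.5)
  p <- preset_params("WT")$params
  sim <- integrate_numeric("PRR5", 1, p, grid)
  expect_equal(sim$level, prr5_analytic(grid, 1, p), tolerance = 1e-6)
  # single-point grid returns c0 only
  s0 <- integrate_numeric("PRR5", 2, p, 0)
  expect_equal(s0$level, 2)
  expect_equal(nrow(s0), 1L)
  # k1 = k2: matches the pure exponential
  pk <- degradation_params(0.6, 0.6, 0.2)
  simk <- integrate_numeric("PRR5", 1, pk, grid)
  expect_equal(simk$level, exp(-0.6 * grid), tolerance = 1e-6)
  expect_error(integrate_numeric("PRR5", 1, p, c(1, 2)), "starting at 0")
  expect_error(integrate_numeric("PRR5", 0, p, grid), "positive")
})

test_that("analytic and numerical solutions agree across a parameter sweep", {
  grid <- seq(0, 24, by = 1)
  for (k1 in c(0.05, 0.3, 1.0)) {
    for (k2 in c(0.05, 0.5, 1.0)) {
      for (k3 in c(0.01, 0.15, 1.0)) {
        p <- degradation_params(k1, k2, k3)
        num <- integrate_numeric("PRR5", 1, p, grid)$level
        ana <- prr5_analytic(grid, 1, p)
        expect_equal(num, ana, tolerance = 1e-6,
                     label = sprintf("k1=%g k2=%g k3=%g", k1, k2, k3))
      }
    }
  }
})

test_that("k3 limits: fast reversion approaches the pure-k2 exponential", {
  tt <- seq(0, 12, by = 0.5)
  target <- exp(-0.8 * tt)
  sup_err <- sapply(c(10, 100, 1000), function(k3) {
    p <- degradation_params(0.14, 0.8, k3)
    max(abs(prr5_analytic(tt, 1, p) - target))
  })
  expect_true(all(diff(sup_err) < 0))
  expect_lt(sup_err[3], 1e-3)
  # explicit Inf branch
  pinf <- degradation_params(0.14, 0.8, Inf)
  expect_equal(prr5_analytic(tt, 1, pinf), target, tolerance = 1e-12)
})

test_that("dark-phase level is non-increasing in k3 when k2 > k1", {
  k3_grid <- c(0.02, 0.05, 0.09, 0.15, 0.7, 2, 10)
  for (t in c(0.5, 2, 6, 12)) {
    lev <- sapply(k3_grid, function(k3)
      prr5_analytic(t, 1, degradation_params(0.14, 0.8, k3)))
    expect_true(all(diff(lev) <= 1e-14),
                label = sprintf("monotone in k3 at t=%g", t))
  }
})

test_that("schedule simulation is piecewise-correct and conservative", {
  wt <- preset_params("WT")$params
  # LL: pure exponential at k1, light fraction pinned at 1
  ll <- simulate_schedule("PRR5", 1, wt, ll_schedule(24), step = 0.5)
  expect_equal(ll$level, exp(-wt$k1 * ll$time_hr), tolerance = 1e-12)
  expect_true(all(ll$ztl_light_fraction == 1))
  # LD: the dark phase equals the closed form on the dusk clock
  sim <- simulate_schedule("PRR5", 1, wt, gen_ld_schedule(), step = 0.25)
  dark <- sim[sim$phase == "dark", ]
  c_dusk <- exp(-wt$k1 * 12)
  expect_equal(dark$level, prr5_analytic(dark$time_hr - 12, c_dusk, wt),
               tolerance = 1e-12)
  # conservation: light + dark fraction = 1, fraction in [0,1]
  expect_true(all(sim$ztl_light_fraction >= 0 & sim$ztl_light_fraction <= 1))
  dark_frac <- 1 - sim$ztl_light_fraction
  expect_equal(sim$ztl_light_fraction + dark_frac, rep(1, nrow(sim)))
  # positivity and monotone decay (pure-degradation model)
  expect_true(all(sim$level > 0))
  expect_true(all(diff(sim$level) <= 1e-14))
  # continuity across the dusk boundary
  i <- which(sim$time_hr == 12)
  expect_length(i, 1L)
  before <- sim$level[i - 1L]
  expect_lt(abs(sim$level[i] - exp(-wt$k1 * 12)) / exp(-wt$k1 * 12), 1e-10)
  expect_lt(sim$level[i] / before, 1)
  # dawn: light fraction resets to 1 at lights-on of the next cycle
  sim2 <- simulate_schedule("PRR5", 1, wt, gen_ld_schedule(12, 12, 2),
                            step = 0.5)
  at_dawn <- sim2[sim2$time_hr == 24, ]
  expect_equal(at_dawn$ztl_light_fraction, 1)
  expect_error(simulate_schedule("PRR5", 0, wt, gen_ld_schedule()), "positive")
})

test_that("slower reversion delays degradation in the dark phase", {
  wt <- preset_params("WT")$params
  g80r <- preset_params("G80R")$params
  tt <- seq(0.25, 12, by = 0.25)
  c_dusk <- exp(-wt$k1 * 12)
  lev_wt <- prr5_analytic(tt, c_dusk, wt)
  lev_g80r <- prr5_analytic(tt, c_dusk, g80r)
  expect_true(all(lev_g80r >= lev_wt))
  expect_gt(max(lev_g80r - lev_wt), 0)
})

test_that("published-model rates convert to light/dark-state parameters", {
  p5 <- convert_pokhilko_params(pokhilko_rates(m17 = 0.2, m24 = 0.6), "PRR5")
  expect_equal(p5$k1, 0.2)
  expect_equal(p5$k2, 0.8)
  t1 <- convert_pokhilko_params(pokhilko_rates(m6 = 0.2, m7 = 0.6, m8 = 0.1),
                                "TOC1")
  expect_equal(t1$k1, 0.2)
  expect_equal(t1$k2, 0.8)
  expect_equal(t1$m8, 0.1)
  # no dark enhancement
  p0 <- convert_pokhilko_params(pokhilko_rates(m17 = 0.3, m24 = 0), "PRR5")
  expect_equal(p0$k1, p0$k2)
  expect_error(convert_pokhilko_params(pokhilko_rates(m17 = 0.2), "PRR5"),
               "m24")
})

test_that("apparent single-exponential rate behaves as a time average", {
  # pure exponential data: exact recovery
  tt <- seq(0, 10, by = 1)
  tc <- protein_timecourse(tt, exp(-0.8 * tt), condition = "LL",
                           species = "PRR5")
  est <- effective_rate_constant(tc)
  expect_equal(est$k, 0.8, tolerance = 1e-10)
  # photocycle-model data: apparent rate strictly between k1 and k2
  p <- degradation_params(0.14, 0.8, 0.15)
  t2 <- seq(0, 12, by = 1)
  tc2 <- protein_timecourse(t2, prr5_analytic(t2, 1, p), condition = "LL",
                            species = "PRR5")
  est2 <- effective_rate_constant(tc2)
  expect_gt(est2$k, 0.14)
  expect_lt(est2$k, 0.8)
  # two-point input: the log-ratio slope, exactly
  tc3 <- data.frame(time_hr = c(0, 4), level = c(1, 0.2))
  est3 <- effective_rate_constant(tc3)
  expect_equal(est3$k, log(1 / 0.2) / 4, tolerance = 1e-12)
  # non-decaying data warns
  tc4 <- data.frame(time_hr = 0:3, level = c(1, 1.2, 1.5, 1.9))
  expect_warning(effective_rate_constant(tc4), "does not decay")
})

test_that("parameter containers validate their invariants", {
  expect_error(degradation_params(-0.1, 0.8, 0.7), "non-negative")
  expect_error(degradation_params(0.1, 0.8, NA), "non-missing")
  expect_error(light_schedule(character(0), numeric(0)), "at least one")
  expect_error(light_schedule("light", -2), "positive")
  expect_error(light_schedule("dusk", 2), "'light' or 'dark'")
  expect_error(gen_ld_schedule(12, 12, 0), "at least 1")
  s <- gen_ld_schedule(16, 8, 2)
  expect_equal(nrow(s), 4L)
  expect_equal(sum(s$duration), 48)
  expect_equal(s$kind, c("light", "dark", "light", "dark"))
  ll <- ll_schedule(24)
  expect_equal(nrow(ll), 1L)
  expect_equal(ll$kind, "light")
})
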