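noiseless <- function(params, schedule, times, species = "PRR5", c0 = 1) {
  gen_protein_timecourse(params, schedule, c0 = c0, times = times,
                         noise = noise_spec(protein_cv = 0, seed = 1),
                         species = species)
}

test_that("noiseless LL data pins down the light-state rate", {
  wt <- preset_params("WT")$params
  tc <- noiseless(wt, ll_schedule(24), times = 0:12)
  fit <- fit_degradation(tc, degradation_params(0.3, 0.8, 0.7), free = "k1",
                         seed = 1)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["k1"]), 0.14, tolerance = 1e-4)
  expect_lt(fit$objective, 1e-10)
})

test_that("noiseless LD dark-phase data recovers the reversion rate", {
  g80r <- preset_params("G80R")$params
  tc <- noiseless(g80r, gen_ld_schedule(), times = 12:24)
  fit <- fit_degradation(tc, degradation_params(0.14, 0.8, 0.5), free = "k3",
                         seed = 1)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["k3"]), 0.15, tolerance = 1e-4)
  # joint recovery of all three rates from richer noiseless data
  wt <- preset_params("WT")$params
  tc2 <- noiseless(wt, gen_ld_schedule(), times = seq(12, 24, by = 0.5))
  fit2 <- fit_degradation(tc2, degradation_params(0.3, 0.5, 0.3, 0),
                          free = c("k1", "k2", "k3"), seed = 2)
  expect_true(fit2$converged)
  expect_equal(unname(coef(fit2)), c(0.14, 0.8, 0.7), tolerance = 1e-2)
})

test_that("identifiability guards refuse what the data cannot inform", {
  wt <- preset_params("WT")$params
  tc_ll <- noiseless(wt, ll_schedule(24), times = 0:12)
  expect_error(fit_degradation(tc_ll, wt, free = "k3"), "not identifiable")
  expect_error(fit_degradation(tc_ll, wt, free = c("k1", "k2")),
               "not identifiable")
  # k1 = k2 makes the dark-phase trajectory independent of k3
  dm <- degradation_params(0.8, 0.8, 0.09)
  tc_ld <- noiseless(dm, gen_ld_schedule(), times = 12:24)
  expect_warning(fit <- fit_degradation(tc_ld, dm, free = "k3", seed = 1),
                 "non-identifiable")
  expect_true(fit$nonidentifiable)
  expect_false(fit$converged)
  # m8 is a TOC1-only channel
  expect_error(fit_degradation(tc_ld, dm, free = "m8"), "TOC1 only")
  expect_error(fit_degradation(tc_ld, dm, free = character(0)), "non-empty")
})

test_that("objective never increases from start to solution and pooling is invariant", {
  g80r <- preset_params("G80R")$params
  tc <- gen_protein_timecourse(g80r, gen_ld_schedule(), times = 12:24,
                               noise = noise_spec(seed = 11))
  fit <- fit_degradation(tc, degradation_params(0.14, 0.8, 0.4), free = "k3",
                         seed = 1)
  expect_lte(fit$objective, fit$objective0)
  # duplicating every replicate leaves the point estimate unchanged
  dup <- protein_timecourse(
    c(tc$time_hr, tc$time_hr), c(tc$level, tc$level),
    c(tc$replicate, tc$replicate + max(tc$replicate)),
    condition = attr(tc, "condition"), species = attr(tc, "species"),
    schedule = attr(tc, "schedule"))
  fit_dup <- fit_degradation(dup, degradation_params(0.14, 0.8, 0.4),
                             free = "k3", seed = 1)
  expect_equal(coef(fit_dup), coef(fit), tolerance = 1e-6)
})

test_that("estimates respect bounds and ties break toward smaller k3", {
  g80r <- preset_params("G80R")
  tc <- gen_protein_timecourse(g80r$params, gen_ld_schedule(), times = 12:24,
                               noise = noise_spec(seed = 5))
  fit <- fit_degradation(tc, g80r$params, free = "k3", seed = 3)
  expect_gte(unname(coef(fit)["k3"]), 0)
  expect_lte(unname(coef(fit)["k3"]), 10)
  expect_true(fit$n_multistart_best >= 1)
})

test_that("bootstrap CIs are deterministic under seed and shrink with noise", {
  g80r <- preset_params("G80R")
  tc <- gen_protein_timecourse(g80r$params, gen_ld_schedule(), times = 12:24,
                               noise = noise_spec(seed = 21))
  fit <- fit_degradation(tc, g80r$params, free = "k3", seed = 1)
  b1 <- bootstrap_ci(fit, n_boot = 100, seed = 9)
  b2 <- bootstrap_ci(fit, n_boot = 100, seed = 9)
  expect_identical(b1$ci, b2$ci)
  expect_lte(b1$ci["k3", "lower"], unname(coef(fit)["k3"]))
  expect_gte(b1$ci["k3", "upper"], unname(coef(fit)["k3"]))
  # near-zero noise: CI width collapses
  tc0 <- gen_protein_timecourse(g80r$params, gen_ld_schedule(), times = 12:24,
                                noise = noise_spec(protein_cv = 1e-4, seed = 2))
  fit0 <- fit_degradation(tc0, g80r$params, free = "k3", seed = 1)
  b0 <- bootstrap_ci(fit0, n_boot = 100, seed = 9)
  expect_lt(b0$ci["k3", "upper"] - b0$ci["k3", "lower"], 0.005)
  expect_lt(b0$ci["k3", "upper"] - b0$ci["k3", "lower"],
            b1$ci["k3", "upper"] - b1$ci["k3", "lower"])
  # single replicate: case bootstrap falls back to residual resampling
  tc1 <- gen_protein_timecourse(g80r$params, gen_ld_schedule(), times = 12:24,
                                noise = noise_spec(n_replicates = 1, seed = 3))
  fit1 <- fit_degradation(tc1, g80r$params, free = "k3", seed = 1)
  expect_warning(br <- bootstrap_ci(fit1, n_boot = 100, seed = 9),
                 "residual bootstrap")
  expect_identical(br$boot_type, "residual")
  expect_error(bootstrap_ci(fit, n_boot = 50), "at least 100")
})

test_that("bootstrap CIs cover the generating k3 at roughly nominal rate", {
  g80r <- preset_params("G80R")
  covered <- sapply(1:20, function(s) {
    tc <- gen_protein_timecourse(g80r$params, gen_ld_schedule(),
                                 times = 12:24,
                                 noise = noise_spec(seed = 100 + s))
    fit <- fit_degradation(tc, g80r$params, free = "k3", seed = 1,
                           n_starts = 1)
    # residual bootstrap: with only 3 replicates the case bootstrap has too
    # few resampling units to reach nominal coverage
    ci <- bootstrap_ci(fit, n_boot = 100, type = "residual", seed = s)$ci
    ci["k3", "lower"] <= 0.15 && 0.15 <= ci["k3", "upper"]
  })
  expect_gte(mean(covered), 0.8)
})

test_that("objective profiles expose identifiability structure", {
  wt <- preset_params("WT")
  # LL data: flat profile in k3
  tc_ll <- gen_protein_timecourse(wt$params, ll_schedule(24), times = 0:12,
                                  noise = noise_spec(seed = 4))
  prof_ll <- profile_objective(tc_ll, wt$params, "k3",
                               grid = c(0.05, 0.15, 0.7, 2))
  expect_equal(nrow(prof_ll), 4L)
  expect_lt(diff(range(prof_ll$objective)), 1e-12)
  # LD data with strong k1/k2 contrast: unimodal profile around the truth
  tc_ld <- noiseless(wt$params, gen_ld_schedule(), times = seq(12, 24, 0.5))
  grid <- seq(0.2, 1.6, by = 0.1)
  prof <- profile_objective(tc_ld, wt$params, "k3", grid = grid)
  i_min <- which.min(prof$objective)
  expect_equal(prof$value[i_min], 0.7, tolerance = 0.1)
  expect_true(all(diff(prof$objective[seq_len(i_min)]) <= 0))
  expect_true(all(diff(prof$objective[i_min:nrow(prof)]) >= 0))
  # grid of one point -> single row
  expect_equal(nrow(profile_objective(tc_ld, wt$params, "k3", 0.7)), 1L)
})

test_that("recovery experiments are exact at zero noise and track failures", {
  g80r <- preset_params("G80R")
  rec0 <- recovery_experiment(g80r$params, gen_ld_schedule(), times = 12:24,
                              noise = noise_spec(protein_cv = 0),
                              free = "k3", n_seeds = 3, seed = 1,
                              n_starts = 1)
  expect_equal(rec0$summary$bias, 0, tolerance = 1e-4)
  expect_equal(rec0$summary$rel_rmse, 0, tolerance = 1e-3)
  expect_equal(rec0$summary$n_fail, 0L)
  # per-seed failures are recorded, not fatal: k1 = k2 truth is flagged
  dm <- degradation_params(0.8, 0.8, 0.09)
  rec_fail <- suppressWarnings(
    recovery_experiment(dm, gen_ld_schedule(), times = 12:24,
                        noise = noise_spec(protein_cv = 0),
                        free = "k3", n_seeds = 2, seed = 1, n_starts = 1))
  expect_equal(rec_fail$summary$n_fail, 2L)
})

test_that("time-course construction enforces its invariants", {
  expect_error(protein_timecourse(0:5, c(1, 1, 0, 1, 1, 1)), "positive")
  expect_error(protein_timecourse(c(0, 0, 0), c(1, 1, 1)),
               "3 distinct")
  expect_error(protein_timecourse(0:5, rep(1, 6), condition = "LL",
                                  schedule = gen_ld_schedule()),
               "LL but the schedule")
  tc <- protein_timecourse(0:5, exp(-0.1 * 0:5), condition = "LL")
  expect_s3_class(tc, "protein_timecourse")
  expect_identical(attr(tc, "condition"), "LL")
})
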