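test_that("settings validation enforces the documented ranges", {
  expect_error(gaims_settings(steps = 0), "steps")
  expect_error(gaims_settings(population_size = 1), "population_size")
  expect_error(gaims_settings(crossover_rate = 1.2), "crossover_rate")
  expect_error(gaims_settings(repeats = 0), "repeats")
  s <- gaims_settings()
  expect_identical(s$steps, 1000000L)
  expect_identical(s$population_size, 20L)
  expect_identical(s$mutations_per_step, 3L)
  expect_equal(s$crossover_rate, 0.05)
  expect_identical(s$repeats, 50L)
})

test_that("objective is the sum of squared residuals", {
  sp <- udp_glcnac_space()
  p <- params_48h(sp)
  obs <- predict_profile(sp, p)
  expect_equal(gaims_objective(p, obs, sp), 0)

  delta0 <- isotopologue_profile(c(1, numeric(16)))
  allun <- parameter_set(sp, c(g0 = 1, r0 = 1, a0 = 1, u0 = 1))
  expect_equal(gaims_objective(allun, delta0, sp), 0)

  # observed all at m0, model all at m6: unit residual at both masses
  g6only <- parameter_set(sp, c(g6 = 1, r0 = 1, a0 = 1, u0 = 1))
  expect_equal(gaims_objective(g6only, delta0, sp), 2)

  expect_error(gaims_objective(p, c(1, 0, 0), sp), "mass channels")
  expect_equal(gaims_objective(g6only, c(1, 0, 0), sp, align = TRUE), 2)
})

test_that("fits are deterministic given a seed", {
  sp <- udp_glcnac_space()
  obs <- predict_profile(sp, params_48h(sp))
  f1 <- gaims_fit(obs, sp, test_settings(seed = 5))
  f2 <- gaims_fit(obs, sp, test_settings(seed = 5))
  expect_identical(f1$best_params, f2$best_params)
  expect_identical(f1$per_repeat_objective, f2$per_repeat_objective)
  f3 <- gaims_fit(obs, sp, test_settings(seed = 6))
  expect_false(identical(f1$per_repeat_objective, f3$per_repeat_objective))
})

test_that("best-so-far objective is non-increasing along the trace", {
  sp <- udp_glcnac_space()
  obs <- predict_profile(sp, params_48h(sp))
  for (s in 1:3) {
    run <- gaims_fit_once(obs, sp, test_settings(), seed = s)
    expect_true(all(diff(run$trace) <= 0))
    expect_equal(run$objective, run$trace[length(run$trace)])
  }
})

test_that("fit results satisfy bounds and per-subunit closure", {
  set.seed(30)
  sp <- udp_glcnac_space()
  for (i in 1:5) {
    obs <- predict_profile(sp, random_params(sp))
    run <- gaims_fit_once(obs, sp, test_settings(steps = 5e3), seed = i)
    p <- run$params
    expect_true(all(p >= 0 & p <= 1))
    for (su in sp$subunits)
      expect_equal(sum(p[su$parameter_names]), 1, tolerance = 1e-9)
  }
})

test_that("a delta observation at m0 recovers the all-unlabeled solution", {
  sp <- udp_glcnac_space()
  run <- gaims_fit_once(isotopologue_profile(c(1, numeric(16))), sp,
                        test_settings(steps = 1e5), seed = 2)
  truth <- parameter_set(sp, c(g0 = 1, r0 = 1, a0 = 1, u0 = 1))
  expect_lt(max(abs(run$params - truth)), 1e-3)
})

test_that("noise-free profiles are deconvoluted back to the truth", {
  sp <- udp_glcnac_space()
  truth <- params_48h(sp)
  obs <- predict_profile(sp, truth)
  run <- gaims_fit_once(obs, sp, gaims_settings(steps = 1e5), seed = 1)
  expect_lt(max(abs(run$params - truth)), 1e-3)
  expect_lt(run$objective, 1e-6)
})

test_that("median recovery error over random truths is below 1e-3", {
  set.seed(77)
  sp <- udp_glcnac_space()
  errs <- replicate(8, {
    truth <- random_params(sp)
    run <- gaims_fit_once(predict_profile(sp, truth), sp,
                          gaims_settings(steps = 1e5),
                          seed = sample.int(1e6, 1))
    max(abs(run$params - truth))
  })
  expect_lt(median(errs), 1e-3)
})

test_that("repeats = 1 reduces to a single run with the derived seed", {
  sp <- udp_glcnac_space()
  obs <- predict_profile(sp, params_48h(sp))
  st <- test_settings(repeats = 1, seed = 9)
  fit <- gaims_fit(obs, sp, st)
  one <- gaims_fit_once(obs, sp, st, seed = moietyfit:::derive_seed(9, 1))
  expect_identical(unclass(fit$best_params), unclass(one$params))
  expect_identical(fit$best_objective, one$objective)
})

test_that("replicate statistics are tight on noise-free data", {
  sp <- udp_glcnac_space()
  obs <- predict_profile(sp, params_48h(sp))
  fit <- gaims_fit(obs, sp, gaims_settings(steps = 1e5, repeats = 8, seed = 3))
  expect_true(all(fit$sd_params < 0.01))
  expect_false(fit$multimodal)
  expect_equal(fit$best_objective,
               gaims_objective(fit$best_params, obs, sp))
  expect_lt(max(abs(fit$mean_params - params_48h(sp))), 0.01)
})

test_that("1% multiplicative noise still yields accurate means", {
  set.seed(55)
  sp <- udp_glcnac_space()
  truth <- params_48h(sp)
  prof <- as.numeric(predict_profile(sp, truth))
  noisy <- normalize_profile(pmax(prof * (1 + rnorm(17, sd = 0.01)), 0))
  fit <- gaims_fit(noisy, sp, gaims_settings(steps = 2e4, repeats = 5, seed = 4))
  expect_lt(max(abs(fit$mean_params - truth)), 0.05)
})
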