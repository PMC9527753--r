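# Global least-squares estimation: starting values, shared-parameter fits,
# model selection, uncertainty, replicate aggregation.

test_that("initial guesses are exact on noise-free mono-exponentials", {
  truth <- eb_truth(A = 25, y0 = 1)
  series <- simulate_series(truth, design_eb_standard(sampling_rate = 5),
                            noise_spec(0, seed = 1))
  g <- initial_guess(series)
  # log-linear closed form: dissociation rate recovered almost exactly
  expect_lt(abs(g$k_d / truth$k_d - 1), 1e-9)
  # per-trace observed rates match k_a*c + k_d
  kobs <- attr(g, "k_obs")
  conc <- attr(g, "concentrations")
  expect_equal(kobs, observed_rate(truth$k_a, conc, truth$k_d),
               tolerance = 1e-6)
  # two noise-free concentrations: k_a from the two-point slope
  two <- series[c(2, 4)]  # highest and third concentration
  g2 <- initial_guess(two)
  expect_lt(abs(g2$k_a / truth$k_a - 1), 1e-6)
  # blanks are excluded from guessing: adding them changes nothing
  g_all <- initial_guess(series)
  g_nb <- initial_guess(Filter(Negate(is_blank), series))
  expect_equal(g_all$k_a, g_nb$k_a)
  expect_equal(g_all$k_d, g_nb$k_d)
})

test_that("unusable traces raise a guess failure with diagnostics", {
  ph <- phase_markers(5, 65, 365)
  flat <- sensorgram_trace(seq(0, 365), rep(3, 366), 1e-6, ph)
  expect_error(initial_guess(list(flat)), class = "guess_failure_error")
  expect_error(initial_guess(list()), class = "guess_failure_error")
})

test_that("noise-free global fits recover the generating parameters", {
  truth <- rate_parameters(1.5e6, 0.359, A = 18, y0 = -0.5, f_res = 0)
  series <- simulate_series(truth, design_eb_standard(sampling_rate = 5),
                            noise_spec(0, seed = 2))
  fit <- fit_global(series)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$k_a / truth$k_a - 1), 1e-6)
  expect_lt(abs(fit$params$k_d / truth$k_d - 1), 1e-6)
  expect_lt(max(abs(fit$params$y0 - truth$y0)), 1e-6)
  # reported constants always satisfy K_A = k_a/k_d exactly
  expect_identical(fit$constants$K_A, fit$params$k_a / fit$params$k_d)
  # incomplete model on complete-dissociation data: f_res collapses to zero
  fit_inc <- fit_global(series, model_spec("incomplete"))
  expect_lt(fit_inc$params$f_res, 1e-3)
})

test_that("shared estimates are invariant to trace order and duplication", {
  truth <- eb_truth(A = 30)
  series <- Filter(Negate(is_blank),
                   simulate_series(truth, design_eb_standard(sampling_rate = 2),
                                   noise_spec(0.5, seed = 9)))
  f1 <- fit_global(series)
  f2 <- fit_global(rev(series))
  expect_equal(f2$params$k_a, f1$params$k_a, tolerance = 1e-6)
  expect_equal(f2$params$k_d, f1$params$k_d, tolerance = 1e-6)
  # at a zero-residual optimum a duplicated trace contributes zero gradient,
  # so shared estimates are unchanged
  series0 <- Filter(Negate(is_blank),
                    simulate_series(truth, design_eb_standard(sampling_rate = 2),
                                    noise_spec(0, seed = 9)))
  g1 <- fit_global(series0)
  g3 <- fit_global(c(series0, series0[1]))
  expect_lt(abs(g3$params$k_a / g1$params$k_a - 1), 1e-8)
  expect_lt(abs(g3$params$k_d / g1$params$k_d - 1), 1e-8)
})

test_that("a single concentration is rejected as unidentifiable", {
  truth <- eb_truth()
  d <- series_design(1e-6, sampling_rate = 2)
  series <- simulate_series(truth, d, noise_spec(0.5, seed = 1))
  expect_error(fit_global(series), class = "identifiability_error")
})

test_that("model selection prefers the dissociation model that generated the data", {
  d <- design_slow_binder(sampling_rate = 2)
  complete_truth <- slow_truth(f_res = 0)
  s0 <- simulate_series(complete_truth, d, noise_spec(0.2, seed = 21))
  sel0 <- select_dissociation_model(s0, seed = 1)
  expect_identical(sel0$model$dissociation_model, "complete")
  partial_truth <- slow_truth(f_res = 0.5)
  s5 <- simulate_series(partial_truth, d, noise_spec(0.2, seed = 22))
  sel5 <- select_dissociation_model(s5, seed = 1)
  expect_identical(sel5$model$dissociation_model, "incomplete")
  expect_lt(abs(sel5$fit$params$f_res - 0.5), 0.05)
})

test_that("uncertainty estimates behave like standard errors should", {
  truth <- eb_truth(A = 30)
  series0 <- simulate_series(truth, design_eb_standard(sampling_rate = 2),
                             noise_spec(0, seed = 1))
  f0 <- fit_global(series0)
  # noise-free data: curvature SEs vanish relative to the parameters
  expect_lt(f0$standard_errors[["k_a"]], 1e-6 * f0$params$k_a)
  expect_lt(f0$standard_errors[["k_d"]], 1e-6 * f0$params$k_d)
  # bootstrap is deterministic under a fixed seed
  series <- simulate_series(truth, design_eb_standard(sampling_rate = 1),
                            noise_spec(1, seed = 5))
  fit <- fit_global(series)
  b1 <- estimate_uncertainty(fit, series, "bootstrap", n_boot = 20, seed = 17)
  b2 <- estimate_uncertainty(fit, series, "bootstrap", n_boot = 20, seed = 17)
  expect_identical(b1$standard_errors, b2$standard_errors)
  # bootstrap and curvature agree on the order of magnitude
  expect_lt(b1$standard_errors[["k_d"]] / fit$standard_errors[["k_d"]], 10)
  expect_gt(b1$standard_errors[["k_d"]] / fit$standard_errors[["k_d"]], 0.1)
})

test_that("95% curvature intervals cover the truth in most repeated simulations", {
  # 200 seeded replicates of a reduced design (3 concentrations, coarse
  # sampling) at 1% full-scale noise
  truth <- eb_truth(A = 30)
  d <- series_design(concentration_ladder(1e-6, 2, 3),
                     association_duration = 30, dissociation_duration = 60,
                     sampling_rate = 5, n_blanks_before = 0, n_blanks_after = 0)
  hits_ka <- hits_kd <- logical(200)
  for (s in 1:200) {
    fit <- fit_global(simulate_series(truth, d, noise_spec(1, seed = 3000 + s)))
    z <- stats::qnorm(0.975)
    hits_ka[s] <- isTRUE(abs(fit$params$k_a - truth$k_a) <=
                           z * fit$standard_errors[["k_a"]])
    hits_kd[s] <- isTRUE(abs(fit$params$k_d - truth$k_d) <=
                           z * fit$standard_errors[["k_d"]])
  }
  expect_gte(mean(hits_ka), 0.90)
  expect_gte(mean(hits_kd), 0.90)
})

test_that("replicate aggregation averages parameters and per-replicate constants", {
  same <- list(fake_fit(2e6, 0.4), fake_fit(2e6, 0.4), fake_fit(2e6, 0.4))
  agg <- aggregate_replicates(same)
  expect_equal(agg$sd, rep(0, nrow(agg)))
  three <- list(fake_fit(1e6, 0.5), fake_fit(2e6, 0.5), fake_fit(3e6, 0.5))
  agg3 <- aggregate_replicates(three)
  expect_equal(agg3$mean[agg3$parameter == "k_a"], 2e6)
  expect_equal(agg3$sd[agg3$parameter == "k_a"], 1e6)
  # Jensen gap: mean of per-replicate K_A differs from ratio of means
  uneq <- list(fake_fit(1e6, 0.1), fake_fit(1e6, 1.0))
  agg_u <- aggregate_replicates(uneq)
  mean_KA <- agg_u$mean[agg_u$parameter == "k_A" | agg_u$parameter == "K_A"]
  ratio_of_means <- mean(c(1e6, 1e6)) / mean(c(0.1, 1.0))
  expect_equal(mean_KA, mean(c(1e6 / 0.1, 1e6 / 1.0)))
  expect_false(isTRUE(all.equal(mean_KA, ratio_of_means)))
  # mismatched conditions are refused
  expect_error(aggregate_replicates(list(fake_fit(1e6, 0.5),
                                         fake_fit(1e6, 0.5, temperature = 37))),
               class = "aggregation_mismatch_error")
  expect_error(aggregate_replicates(list(fake_fit(1e6, 0.5))),
               class = "aggregation_mismatch_error")
})
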