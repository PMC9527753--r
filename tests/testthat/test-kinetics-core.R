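# Closed-form 1:1 model layer: observed rate, phase signals, equilibrium
# constants, piecewise trace assembly.

test_that("observed rate is k_a*c + k_d with the right limits", {
  expect_equal(observed_rate(1.5e6, 0, 0.358), 0.358)
  expect_equal(observed_rate(6.98e5, 1e-6, 0.358), 1.056)
  # linearity in concentration: doubling c doubles k_obs - k_d
  k1 <- observed_rate(6.98e5, 2.5e-7, 0.358) - 0.358
  k2 <- observed_rate(6.98e5, 5.0e-7, 0.358) - 0.358
  expect_equal(k2, 2 * k1)
  expect_true(all(observed_rate(77.7, c(0, 1e-5, 2e-4), 8.77e-3) >= 8.77e-3))
  expect_error(observed_rate(-1, 1e-6, 0.358), class = "invalid_parameter_error")
  expect_error(observed_rate(1e5, -1e-6, 0.358), class = "invalid_parameter_error")
  expect_error(observed_rate(1e5, 1e-6, Inf), class = "invalid_parameter_error")
})

test_that("association signal rises from baseline toward y0 + A", {
  ph <- phase_markers(0, 30, 90)
  p <- rate_parameters(1.5e6, 0.359, A = 10, y0 = 0)
  expect_equal(association_signal(0, p, 1e-6, ph), 0)
  # frozen independent evaluation of the closed form at k_obs = 1.859 s^-1
  expect_equal(association_signal(1, p, 1e-6, ph), 8.44171619139368,
               tolerance = 1e-12)
  # plateau identity
  p2 <- rate_parameters(1e6, 0.3, A = 10, y0 = 2)
  expect_equal(association_signal(30, p2, 1e-3, ph), 12, tolerance = 1e-9)
  expect_error(association_signal(31, p, 1e-6, ph), class = "out_of_window_error")
  expect_error(association_signal(-1, p, 1e-6, ph), class = "out_of_window_error")
})

test_that("association signal depends on time only through k_obs*(t - t_a)", {
  ph <- phase_markers(0, 1e4, 2e4)
  sets <- list(list(k_a = 1e6, c = 1e-6, k_d = 0.5),   # k_obs = 1.5
               list(k_a = 10, c = 0.05, k_d = 1.0))    # k_obs = 1.5
  u <- c(0.1, 0.5, 1, 2, 5)  # dimensionless k_obs * t
  vals <- lapply(sets, function(s) {
    p <- rate_parameters(s$k_a, s$k_d, A = 7, y0 = 1)
    kobs <- observed_rate(s$k_a, s$c, s$k_d)
    association_signal(u / kobs, p, s$c, ph)
  })
  expect_equal(vals[[1]], vals[[2]], tolerance = 1e-12)
})

test_that("dissociation signal decays to the residual plateau", {
  ph <- phase_markers(0, 10, 400)
  p <- rate_parameters(1e5, 0.359, A = 10, y0 = 0, f_res = 0)
  expect_equal(dissociation_signal(10, p, ph, A_d = 10), 10)
  # half-life identity
  expect_equal(dissociation_signal(10 + log(2) / 0.359, p, ph, A_d = 10), 5)
  # fully non-dissociating limit is constant
  p1 <- rate_parameters(1e5, 0.359, A = 10, y0 = 3, f_res = 1)
  tt <- c(10, 50, 200, 400)
  expect_equal(dissociation_signal(tt, p1, ph, A_d = 10), rep(13, 4))
  # residual plateau y0 + A_d * f_res
  p02 <- rate_parameters(1e5, 0.359, A = 10, y0 = 0, f_res = 0.2)
  expect_equal(dissociation_signal(10 + 200, p02, ph, A_d = 10), 2,
               tolerance = 1e-9)
  expect_error(dissociation_signal(5, p, ph, A_d = 10),
               class = "out_of_window_error")
  expect_error(dissociation_signal(20, p, ph, A_d = -1),
               class = "invalid_parameter_error")
  expect_error(rate_parameters(1e5, 0.359, f_res = 1.2),
               class = "invalid_parameter_error")
})

test_that("equilibrium constants match the printed table rows and are exact reciprocals", {
  # fast intercalator, standard mode, 25 degC
  eq <- equilibrium_constants(6.98e5, 0.358)
  expect_equal(signif(eq$K_A, 3), 1.95e6)
  expect_equal(signif(eq$K_D, 3), 5.13e-7)
  # slow sulfonamide binder, 37 degC
  eq2 <- equilibrium_constants(15.4, 1.19e-2)
  expect_equal(signif(eq2$K_A, 3), 1.29e3)
  expect_equal(signif(eq2$K_D, 3), 7.73e-4)
  expect_equal(equilibrium_constants(0.42, 0.42)$K_A, 1)
  # K_A * K_D = 1 to machine precision for arbitrary valid rates
  set.seed(5)
  for (i in 1:50) {
    ka <- 10^stats::runif(1, -2, 7)
    kd <- 10^stats::runif(1, -4, 1)
    eqi <- equilibrium_constants(ka, kd)
    expect_equal(eqi$K_A * eqi$K_D, 1, tolerance = 1e-15)
  }
  expect_error(equilibrium_constants(0, 0.3), class = "invalid_parameter_error")
  expect_error(equilibrium_constants(1e5, -1), class = "invalid_parameter_error")
})

test_that("model traces are continuous, piecewise monotone, and flat for blanks", {
  ph <- phase_markers(5, 65, 365)
  p <- rate_parameters(6.98e5, 0.358, A = 20, y0 = 2, f_res = 0.25)
  tr <- model_trace(p, 1e-6, ph, sampling_rate = 10)
  expect_s3_class(tr, "sensorgram_trace")
  # continuity at t_d: limit from association equals dissociation start
  kobs <- observed_rate(p$k_a, 1e-6, p$k_d)
  A_d <- p$A * (1 - exp(-kobs * (ph$t_d - ph$t_a)))
  expect_equal(tr$signal[tr$time == ph$t_d],
               association_signal(ph$t_d, p, 1e-6, ph), tolerance = 1e-12)
  expect_equal(tr$signal[tr$time == ph$t_d],
               dissociation_signal(ph$t_d, p, ph, A_d), tolerance = 1e-12)
  # phases are monotone; strictly so while the exponential increments stay
  # above double-precision resolution (the saturated tail is numerically flat)
  assoc <- tr$signal[tr$time >= ph$t_a & tr$time < ph$t_d]
  diss <- tr$signal[tr$time >= ph$t_d]
  expect_true(all(diff(assoc) >= 0) && all(diff(diss) <= 0))
  resolved_a <- tr$time >= ph$t_a & tr$time < ph$t_a + 20 / kobs
  resolved_d <- tr$time >= ph$t_d & tr$time < ph$t_d + 20 / p$k_d
  expect_true(all(diff(tr$signal[resolved_a]) > 0))
  expect_true(all(diff(tr$signal[resolved_d]) < 0))
  # blank is flat at the baseline
  bl <- model_trace(p, 0, ph, sampling_rate = 10)
  expect_equal(bl$signal, rep(2, length(bl$time)))
  # long association window: dissociating amplitude approaches A
  ph_long <- phase_markers(1, 1001, 1100)
  tr_long <- model_trace(rate_parameters(1e6, 0.5, A = 12, y0 = 0), 1e-5,
                         ph_long, sampling_rate = 1)
  expect_equal(max(tr_long$signal), 12, tolerance = 1e-9)
})

test_that("zero residual fraction reproduces the complete-dissociation model pointwise", {
  ph <- phase_markers(5, 35, 100)
  p0 <- rate_parameters(1e5, 0.2, A = 15, y0 = 1, f_res = 0)
  tr <- model_trace(p0, 5e-6, ph, sampling_rate = 5)
  td_idx <- tr$time >= ph$t_d
  kobs <- observed_rate(p0$k_a, 5e-6, p0$k_d)
  A_d <- p0$A * (1 - exp(-kobs * (ph$t_d - ph$t_a)))
  manual <- p0$y0 + A_d * exp(-p0$k_d * (tr$time[td_idx] - ph$t_d))
  expect_equal(tr$signal[td_idx], manual, tolerance = 1e-12)
})

test_that("trace and phase constructors enforce their invariants", {
  expect_error(phase_markers(10, 5, 100), class = "invalid_parameter_error")
  expect_error(phase_markers(-1, 5, 100), class = "invalid_parameter_error")
  expect_error(phase_markers(1, 5, 5), class = "invalid_parameter_error")
  ph <- phase_markers(1, 5, 10)
  expect_error(sensorgram_trace(c(0, 1, 1), c(0, 0, 0), 1e-6, ph),
               class = "invalid_parameter_error")
  expect_error(sensorgram_trace(c(0, 1), c(0, 0, 0), 1e-6, ph),
               class = "invalid_parameter_error")
  expect_error(sensorgram_trace(c(0, 1), c(0, 0), -1e-6, ph),
               class = "invalid_parameter_error")
  expect_true(is_blank(sensorgram_trace(c(0, 1), c(0, 0), 0, ph)))
  expect_false(is_blank(sensorgram_trace(c(0, 1), c(0, 0), 1e-6, ph)))
})
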