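# Global weighted least-squares estimation of the shared rate constants
# (k_a, k_d, optionally f_res) over a concentration series, with per-trace
# amplitude and baseline. The optimizer is bounded Levenberg-Marquardt
# (minpack.lm::nls.lm); rates are fitted on the log scale for conditioning
# and positivity, f_res is box-constrained to [0, 1].

#' Model specification for the global fit
#'
#' @param dissociation_model `"complete"` (decay to baseline, `f_res` fixed
#'   at 0) or `"incomplete"` (shared residual bound fraction `f_res` in
#'   `[0, 1]` fitted).
#' @param share_amplitudes if `TRUE`, per-trace amplitudes are tied through
#'   the saturation law `A(c) = A_max * c / (c + k_d/k_a)` with a single
#'   fitted `A_max`; default leaves one free amplitude per trace, matching
#'   how the instrument software treats each curve.
#' @param weighting `"uniform"` or `"inverse_variance"` (per-trace weights
#'   from the baseline noise estimate).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(dissociation_model = c("complete", "incomplete"),
                       share_amplitudes = FALSE,
                       weighting = c("uniform", "inverse_variance")) {
  structure(list(dissociation_model = match.arg(dissociation_model),
                 share_amplitudes = isTRUE(share_amplitudes),
                 weighting = match.arg(weighting)),
            class = "model_spec")
}

# Decay rate from the log-linear regression of first differences.
# For y(t) = C + B*exp(-k*t) on a uniform grid, successive differences are
# proportional to exp(-k*t), so log|diff| is exactly linear in t with slope
# -k regardless of the (possibly unreached) plateau C. Long noisy segments
# are first averaged into coarse bins: equal-size bins on a uniform grid
# keep the binned means exactly exponential in the bin-centre times while
# suppressing the noise that would otherwise dominate the differences.
# Returns NA when the segment carries no usable exponential structure.
.decay_rate <- function(time, values, n_bins = 60) {
  n <- length(values)
  if (n < 4) return(NA_real_)
  if (n >= 3 * n_bins) {
    bs <- n %/% n_bins
    m <- bs * n_bins
    time <- colMeans(matrix(time[seq_len(m)], nrow = bs))
    values <- colMeans(matrix(values[seq_len(m)], nrow = bs))
  }
  d <- diff(values)
  tm <- time[-length(time)]
  mx <- max(abs(d))
  if (!is.finite(mx) || mx == 0) return(NA_real_)
  sgn <- sign(sum(sign(d)))
  if (sgn == 0) sgn <- sign(d[which.max(abs(d))])
  keep <- sign(d) == sgn & abs(d) > mx * 0.02
  if (sum(keep) < 3) keep <- abs(d) > mx * 1e-6
  if (sum(keep) < 3) return(NA_real_)
  co <- stats::lm.fit(cbind(1, tm[keep]), log(abs(d[keep])))$coefficients
  k <- -co[[2]]
  if (!is.finite(k) || k <= 0) NA_real_ else k
}

.baseline_of <- function(trace) {
  idx <- trace$time < trace$phases$t_a
  if (any(idx)) mean(trace$signal[idx]) else trace$signal[1]
}

# Half-life fallback for coarsely sampled phases: locate (by linear
# interpolation) where the signal crosses halfway between its value at t0
# and its plateau, giving k = log(2) / t_half. Far less precise than the
# log-difference regression but usable with only a handful of samples.
.halflife_rate <- function(time, values, t0) {
  if (length(values) < 2) return(NA_real_)
  start <- values[1]
  plateau <- mean(utils::tail(values, max(2, length(values) %/% 5)))
  if (!is.finite(plateau) || plateau == start) return(NA_real_)
  half <- (start + plateau) / 2
  crossed <- if (plateau > start) values >= half else values <= half
  i <- which(crossed)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) i <- 2
  # interpolate the crossing time between samples i-1 and i
  frac <- (half - values[i - 1]) / (values[i] - values[i - 1])
  t_half <- time[i - 1] + frac * (time[i] - time[i - 1]) - t0
  if (!is.finite(t_half) || t_half <= 0) return(NA_real_)
  log(2) / t_half
}

#' Heuristic starting values for the global fit
#'
#' Per trace: baseline from the pre-association segment, amplitude from the
#' largest baseline deviation, observed association rate `k_obs` and
#' dissociation rate from log-linear regressions of the phase-wise signal
#' differences (exact for noise-free mono-exponentials on a uniform grid).
#' Globally: `k_d` as the median per-trace dissociation rate, `k_a` as the
#' least-squares slope of `k_obs` against concentration (floored at a small
#' positive value), and `f_res` from the ratio of the dissociation-end
#' plateau to the end-of-association signal. Blank traces are ignored.
#'
#' @param series list of [sensorgram_trace()] objects.
#' @return A [rate_parameters()] object with per-trace `A`, `y0` vectors and
#'   attributes `k_obs` (per-trace observed rates) and `concentrations`.
#' @export
initial_guess <- function(series) {
  traces <- Filter(Negate(is_blank), series)
  if (length(traces) == 0) {
    skn_stop("guess_failure_error", "no non-blank traces to guess from")
  }
  n <- length(traces)
  y0 <- A <- k_obs <- k_d_i <- f_i <- rep(NA_real_, n)
  conc <- vapply(traces, function(tr) tr$concentration, numeric(1))
  diagnostics <- character(0)
  for (i in seq_len(n)) {
    tr <- traces[[i]]
    ph <- tr$phases
    y0[i] <- .baseline_of(tr)
    dev <- tr$signal - y0[i]
    A[i] <- dev[which.max(abs(dev))]
    ai <- tr$time >= ph$t_a & tr$time < ph$t_d
    di <- tr$time >= ph$t_d
    k_obs[i] <- .decay_rate(tr$time[ai], tr$signal[ai])
    if (is.na(k_obs[i])) {
      k_obs[i] <- .halflife_rate(tr$time[ai], tr$signal[ai], ph$t_a)
    }
    k_d_i[i] <- .decay_rate(tr$time[di], tr$signal[di])
    if (is.na(k_d_i[i])) {
      k_d_i[i] <- .halflife_rate(tr$time[di], tr$signal[di], ph$t_d)
    }
    if (is.na(k_obs[i])) {
      diagnostics <- c(diagnostics,
                       sprintf("trace %d (%s): association segment unusable for rate guess",
                               i, tr$label))
    }
    if (any(ai) && any(di)) {
      y_end_assoc <- tr$signal[max(which(ai))] - y0[i]
      y_plateau <- mean(utils::tail(tr$signal[di], 5)) - y0[i]
      if (is.finite(y_end_assoc) && abs(y_end_assoc) > 0) {
        f_i[i] <- min(max(y_plateau / y_end_assoc, 0), 1)
      }
    }
  }
  if (all(is.na(k_obs)) || all(is.na(k_d_i))) {
    skn_stop("guess_failure_error",
             paste(c("unable to derive rate guesses from any trace:", diagnostics),
                   collapse = "\n"),
             diagnostics = diagnostics)
  }
  k_d <- stats::median(k_d_i, na.rm = TRUE)
  ok <- is.finite(k_obs) & is.finite(conc)
  if (sum(ok) >= 2 && length(unique(conc[ok])) >= 2) {
    sl <- stats::lm.fit(cbind(1, conc[ok]), k_obs[ok])$coefficients[[2]]
  } else {
    sl <- (k_obs[ok][1] - k_d) / conc[ok][1]
  }
  # floor keeps the start in a regime where the concentration dependence is
  # non-negligible (k_a * c_max at least a few % of k_d)
  k_a <- max(sl, 1e-6, 0.05 * k_d / max(conc))
  out <- rate_parameters(k_a, k_d, A = A, y0 = y0,
                         f_res = if (all(is.na(f_i))) 0 else
                           min(max(mean(f_i, na.rm = TRUE), 0), 1))
  attr(out, "k_obs") <- k_obs
  attr(out, "concentrations") <- conc
  attr(out, "diagnostics") <- diagnostics
  out
}

# Per-trace noise SD estimated from first differences of the baseline
# segment (robust to the baseline level itself).
.noise_sd <- function(trace) {
  idx <- trace$time < trace$phases$t_a
  if (sum(idx) >= 3) stats::sd(diff(trace$signal[idx])) / sqrt(2) else NA_real_
}

# Pack/unpack helpers: p = (log k_a, log k_d, [f_res], A... or A_max, y0...)
.par_layout <- function(n_traces, model) {
  n_shared <- 2L + (model$dissociation_model == "incomplete")
  n_amp <- if (model$share_amplitudes) 1L else n_traces
  list(n_shared = n_shared, n_amp = n_amp,
       idx_f = if (n_shared == 3L) 3L else NA_integer_,
       idx_A = n_shared + seq_len(n_amp),
       idx_y0 = n_shared + n_amp + seq_len(n_traces),
       n_par = n_shared + n_amp + n_traces)
}

.predict_series <- function(p, traces, conc, model, layout) {
  k_a <- exp(p[1]); k_d <- exp(p[2])
  f_res <- if (!is.na(layout$idx_f)) p[layout$idx_f] else 0
  lapply(seq_along(traces), function(i) {
    A_i <- if (model$share_amplitudes) {
      p[layout$idx_A[1]] * conc[i] / (conc[i] + k_d / k_a)
    } else {
      p[layout$idx_A[i]]
    }
    .trace_signal(traces[[i]]$time, k_a, k_d, f_res, A_i,
                  p[layout$idx_y0[i]], conc[i], traces[[i]]$phases)
  })
}

#' Global fit of a concentration series
#'
#' Minimizes the summed squared residuals over every non-blank trace of the
#' series simultaneously, with the rate constants (and the residual bound
#' fraction, for the incomplete model) shared across traces and amplitude
#' and baseline free per trace. Requires at least two distinct analyte
#' concentrations: a single trace only determines the composite rate
#' `k_obs = k_a*c + k_d`, not the two rates separately.
#'
#' The fit is deterministic given the data, model and seed; the seed only
#' matters when `n_starts > 1`, which adds seeded log-scale jitter to the
#' starting rates as a guard against local minima.
#'
#' @param series list of [sensorgram_trace()] objects (blanks are dropped;
#'   apply [blank_correct()] first if blank subtraction is wanted).
#' @param model a [model_spec()].
#' @param seed integer seed (multi-start jitter only).
#' @param n_starts number of optimizer starts.
#' @param start optional [rate_parameters()] overriding [initial_guess()].
#' @param warn_identifiability warn when the association window is too short
#'   to approach the plateau (`max(k_obs) * duration < 1`).
#' @return An object of class `kinetic_fit` with elements `params`
#'   ([rate_parameters()]; per-trace `A`, `y0`), `constants`
#'   ([equilibrium_constants()], always `k_a/k_d` of the fit), shared-parameter
#'   `standard_errors` and `covariance` (curvature-based),
#'   `residual_sum_squares`, `n_points`, `information_criterion` (AICc),
#'   `model`, `converged`, per-trace `fitted` curves and `residuals`, and
#'   series metadata.
#' @examples
#' series <- simulate_series(rate_parameters(6.98e5, 0.358, A = 30),
#'                           design_eb_standard(sampling_rate = 2),
#'                           noise_spec(0.5, seed = 7))
#' fit <- fit_global(series)
#' fit$params$k_a
#' @export
fit_global <- function(series, model = model_spec(), seed = 1L,
                       n_starts = 1L, start = NULL,
                       warn_identifiability = TRUE) {
  stopifnot(inherits(model, "model_spec"))
  traces <- Filter(Negate(is_blank), series)
  conc <- vapply(traces, function(tr) tr$concentration, numeric(1))
  if (length(unique(conc)) < 2) {
    skn_stop("identifiability_error",
             "need >= 2 distinct non-blank concentrations: k_a and k_d are not separable from a single observed rate")
  }
  ph0 <- traces[[1]]$phases
  for (tr in traces) {
    if (abs(tr$phases$t_a - ph0$t_a) > 1e-8 || abs(tr$phases$t_d - ph0$t_d) > 1e-8) {
      skn_stop("invalid_parameter_error",
               "all traces in a series must share the same phase structure")
    }
  }
  if (model$dissociation_model == "incomplete" &&
      any(vapply(traces, function(tr) !any(tr$time >= tr$phases$t_d), logical(1)))) {
    skn_stop("invalid_parameter_error",
             "the incomplete model requires a dissociation window in every trace")
  }

  guess <- if (is.null(start)) initial_guess(traces) else start
  layout <- .par_layout(length(traces), model)
  p0 <- numeric(layout$n_par)
  p0[1] <- log(guess$k_a); p0[2] <- log(guess$k_d)
  if (!is.na(layout$idx_f)) p0[layout$idx_f] <- min(max(guess$f_res, 1e-3), 0.999)
  gA <- rep_len(guess$A, length(traces))
  p0[layout$idx_A] <- if (model$share_amplitudes) max(abs(gA)) * sign(gA[1]) else gA
  p0[layout$idx_y0] <- rep_len(guess$y0, length(traces))

  w <- rep(1, length(traces))
  if (model$weighting == "inverse_variance") {
    sds <- vapply(traces, .noise_sd, numeric(1))
    pooled <- stats::median(sds, na.rm = TRUE)
    sds[!is.finite(sds) | sds <= 0] <- pooled
    if (is.finite(pooled) && pooled > 0) w <- 1 / sds
  }

  sig_list <- lapply(traces, function(tr) tr$signal)
  resid_fn <- function(p) {
    pred <- .predict_series(p, traces, conc, model, layout)
    unlist(lapply(seq_along(traces), function(i) w[i] * (pred[[i]] - sig_list[[i]])),
           use.names = FALSE)
  }

  lower <- rep(-Inf, layout$n_par); upper <- rep(Inf, layout$n_par)
  lower[1:2] <- log(1e-12); upper[1:2] <- log(1e12)
  if (!is.na(layout$idx_f)) { lower[layout$idx_f] <- 0; upper[layout$idx_f] <- 1 }

  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15, gtol = 0,
                                     maxiter = 1024, maxfev = 100000)
  starts <- list(p0)
  if (n_starts > 1) {
    jit <- withr::with_seed(seed,
      replicate(n_starts - 1, stats::rnorm(2, 0, 1), simplify = FALSE))
    for (j in jit) {
      pj <- p0; pj[1:2] <- pj[1:2] + j
      starts <- c(starts, list(pj))
    }
  }
  best <- NULL
  for (s in starts) {
    res <- minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                              fn = resid_fn, control = ctrl)
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  # rescue pass for degenerate local minima: an optimum where
  # k_a * c_max << k_d has lost all concentration dependence, and one where
  # even the lowest concentration equilibrates within a single sample
  # (k_obs * dt >> 1 for every trace) has pushed the transient below the
  # sampling resolution; both are almost never the global optimum for a
  # concentration series. Retry from seeded jittered starts.
  dt_med <- stats::median(diff(traces[[1]]$time))
  degenerate <- exp(best$par[1]) * max(conc) < 0.01 * exp(best$par[2]) ||
    exp(best$par[1]) * min(conc) * dt_med > 3
  if (degenerate) {
    jit <- withr::with_seed(seed + 1L,
      replicate(6, stats::rnorm(2, 0, 1.5), simplify = FALSE))
    for (j in jit) {
      pj <- p0
      pj[1] <- log(max(observed_rate(exp(p0[1]), max(conc), exp(p0[2])) /
                         max(conc), 1e-6)) + j[1]
      pj[2] <- pj[2] + j[2]
      res <- minpack.lm::nls.lm(par = pj, lower = lower, upper = upper,
                                fn = resid_fn, control = ctrl)
      if (res$deviance < best$deviance) best <- res
    }
  }
  converged <- best$info %in% 1:3
  if (!converged) {
    warning(sprintf("global fit did not converge cleanly (nls.lm info %d: %s)",
                    best$info, best$message), call. = FALSE)
  }

  p_hat <- best$par
  k_a <- exp(p_hat[1]); k_d <- exp(p_hat[2])
  f_res <- if (!is.na(layout$idx_f)) p_hat[layout$idx_f] else 0
  A_hat <- if (model$share_amplitudes) {
    p_hat[layout$idx_A[1]] * conc / (conc + k_d / k_a)
  } else {
    p_hat[layout$idx_A]
  }
  y0_hat <- p_hat[layout$idx_y0]

  n_pts <- sum(lengths(sig_list))
  pred <- .predict_series(p_hat, traces, conc, model, layout)
  rss <- sum(vapply(seq_along(traces),
                    function(i) sum((pred[[i]] - sig_list[[i]])^2), numeric(1)))

  k_par <- layout$n_par + 1  # + residual variance
  aicc <- n_pts * log(max(rss, 1e-300) / n_pts) + 2 * k_par +
    2 * k_par * (k_par + 1) / max(n_pts - k_par - 1, 1)

  unc <- .curvature_se(best, layout, k_a, k_d, rss, n_pts)

  params <- rate_parameters(k_a, k_d, A = A_hat, y0 = y0_hat, f_res = f_res)
  kobs_max <- max(observed_rate(k_a, conc, k_d))
  if (warn_identifiability &&
      kobs_max * (ph0$t_d - ph0$t_a) < 1) {
    warning(sprintf("association window may be too short: max(k_obs) * duration = %.3g < 1 (plateau not approached)",
                    kobs_max * (ph0$t_d - ph0$t_a)), call. = FALSE)
  }

  structure(list(
    params = params,
    constants = equilibrium_constants(k_a, k_d),
    standard_errors = unc$se,
    covariance = unc$cov,
    residual_sum_squares = rss,
    n_points = n_pts,
    information_criterion = aicc,
    model = model,
    converged = converged,
    optimizer = list(info = best$info, message = best$message,
                     deviance = best$deviance, niter = best$niter),
    uncertainty_method = "curvature",
    fitted = lapply(seq_along(traces), function(i)
      list(time = traces[[i]]$time, signal = pred[[i]])),
    residuals = lapply(seq_along(traces), function(i) sig_list[[i]] - pred[[i]]),
    concentrations = conc,
    trace_labels = vapply(traces, function(tr) tr$label, character(1)),
    temperature = unique(vapply(traces, function(tr) tr$temperature, numeric(1))),
    mode = unique(vapply(traces, function(tr) tr$mode, character(1))),
    seed = as.integer(seed)
  ), class = "kinetic_fit")
}

# Curvature (local quadratic) standard errors for the shared parameters,
# transformed from the log-rate scale to the natural scale by the delta
# method. Returns NA SEs with a diagnostic when J'J is singular.
.curvature_se <- function(lm_res, layout, k_a, k_d, rss, n_pts) {
  shared <- seq_len(layout$n_shared)
  nm <- c("k_a", "k_d", if (layout$n_shared == 3) "f_res")
  dof <- max(n_pts - layout$n_par, 1)
  sigma2 <- rss / dof
  cov_all <- tryCatch(sigma2 * solve(lm_res$hessian), error = function(e) NULL)
  if (is.null(cov_all) || anyNA(cov_all[shared, shared])) {
    se <- stats::setNames(rep(NA_real_, length(shared)), nm)
    return(list(se = se, cov = NULL,
                diagnostic = "singular curvature: standard errors unavailable"))
  }
  D <- diag(c(k_a, k_d, if (layout$n_shared == 3) 1), nrow = length(shared))
  cov_nat <- D %*% cov_all[shared, shared, drop = FALSE] %*% D
  dimnames(cov_nat) <- list(nm, nm)
  se <- stats::setNames(sqrt(pmax(diag(cov_nat), 0)), nm)
  list(se = se, cov = cov_nat, diagnostic = NULL)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Global 1:1 kinetic fit (%s dissociation, %s weighting)%s\n",
              x$model$dissociation_model, x$model$weighting,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  se <- x$standard_errors
  cat(sprintf("  k_a = %.4g +/- %.2g M^-1 s^-1\n", x$params$k_a, se[["k_a"]]))
  cat(sprintf("  k_d = %.4g +/- %.2g s^-1\n", x$params$k_d, se[["k_d"]]))
  if (x$model$dissociation_model == "incomplete") {
    cat(sprintf("  f_res = %.3g +/- %.2g\n", x$params$f_res, se[["f_res"]]))
  }
  cat(sprintf("  K_A = %.4g M^-1, K_D = %.4g M\n", x$constants$K_A, x$constants$K_D))
  cat(sprintf("  RSS = %.4g over %d points, AICc = %.4g\n",
              x$residual_sum_squares, x$n_points, x$information_criterion))
  invisible(x)
}

#' Choose between complete and incomplete dissociation models
#'
#' Fits both dissociation models and returns the one with the lower
#' small-sample-corrected information criterion (AICc); ties favour the
#' simpler complete model. Motivated by analytes whose signal does not
#' return to baseline under buffer flow.
#'
#' @param series list of [sensorgram_trace()] objects.
#' @param seed integer seed passed to both fits.
#' @param ... further arguments to [fit_global()].
#' @return A list with elements `model` (the selected [model_spec()]), `fit`
#'   (the selected `kinetic_fit`), and `criteria` (named AICc values).
#' @export
select_dissociation_model <- function(series, seed = 1L, ...) {
  f_c <- fit_global(series, model_spec("complete"), seed = seed, ...)
  f_i <- fit_global(series, model_spec("incomplete"), seed = seed, ...)
  crit <- c(complete = f_c$information_criterion,
            incomplete = f_i$information_criterion)
  pick_incomplete <- f_i$converged &&
    (!f_c$converged || f_i$information_criterion < f_c$information_criterion)
  fit <- if (pick_incomplete) f_i else f_c
  list(model = fit$model, fit = fit, criteria = crit)
}

#' Uncertainty estimates for the shared fit parameters
#'
#' `"curvature"` recomputes standard errors from the local quadratic
#' approximation at the optimum (the default already attached by
#' [fit_global()]). `"bootstrap"` resamples residuals within each trace,
#' refits `n_boot` times from the fitted optimum, and reports the bootstrap
#' SD and covariance; it is deterministic given `seed`.
#'
#' @param fit a converged `kinetic_fit`.
#' @param series the series the fit was computed from.
#' @param method `"curvature"` or `"bootstrap"`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return The `kinetic_fit` with updated `standard_errors`, `covariance`,
#'   `uncertainty_method` (and, for the bootstrap, a `bootstrap` matrix of
#'   resampled shared parameters).
#' @export
estimate_uncertainty <- function(fit, series,
                                 method = c("curvature", "bootstrap"),
                                 n_boot = 200L, seed = 1L) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (!fit$converged) {
    skn_stop("invalid_parameter_error", "uncertainty requires a converged fit")
  }
  method <- match.arg(method)
  if (method == "curvature") {
    fit$uncertainty_method <- "curvature"
    return(fit)
  }
  traces <- Filter(Negate(is_blank), series)
  nm <- names(fit$standard_errors)
  boot_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_boot))
  draws <- matrix(NA_real_, n_boot, length(nm), dimnames = list(NULL, nm))
  for (b in seq_len(n_boot)) {
    pert <- withr::with_seed(boot_seeds[b], lapply(seq_along(traces), function(i) {
      r <- fit$residuals[[i]]
      fit$fitted[[i]]$signal + sample(r, length(r), replace = TRUE)
    }))
    boot_traces <- lapply(seq_along(traces), function(i) {
      tr <- traces[[i]]
      sensorgram_trace(tr$time, pert[[i]], tr$concentration, tr$phases,
                       temperature = tr$temperature, mode = tr$mode,
                       label = tr$label)
    })
    bf <- tryCatch(
      suppressWarnings(fit_global(boot_traces, model = fit$model,
                                  seed = fit$seed, start = fit$params,
                                  warn_identifiability = FALSE)),
      switchkin_error = function(e) NULL)
    if (!is.null(bf) && bf$converged) {
      draws[b, ] <- c(bf$params$k_a, bf$params$k_d,
                      if ("f_res" %in% nm) bf$params$f_res)
    }
  }
  ok <- stats::complete.cases(draws)
  if (sum(ok) < 2) {
    skn_stop("invalid_parameter_error", "bootstrap produced < 2 usable refits")
  }
  fit$standard_errors <- apply(draws[ok, , drop = FALSE], 2, stats::sd)
  fit$covariance <- stats::cov(draws[ok, , drop = FALSE])
  fit$bootstrap <- draws[ok, , drop = FALSE]
  fit$uncertainty_method <- "bootstrap"
  fit
}

#' Aggregate replicate fits into mean +/- SD summaries
#'
#' Replicate experiments on the same system, temperature and mode are
#' summarized as the arithmetic mean and sample SD of each shared parameter.
#' The equilibrium constants are summarized from the per-replicate
#' `K_A = k_a/k_d` values, not from the ratio of the means (the two differ
#' whenever replicates disagree).
#'
#' @param results list of >= 2 converged `kinetic_fit` objects sharing
#'   temperature and mode (and dissociation model).
#' @return A data frame with columns `parameter`, `mean`, `sd`, `n`, plus
#'   attributes `temperature` and `mode`.
#' @export
aggregate_replicates <- function(results) {
  if (length(results) < 2) {
    skn_stop("aggregation_mismatch_error", "need >= 2 replicate fits")
  }
  for (r in results) {
    stopifnot(inherits(r, "kinetic_fit"))
    if (!r$converged) {
      skn_stop("aggregation_mismatch_error", "all replicate fits must have converged")
    }
  }
  temps <- unique(unlist(lapply(results, `[[`, "temperature")))
  modes <- unique(unlist(lapply(results, `[[`, "mode")))
  dmods <- unique(vapply(results, function(r) r$model$dissociation_model, character(1)))
  if (length(temps) != 1 || length(modes) != 1 || length(dmods) != 1) {
    skn_stop("aggregation_mismatch_error",
             "replicates must share temperature, mode and dissociation model")
  }
  grab <- function(f) vapply(results, f, numeric(1))
  vals <- list(k_a = grab(function(r) r$params$k_a),
               k_d = grab(function(r) r$params$k_d))
  if (dmods == "incomplete") {
    vals$f_res <- grab(function(r) r$params$f_res)
  }
  vals$K_A <- grab(function(r) r$constants$K_A)
  vals$K_D <- grab(function(r) r$constants$K_D)
  out <- data.frame(
    parameter = names(vals),
    mean = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, stats::sd, numeric(1)),
    n = length(results),
    row.names = NULL
  )
  attr(out, "temperature") <- temps
  attr(out, "mode") <- modes
  out
}
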