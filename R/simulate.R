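# Seeded generators for synthetic sensorgram series and docking pose sets.
# These emulate the statistical structure the analysis assumes so the whole
# pipeline can be exercised without instrument data.

#' Descending concentration ladder
#'
#' @param top highest concentration (M).
#' @param factor dilution factor between consecutive levels.
#' @param n number of levels.
#' @return Numeric vector, descending.
#' @examples
#' concentration_ladder(1e-6, 2, 5)
#' @export
concentration_ladder <- function(top, factor = 2, n = 5) {
  .check_finite(top, "top"); .check_finite(factor, "factor")
  if (top <= 0 || factor <= 1 || n < 1) {
    skn_stop("invalid_design_error", "need top > 0, factor > 1, n >= 1")
  }
  top / factor^(seq_len(n) - 1)
}

#' Design of a concentration-series experiment
#'
#' Captures the measurement design: the concentration ladder, phase
#' durations, sampling rate, how many blank (buffer-only) runs bracket the
#' series, and the measurement metadata. The trace timeline is
#' `[0, baseline_duration)` baseline, then the association phase, then the
#' dissociation phase.
#'
#' @param concentrations distinct positive analyte concentrations (M);
#'   stored in descending order.
#' @param association_duration association phase length (s).
#' @param dissociation_duration dissociation phase length (s).
#' @param sampling_rate sampling rate (Hz).
#' @param n_blanks_before,n_blanks_after number of blank runs before/after
#'   the ladder.
#' @param temperature deg C.
#' @param mode `"static_standard"` or `"static_weak_binder"`.
#' @param baseline_duration pre-association baseline length (s).
#' @param dilution_factor optional dilution factor metadata.
#' @return An object of class `series_design`.
#' @seealso [design_eb_standard()], [design_eb_weak_binder()],
#'   [design_slow_binder()] for the built-in designs.
#' @export
series_design <- function(concentrations,
                          association_duration = 60,
                          dissociation_duration = 300,
                          sampling_rate = 10,
                          n_blanks_before = 1, n_blanks_after = 1,
                          temperature = 25, mode = "static_standard",
                          baseline_duration = 5,
                          dilution_factor = NULL) {
  if (length(concentrations) < 1) {
    skn_stop("invalid_design_error", "`concentrations` must be non-empty")
  }
  .check_finite(concentrations, "concentrations")
  if (any(concentrations <= 0)) {
    skn_stop("invalid_design_error", "all concentrations must be > 0")
  }
  if (anyDuplicated(concentrations)) {
    skn_stop("invalid_design_error", "concentrations must be distinct")
  }
  if (association_duration <= 0 || dissociation_duration <= 0 ||
      sampling_rate <= 0 || baseline_duration <= 0) {
    skn_stop("invalid_design_error", "durations and sampling rate must be > 0")
  }
  mode <- match.arg(mode, c("static_standard", "static_weak_binder"))
  structure(
    list(concentrations = sort(concentrations, decreasing = TRUE),
         association_duration = association_duration,
         dissociation_duration = dissociation_duration,
         sampling_rate = sampling_rate,
         n_blanks_before = as.integer(n_blanks_before),
         n_blanks_after = as.integer(n_blanks_after),
         temperature = temperature, mode = mode,
         baseline_duration = baseline_duration,
         dilution_factor = dilution_factor),
    class = "series_design"
  )
}

#' @export
print.series_design <- function(x, ...) {
  cat(sprintf("Series design (%s, %g degC): %d concentrations %.3g..%.3g M,\n",
              x$mode, x$temperature, length(x$concentrations),
              max(x$concentrations), min(x$concentrations)))
  cat(sprintf("  association %g s, dissociation %g s, %g Hz, blanks %d before / %d after\n",
              x$association_duration, x$dissociation_duration, x$sampling_rate,
              x$n_blanks_before, x$n_blanks_after))
  invisible(x)
}

#' Phase markers implied by a series design
#'
#' @param design a [series_design()].
#' @return A [phase_markers()] object.
#' @export
design_phases <- function(design) {
  stopifnot(inherits(design, "series_design"))
  t_a <- design$baseline_duration
  t_d <- t_a + design$association_duration
  phase_markers(t_a, t_d, t_d + design$dissociation_duration)
}

#' Built-in measurement designs
#'
#' `design_eb_standard()` is the static standard-kinetics design used for a
#' fast intercalator such as ethidium bromide: five concentrations from
#' 1e-6 M down by factor 2, 60 s association, 300 s dissociation.
#' `design_eb_weak_binder()` is the shortened weak-binder variant (30 s / 60 s,
#' six concentrations down to 3.125e-8 M). `design_slow_binder()` is the
#' extended design for slowly associating, incompletely dissociating
#' analytes (2e-4 M down by factor 2 to 2.5e-5 M, 240 s / 480 s).
#'
#' @param temperature deg C.
#' @param sampling_rate Hz.
#' @return A [series_design()].
#' @export
design_eb_standard <- function(temperature = 25, sampling_rate = 10) {
  series_design(concentration_ladder(1e-6, 2, 5),
                association_duration = 60, dissociation_duration = 300,
                sampling_rate = sampling_rate, temperature = temperature,
                mode = "static_standard", dilution_factor = 2)
}

#' @rdname design_eb_standard
#' @export
design_eb_weak_binder <- function(temperature = 25, sampling_rate = 10) {
  series_design(concentration_ladder(1e-6, 2, 6),
                association_duration = 30, dissociation_duration = 60,
                sampling_rate = sampling_rate, temperature = temperature,
                mode = "static_weak_binder", dilution_factor = 2)
}

#' @rdname design_eb_standard
#' @export
design_slow_binder <- function(temperature = 25, sampling_rate = 10) {
  series_design(concentration_ladder(2e-4, 2, 4),
                association_duration = 240, dissociation_duration = 480,
                sampling_rate = sampling_rate, temperature = temperature,
                mode = "static_weak_binder", dilution_factor = 2)
}

#' Additive noise specification
#'
#' Noise is additive, homoscedastic and normally distributed, with standard
#' deviation expressed as a percentage of the maximum noise-free amplitude
#' of the series ("full scale"), so blanks carry the same noise floor as
#' analyte traces. An optional linear baseline drift can be added.
#'
#' @param sigma_pct_fullscale noise SD as % of full-scale amplitude, `>= 0`.
#' @param drift_per_s linear baseline drift (% per s).
#' @param seed integer random seed; identical seeds give identical output.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_pct_fullscale = 0.5, drift_per_s = 0, seed = 1L) {
  .check_finite(sigma_pct_fullscale, "sigma_pct_fullscale")
  .check_finite(drift_per_s, "drift_per_s")
  if (sigma_pct_fullscale < 0) {
    skn_stop("invalid_parameter_error", "`sigma_pct_fullscale` must be >= 0")
  }
  structure(list(sigma_pct_fullscale = sigma_pct_fullscale,
                 drift_per_s = drift_per_s, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Simulate one noisy sensorgram trace
#'
#' [model_trace()] plus seeded additive Gaussian noise (and optional drift).
#' The generating parameters are recorded in the `"truth"` attribute so
#' recovery tests can compare estimates against them.
#'
#' @param truth a [rate_parameters()] object (scalar `A`, `y0`).
#' @param c analyte concentration (M); 0 gives a blank.
#' @param design a [series_design()].
#' @param noise a [noise_spec()].
#' @param full_scale amplitude (%) defining 100% of the noise scale;
#'   defaults to `|truth$A|`. [simulate_series()] passes the series maximum
#'   so every trace of a series shares one noise floor.
#' @param label trace label.
#' @return A [sensorgram_trace()] with a `"truth"` attribute.
#' @export
simulate_trace <- function(truth, c, design, noise, full_scale = NULL,
                           label = "") {
  stopifnot(inherits(truth, "rate_parameters"), inherits(design, "series_design"),
            inherits(noise, "noise_spec"))
  phases <- design_phases(design)
  clean <- model_trace(truth, c, phases, design$sampling_rate,
                       temperature = design$temperature, mode = design$mode,
                       label = label)
  fs <- if (is.null(full_scale)) abs(truth$A[1]) else abs(full_scale)
  sd_abs <- noise$sigma_pct_fullscale / 100 * fs
  eps <- withr::with_seed(noise$seed, stats::rnorm(length(clean$time), 0, sd_abs))
  sig <- clean$signal + eps + noise$drift_per_s * clean$time
  out <- sensorgram_trace(clean$time, sig, c, phases,
                          temperature = design$temperature, mode = design$mode,
                          label = label)
  attr(out, "truth") <- list(params = truth, concentration = c,
                             noise = noise, full_scale = fs)
  out
}

#' Simulate a full concentration series
#'
#' One noisy trace per concentration of the design, bracketed by the
#' requested number of zero-concentration blanks before and after. By
#' default the per-trace amplitude follows the equilibrium saturation law
#' `A(c) = A_max * c / (c + K_D)` with `K_D = k_d / k_a` from the truth and
#' `A_max = truth$A`, reproducing the concentration-response correlation a
#' real series shows; `amplitude_model = "free"` instead draws independent
#' amplitudes uniformly in `[0.3, 1] * A_max`. Per-trace noise seeds are
#' derived deterministically from `noise$seed`.
#'
#' @param truth a [rate_parameters()] object; `truth$A` is the saturating
#'   amplitude `A_max`.
#' @param design a [series_design()].
#' @param noise a [noise_spec()].
#' @param amplitude_model `"saturation"` (default) or `"free"`.
#' @return A list of [sensorgram_trace()] objects (class
#'   `sensorgram_series`): blanks first, then descending concentrations,
#'   then trailing blanks.
#' @examples
#' series <- simulate_series(rate_parameters(6.98e5, 0.358, A = 30),
#'                           design_eb_standard(), noise_spec(seed = 42))
#' length(series)  # 5 concentrations + 2 blanks
#' @export
simulate_series <- function(truth, design, noise,
                            amplitude_model = c("saturation", "free")) {
  stopifnot(inherits(truth, "rate_parameters"), inherits(design, "series_design"),
            inherits(noise, "noise_spec"))
  amplitude_model <- match.arg(amplitude_model)
  concs <- design$concentrations
  n <- length(concs)
  K_D <- truth$k_d / truth$k_a
  n_total <- design$n_blanks_before + n + design$n_blanks_after

  draws <- withr::with_seed(noise$seed, list(
    sub_seeds = sample.int(.Machine$integer.max, n_total),
    free_A = stats::runif(n, 0.3, 1)
  ))
  A_c <- switch(amplitude_model,
                saturation = truth$A[1] * concs / (concs + K_D),
                free = truth$A[1] * draws$free_A)
  full_scale <- max(abs(A_c))

  all_conc <- c(rep(0, design$n_blanks_before), concs,
                rep(0, design$n_blanks_after))
  labels <- c(sprintf("blank_pre_%d", seq_len(design$n_blanks_before)),
              sprintf("c_%0.4g_M", concs),
              sprintf("blank_post_%d", seq_len(design$n_blanks_after)))
  all_A <- c(rep(0, design$n_blanks_before), A_c, rep(0, design$n_blanks_after))

  out <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    tr_truth <- rate_parameters(truth$k_a, truth$k_d,
                                A = if (all_conc[i] > 0) all_A[i] else truth$A[1],
                                y0 = truth$y0[1], f_res = truth$f_res)
    if (all_conc[i] == 0) {
      # blanks have zero amplitude by construction (c = 0 short-circuits the
      # model); keep truth$A for the record
      tr_truth$A <- 0
    }
    tr_noise <- noise_spec(noise$sigma_pct_fullscale, noise$drift_per_s,
                           seed = draws$sub_seeds[i])
    out[[i]] <- simulate_trace(tr_truth, all_conc[i], design, tr_noise,
                               full_scale = full_scale, label = labels[i])
  }
  structure(out, class = "sensorgram_series",
            truth = list(params = truth, design = design, noise = noise,
                         amplitudes = A_c, amplitude_model = amplitude_model))
}

#' @export
print.sensorgram_series <- function(x, ...) {
  concs <- vapply(x, function(tr) tr$concentration, numeric(1))
  cat(sprintf("Sensorgram series: %d traces (%d blanks), concentrations %s M\n",
              length(x), sum(concs == 0),
              paste(signif(sort(unique(concs[concs > 0]), decreasing = TRUE), 3),
                    collapse = ", ")))
  invisible(x)
}

#' Diagnostic overlay of a series (and optionally a fit)
#'
#' @param x a `sensorgram_series`.
#' @param fit optional [fit_global()] result whose fitted curves are drawn
#'   over the non-blank traces.
#' @param ... passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.sensorgram_series <- function(x, fit = NULL, ...) {
  times <- x[[1]]$time
  sig <- vapply(x, function(tr) tr$signal, numeric(length(times)))
  graphics::matplot(times, sig, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "fluorescence change (%)", ...)
  if (!is.null(fit)) {
    for (i in seq_along(fit$fitted)) {
      graphics::lines(fit$fitted[[i]]$time, fit$fitted[[i]]$signal, lwd = 2)
    }
  }
  invisible(x)
}

#' Simulate a docking pose set
#'
#' Draws `n_poses` poses from a mixture of binding sites: each site has a
#' 3-D centroid (Angstrom), an isotropic Gaussian positional spread, an
#' abundance weight, and a Gaussian energy distribution (kcal/mol,
#' magnitudes: larger = stronger). The generating site of each pose is
#' recorded as hidden truth for recovery tests.
#'
#' @param site_specs list of site specifications, each a list with fields
#'   `centroid` (length-3 numeric), `spread` (> 0), `weight` (>= 0),
#'   `energy_mean`, `energy_sd`.
#' @param n_poses number of poses to draw, `> 0`.
#' @param seed integer seed.
#' @return A [pose_set()] with a `"true_site"` attribute.
#' @export
simulate_pose_set <- function(site_specs, n_poses, seed = 1L) {
  if (n_poses < 1) skn_stop("invalid_spec_error", "`n_poses` must be > 0")
  for (s in site_specs) {
    if (length(s$centroid) != 3 || !all(is.finite(s$centroid))) {
      skn_stop("invalid_spec_error", "each site needs a finite length-3 centroid")
    }
    if (!isTRUE(s$spread > 0)) {
      skn_stop("invalid_spec_error", "site spreads must be > 0")
    }
  }
  w <- vapply(site_specs, function(s) s$weight, numeric(1))
  if (any(w < 0) || sum(w) <= 0) {
    skn_stop("invalid_spec_error", "weights must be >= 0 and sum to a positive value")
  }
  draws <- withr::with_seed(seed, {
    site <- sample.int(length(site_specs), n_poses, replace = TRUE, prob = w)
    xyz <- t(vapply(site, function(i) {
      site_specs[[i]]$centroid + stats::rnorm(3, 0, site_specs[[i]]$spread)
    }, numeric(3)))
    energy <- vapply(site, function(i) {
      stats::rnorm(1, site_specs[[i]]$energy_mean, site_specs[[i]]$energy_sd)
    }, numeric(1))
    list(site = site, xyz = xyz, energy = pmax(energy, 0))
  })
  ps <- pose_set(data.frame(id = sprintf("pose_%03d", seq_len(n_poses)),
                            x = draws$xyz[, 1], y = draws$xyz[, 2],
                            z = draws$xyz[, 3], energy = draws$energy))
  attr(ps, "true_site") <- draws$site
  ps
}
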