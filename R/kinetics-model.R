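# Core 1:1 interaction model for switchSense-style sensorgrams.
#
# Units are fixed throughout the package: time in seconds, analyte
# concentration in molar, signal in percent fluorescence change relative to
# the reference. All unit conversions belong at I/O boundaries.

#' Signal a classed package error
#'
#' @param class condition subclass, e.g. `"invalid_parameter_error"`.
#' @param msg message.
#' @param ... extra condition fields.
#' @noRd
skn_stop <- function(class, msg, ...) {
  cond <- structure(
    class = c(class, "switchkin_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  )
  stop(cond)
}

.check_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    skn_stop("invalid_parameter_error",
             sprintf("`%s` must be finite numeric, got: %s",
                     name, paste(utils::head(x, 3), collapse = ", ")))
  }
  invisible(x)
}

#' Phase markers of a sensorgram
#'
#' Start times of the association and dissociation phases and the end of the
#' record. The interval `[0, t_a)` is the pre-association baseline,
#' `[t_a, t_d)` the association phase (analyte flowing), `[t_d, t_end]` the
#' dissociation phase (buffer flowing).
#'
#' @param t_a association start time (s), `>= 0`.
#' @param t_d dissociation start time (s), `> t_a`.
#' @param t_end end of trace (s), `> t_d`.
#' @return An object of class `phase_markers`.
#' @examples
#' phase_markers(5, 65, 365)
#' @export
phase_markers <- function(t_a, t_d, t_end) {
  .check_finite(t_a, "t_a"); .check_finite(t_d, "t_d"); .check_finite(t_end, "t_end")
  if (!(t_a >= 0 && t_a < t_d && t_d < t_end)) {
    skn_stop("invalid_parameter_error",
             sprintf("phase markers must satisfy 0 <= t_a < t_d < t_end (got %g, %g, %g)",
                     t_a, t_d, t_end))
  }
  structure(list(t_a = t_a, t_d = t_d, t_end = t_end), class = "phase_markers")
}

#' @export
print.phase_markers <- function(x, ...) {
  cat(sprintf("Phase markers: baseline [0, %g) s, association [%g, %g) s, dissociation [%g, %g] s\n",
              x$t_a, x$t_a, x$t_d, x$t_d, x$t_end))
  invisible(x)
}

#' Kinetic and per-trace signal parameters
#'
#' Bundles the shared rate constants of the 1:1 model with the per-trace
#' signal parameters. `A` and `y0` may be vectors (one entry per trace in a
#' series); the rates and the residual bound fraction are scalars shared
#' across a series.
#'
#' @param k_a association rate constant (M^-1 s^-1), `> 0`.
#' @param k_d dissociation rate constant (s^-1), `> 0`.
#' @param A signal amplitude(s) (% fluorescence change); may be negative for
#'   analytes that quench the reporter dye.
#' @param y0 baseline(s) (%).
#' @param f_res residual bound fraction in `[0, 1]`; `0` means complete
#'   dissociation and recovers the plain exponential decay.
#' @return An object of class `rate_parameters`.
#' @examples
#' rate_parameters(k_a = 6.98e5, k_d = 0.358, A = 20, y0 = 0)
#' @export
rate_parameters <- function(k_a, k_d, A = 10, y0 = 0, f_res = 0) {
  .check_finite(k_a, "k_a"); .check_finite(k_d, "k_d")
  .check_finite(A, "A"); .check_finite(y0, "y0"); .check_finite(f_res, "f_res")
  if (k_a <= 0) skn_stop("invalid_parameter_error", "`k_a` must be > 0")
  if (k_d <= 0) skn_stop("invalid_parameter_error", "`k_d` must be > 0")
  if (f_res < 0 || f_res > 1) {
    skn_stop("invalid_parameter_error", "`f_res` must lie in [0, 1]")
  }
  structure(list(k_a = k_a, k_d = k_d, A = A, y0 = y0, f_res = f_res),
            class = "rate_parameters")
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat(sprintf("Rate parameters: k_a = %.4g M^-1 s^-1, k_d = %.4g s^-1, f_res = %.3g\n",
              x$k_a, x$k_d, x$f_res))
  cat(sprintf("  amplitudes A: %s %%\n", paste(signif(x$A, 4), collapse = ", ")))
  cat(sprintf("  baselines y0: %s %%\n", paste(signif(x$y0, 4), collapse = ", ")))
  invisible(x)
}

#' Pseudo-first-order observed association rate
#'
#' In the 1:1 interaction model the association phase relaxes with the
#' composite rate `k_obs = k_a * c + k_d`: the approach to the new
#' equilibrium is governed by both complex formation and decay. At zero
#' concentration `k_obs` reduces to `k_d`.
#'
#' @param k_a association rate constant (M^-1 s^-1), `> 0`.
#' @param c analyte concentration (M), `>= 0`; may be a vector.
#' @param k_d dissociation rate constant (s^-1), `> 0`.
#' @return Observed rate(s) `k_obs` (s^-1), always `>= k_d`.
#' @examples
#' observed_rate(6.98e5, 1e-6, 0.358)  # 1.056 s^-1
#' @export
observed_rate <- function(k_a, c, k_d) {
  .check_finite(k_a, "k_a"); .check_finite(c, "c"); .check_finite(k_d, "k_d")
  if (k_a <= 0) skn_stop("invalid_parameter_error", "`k_a` must be > 0")
  if (k_d <= 0) skn_stop("invalid_parameter_error", "`k_d` must be > 0")
  if (any(c < 0)) skn_stop("invalid_parameter_error", "`c` must be >= 0")
  k_a * c + k_d
}

#' Association-phase model signal
#'
#' Mono-exponential rise from the baseline toward the equilibrium plateau:
#' `F(t) = y0 + A * (1 - exp(-(k_a*c + k_d) * (t - t_a)))` for
#' `t_a <= t <= t_d`. The value at `t = t_a` is exactly `y0`; the
#' asymptote is `y0 + A`.
#'
#' @param t time(s) (s), all within `[t_a, t_d]`.
#' @param params a [rate_parameters()] object (scalar `A`, `y0` used).
#' @param c analyte concentration (M).
#' @param phases a [phase_markers()] object.
#' @return Model signal (%) at `t`.
#' @examples
#' ph <- phase_markers(0, 30, 90)
#' association_signal(1, rate_parameters(1.5e6, 0.359, A = 10, y0 = 0), 1e-6, ph)
#' @export
association_signal <- function(t, params, c, phases) {
  stopifnot(inherits(params, "rate_parameters"), inherits(phases, "phase_markers"))
  .check_finite(t, "t")
  if (any(t < phases$t_a) || any(t > phases$t_d)) {
    skn_stop("out_of_window_error",
             sprintf("`t` must lie in the association window [%g, %g] s",
                     phases$t_a, phases$t_d))
  }
  kobs <- observed_rate(params$k_a, c, params$k_d)
  params$y0[1] + params$A[1] * (1 - exp(-kobs * (t - phases$t_a)))
}

#' Dissociation-phase model signal
#'
#' Exponential decay from the end-of-association signal toward the residual
#' plateau: `F(t) = y0 + A_d * (f_res + (1 - f_res) * exp(-k_d * (t - t_d)))`
#' for `t >= t_d`. With `f_res = 0` this is the complete-dissociation decay
#' to baseline; with `f_res = 1` the signal never decays (fully
#' non-dissociating adduct).
#'
#' @param t time(s) (s), all `>= t_d`.
#' @param params a [rate_parameters()] object (`k_d`, `y0`, `f_res` used).
#' @param phases a [phase_markers()] object.
#' @param A_d dissociating amplitude (%) at the start of the phase, `>= 0`.
#' @return Model signal (%) at `t`.
#' @export
dissociation_signal <- function(t, params, phases, A_d) {
  stopifnot(inherits(params, "rate_parameters"), inherits(phases, "phase_markers"))
  .check_finite(t, "t"); .check_finite(A_d, "A_d")
  if (A_d < 0) skn_stop("invalid_parameter_error", "`A_d` must be >= 0")
  if (any(t < phases$t_d)) {
    skn_stop("out_of_window_error",
             sprintf("`t` must be >= t_d = %g s", phases$t_d))
  }
  f <- params$f_res
  params$y0[1] + A_d * (f + (1 - f) * exp(-params$k_d * (t - phases$t_d)))
}

#' Equilibrium association and dissociation constants
#'
#' At equilibrium the 1:1 model gives `K_A = k_a / k_d` (M^-1) and its
#' reciprocal `K_D = k_d / k_a` (M). `K_A * K_D = 1` holds exactly by
#' construction.
#'
#' @param k_a association rate constant (M^-1 s^-1), `> 0`.
#' @param k_d dissociation rate constant (s^-1), `> 0`.
#' @return An object of class `equilibrium_constants` with fields `K_A`, `K_D`.
#' @examples
#' equilibrium_constants(6.98e5, 0.358)  # K_A = 1.95e6 M^-1, K_D = 5.13e-7 M
#' @export
equilibrium_constants <- function(k_a, k_d) {
  .check_finite(k_a, "k_a"); .check_finite(k_d, "k_d")
  if (k_a <= 0 || k_d <= 0) {
    skn_stop("invalid_parameter_error", "rates must be > 0 to form equilibrium constants")
  }
  structure(list(K_A = k_a / k_d, K_D = k_d / k_a),
            class = "equilibrium_constants")
}

#' @export
print.equilibrium_constants <- function(x, ...) {
  cat(sprintf("K_A = %.4g M^-1, K_D = %.4g M\n", x$K_A, x$K_D))
  invisible(x)
}

#' A single sensorgram trace
#'
#' One time-resolved fluorescence record with its concentration metadata and
#' phase markers. Concentration `0` marks a blank (buffer-only) run.
#'
#' @param time strictly increasing timestamps (s).
#' @param signal fluorescence change (%) at each timestamp; same length as
#'   `time`.
#' @param concentration analyte concentration (M), `>= 0`; `NA` allowed when
#'   the metadata is supplied later (e.g. from a series manifest).
#' @param phases a [phase_markers()] object.
#' @param temperature measurement temperature (deg C).
#' @param mode `"static_standard"` or `"static_weak_binder"`.
#' @param label free-text label.
#' @return An object of class `sensorgram_trace`.
#' @export
sensorgram_trace <- function(time, signal, concentration, phases,
                             temperature = 25, mode = "static_standard",
                             label = "") {
  .check_finite(time, "time"); .check_finite(signal, "signal")
  stopifnot(inherits(phases, "phase_markers"))
  if (length(time) != length(signal)) {
    skn_stop("invalid_parameter_error", "`time` and `signal` must have equal length")
  }
  if (length(time) > 1 && any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1] + 1
    skn_stop("invalid_parameter_error",
             sprintf("`time` must be strictly increasing (violation at index %d)", bad))
  }
  if (!is.na(concentration)) {
    .check_finite(concentration, "concentration")
    if (concentration < 0) {
      skn_stop("invalid_parameter_error", "`concentration` must be >= 0")
    }
  }
  mode <- match.arg(mode, c("static_standard", "static_weak_binder"))
  structure(
    list(time = as.numeric(time), signal = as.numeric(signal),
         concentration = as.numeric(concentration), phases = phases,
         temperature = temperature, mode = mode, label = label),
    class = "sensorgram_trace"
  )
}

#' @export
print.sensorgram_trace <- function(x, ...) {
  what <- if (is_blank(x)) "blank" else sprintf("c = %.3g M", x$concentration)
  cat(sprintf("Sensorgram trace%s: %s, %d points over %g s, %s, %g degC\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              what, length(x$time), max(x$time), x$mode, x$temperature))
  invisible(x)
}

#' @export
as.data.frame.sensorgram_trace <- function(x, ...) {
  data.frame(time_s = x$time, signal_pct = x$signal)
}

#' Is a trace a blank (zero-concentration) run?
#'
#' @param trace a [sensorgram_trace()].
#' @return `TRUE` for concentration exactly 0, `FALSE` otherwise (including
#'   `NA` concentration).
#' @export
is_blank <- function(trace) {
  isTRUE(trace$concentration == 0)
}

# Piecewise noise-free signal over an arbitrary time grid; the workhorse
# shared by model_trace() and the global-fit residual. A blank (c == 0) is a
# flat baseline: with no analyte there is nothing to bind, so the amplitude
# term does not apply.
.trace_signal <- function(time, k_a, k_d, f_res, A, y0, conc, phases) {
  y <- rep(y0, length(time))
  if (conc > 0) {
    kobs <- k_a * conc + k_d
    ia <- time >= phases$t_a & time < phases$t_d
    y[ia] <- y0 + A * (1 - exp(-kobs * (time[ia] - phases$t_a)))
    A_d <- A * (1 - exp(-kobs * (phases$t_d - phases$t_a)))
    id <- time >= phases$t_d
    y[id] <- y0 + A_d * (f_res + (1 - f_res) * exp(-k_d * (time[id] - phases$t_d)))
  }
  y
}

#' Noise-free model sensorgram
#'
#' Joins the baseline, association and dissociation segments into one
#' continuous trace on a regular time grid. The dissociation amplitude is
#' pinned to the association signal at `t_d` (minus baseline), so the trace
#' is continuous at the phase boundary by construction; a blank
#' (`c = 0`) yields a flat trace at `y0`.
#'
#' @param params a [rate_parameters()] object (scalar `A`, `y0`).
#' @param c analyte concentration (M), `>= 0`.
#' @param phases a [phase_markers()] object.
#' @param sampling_rate sampling rate (Hz), `> 0`.
#' @param temperature,mode,label trace metadata, see [sensorgram_trace()].
#' @return A noise-free [sensorgram_trace()].
#' @examples
#' tr <- model_trace(rate_parameters(6.98e5, 0.358, A = 20), 1e-6,
#'                   phase_markers(5, 65, 365), sampling_rate = 10)
#' @export
model_trace <- function(params, c, phases, sampling_rate,
                        temperature = 25, mode = "static_standard", label = "") {
  stopifnot(inherits(params, "rate_parameters"), inherits(phases, "phase_markers"))
  .check_finite(c, "c"); .check_finite(sampling_rate, "sampling_rate")
  if (c < 0) skn_stop("invalid_parameter_error", "`c` must be >= 0")
  if (sampling_rate <= 0) skn_stop("invalid_parameter_error", "`sampling_rate` must be > 0")
  time <- seq(0, phases$t_end, by = 1 / sampling_rate)
  sig <- .trace_signal(time, params$k_a, params$k_d, params$f_res,
                       params$A[1], params$y0[1], c, phases)
  sensorgram_trace(time, sig, c, phases, temperature = temperature,
                   mode = mode, label = label)
}
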