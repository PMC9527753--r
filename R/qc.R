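# Quality checks and reporting: blank correction, percent-fluorescence-change
# reliability, concentration-response linearity, and kinetic summary tables.

#' Subtract the mean blank from every analyte trace
#'
#' The pointwise mean of all zero-concentration (blank) traces — typically
#' one recorded before and one after the concentration ladder — is linearly
#' interpolated onto each analyte trace's time grid and subtracted. Blanks
#' are removed from the output, so the operation is idempotent once applied.
#' With no blank present the series is returned unchanged with a warning
#' recorded in the `"qc_warnings"` attribute (and raised).
#'
#' @param series list of [sensorgram_trace()] objects.
#' @return The blank-corrected analyte traces (blanks removed), with a
#'   `"qc_warnings"` character attribute.
#' @export
blank_correct <- function(series) {
  blanks <- Filter(is_blank, series)
  analytes <- Filter(Negate(is_blank), series)
  if (length(blanks) == 0) {
    warning("no blank traces present; returning series unchanged", call. = FALSE)
    attr(series, "qc_warnings") <-
      c(attr(series, "qc_warnings"), "no blanks: identity transform applied")
    return(series)
  }
  ref_time <- blanks[[1]]$time
  blank_mat <- vapply(blanks, function(b) {
    stats::approx(b$time, b$signal, xout = ref_time, rule = 2)$y
  }, numeric(length(ref_time)))
  blank_mean <- rowMeans(blank_mat)
  out <- lapply(analytes, function(tr) {
    corr <- stats::approx(ref_time, blank_mean, xout = tr$time, rule = 2)$y
    sensorgram_trace(tr$time, tr$signal - corr, tr$concentration, tr$phases,
                     temperature = tr$temperature, mode = tr$mode,
                     label = tr$label)
  })
  attr(out, "qc_warnings") <- character(0)
  class(out) <- class(series)
  out
}

#' Peak percent fluorescence change and its reliability flag
#'
#' The maximum absolute change of the association-phase signal relative to
#' the pre-association baseline (mean of the baseline window). Changes below
#' about 1% make the fitted kinetic parameters unreliable (high standard
#' deviations), so such traces are flagged; the favourable working range is
#' roughly 2-30%.
#'
#' @param trace a [sensorgram_trace()] containing an association window.
#' @param threshold reliability threshold (%), default 1.
#' @return A list of class `percent_change` with fields `max_pct_change` and
#'   `reliable`.
#' @export
percent_change <- function(trace, threshold = 1) {
  stopifnot(inherits(trace, "sensorgram_trace"))
  ph <- trace$phases
  idx <- trace$time >= ph$t_a & trace$time < ph$t_d
  if (!any(idx)) {
    skn_stop("invalid_parameter_error", "trace has no association window samples")
  }
  base <- .baseline_of(trace)
  peak <- max(abs(trace$signal[idx] - base))
  structure(list(max_pct_change = peak, reliable = peak >= threshold,
                 threshold = threshold),
            class = "percent_change")
}

#' @export
print.percent_change <- function(x, ...) {
  cat(sprintf("Peak fluorescence change: %.3g%% (%s, threshold %g%%)\n",
              x$max_pct_change, if (x$reliable) "reliable" else "UNRELIABLE",
              x$threshold))
  invisible(x)
}

#' Concentration-response linearity check
#'
#' Ordinary least-squares line through (concentration, response) points and
#' its coefficient of determination. A linear concentration-signal
#' correlation across the ladder is the paper-style sanity check that the
#' series was measured in a well-behaved regime; the check is descriptive
#' only.
#'
#' @param amplitudes data frame (or list of pairs) with columns
#'   `concentration` (M) and `response` (%).
#' @return An object of class `linearity_result` with fields `slope`
#'   (% per M), `intercept` (%), `r_squared`, `n_points`, `degenerate`.
#' @export
linearity_check <- function(amplitudes) {
  df <- as.data.frame(amplitudes)
  if (!all(c("concentration", "response") %in% names(df))) {
    names(df)[1:2] <- c("concentration", "response")
  }
  if (nrow(df) < 3) {
    skn_stop("degenerate_input_error", "need >= 3 points for a linearity check")
  }
  if (length(unique(df$concentration)) < 2) {
    skn_stop("degenerate_input_error", "need >= 2 distinct concentrations")
  }
  fit <- stats::lm(response ~ concentration, data = df)
  degenerate <- stats::var(df$response) == 0
  r2 <- if (degenerate) 0 else
    1 - sum(stats::residuals(fit)^2) / sum((df$response - mean(df$response))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n_points = nrow(df),
                 degenerate = degenerate),
            class = "linearity_result")
}

#' @export
print.linearity_result <- function(x, ...) {
  cat(sprintf("Linearity: slope %.4g %%/M, intercept %.4g %%, R^2 = %.4g (n = %d)%s\n",
              x$slope, x$intercept, x$r_squared, x$n_points,
              if (x$degenerate) " [degenerate: constant response]" else ""))
  invisible(x)
}

# --- publication-style value formatting ------------------------------------

#' Format and parse "(value +/- SD) x 10^n" measures
#'
#' `format_measure()` renders a value and its SD at 3 significant figures in
#' the style of kinetic summary tables: scientific with a shared power of
#' ten when the exponent is outside `[-2, 2]` (e.g. `(6.98 ± 0.63) × 10^5`),
#' plain otherwise (e.g. `0.358 ± 0.007`). `parse_measure()` inverts it.
#'
#' @param value,sd numeric value and its standard deviation.
#' @param text a string produced by `format_measure()`.
#' @return `format_measure()`: a string. `parse_measure()`: a list with
#'   `value` and `sd`.
#' @export
format_measure <- function(value, sd) {
  if (!is.finite(value) || !is.finite(sd)) return(NA_character_)
  if (value == 0) return(sprintf("0 ± %s", format(signif(sd, 2))))
  n <- floor(log10(abs(value)))
  if (n >= -2 && n <= 2) {
    sprintf("%s ± %s", format(signif(value, 3), scientific = FALSE),
            format(signif(sd, 2), scientific = FALSE))
  } else {
    sprintf("(%s ± %s) × 10^%d",
            format(signif(value / 10^n, 3)), format(signif(sd / 10^n, 2)), n)
  }
}

#' @rdname format_measure
#' @export
parse_measure <- function(text) {
  text <- trimws(text)
  sci <- regmatches(text, regexec(
    "^\\(([-0-9.]+) ± ([0-9.]+)\\) × 10\\^(-?[0-9]+)$", text))[[1]]
  if (length(sci) == 4) {
    pow <- 10^as.numeric(sci[4])
    return(list(value = as.numeric(sci[2]) * pow, sd = as.numeric(sci[3]) * pow))
  }
  plain <- regmatches(text, regexec("^([-0-9.eE+]+) ± ([0-9.eE+-]+)$", text))[[1]]
  if (length(plain) == 3) {
    return(list(value = as.numeric(plain[2]), sd = as.numeric(plain[3])))
  }
  skn_stop("invalid_parameter_error", sprintf("cannot parse measure: '%s'", text))
}

#' Render a kinetic summary table
#'
#' Formats aggregated rate constants and equilibrium constants in the column
#' order `k_a`, `k_d`, `K_D`, `K_A` with `(value ± SD) × 10^n` entries at 3
#' significant figures. Each input row must supply `system`, `temperature`,
#' `mode`, and value/SD pairs `k_a`, `k_a_sd`, ..., `K_A`, `K_A_sd`; rows
#' with missing fields are skipped with a logged reason (attribute
#' `"skipped"`).
#'
#' @param rows a data frame of aggregated summaries (see [kinetic_row()] to
#'   build one from fits).
#' @return A data frame of formatted strings, class `kinetic_table`.
#' @export
kinetic_table <- function(rows) {
  rows <- as.data.frame(rows)
  need <- c("system", "temperature", "mode",
            "k_a", "k_a_sd", "k_d", "k_d_sd", "K_D", "K_D_sd", "K_A", "K_A_sd")
  out <- list(); skipped <- character(0)
  for (i in seq_len(nrow(rows))) {
    row <- rows[i, , drop = FALSE]
    missing <- setdiff(need, names(row)[!is.na(unlist(row))])
    if (length(missing) > 0) {
      skipped <- c(skipped, sprintf("row %d skipped: missing %s",
                                    i, paste(missing, collapse = ", ")))
      next
    }
    out[[length(out) + 1]] <- data.frame(
      system = row$system, temperature = row$temperature, mode = row$mode,
      k_a = format_measure(row$k_a, row$k_a_sd),
      k_d = format_measure(row$k_d, row$k_d_sd),
      K_D = format_measure(row$K_D, row$K_D_sd),
      K_A = format_measure(row$K_A, row$K_A_sd),
      stringsAsFactors = FALSE
    )
  }
  for (msg in skipped) message(msg)
  tab <- if (length(out)) do.call(rbind, out) else
    data.frame(system = character(0), temperature = numeric(0),
               mode = character(0), k_a = character(0), k_d = character(0),
               K_D = character(0), K_A = character(0))
  attr(tab, "skipped") <- skipped
  class(tab) <- c("kinetic_table", "data.frame")
  tab
}

#' Build a kinetic-table row from a fit or replicate aggregate
#'
#' From a single `kinetic_fit` the SDs are the curvature/bootstrap standard
#' errors; from an [aggregate_replicates()] data frame they are the
#' replicate SDs.
#'
#' @param x a `kinetic_fit` or an [aggregate_replicates()] result.
#' @param system system label (e.g. analyte name).
#' @return One-row data frame suitable for [kinetic_table()].
#' @export
kinetic_row <- function(x, system = "") {
  if (inherits(x, "kinetic_fit")) {
    se <- x$standard_errors
    ka <- x$params$k_a; kd <- x$params$k_d
    ka_sd <- unname(se[["k_a"]]); kd_sd <- unname(se[["k_d"]])
    # first-order error propagation for the derived constants
    KD <- x$constants$K_D; KA <- x$constants$K_A
    rel <- sqrt((ka_sd / ka)^2 + (kd_sd / kd)^2)
    data.frame(system = system, temperature = x$temperature[1], mode = x$mode[1],
               k_a = ka, k_a_sd = ka_sd, k_d = kd, k_d_sd = kd_sd,
               K_D = KD, K_D_sd = KD * rel, K_A = KA, K_A_sd = KA * rel,
               stringsAsFactors = FALSE)
  } else {
    agg <- as.data.frame(x)
    g <- function(p, col) agg[agg$parameter == p, col]
    data.frame(system = system,
               temperature = attr(x, "temperature"), mode = attr(x, "mode"),
               k_a = g("k_a", "mean"), k_a_sd = g("k_a", "sd"),
               k_d = g("k_d", "mean"), k_d_sd = g("k_d", "sd"),
               K_D = g("K_D", "mean"), K_D_sd = g("K_D", "sd"),
               K_A = g("K_A", "mean"), K_A_sd = g("K_A", "sd"),
               stringsAsFactors = FALSE)
  }
}
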