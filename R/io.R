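# Readers and writers for trace CSVs, pose CSVs, series manifests (YAML),
# and structured results. Canonical units everywhere: seconds, molar,
# percent fluorescence change.

#' Read a sensorgram trace from CSV
#'
#' Expects header columns `time_s` and `signal_pct`; extra columns are
#' preserved in the `"extra"` attribute. Time must be strictly increasing;
#' parse errors name the offending data row.
#'
#' @param path CSV file path.
#' @param concentration analyte concentration (M); usually supplied by the
#'   series manifest.
#' @param phases optional [phase_markers()]; if `NULL`, a provisional
#'   marker set spanning the record is attached (baseline first 2% of the
#'   record, dissociation at 40%).
#' @param temperature,mode,label trace metadata.
#' @return A [sensorgram_trace()].
#' @export
read_trace_csv <- function(path, concentration = NA_real_, phases = NULL,
                           temperature = 25, mode = "static_standard",
                           label = basename(path)) {
  if (!file.exists(path)) {
    skn_stop("parse_error", sprintf("trace file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "signal_pct")
  if (!all(need %in% names(df))) {
    skn_stop("parse_error",
             sprintf("%s: missing required column(s) %s", path,
                     paste(setdiff(need, names(df)), collapse = ", ")))
  }
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) | is.na(df[[col]]))
    if (length(bad) > 0) {
      skn_stop("parse_error",
               sprintf("%s: non-numeric `%s` at data row %d", path, col, bad[1]))
    }
    df[[col]] <- v
  }
  if (nrow(df) > 1 && any(diff(df$time_s) <= 0)) {
    bad <- which(diff(df$time_s) <= 0)[1] + 1
    skn_stop("parse_error",
             sprintf("%s: time not strictly increasing at data row %d", path, bad))
  }
  if (is.null(phases)) {
    t_end <- max(df$time_s)
    phases <- phase_markers(0.02 * t_end, 0.4 * t_end, t_end)
  }
  tr <- sensorgram_trace(df$time_s, df$signal_pct, concentration, phases,
                         temperature = temperature, mode = mode, label = label)
  extra <- setdiff(names(df), need)
  if (length(extra) > 0) attr(tr, "extra") <- df[extra]
  tr
}

#' Write a sensorgram trace to CSV
#'
#' @param trace a [sensorgram_trace()].
#' @param path destination path.
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sensorgram_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a docking pose table from CSV
#'
#' Columns: `id`, `x`, `y`, `z`, `energy_kcal_mol` (or `energy`).
#'
#' @param path CSV file path.
#' @return A [pose_set()].
#' @export
read_pose_csv <- function(path) {
  if (!file.exists(path)) {
    skn_stop("parse_error", sprintf("pose file not found: %s", path))
  }
  pose_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_pose_csv
#' @param poses a [pose_set()].
#' @export
write_pose_csv <- function(poses, path) {
  stopifnot(inherits(poses, "pose_set"))
  df <- as.data.frame(poses)
  names(df)[names(df) == "energy"] <- "energy_kcal_mol"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.manifest_defaults <- list(temperature = 25, mode = "static_standard",
                           model = "auto", weighting = "uniform", seed = 1L)

#' Parse a series manifest
#'
#' The manifest is a YAML file describing one concentration series: the
#' shared phase markers, measurement metadata, analysis options, and one
#' record per trace file. Validation collects *all* failures before
#' reporting them together.
#'
#' Layout:
#' ```yaml
#' phases: {t_a: 5, t_d: 65, t_end: 365}
#' temperature: 25
#' mode: static_standard
#' options: {model: auto, weighting: uniform, seed: 1}
#' traces:
#'   - {file: blank_pre_1.csv, concentration_M: 0}
#'   - {file: c_1e-06_M.csv, concentration_M: 1.0e-06}
#' ```
#' Defaults: temperature 25, mode `static_standard`, model `auto`,
#' weighting `uniform`, seed 1; `is_blank` is inferred from a zero
#' concentration when absent.
#'
#' @param path manifest file path.
#' @return A list of class `series_manifest`.
#' @export
parse_manifest <- function(path) {
  if (!file.exists(path)) {
    skn_stop("validation_error", sprintf("manifest not found: %s", path))
  }
  m <- yaml::read_yaml(path)
  problems <- character(0)
  for (nm in names(.manifest_defaults)) {
    src <- if (nm %in% c("model", "weighting", "seed")) m$options else m
    if (is.null(src[[nm]])) {
      if (nm %in% c("model", "weighting", "seed")) {
        m$options[[nm]] <- .manifest_defaults[[nm]]
      } else {
        m[[nm]] <- .manifest_defaults[[nm]]
      }
    }
  }
  if (is.null(m$phases) || !all(c("t_a", "t_d", "t_end") %in% names(m$phases))) {
    problems <- c(problems, "phases must define t_a, t_d and t_end")
  } else {
    ph <- m$phases
    if (!(ph$t_a >= 0 && ph$t_a < ph$t_d && ph$t_d < ph$t_end)) {
      problems <- c(problems,
                    sprintf("phases must satisfy 0 <= t_a < t_d < t_end (got %g, %g, %g)",
                            ph$t_a, ph$t_d, ph$t_end))
    }
  }
  if (!m$mode %in% c("static_standard", "static_weak_binder")) {
    problems <- c(problems, sprintf("unknown mode '%s'", m$mode))
  }
  if (!m$options$model %in% c("auto", "complete", "incomplete")) {
    problems <- c(problems, sprintf("unknown model '%s'", m$options$model))
  }
  if (is.null(m$traces) || length(m$traces) == 0) {
    problems <- c(problems, "manifest lists no traces")
  } else {
    for (i in seq_along(m$traces)) {
      tr <- m$traces[[i]]
      if (is.null(tr$file)) {
        problems <- c(problems, sprintf("trace %d: missing file", i))
      }
      if (is.null(tr$concentration_M)) {
        problems <- c(problems, sprintf("trace %d: missing concentration_M", i))
      } else if (tr$concentration_M < 0) {
        problems <- c(problems, sprintf("trace %d: concentration_M must be >= 0", i))
      } else if (is.null(tr$is_blank)) {
        m$traces[[i]]$is_blank <- tr$concentration_M == 0
      }
    }
  }
  if (length(problems) > 0) {
    skn_stop("validation_error",
             paste(c("manifest validation failed:", problems), collapse = "\n  - "),
             problems = problems)
  }
  structure(m, class = "series_manifest", dir = dirname(path))
}

#' Load the traces referenced by a manifest
#'
#' @param manifest a [parse_manifest()] result.
#' @param dir directory trace paths are relative to; defaults to the
#'   manifest's own directory.
#' @return List of [sensorgram_trace()] objects (class `sensorgram_series`).
#' @export
read_series <- function(manifest, dir = attr(manifest, "dir")) {
  stopifnot(inherits(manifest, "series_manifest"))
  ph <- phase_markers(manifest$phases$t_a, manifest$phases$t_d,
                      manifest$phases$t_end)
  out <- lapply(manifest$traces, function(tr) {
    read_trace_csv(file.path(dir, tr$file),
                   concentration = tr$concentration_M, phases = ph,
                   temperature = manifest$temperature, mode = manifest$mode,
                   label = tr$file)
  })
  structure(out, class = "sensorgram_series")
}

#' Write a simulated series to trace CSVs plus a manifest
#'
#' @param series a list of [sensorgram_trace()] objects.
#' @param dir output directory (created if needed).
#' @param options analysis options stored in the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_series <- function(series, dir, options = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- series[[1]]$phases
  recs <- lapply(seq_along(series), function(i) {
    tr <- series[[i]]
    fn <- sprintf("trace_%02d.csv", i)
    write_trace_csv(tr, file.path(dir, fn))
    list(file = fn, concentration_M = tr$concentration,
         is_blank = is_blank(tr))
  })
  m <- list(phases = list(t_a = ph$t_a, t_d = ph$t_d, t_end = ph$t_end),
            temperature = series[[1]]$temperature, mode = series[[1]]$mode,
            options = utils::modifyList(.manifest_defaults[c("model", "weighting", "seed")],
                                        options),
            traces = recs)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(m, path)
  invisible(path)
}

#' Write fit results, kinetic table and run log
#'
#' Produces three files in `out_dir`: `results.json` (machine-readable fit
#' record), `kinetic_table.tsv`, and `run_log.txt` (seeds, package and R
#' versions — everything needed to reproduce the run; deliberately no
#' timestamps so identical runs are byte-identical).
#'
#' @param fit a `kinetic_fit`.
#' @param out_dir output directory (created if needed).
#' @param system system label for the table row.
#' @param qc optional list of QC records to embed (e.g. linearity, percent
#'   change).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(fit, out_dir, system = "", qc = NULL) {
  stopifnot(inherits(fit, "kinetic_fit"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res_path <- file.path(out_dir, "results.json")
  tab_path <- file.path(out_dir, "kinetic_table.tsv")
  log_path <- file.path(out_dir, "run_log.txt")

  rec <- list(
    system = system,
    model = unclass(fit$model),
    converged = fit$converged,
    parameters = list(k_a = fit$params$k_a, k_d = fit$params$k_d,
                      f_res = fit$params$f_res,
                      A = fit$params$A, y0 = fit$params$y0),
    standard_errors = as.list(fit$standard_errors),
    constants = list(K_A = fit$constants$K_A, K_D = fit$constants$K_D),
    residual_sum_squares = fit$residual_sum_squares,
    n_points = fit$n_points,
    information_criterion = fit$information_criterion,
    concentrations = fit$concentrations,
    temperature = fit$temperature, mode = fit$mode,
    seed = fit$seed,
    uncertainty_method = fit$uncertainty_method,
    qc = qc
  )
  jsonlite::write_json(rec, res_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  tab <- kinetic_table(kinetic_row(fit, system = system))
  utils::write.table(tab, tab_path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")

  writeLines(c(
    "switchkin run log",
    sprintf("package_version: %s", as.character(utils::packageVersion("switchkin"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("fit_seed: %d", fit$seed),
    sprintf("model: %s", fit$model$dissociation_model),
    sprintf("weighting: %s", fit$model$weighting),
    sprintf("converged: %s", fit$converged)
  ), log_path)

  invisible(c(results = res_path, table = tab_path, log = log_path))
}

#' Read back a results record written by [write_results()]
#'
#' @param path path to `results.json`.
#' @return The parsed record (list).
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
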