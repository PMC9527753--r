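# Shared fixtures: all synthetic, generated in code.

# Fast intercalator-like truth (static standard design scale)
eb_truth <- function(A = 30, y0 = 0, f_res = 0) {
  rate_parameters(6.98e5, 0.358, A = A, y0 = y0, f_res = f_res)
}

# Slow, incompletely dissociating binder truth (weak-binder design scale)
slow_truth <- function(f_res = 0.35, A = 20) {
  rate_parameters(77.7, 8.77e-3, A = A, y0 = 0, f_res = f_res)
}

# A design adapted to arbitrary rates: concentration ladder around K_D and
# phase durations scaled to the relaxation times, with ~`pts` samples per
# dissociation phase. Used for oracle-equivalence checks across wide
# parameter ranges.
scaled_design <- function(k_a, k_d, n_conc = 4, pts = 150) {
  KD <- k_d / k_a
  concs <- concentration_ladder(4 * KD, 2, n_conc)
  kobs_min <- k_a * min(concs) + k_d
  t_assoc <- 3 / kobs_min
  t_diss <- 4 / k_d
  rate <- pts / t_diss
  series_design(concs,
                association_duration = t_assoc,
                dissociation_duration = t_diss,
                sampling_rate = rate,
                baseline_duration = max(t_assoc / 20, 2 / rate),
                n_blanks_before = 0, n_blanks_after = 0)
}

# Independent single-linkage oracle: transitive closure over the pairwise
# adjacency (distance <= cutoff), no hclust involved. Returns component
# labels renumbered by first appearance.
brute_force_single_linkage <- function(xyz, cutoff) {
  n <- nrow(xyz)
  adj <- as.matrix(stats::dist(xyz)) <= cutoff
  labels <- rep(NA_integer_, n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    comp <- comp + 1L
    frontier <- i
    labels[i] <- comp
    while (length(frontier) > 0) {
      nxt <- which(adj[frontier[1], ] & is.na(labels))
      labels[nxt] <- comp
      frontier <- c(frontier[-1], nxt)
    }
  }
  labels
}

# Minimal converged fit stub for replicate-aggregation unit tests.
fake_fit <- function(k_a, k_d, f_res = 0, temperature = 25,
                     mode = "static_standard",
                     dissociation_model = "complete") {
  structure(list(
    params = rate_parameters(k_a, k_d, f_res = f_res),
    constants = equilibrium_constants(k_a, k_d),
    converged = TRUE,
    temperature = temperature, mode = mode,
    model = model_spec(dissociation_model)
  ), class = "kinetic_fit")
}
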