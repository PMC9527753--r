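# Post-analysis of docking pose sets: spatial clustering of pose centroids
# into candidate binding sites, ranking by abundance ("most common site")
# and by best binding energy ("most strongly bonded site"), and
# energy-fraction summaries.

#' Construct a docking pose set
#'
#' Binding energies are stored as positive magnitudes (larger = stronger
#' binding); negative input energies — docking engines usually report
#' favourable binding as negative Delta G — are converted to their absolute
#' value with a message.
#'
#' @param df data frame with columns `id`, `x`, `y`, `z` (Angstrom) and
#'   `energy` (kcal/mol). An `energy_kcal_mol` column is accepted as an
#'   alias for `energy`.
#' @return A data frame of class `pose_set`.
#' @export
pose_set <- function(df) {
  df <- as.data.frame(df)
  if ("energy_kcal_mol" %in% names(df) && !"energy" %in% names(df)) {
    names(df)[names(df) == "energy_kcal_mol"] <- "energy"
  }
  need <- c("id", "x", "y", "z", "energy")
  if (!all(need %in% names(df))) {
    skn_stop("invalid_parameter_error",
             sprintf("pose table must have columns %s", paste(need, collapse = ", ")))
  }
  for (col in c("x", "y", "z", "energy")) {
    if (!is.numeric(df[[col]]) || any(!is.finite(df[[col]]))) {
      skn_stop("invalid_parameter_error",
               sprintf("pose column `%s` must be finite numeric", col))
    }
  }
  if (any(df$energy < 0)) {
    message("negative binding energies supplied; taking absolute values (magnitude convention)")
    df$energy <- abs(df$energy)
  }
  df$id <- as.character(df$id)
  structure(df[need], class = c("pose_set", "data.frame"))
}

#' Single-linkage clustering of poses into binding sites
#'
#' Partitions the poses so that two poses share a cluster exactly when they
#' are connected by a chain of pairwise Euclidean distances `<= cutoff`
#' (single linkage on pose centroids). The default 3.5 Angstrom cutoff is on
#' the order of a hydrogen-bond contact and groups poses occupying the same
#' groove region. Clusters are numbered by first pose appearance, so the
#' result is deterministic.
#'
#' @param poses a [pose_set()].
#' @param cutoff linkage distance cutoff (Angstrom), `> 0`.
#' @return A list of `site_cluster` objects, each with `members` (pose ids),
#'   `centroid` (mean member position), `abundance` (member count),
#'   `best_energy` (max member energy) and `representative` (id of the
#'   best-energy member). An empty pose set gives an empty list.
#' @examples
#' ps <- simulate_pose_set(list(
#'   list(centroid = c(0, 0, 0), spread = 0.5, weight = 3,
#'        energy_mean = 6.9, energy_sd = 0.3),
#'   list(centroid = c(12, 0, 0), spread = 0.5, weight = 1,
#'        energy_mean = 8.0, energy_sd = 0.3)), n_poses = 40, seed = 1)
#' length(cluster_poses(ps, cutoff = 3.5))
#' @export
cluster_poses <- function(poses, cutoff = 3.5) {
  stopifnot(inherits(poses, "pose_set"))
  if (!isTRUE(cutoff > 0)) skn_stop("invalid_parameter_error", "`cutoff` must be > 0")
  n <- nrow(poses)
  if (n == 0) return(list())
  if (n == 1) {
    grp <- 1L
  } else {
    hc <- stats::hclust(stats::dist(poses[, c("x", "y", "z")]), method = "single")
    grp <- stats::cutree(hc, h = cutoff)
    # renumber clusters by order of first appearance
    grp <- match(grp, unique(grp))
  }
  lapply(seq_len(max(grp)), function(g) {
    m <- which(grp == g)
    best <- m[which.max(poses$energy[m])]
    structure(list(
      members = poses$id[m],
      centroid = colMeans(poses[m, c("x", "y", "z"), drop = FALSE]),
      abundance = length(m),
      best_energy = poses$energy[best],
      representative = poses$id[best]
    ), class = "site_cluster")
  })
}

#' @export
print.site_cluster <- function(x, ...) {
  cat(sprintf("Site cluster: %d poses, centroid (%.2f, %.2f, %.2f) A, best energy %.3g kcal/mol (%s)\n",
              x$abundance, x$centroid[1], x$centroid[2], x$centroid[3],
              x$best_energy, x$representative))
  invisible(x)
}

#' Rank binding sites by abundance and by best energy
#'
#' Returns both the most common binding site (highest pose count) and the
#' most strongly bonded one (highest best member energy); the two may be the
#' same cluster. Ties on abundance are broken by higher best energy, ties on
#' best energy by higher abundance, and full ties by lower cluster index.
#'
#' @param clusters non-empty list of `site_cluster` objects from
#'   [cluster_poses()].
#' @return A list with elements `most_popular` and `strongest`.
#' @export
rank_sites <- function(clusters) {
  if (length(clusters) == 0) {
    skn_stop("invalid_parameter_error", "need >= 1 cluster to rank")
  }
  ab <- vapply(clusters, `[[`, numeric(1), "abundance")
  en <- vapply(clusters, `[[`, numeric(1), "best_energy")
  idx <- seq_along(clusters)
  pop <- idx[order(-ab, -en, idx)][1]
  str <- idx[order(-en, -ab, idx)][1]
  list(most_popular = clusters[[pop]], strongest = clusters[[str]])
}

#' Fraction of poses with binding energy above a threshold
#'
#' @param poses a non-empty [pose_set()].
#' @param threshold energy threshold (kcal/mol); poses with energy strictly
#'   greater are counted.
#' @return Fraction in `[0, 1]`.
#' @examples
#' # e.g. "over 90% of dockings exhibit energy over 5.5 kcal/mol"
#' @export
energy_fraction_above <- function(poses, threshold) {
  stopifnot(inherits(poses, "pose_set"))
  if (nrow(poses) == 0) {
    skn_stop("undefined_error", "energy fraction is undefined for an empty pose set")
  }
  .check_finite(threshold, "threshold")
  mean(poses$energy > threshold)
}

#' Site report for a pose set
#'
#' Convenience wrapper: clusters poses, ranks sites, and returns structured
#' records (one per cluster, ordered by abundance).
#'
#' @param poses a [pose_set()].
#' @param cutoff clustering cutoff (Angstrom).
#' @return A list with `clusters` (data frame summary), `most_popular`,
#'   `strongest` and `cutoff`.
#' @export
site_report <- function(poses, cutoff = 3.5) {
  cl <- cluster_poses(poses, cutoff)
  if (length(cl) == 0) {
    return(list(clusters = data.frame(), most_popular = NULL,
                strongest = NULL, cutoff = cutoff))
  }
  ranked <- rank_sites(cl)
  df <- do.call(rbind, lapply(seq_along(cl), function(i) {
    data.frame(cluster = i, abundance = cl[[i]]$abundance,
               x = cl[[i]]$centroid[1], y = cl[[i]]$centroid[2],
               z = cl[[i]]$centroid[3],
               best_energy = cl[[i]]$best_energy,
               representative = cl[[i]]$representative,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(-df$abundance), ]
  rownames(df) <- NULL
  list(clusters = df, most_popular = ranked$most_popular,
       strongest = ranked$strongest, cutoff = cutoff)
}
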