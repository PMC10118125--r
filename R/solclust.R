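# Trajectory clustering and canonical solubility-class labeling.
#
# Mean P_index trajectories are clustered by agglomerative hierarchical
# clustering (complete linkage on Euclidean distance) and the tree is cut at
# the smallest distance threshold yielding the requested number of clusters,
# i.e. a distance-criterion cut. Cluster median profiles are then mapped to
# the five canonical solubility classes by shape rules.

.solubility_classes <- c("mostly_pellet", "mostly_supernatant",
                         "transient_solubilization",
                         "gradual_desolubilization",
                         "gradual_solubilization")

#' Cluster mean P_index trajectories
#'
#' Complete-linkage agglomerative clustering on the Euclidean distance
#' between mean trajectories, cut with a distance criterion: the threshold is
#' searched over the merge heights for the smallest value yielding exactly
#' `n_clusters` flat clusters. When tied merge heights make a pure distance
#' cut impossible (e.g. duplicated trajectories), the cut fails unless
#' `force_split = TRUE`, in which case the tie is broken by merge order
#' (smallest-index-first, the deterministic `stats::hclust` order).
#'
#' Cluster ids are renumbered by order of first appearance in the input, so
#' the partition is invariant to protein input order up to this relabeling.
#'
#' @param matrix proteins x time points matrix of mean P_index (no missing
#'   cells).
#' @param n_clusters number of flat clusters (default 5).
#' @param force_split break merge-height ties by merge order instead of
#'   erroring (default FALSE).
#' @return list with `assignments` (data.table `protein_id`, `cluster_id`),
#'   `profiles` (`cluster_profiles`: median-trajectory matrix with a `size`
#'   attribute), `tree` (the `hclust` object), and `threshold` (the distance
#'   cut, NA when forced by merge order).
#' @export
cluster_trajectories <- function(matrix, n_clusters = 5L, force_split = FALSE) {
  m <- unclass(matrix)
  attr(m, "missing") <- NULL
  if (anyNA(m))
    stopf("trajectory matrix has missing cells; clustering requires complete trajectories",
          class = "solubilome_validation_error")
  n <- nrow(m)
  if (n_clusters > n)
    stopf("n_clusters (%d) exceeds number of proteins (%d)", n_clusters, n,
          class = "solubilome_domain_error")
  tree <- hclust(dist(m, method = "euclidean"), method = "complete")
  heights <- tree$height
  if (n_clusters == n) {
    cl <- seq_len(n)
  } else {
    # cutting at threshold t keeps merges with height <= t:
    # exactly k clusters needs the (n-k)-th height < threshold <= impossible
    # when heights tie across the cut boundary
    h_lo <- heights[n - n_clusters]                # last merge kept
    h_hi <- if (n_clusters > 1) heights[n - n_clusters + 1] else Inf
    if (h_hi <= h_lo && !force_split)
      stopf(paste0("no distance threshold yields exactly %d clusters ",
                   "(tied merge heights at %g); set force_split = TRUE ",
                   "to break ties by merge order"), n_clusters, h_lo,
            class = "solubilome_cut_error")
    cl <- cutree(tree, k = n_clusters)
  }
  threshold <- if (n_clusters < n && n_clusters > 1) {
    if (heights[n - n_clusters + 1] > heights[n - n_clusters])
      mean(heights[n - n_clusters + 0:1]) else NA_real_
  } else NA_real_

  # renumber clusters by first appearance in input order
  relabel <- match(cl, unique(cl))
  assignments <- data.table::data.table(protein_id = rownames(m),
                                        cluster_id = relabel)
  profiles <- cluster_profiles(m, relabel)
  list(assignments = assignments, profiles = profiles, tree = tree,
       threshold = threshold)
}

#' Per-cluster median trajectory profiles
#'
#' @param m trajectory matrix.
#' @param cluster_id integer cluster id per row of `m`.
#' @return matrix (clusters x time points) of class `cluster_profiles` with
#'   `size` attribute (cluster sizes, summing to `nrow(m)`).
#' @export
cluster_profiles <- function(m, cluster_id) {
  ids <- sort(unique(cluster_id))
  prof <- t(vapply(ids, function(k) apply(m[cluster_id == k, , drop = FALSE], 2, median),
                   numeric(ncol(m))))
  rownames(prof) <- ids
  colnames(prof) <- colnames(m)
  attr(prof, "size") <- vapply(ids, function(k) sum(cluster_id == k), integer(1))
  class(prof) <- c("cluster_profiles", class(prof))
  prof
}

#' Map cluster median profiles to canonical solubility classes
#'
#' Rule-based labeling of median trajectories `m` with range
#' `r = max(m) - min(m)`:
#' \itemize{
#'   \item static (`r < static_range`): `mostly_pellet` if `mean(m) >= 0.5`,
#'     else `mostly_supernatant`;
#'   \item dynamic with the minimum at an interior time point and both first
#'     and last values exceeding `min + interior_margin`:
#'     `transient_solubilization`;
#'   \item otherwise `gradual_desolubilization` if
#'     `last - first >= monotone_margin`, `gradual_solubilization` if
#'     `first - last >= monotone_margin`;
#'   \item anything else is an error (ambiguous profile).
#' }
#' Each canonical label may be used at most once; two profiles claiming the
#' same label raise an ambiguity error that prints both medians.
#'
#' @param profiles `cluster_profiles` matrix (>= 4 time points).
#' @param static_range range below which a profile is static (default 0.25).
#' @param interior_margin required excess of the endpoints over an interior
#'   minimum for a transient dip (default 0.2).
#' @param monotone_margin minimum net start-to-end change for gradual classes
#'   (default 0.15).
#' @return named character vector mapping cluster id to class label.
#' @export
assign_class_labels <- function(profiles, static_range = 0.25,
                                interior_margin = 0.2, monotone_margin = 0.15) {
  if (ncol(profiles) < 4)
    stopf("class labeling needs >= 4 time points", class = "solubilome_domain_error")
  lab1 <- function(m) {
    r <- max(m) - min(m)
    if (r < static_range)
      return(if (mean(m) >= 0.5) "mostly_pellet" else "mostly_supernatant")
    i_min <- which.min(m)
    nt <- length(m)
    if (i_min > 1 && i_min < nt &&
        m[1] > m[i_min] + interior_margin && m[nt] > m[i_min] + interior_margin)
      return("transient_solubilization")
    if (m[nt] - m[1] >= monotone_margin) return("gradual_desolubilization")
    if (m[1] - m[nt] >= monotone_margin) return("gradual_solubilization")
    stopf("ambiguous cluster profile, no labeling rule matches: (%s)",
          paste(signif(m, 3), collapse = ", "), class = "solubilome_label_error")
  }
  labels <- vapply(seq_len(nrow(profiles)), function(i) lab1(profiles[i, ]),
                   character(1))
  names(labels) <- rownames(profiles)
  dup <- unique(labels[duplicated(labels)])
  if (length(dup) > 0) {
    offender <- which(labels == dup[1])
    stopf("ambiguity: clusters %s both label as '%s'; medians: [%s] vs [%s]",
          paste(names(labels)[offender], collapse = ", "), dup[1],
          paste(signif(profiles[offender[1], ], 3), collapse = ", "),
          paste(signif(profiles[offender[2], ], 3), collapse = ", "),
          class = "solubilome_label_error")
  }
  labels
}

#' Classify trajectories end to end
#'
#' Convenience wrapper: cluster, compute profiles, assign class labels, and
#' return per-protein assignments.
#'
#' @inheritParams cluster_trajectories
#' @param ... passed to [assign_class_labels()].
#' @return list as [cluster_trajectories()] plus `labels` (cluster -> class)
#'   and `assignments` gaining a `class_label` column.
#' @export
classify_trajectories <- function(matrix, n_clusters = 5L, force_split = FALSE,
                                  ...) {
  res <- cluster_trajectories(matrix, n_clusters, force_split)
  res$labels <- assign_class_labels(res$profiles, ...)
  res$assignments[, class_label := unname(res$labels[as.character(cluster_id)])]
  res
}

#' Extract the changing (dynamic-trajectory) protein set
#'
#' The union of proteins labeled `transient_solubilization`,
#' `gradual_desolubilization` or `gradual_solubilization`, in input order.
#'
#' @param assignments data.frame with `protein_id` and `class_label`.
#' @return character vector of protein ids.
#' @export
extract_changing_set <- function(assignments) {
  dynamic <- c("transient_solubilization", "gradual_desolubilization",
               "gradual_solubilization")
  assignments$protein_id[assignments$class_label %in% dynamic]
}

#' PCA of protein physicochemical properties
#'
#' Standardizes the feature columns (zero mean, unit variance), drops
#' zero-variance features with a warning, and decomposes with
#' [stats::prcomp]. Sign convention: within each component the
#' largest-magnitude loading is made positive, so results are deterministic
#' across platforms.
#'
#' @param props data.frame with a `protein_id` column and numeric feature
#'   columns (e.g. molecular weight, isoelectric point, mean abundance,
#'   prion-likeness, condensation propensity, median disorder).
#' @return list of class `pca_result`: `loadings` (features x components),
#'   `scores` (proteins x components), `explained_variance` (fractions,
#'   non-increasing, summing to 1).
#' @export
pca_protein_properties <- function(props) {
  df <- as.data.frame(props)
  if (!("protein_id" %in% names(df)))
    stopf("props needs a protein_id column", class = "solubilome_schema_error")
  feats <- df[, setdiff(names(df), "protein_id"), drop = FALSE]
  num <- vapply(feats, is.numeric, logical(1))
  feats <- feats[, num, drop = FALSE]
  if (ncol(feats) < 2 || nrow(feats) < 3)
    stopf("PCA needs >= 2 numeric features and >= 3 proteins",
          class = "solubilome_domain_error")
  if (anyNA(feats))
    stopf("PCA features must be complete (no NA)", class = "solubilome_validation_error")
  vars <- vapply(feats, function(x) stats::var(x), numeric(1))
  if (any(vars == 0)) {
    warnf("dropping zero-variance feature(s): %s",
          paste(names(feats)[vars == 0], collapse = ", "))
    feats <- feats[, vars > 0, drop = FALSE]
    if (ncol(feats) < 2)
      stopf("fewer than 2 features remain after dropping zero variance",
            class = "solubilome_domain_error")
  }
  pc <- prcomp(feats, center = TRUE, scale. = TRUE)
  # deterministic sign: largest-|loading| entry positive per component
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  rownames(scores) <- df$protein_id
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = loadings, scores = scores,
                 explained_variance = ev),
            class = "pca_result")
}

#' Interacting pairs within a protein set
#'
#' Returns each normalized edge whose two endpoints both belong to
#' `protein_set`, once per unordered pair. Used to scan the changing set
#' against a physical-interaction edge list.
#'
#' @param protein_set character vector of protein ids.
#' @param edges an `edge_list` (see [read_edge_list()]/[normalize_edges()]).
#' @return data.table with columns `a`, `b` (each qualifying pair once).
#' @export
interaction_pairs <- function(protein_set, edges) {
  dt <- normalize_edges(edges)
  dt[a %in% protein_set & b %in% protein_set, .(a, b)]
}
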