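# Internuclear pairwise distances (IPD) and density-based spatial
# clustering of scored nuclei.

#' Compute the internuclear pairwise-distance (IPD) matrix
#'
#' Exact Euclidean distances in micrometres between nuclear centroids:
#' `IPD[i, j] = sqrt((x_i - x_j)^2 + (y_i - y_j)^2)`. The matrix is
#' symmetric with a zero diagonal; element (i, j) corresponds to the i-th
#' and j-th entries of the ordered id list (stored as dimnames).
#'
#' @param records data.frame with columns `id`, `x_um`, `y_um` (e.g.
#'   `segment_nuclei(...)$records`), or a `nucleus_records` object.
#' @return an `ipd_matrix`: numeric n x n matrix with ids as dimnames.
#' @export
compute_ipd_matrix <- function(records) {
  if (inherits(records, "nucleus_records")) records <- records$records
  stopifnot(all(c("id", "x_um", "y_um") %in% names(records)),
            nrow(records) >= 2L)
  if (anyDuplicated(records$id)) stop("duplicate nucleus ids")
  m <- as.matrix(dist(records[, c("x_um", "y_um")]))
  dimnames(m) <- list(records$id, records$id)
  class(m) <- c("ipd_matrix", class(m))
  m
}

#' Dispersion of an IPD matrix
#'
#' Sample standard deviation (n - 1 denominator) of the distances in the
#' strict upper triangle - each unordered nucleus pair counted once. Used
#' as the spreading readout for implanted-cell populations.
#'
#' @param matrix an `ipd_matrix` (or any symmetric distance matrix).
#' @return scalar dispersion in micrometres; 0 (with a message) for the
#'   two-point case, which has a single distance.
#' @export
ipd_dispersion <- function(matrix) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            nrow(matrix) >= 2L)
  d <- matrix[upper.tri(matrix)]
  if (length(d) < 2L) {
    msg("only one nucleus pair: dispersion reported as 0")
    return(0)
  }
  sd(d)
}

#' Density-based spatial clustering of scored nuclei
#'
#' Groups nuclei by position plus cell-state score (or position plus the
#' full feature vector) using an epsilon-free hierarchical density-based
#' clusterer. All selected columns are min-max normalized to `[0, 1]`
#' before clustering; noise points get label -1.
#'
#' @param records data.frame with `id`, `x_um`, `y_um` and (depending on
#'   `feature_set`) a `score` column or feature columns, or a
#'   `nucleus_records` object combined with `scores`.
#' @param scores optional `score_set` (or data.frame with `id`, `score`)
#'   merged onto `records` by id.
#' @param feature_set `"xy+score"` (default: centroids + normalized LDA1
#'   score) or `"xy+features"` (centroids + all feature columns present).
#' @param min_cluster_size smallest cluster size (default 5).
#' @param allow_single_cluster whether the hierarchy root may be reported
#'   as a single cluster (default `TRUE`; with `FALSE` a scene that never
#'   splits into two dense groups is reported as all noise).
#' @return object of class `cluster_assignment`: list with
#'   `labels` (integer per nucleus, -1 = noise), `ids`, and `clusters`
#'   (data.frame: cluster, n, mean_score, mean_angular_diff_deg - the
#'   angular column filled by [cluster_angular_difference()], `NA` until
#'   then).
#' @export
cluster_nuclei <- function(records, scores = NULL,
                           feature_set = c("xy+score", "xy+features"),
                           min_cluster_size = 5L,
                           allow_single_cluster = TRUE) {
  feature_set <- match.arg(feature_set)
  if (inherits(records, "nucleus_records")) records <- records$records
  records <- as.data.frame(records)
  if (!is.null(scores)) {
    if (inherits(scores, "score_set")) scores <- scores$scores
    records <- merge(records, scores[, c("id", "score")], by = "id",
                     sort = TRUE)
  }
  stopifnot(all(c("id", "x_um", "y_um") %in% names(records)))
  if (feature_set == "xy+score") {
    if (!"score" %in% names(records))
      stop("feature_set \"xy+score\" needs a `score` column (or `scores`)")
    cols <- c("x_um", "y_um", "score")
  } else {
    feat <- intersect(names(FEATURE_GROUPS), names(records))
    if (length(feat) == 0L)
      stop("feature_set \"xy+features\" needs feature columns")
    cols <- c("x_um", "y_um", feat)
  }
  X <- apply(as.matrix(records[, cols, drop = FALSE]), 2, minmax01)
  n <- nrow(records)
  if (n < min_cluster_size) {
    labels <- rep(-1L, n)
  } else {
    labels <- hdbscan_fit(X, min_cluster_size = min_cluster_size,
                          allow_single_cluster = allow_single_cluster)$labels
  }
  cl_ids <- sort(unique(labels[labels > 0L]))
  if (length(cl_ids) == 0L) {
    msg("all %d nuclei labeled noise", n)
    clusters <- data.frame(cluster = integer(), n = integer(),
                           mean_score = numeric(),
                           mean_angular_diff_deg = numeric())
  } else {
    clusters <- do.call(rbind, lapply(cl_ids, function(cl) {
      sel <- labels == cl
      data.frame(cluster = cl, n = sum(sel),
                 mean_score = if ("score" %in% names(records))
                   mean(records$score[sel]) else NA_real_,
                 mean_angular_diff_deg = NA_real_)
    }))
  }
  structure(list(labels = labels, ids = records$id, clusters = clusters),
            class = "cluster_assignment")
}

#' Mean pairwise axial angular difference within each cluster
#'
#' For every non-noise cluster with at least two members, the mean over
#' all unordered nucleus pairs of the axial angular difference
#' `min(|a - b|, 180 - |a - b|)` between their long-axis orientations.
#' Singleton clusters report `NA`.
#'
#' @param assignment a `cluster_assignment` from [cluster_nuclei()].
#' @param records data.frame with `id` and `orientation_deg`, or a
#'   `nucleus_records` object.
#' @return the `cluster_assignment` with `clusters$mean_angular_diff_deg`
#'   filled in (degrees, in `[0, 90]`).
#' @export
cluster_angular_difference <- function(assignment, records) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (inherits(records, "nucleus_records")) records <- records$records
  stopifnot(all(c("id", "orientation_deg") %in% names(records)))
  ori <- records$orientation_deg[match(assignment$ids, records$id)]
  for (k in seq_len(nrow(assignment$clusters))) {
    cl <- assignment$clusters$cluster[k]
    a <- ori[assignment$labels == cl]
    assignment$clusters$mean_angular_diff_deg[k] <-
      mean_pairwise_axial_diff(a[!is.na(a)])
  }
  assignment
}

#' Write an IPD matrix as a square CSV with id header row/column
#'
#' @param matrix an `ipd_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ipd_matrix <- function(matrix, path) {
  write.csv(as.data.frame(unclass(matrix)), path, row.names = TRUE)
  invisible(path)
}
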