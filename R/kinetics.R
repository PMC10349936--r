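# Clustering of significantly changing features over the depletion time
# course into response groups with summary kinetic traces.

#' Standardized per-timepoint response profiles
#'
#' Normalizes counts by size factors, averages replicates within each
#' timepoint, and z-scores each feature's profile across timepoints (mean
#' 0, sd 1). Zero-variance features are dropped with a message.
#'
#' @param counts a [count_matrix()].
#' @param dynamic_ids feature subset to standardize.
#' @param factors size factors (computed when `NULL`).
#' @return Numeric matrix features x timepoints of z-scores; dropped
#'   feature ids in `attr(, "dropped")`.
#' @export
standardize_profiles <- function(counts, dynamic_ids, factors = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  miss <- setdiff(dynamic_ids, rownames(counts$counts))
  if (length(miss)) stop("unknown feature id(s): ", paste(head(miss, 3), collapse = ", "))
  if (is.null(factors)) factors <- size_factors(counts)
  k <- sweep(counts$counts[dynamic_ids, , drop = FALSE], 2, factors, "/")
  tps <- sort(unique(counts$meta$timepoint))
  means <- vapply(tps, function(tp) {
    rowMeans(k[, counts$meta$timepoint == tp, drop = FALSE])
  }, numeric(nrow(k)))
  means <- matrix(means, nrow = nrow(k),
                  dimnames = list(dynamic_ids, as.character(tps)))
  sds <- apply(means, 1, sd)
  drop <- sds < 1e-12
  if (any(drop)) {
    message(sum(drop), " zero-variance feature(s) dropped from profiles")
  }
  z <- (means[!drop, , drop = FALSE] - rowMeans(means[!drop, , drop = FALSE])) /
    sds[!drop]
  attr(z, "dropped") <- dynamic_ids[drop]
  z
}

#' Hierarchical clustering of response profiles
#'
#' Clusters standardized profiles with distance `1 - Pearson correlation`
#' and Ward linkage. When `k` is `NULL`, the smallest `k` in `2..k_max`
#' maximizing the mean silhouette width is chosen. Clusters below
#' `min_size` are merged into the nearest centroid (by correlation), or
#' discarded when `discard_small = TRUE`. Rows are ordered by feature id
#' before clustering, so memberships do not depend on input order.
#'
#' @param z standardized matrix from [standardize_profiles()].
#' @param k number of clusters, or `NULL` for the silhouette heuristic.
#' @param min_size minimum cluster size (default 15).
#' @param k_max largest k tried by the heuristic.
#' @param discard_small drop (rather than merge) undersized clusters.
#' @return List of `response_cluster`s: each has `cluster_id`, `members`,
#'   `centroid` (per-timepoint median), `iqr_low`, `iqr_high`, `size`.
#' @export
cluster_profiles <- function(z, k = NULL, min_size = 15, k_max = 8,
                             discard_small = FALSE) {
  z <- z[order(rownames(z)), , drop = FALSE]
  n <- nrow(z)
  if (!is.null(k) && k > n) stop("k exceeds the number of features")
  if (n < 2 * min_size) stop("need at least 2 * min_size features")
  d <- as.dist(1 - cor(t(z)))
  tree <- hclust(d, method = "ward.D2")
  if (is.null(k)) {
    ks <- 2:min(k_max, n - 1)
    sil <- vapply(ks, function(kk) {
      mean(cluster::silhouette(cutree(tree, kk), d)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  member <- cutree(tree, k)
  centroid_of <- function(ids) apply(z[ids, , drop = FALSE], 2, median)
  sizes <- table(member)
  small <- as.integer(names(sizes)[sizes < min_size])
  big <- setdiff(unique(member), small)
  if (length(small) && length(big)) {
    if (discard_small) {
      member[member %in% small] <- NA
    } else {
      cents <- vapply(big, function(cl) centroid_of(names(member)[member == cl]),
                      numeric(ncol(z)))
      for (cl in small) {
        ids <- names(member)[!is.na(member) & member == cl]
        sim <- cor(centroid_of(ids), cents)
        member[ids] <- big[which.max(sim)]
      }
    }
  }
  out <- lapply(sort(unique(member[!is.na(member)])), function(cl) {
    ids <- sort(names(member)[!is.na(member) & member == cl])
    sub <- z[ids, , drop = FALSE]
    structure(list(cluster_id = cl, members = ids,
                   centroid = apply(sub, 2, median),
                   iqr_low = apply(sub, 2, quantile, 0.25),
                   iqr_high = apply(sub, 2, quantile, 0.75),
                   size = length(ids)), class = "response_cluster")
  })
  attr(out, "k") <- k
  out
}
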