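#' K-means partition of MDS coordinates
#'
#' Lloyd's algorithm with k-means++ seeding, best of `n_restarts` runs by
#' within-cluster sum of squares. The reported distortion is the mean
#' squared Euclidean distance from each object to its assigned centroid
#' (squared-error distortion), the quantity plotted against k in the elbow
#' analysis.
#'
#' @param X n x d coordinate matrix (MDS configuration).
#' @param k number of clusters (1..n).
#' @param n_restarts independent seeded runs; the best is kept.
#' @param seed integer seed.
#' @return list with `labels` (integer vector 1..k, one per object),
#'   `k`, `method = "kmeans"`, `distortion`, `centers`.
#' @export
kmeans_partition <- function(X, k, n_restarts = 50L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1 || k > n) stop("k must be in [1, nrow(X)]", call. = FALSE)
  if (k == n) {
    return(list(
      labels = seq_len(n), k = as.integer(k), method = "kmeans",
      distortion = 0, centers = X
    ))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(child_seed(seed, r), {
      centers <- kmeanspp_centers(X, k)
      tryCatch(
        suppressWarnings(
          kmeans(X, centers = centers, iter.max = 100L, algorithm = "Lloyd")
        ),
        error = function(e) NULL # empty-cluster run: drop and re-seed
      )
    })
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("k-means failed on every restart", call. = FALSE)
  list(
    labels = as.integer(best$cluster), k = as.integer(k), method = "kmeans",
    distortion = best$tot.withinss / n, centers = best$centers
  )
}

# k-means++ seeding: first center uniform, later centers drawn with
# probability proportional to squared distance to the nearest chosen center
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1) {
    d2 <- rowSums((X - matrix(X[idx[1], ], n, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        idx[j] <- sample.int(n, 1L)
      } else {
        idx[j] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, rowSums((X - matrix(X[idx[j], ], n, ncol(X), byrow = TRUE))^2))
    }
  }
  X[idx, , drop = FALSE] + 1e-10 * seq_len(k) # break exact duplicates
}

#' Distortion profile and elbow over cluster counts
#'
#' Runs [kmeans_partition()] for each k, collects the squared-error
#' distortion, and applies the kneedle elbow detector — the procedure that
#' selects the number of global categories. As for the stress scree, the
#' elbow is detected on the root scale by default (`sqrt(distortion)`, the
#' RMS distance of objects to their centroid, in input units); the profile
#' itself reports the squared-error distortion.
#'
#' @inheritParams kmeans_partition
#' @param k_range integer grid of cluster counts (e.g. 1:15).
#' @param sensitivity kneedle sensitivity.
#' @param scale `"root"` (default) or `"raw"` for the elbow detection.
#' @return list with `profile` (data.frame of `k`, `distortion`),
#'   `k_at_elbow` (NA if no elbow), `elbow` (full kneedle result).
#' @export
distortion_elbow <- function(X, k_range = 1:15, n_restarts = 50L, seed = 1L,
                             sensitivity = 1, scale = c("root", "raw")) {
  scale <- match.arg(scale)
  k_range <- sort(unique(as.integer(k_range)))
  dist_k <- vapply(seq_along(k_range), function(i) {
    kmeans_partition(X, k_range[i],
      n_restarts = n_restarts,
      seed = child_seed(seed, i)
    )$distortion
  }, numeric(1))
  profile <- data.frame(k = k_range, distortion = dist_k)
  ys <- if (scale == "root") sqrt(profile$distortion) else profile$distortion
  elbow <- kneedle_elbow(profile$k, ys, sensitivity)
  list(
    profile = profile,
    k_at_elbow = if (elbow$found) as.integer(elbow$x_at_elbow) else NA_integer_,
    elbow = elbow
  )
}

#' Ward agglomerative clustering of a distance matrix
#'
#' Agglomerative hierarchy under Ward's criterion: each merge minimizes the
#' increase in total within-cluster variance. Accepts the MDS-space distance
#' matrix (Euclidean distances of the configuration), for which the variance
#' interpretation is exact. Implemented via `stats::hclust(method =
#' "ward.D2")`, which applies the Lance-Williams update on squared distances
#' and reports heights on the distance scale.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @return an object of classes `ward_tree` and `hclust` (fields `merge`,
#'   `height`, `order`); heights are non-decreasing.
#' @export
ward_tree <- function(D) {
  check_dissim(D)
  h <- hclust(as.dist(D), method = "ward.D2")
  class(h) <- c("ward_tree", "hclust")
  h
}

#' Cut a dendrogram into c flat clusters
#'
#' Undoes the last `c - 1` merges, yielding the partition a vertical cut of
#' the dendrogram produces.
#'
#' @param tree a `ward_tree` / `hclust` object.
#' @param c number of clusters (1..n leaves).
#' @return list with `labels`, `k`, `method = "ward"`.
#' @export
cut_tree <- function(tree, c) {
  n <- length(tree$order)
  if (c < 1 || c > n) stop("c must be in [1, n]", call. = FALSE)
  cl <- unclass(tree)
  class(cl) <- "hclust"
  list(labels = as.integer(cutree(cl, k = c)), k = as.integer(c), method = "ward")
}

#' Quartile binning of the ranked pair table
#'
#' Splits the similarity-ranked pairs into four rank quartiles: Q1 holds the
#' most similar pairs, Q4 the least similar. When the pair count is not a
#' multiple of four, earlier quartiles take the extra pairs (sizes differ by
#' at most one; 435 pairs split 109/109/109/108). Cutoff distances (the
#' largest distance in each quartile) are reported.
#'
#' @param ranked_pairs output of [ranked_pair_table()] (sorted ascending).
#' @return list with `table` (the input plus a `quartile` factor column) and
#'   `cutoffs` (named numeric vector of per-quartile maximum distances).
#' @export
quartile_bins <- function(ranked_pairs) {
  m <- nrow(ranked_pairs)
  if (m < 4) stop("need at least 4 pairs", call. = FALSE)
  base <- m %/% 4L
  extra <- m %% 4L
  sizes <- base + as.integer(seq_len(4L) <= extra)
  q <- factor(rep(paste0("Q", 1:4), times = sizes), levels = paste0("Q", 1:4))
  tab <- cbind(ranked_pairs, quartile = q)
  cutoffs <- tapply(tab$distance, tab$quartile, max)
  list(table = tab, cutoffs = cutoffs)
}
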