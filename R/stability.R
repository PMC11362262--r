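#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects,
#' computed from the contingency table:
#' `(Index - ExpectedIndex) / (MaxIndex - ExpectedIndex)` where Index is the
#' number of agreeing object pairs. 1 means identical partitions (up to
#' label permutation), values near 0 chance-level agreement.
#'
#' @param p1,p2 partitions: integer/character label vectors of equal length,
#'   or lists with a `labels` field as returned by the clustering functions.
#' @return scalar ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(p1, p2) {
  l1 <- if (is.list(p1)) p1$labels else p1
  l2 <- if (is.list(p2)) p2$labels else p2
  if (length(l1) != length(l2)) {
    stop("partitions must label the same object set", call. = FALSE)
  }
  n <- length(l1)
  tab <- table(l1, l2)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  expected <- a * b / total
  max_index <- (a + b) / 2
  if (max_index == expected) {
    return(1) # both partitions trivial (all-singletons or one cluster)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Bootstrap clustering partitions over participants
#'
#' The stability protocol: each replicate resamples participants with
#' replacement, averages their dissimilarity matrices, re-embeds with
#' metric SMACOF at a fixed dimensionality, and re-clusters at a fixed
#' cluster count — k-means on the MDS coordinates, or a Ward dendrogram cut
#' on the MDS-space distance matrix.
#'
#' @param matrices list of per-participant dissimilarity matrices (the
#'   resampling unit).
#' @param method `"kmeans"` or `"ward"`.
#' @param n_replicates bootstrap replicates (the study used 1000).
#' @param sample_size participants drawn per replicate; defaults to
#'   `length(matrices)`, mirroring the original sample size.
#' @param fixed_k cluster count held fixed across replicates (study: 7).
#' @param embed_dim embedding dimensionality (study: 3).
#' @param n_starts SMACOF random starts per replicate (reduced relative to
#'   the final fit for tractability).
#' @param kmeans_restarts k-means restarts per replicate.
#' @param seed integer seed; replicate b and its embedding/clustering all
#'   derive child seeds from it.
#' @return list of partition objects (as from the clustering functions).
#' @export
bootstrap_partitions <- function(matrices, method = c("kmeans", "ward"),
                                 n_replicates = 1000L, sample_size = NULL,
                                 fixed_k = 7L, embed_dim = 3L,
                                 n_starts = 4L, kmeans_restarts = 10L,
                                 seed = 1L) {
  method <- match.arg(method)
  if (length(matrices) < 2) stop("need at least 2 participants", call. = FALSE)
  if (is.null(sample_size)) sample_size <- length(matrices)
  lapply(seq_len(n_replicates), function(b) {
    idx <- with_seed(
      child_seed(seed, 2L * b),
      sample.int(length(matrices), sample_size, replace = TRUE)
    )
    M <- group_matrix(matrices[idx])
    fit <- smacof_embed(M, embed_dim,
      n_starts = n_starts,
      seed = child_seed(seed, 2L * b + 1L)
    )
    if (method == "kmeans") {
      kmeans_partition(fit$coordinates, fixed_k,
        n_restarts = kmeans_restarts,
        seed = child_seed(seed, 7919L + b)
      )
    } else {
      cut_tree(ward_tree(as.matrix(dist(fit$coordinates))), fixed_k)
    }
  })
}

# mean ARI over all unordered pairs of a partition list
mean_pairwise_ari <- function(parts) {
  B <- length(parts)
  if (B < 2) {
    warning("fewer than 2 replicates: within-method mean ARI undefined")
    return(NA_real_)
  }
  ij <- pair_index(B)
  mean(vapply(
    seq_len(nrow(ij)),
    function(r) adjusted_rand_index(parts[[ij[r, 1]]], parts[[ij[r, 2]]]),
    numeric(1)
  ))
}

#' Summarize clustering stability
#'
#' Within-method stability is the mean ARI over all unordered pairs of
#' bootstrap partitions, per method. Cross-method agreement is reported two
#' ways: `mean_ari_cross` averages replicate-matched comparisons
#' (k-means replicate b vs Ward replicate b) across replicates — the primary
#' figure — and, when reference partitions fit on the original (non-resampled)
#' data are supplied, `ari_cross_original` is their single comparison.
#'
#' @param kmeans_parts,ward_parts equal-length lists of bootstrap partitions.
#' @param kmeans_original,ward_original optional partitions from the
#'   original data set.
#' @return object of class `stability_report`: list with `mean_ari_kmeans`,
#'   `mean_ari_ward`, `mean_ari_cross`, `ari_cross_original` (NA when not
#'   supplied), and `n_replicates`.
#' @export
stability_summary <- function(kmeans_parts, ward_parts,
                              kmeans_original = NULL, ward_original = NULL) {
  if (length(kmeans_parts) != length(ward_parts)) {
    stop("partition lists must have equal length", call. = FALSE)
  }
  B <- length(kmeans_parts)
  cross <- if (B >= 1) {
    mean(vapply(
      seq_len(B),
      function(b) adjusted_rand_index(kmeans_parts[[b]], ward_parts[[b]]),
      numeric(1)
    ))
  } else {
    NA_real_
  }
  structure(
    list(
      mean_ari_kmeans = mean_pairwise_ari(kmeans_parts),
      mean_ari_ward = mean_pairwise_ari(ward_parts),
      mean_ari_cross = cross,
      ari_cross_original = if (!is.null(kmeans_original) && !is.null(ward_original)) {
        adjusted_rand_index(kmeans_original, ward_original)
      } else {
        NA_real_
      },
      n_replicates = B
    ),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Clustering stability over %d bootstrap replicates\n",
      "  mean ARI, k-means:      %.3f\n",
      "  mean ARI, Ward:         %.3f\n",
      "  mean ARI, cross-method: %.3f\n"
    ),
    x$n_replicates, x$mean_ari_kmeans, x$mean_ari_ward, x$mean_ari_cross
  ))
  if (!is.na(x$ari_cross_original)) {
    cat(sprintf("  cross-method ARI on original data: %.3f\n", x$ari_cross_original))
  }
  invisible(x)
}
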