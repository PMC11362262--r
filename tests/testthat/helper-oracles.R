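# Independent brute-force oracles used to cross-check the package's own
# implementations. These deliberately use different formulas / algorithms
# than the code under test.

# ARI via direct pair counting (not the contingency-table formula):
# classify every object pair as agreeing or not in each partition.
ari_pair_counting <- function(l1, l2) {
  n <- length(l1)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s1 <- l1[i] == l1[j]
      s2 <- l2[i] == l2[j]
      if (s1 && s2) n11 <- n11 + 1 else if (!s1 && !s2) n00 <- n00 + 1
      else if (s1 && !s2) n10 <- n10 + 1 else n01 <- n01 + 1
    }
  }
  denom <- (n00 + n01) * (n01 + n11) + (n00 + n10) * (n10 + n11)
  if (denom == 0) return(1)
  2 * (n00 * n11 - n01 * n10) / denom
}

# exact covering number by iterative-deepening DFS over k-subsets
exact_cover_number <- function(n, k) {
  pairs <- t(combn(n, 2))
  np <- nrow(pairs)
  pair_id <- matrix(0L, n, n)
  for (r in seq_len(np)) {
    pair_id[pairs[r, 1], pairs[r, 2]] <- r
    pair_id[pairs[r, 2], pairs[r, 1]] <- r
  }
  blocks <- combn(n, k)
  block_pairs <- lapply(seq_len(ncol(blocks)), function(c) {
    ij <- combn(blocks[, c], 2)
    vapply(seq_len(ncol(ij)), function(p) pair_id[ij[1, p], ij[2, p]], integer(1))
  })
  # blocks containing each pair
  by_pair <- lapply(seq_len(np), function(p) {
    which(vapply(block_pairs, function(bp) p %in% bp, logical(1)))
  })
  per_block <- choose(k, 2)
  dfs <- function(covered, depth) {
    unc <- which(!covered)
    if (length(unc) == 0) return(TRUE)
    if (depth == 0 || length(unc) > depth * per_block) return(FALSE)
    for (b in by_pair[[unc[1]]]) {
      cov2 <- covered
      cov2[block_pairs[[b]]] <- TRUE
      if (dfs(cov2, depth - 1)) return(TRUE)
    }
    FALSE
  }
  m <- ceiling(np / per_block)
  while (!dfs(rep(FALSE, np), m)) m <- m + 1
  m
}

# Ward agglomeration directly from coordinates: at each step merge the two
# clusters with the smallest increase in total within-cluster sum of squares
# (Delta ESS = |A||B|/(|A|+|B|) * ||mean_A - mean_B||^2). Heights on the
# ward.D2 scale are sqrt(2 * Delta ESS).
ward_oracle <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    for (a in seq_len(length(clusters) - 1)) {
      for (b in (a + 1):length(clusters)) {
        ma <- colMeans(X[clusters[[a]], , drop = FALSE])
        mb <- colMeans(X[clusters[[b]], , drop = FALSE])
        na <- length(clusters[[a]])
        nb <- length(clusters[[b]])
        dess <- na * nb / (na + nb) * sum((ma - mb)^2)
        if (is.null(best) || dess < best$dess) best <- list(a = a, b = b, dess = dess)
      }
    }
    merged <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    merges[[length(merges) + 1]] <- merged
    heights <- c(heights, sqrt(2 * best$dess))
    clusters <- c(clusters[-c(best$a, best$b)], list(merged))
  }
  list(merges = merges, heights = heights)
}

# recover the merged leaf sets and heights from an hclust object
hclust_merge_sets <- function(h) {
  sets <- vector("list", nrow(h$merge))
  for (s in seq_len(nrow(h$merge))) {
    members <- unlist(lapply(h$merge[s, ], function(m) {
      if (m < 0) -m else sets[[m]]
    }))
    sets[[s]] <- sort(members)
  }
  list(merges = sets, heights = h$height)
}

# Spearman rho with average ranks, computed from first principles
spearman_oracle <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(xi) sum(v < xi) + (1 + sum(v == xi)) / 2, numeric(1))
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# two-pass sample standard deviation
sd_oracle <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# area-average downsampling by explicit block means (dimensions divisible
# by the target): independent of the weight-matrix implementation
block_mean_oracle <- function(mat, target) {
  f <- nrow(mat) / target
  out <- matrix(0, target, target)
  for (r in seq_len(target)) {
    for (c in seq_len(target)) {
      out[r, c] <- mean(mat[((r - 1) * f + 1):(r * f), ((c - 1) * f + 1):(c * f)])
    }
  }
  out
}

# small synthetic world + arrangement data shared across tests
tiny_pipeline_data <- function(seed = 42, n_participants = 10, sigma_place = 10,
                               latent_dim = 3) {
  world <- make_world(seed = seed, latent_dim = latent_dim)
  design <- minimal_blocks(30, 16, restarts = 10, seed = seed)$design
  arr <- simulate_arrangements(world, design,
    n_participants = n_participants,
    sigma_place = sigma_place, seed = seed + 1
  )
  list(
    world = world, design = design, arr = arr,
    mats = participant_matrices(arr, design)
  )
}

# upper-triangle values of a square matrix
uv <- function(M) M[upper.tri(M)]
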