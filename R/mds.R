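#' Raw (un-normalized) MDS stress
#'
#' The loss minimized by metric SMACOF here: the sum over unordered pairs of
#' squared differences between input dissimilarities and configuration
#' distances, `sum_{i<j} (d_ij - dhat_ij)^2`. No normalization is applied,
#' so the value is in squared input units.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal.
#' @param X numeric n x d configuration matrix.
#' @return non-negative scalar.
#' @export
raw_stress <- function(D, X) {
  check_dissim(D)
  X <- as.matrix(X)
  if (nrow(X) != nrow(D)) stop("D and X shapes disagree", call. = FALSE)
  dhat <- as.matrix(dist(X))
  sum((upper_vals(D) - upper_vals(dhat))^2)
}

# one SMACOF run from a given start: Guttman transform iterations.
# Stress is non-increasing by majorization; we record the trace so tests can
# assert monotonicity.
smacof_one <- function(D, X, max_iter, tol) {
  n <- nrow(D)
  dhat <- as.matrix(dist(X))
  s <- sum((upper_vals(D) - upper_vals(dhat))^2)
  trace <- s
  for (it in seq_len(max_iter)) {
    ratio <- ifelse(dhat > 0, D / dhat, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
    dhat <- as.matrix(dist(X))
    s_new <- sum((upper_vals(D) - upper_vals(dhat))^2)
    trace <- c(trace, s_new)
    if (s > 0 && (s - s_new) / s < tol) {
      s <- s_new
      break
    }
    s <- s_new
  }
  list(X = X, stress = s, trace = trace, iterations = length(trace) - 1L)
}

#' Metric SMACOF multidimensional scaling
#'
#' Embeds a complete dissimilarity matrix in `dim` dimensions by iterative
#' majorization (Guttman transform), minimizing raw stress
#' (see [raw_stress()]). The ratio variant is used: configuration distances
#' are fit to the dissimilarities directly, with no intercept and no
#' normalization. Several random starts are run and the lowest-stress
#' configuration returned; within each start the stress sequence is
#' non-increasing.
#'
#' @param D symmetric dissimilarity matrix, complete (metric MDS requires no
#'   missing entries) with zero diagonal.
#' @param dim target dimensionality (>= 1).
#' @param n_starts random initializations; the best is kept.
#' @param max_iter majorization iterations per start.
#' @param tol relative stress-decrease convergence threshold.
#' @param seed integer seed; start `s` uses a derived child seed.
#' @return object of class `mds_fit`: list with `coordinates` (n x dim),
#'   `stress`, `dim`, `n_starts`, `seed`, `stress_trace` (of the winning
#'   start).
#' @export
smacof_embed <- function(D, dim, n_starts = 8L, max_iter = 300L,
                         tol = 1e-6, seed = 1L) {
  check_dissim(D)
  stopifnot(dim >= 1, n_starts >= 1)
  n <- nrow(D)
  half_width <- mean(upper_vals(D)) # init hypercube scaled to the data
  best <- NULL
  for (s in seq_len(n_starts)) {
    X0 <- with_seed(
      child_seed(seed, s),
      matrix(runif(n * dim, -half_width, half_width), n, dim)
    )
    fit <- smacof_one(D, X0, max_iter, tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  structure(
    list(
      coordinates = best$X, stress = best$stress, dim = as.integer(dim),
      n_starts = as.integer(n_starts), seed = seed,
      stress_trace = best$trace
    ),
    class = "mds_fit"
  )
}

#' @export
print.mds_fit <- function(x, ...) {
  cat(sprintf(
    "Metric SMACOF fit: %d objects in %d dimensions, raw stress %.6g (%d starts)\n",
    nrow(x$coordinates), x$dim, x$stress, x$n_starts
  ))
  invisible(x)
}

#' Stress profile across dimensionalities
#'
#' Repeats independently initialized SMACOF fits at each candidate
#' dimensionality and summarizes the stress distribution — the scree data
#' from which the elbow (optimal dimensionality) is read. Averaging over
#' replicates suppresses start-configuration variability.
#'
#' @param D dissimilarity matrix.
#' @param dims increasing integer grid of dimensionalities (e.g. 1:7).
#' @param replicates independent single-start fits per dimensionality (the
#'   study used 1000).
#' @inheritParams smacof_embed
#' @return data.frame of class `stress_profile` with columns `dim`,
#'   `mean_stress`, `sd_stress`, `n_replicates`.
#' @export
stress_profile <- function(D, dims = 1:7, replicates = 100L, max_iter = 300L,
                           tol = 1e-6, seed = 1L) {
  if (length(dims) == 0) stop("dims must be non-empty", call. = FALSE)
  dims <- as.integer(dims)
  out <- lapply(seq_along(dims), function(di) {
    st <- vapply(seq_len(replicates), function(r) {
      smacof_embed(D, dims[di],
        n_starts = 1L, max_iter = max_iter, tol = tol,
        seed = child_seed(seed, (di - 1L) * replicates + r)
      )$stress
    }, numeric(1))
    data.frame(
      dim = dims[di], mean_stress = mean(st),
      sd_stress = if (replicates > 1) sd(st) else 0,
      n_replicates = replicates
    )
  })
  structure(do.call(rbind, out), class = c("stress_profile", "data.frame"))
}

#' Kneedle elbow detection on a decreasing curve
#'
#' Discrete kneedle for positively concave (decreasing, convex) curves such
#' as scree or distortion plots: min-max normalize both axes, invert the
#' y-axis so the elbow becomes a knee, and return the grid point maximizing
#' the difference curve `y_inverted - x_normalized`. A candidate only counts
#' when its difference exceeds `sensitivity` times the mean x-grid step;
#' (near-)linear curves therefore yield `found = FALSE`.
#'
#' @param xs strictly increasing numeric grid.
#' @param ys curve values at `xs`.
#' @param sensitivity kneedle sensitivity S (default 1).
#' @return list with `x_at_elbow` (a member of `xs`, or `NA` if none),
#'   `found`, `sensitivity`, and `difference` (the normalized difference
#'   curve, for plotting).
#' @export
kneedle_elbow <- function(xs, ys, sensitivity = 1) {
  if (length(xs) != length(ys) || length(xs) < 3) {
    stop("xs and ys must have equal length >= 3", call. = FALSE)
  }
  if (any(diff(xs) <= 0)) stop("xs must be strictly increasing", call. = FALSE)
  xn <- (xs - min(xs)) / (max(xs) - min(xs))
  yr <- max(ys) - min(ys)
  if (yr == 0) {
    return(list(
      x_at_elbow = NA_real_, found = FALSE,
      sensitivity = sensitivity, difference = rep(0, length(xs))
    ))
  }
  yn <- (ys - min(ys)) / yr
  diff_curve <- (1 - yn) - xn # inverted knee graph for decreasing curves
  i <- which.max(diff_curve)
  threshold <- sensitivity * mean(diff(xn))
  found <- diff_curve[i] > threshold
  list(
    x_at_elbow = if (found) xs[i] else NA_real_, found = found,
    sensitivity = sensitivity, difference = diff_curve
  )
}

#' Select MDS dimensionality from a stress profile
#'
#' Kneedle elbow on the scree curve. By default the elbow is detected on the
#' root scale, `sqrt(mean_stress)` — the scale of a Kruskal stress-1 scree
#' and of the distances themselves. On the raw squared scale the
#' one-dimensional point dominates the min-max normalization for any
#' Euclidean configuration and masks later elbows; `scale = "raw"` is
#' available for comparison.
#'
#' @param profile a `stress_profile`.
#' @param scale `"root"` (default) or `"raw"`.
#' @inheritParams kneedle_elbow
#' @return the elbow dimensionality (integer) or `NA` if no elbow is found.
#' @export
select_dimensionality <- function(profile, sensitivity = 1,
                                  scale = c("root", "raw")) {
  scale <- match.arg(scale)
  ys <- if (scale == "root") sqrt(profile$mean_stress) else profile$mean_stress
  res <- kneedle_elbow(profile$dim, ys, sensitivity)
  if (res$found) as.integer(res$x_at_elbow) else NA_integer_
}

#' Rank object pairs by embedded distance
#'
#' All unordered pairs sorted by their Euclidean distance in the MDS
#' configuration, most similar (smallest distance) first; ties keep lexical
#' (i, j) order. For 30 objects this is the 435-pair similarity ranking.
#'
#' @param fit an `mds_fit` (or a bare coordinate matrix).
#' @return data.frame with columns `rank`, `i`, `j`, `distance`.
#' @export
ranked_pair_table <- function(fit) {
  X <- if (inherits(fit, "mds_fit")) fit$coordinates else as.matrix(fit)
  dm <- as.matrix(dist(X))
  ij <- pair_index(nrow(X))
  tab <- data.frame(i = ij[, 1], j = ij[, 2], distance = dm[ij])
  ord <- order(tab$distance, tab$i, tab$j)
  tab <- tab[ord, ]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}
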