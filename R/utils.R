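#' Derive a child RNG seed
#'
#' Deterministically maps a parent seed and a stream index to a new seed so
#' that independent stages (restarts, participants, bootstrap replicates)
#' draw from reproducible, non-overlapping streams. Kept within the 32-bit
#' integer range R's RNG accepts.
#'
#' @param seed parent integer seed.
#' @param i stream index (non-negative integer).
#' @return an integer seed in \[0, 2^31 - 2\].
#' @export
child_seed <- function(seed, i) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(i), length(i) == 1)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(seed) %% m)
  # one multiplicative-congruential step per index keeps streams decorrelated
  as.integer((s * 48271 + i * 69621 + 1) %% m)
}

# run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards so library code never disturbs user RNG
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# validate a dissimilarity matrix: square, symmetric, non-negative,
# zero diagonal; returns the matrix invisibly
check_dissim <- function(D, tol = 1e-8) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("dissimilarity matrix must be square", call. = FALSE)
  }
  if (any(!is.finite(D))) {
    stop("dissimilarity matrix has missing or non-finite entries", call. = FALSE)
  }
  if (max(abs(D - t(D))) > tol) {
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  }
  if (any(D < -tol)) {
    stop("dissimilarity matrix must be non-negative", call. = FALSE)
  }
  if (any(abs(diag(D)) > tol)) {
    stop("dissimilarity matrix must have a zero diagonal", call. = FALSE)
  }
  invisible(D)
}

# upper-triangle (i < j) values of a square matrix, in column-major order
upper_vals <- function(D) D[upper.tri(D)]

# all unordered pairs of 1..n as a 2-column matrix, lexical (i, j) order
pair_index <- function(n) {
  ij <- t(combn(n, 2L))
  colnames(ij) <- c("i", "j")
  ij
}
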