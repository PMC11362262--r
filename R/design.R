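#' Number of unordered object pairs
#'
#' @param n number of objects (>= 2).
#' @return `n * (n - 1) / 2`, the number of distinct unordered pairs; for the
#'   30-object roster this is 435.
#' @examples
#' count_pairs(30) # 435
#' @export
count_pairs <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    stop("n must be a single integer >= 2", call. = FALSE)
  }
  as.integer(n * (n - 1) / 2)
}

#' Generate a pair-covering block design
#'
#' Builds trials ("blocks") of `block_size` objects so that every unordered
#' pair of the `n_objects` roster co-occurs in at least one trial — the
#' requirement that lets a spatial-arrangement study measure all pairwise
#' distances. Uses a randomized greedy: each block is seeded with a
#' least-covered pair and grown by adding the object that covers the most
#' still-uncovered pairs, ties broken uniformly at random; blocks are added
#' until no pair is uncovered.
#'
#' @param n_objects roster size (the study uses 30).
#' @param block_size objects shown per trial (the study uses 16).
#' @param seed integer seed; the design is reproducible bit-for-bit.
#' @return an object of class `trial_design`: a list with `blocks` (list of
#'   integer vectors of object ids), `n_objects` and `block_size`.
#' @examples
#' d <- generate_blocks(30, 16, seed = 1)
#' length(d$blocks)
#' @export
generate_blocks <- function(n_objects, block_size, seed = 1L) {
  if (!is.numeric(block_size) || block_size < 2) {
    stop("block_size must be at least 2", call. = FALSE)
  }
  if (block_size > n_objects) {
    stop("block_size cannot exceed n_objects", call. = FALSE)
  }
  n <- as.integer(n_objects)
  k <- as.integer(block_size)
  with_seed(seed, {
    cover <- matrix(0L, n, n) # co-occurrence counts
    diag(cover) <- NA_integer_
    blocks <- list()
    repeat {
      unc <- which(upper.tri(cover) & cover == 0L, arr.ind = TRUE)
      if (nrow(unc) == 0) break
      # seed the block with a least-covered (i.e., uncovered) pair
      pick <- unc[sample.int(nrow(unc), 1L), ]
      block <- as.integer(pick)
      while (length(block) < k) {
        cand <- setdiff(seq_len(n), block)
        # newly covered pairs each candidate would add
        gain <- vapply(cand, function(o) sum(cover[o, block] == 0L), integer(1))
        best <- cand[gain == max(gain)]
        block <- c(block, if (length(best) == 1L) best else
          best[sample.int(length(best), 1L)])
      }
      block <- sort(block)
      ij <- combn(block, 2L)
      for (p in seq_len(ncol(ij))) {
        cover[ij[1, p], ij[2, p]] <- cover[ij[1, p], ij[2, p]] + 1L
        cover[ij[2, p], ij[1, p]] <- cover[ij[2, p], ij[1, p]] + 1L
      }
      blocks[[length(blocks) + 1L]] <- block
    }
    structure(
      list(blocks = blocks, n_objects = n, block_size = k, seed = seed),
      class = "trial_design"
    )
  })
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(
    "Pair-covering trial design: %d objects, %d trials of %d (covers %d pairs)\n",
    x$n_objects, length(x$blocks), x$block_size, count_pairs(x$n_objects)
  ))
  invisible(x)
}

#' Best (fewest-trial) covering design over random restarts
#'
#' Reruns [generate_blocks()] under `restarts` independent seeds and keeps
#' the design with the fewest trials — the simulation strategy used to
#' establish that 30 objects in blocks of 16 need a minimum of six trials.
#'
#' @inheritParams generate_blocks
#' @param restarts number of independent greedy runs.
#' @return list with `n_blocks` (smallest trial count achieved) and `design`
#'   (a `trial_design` attaining it).
#' @export
minimal_blocks <- function(n_objects, block_size, restarts = 1000L, seed = 1L) {
  stopifnot(restarts >= 1)
  best <- NULL
  for (r in seq_len(restarts)) {
    d <- generate_blocks(n_objects, block_size, seed = child_seed(seed, r))
    if (is.null(best) || length(d$blocks) < length(best$blocks)) best <- d
  }
  list(n_blocks = length(best$blocks), design = best)
}

#' Sweep the block size and report minimal trial counts
#'
#' For each candidate block size `k` (objects per trial), finds the smallest
#' number of trials achieving full pair coverage over `restarts` randomized
#' runs — the trade-off curve used to pick 16 objects per trial for the
#' 30-object roster.
#'
#' @param n_objects roster size.
#' @param k_range integer vector of block sizes to try (study swept 8 to 19).
#' @param restarts randomized runs per block size.
#' @param seed integer seed.
#' @return data.frame with columns `k` and `min_blocks`.
#' @export
sweep_block_size <- function(n_objects, k_range, restarts = 1000L, seed = 1L) {
  if (length(k_range) == 0) stop("k_range must be non-empty", call. = FALSE)
  if (any(k_range < 2 | k_range > n_objects)) {
    stop("k_range must lie within [2, n_objects]", call. = FALSE)
  }
  k_range <- sort(unique(as.integer(k_range)))
  mins <- vapply(seq_along(k_range), function(idx) {
    minimal_blocks(n_objects, k_range[idx],
      restarts = restarts,
      seed = child_seed(seed, idx)
    )$n_blocks
  }, integer(1))
  data.frame(k = k_range, min_blocks = mins)
}

#' Audit pair coverage of a trial design
#'
#' @param design a `trial_design`.
#' @return object of class `coverage_report`: list with `n_pairs_total`,
#'   `n_pairs_covered`, `multiplicity` (symmetric matrix of per-pair
#'   co-occurrence counts), and `uncovered` (2-column matrix of missed pairs,
#'   zero rows iff the design is a valid covering).
#' @export
verify_coverage <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  n <- design$n_objects
  mult <- matrix(0L, n, n)
  for (b in design$blocks) {
    if (anyDuplicated(b) || any(b < 1) || any(b > n)) {
      stop("malformed design: duplicate or out-of-range object ids in a block",
        call. = FALSE
      )
    }
    ij <- combn(b, 2L)
    for (p in seq_len(ncol(ij))) {
      mult[ij[1, p], ij[2, p]] <- mult[ij[1, p], ij[2, p]] + 1L
      mult[ij[2, p], ij[1, p]] <- mult[ij[2, p], ij[1, p]] + 1L
    }
  }
  unc <- which(upper.tri(mult) & mult == 0L, arr.ind = TRUE)
  colnames(unc) <- c("i", "j")
  structure(
    list(
      n_pairs_total = count_pairs(n),
      n_pairs_covered = count_pairs(n) - nrow(unc),
      multiplicity = mult,
      uncovered = unc
    ),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf(
    "Coverage: %d / %d pairs%s\n", x$n_pairs_covered, x$n_pairs_total,
    if (nrow(x$uncovered) == 0) " (complete)" else ""
  ))
  invisible(x)
}

#' Write a trial design to CSV
#'
#' Long format, one row per displayed object: `trial_index`, `slot`,
#' `object_id`.
#'
#' @param design a `trial_design`.
#' @param path output CSV path.
#' @export
write_design_csv <- function(design, path) {
  rows <- do.call(rbind, lapply(seq_along(design$blocks), function(t) {
    b <- design$blocks[[t]]
    data.frame(trial_index = t, slot = seq_along(b), object_id = b)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial design from CSV
#'
#' @param path CSV written by [write_design_csv()].
#' @param n_objects roster size; defaults to the largest object id present.
#' @return a `trial_design`.
#' @export
read_design_csv <- function(path, n_objects = NULL) {
  df <- read.csv(path)
  stopifnot(all(c("trial_index", "object_id") %in% names(df)))
  blocks <- lapply(split(df$object_id, df$trial_index), function(b) sort(as.integer(b)))
  names(blocks) <- NULL
  sizes <- lengths(blocks)
  structure(
    list(
      blocks = blocks,
      n_objects = as.integer(if (is.null(n_objects)) max(df$object_id) else n_objects),
      block_size = as.integer(max(sizes)),
      seed = NA_integer_
    ),
    class = "trial_design"
  )
}
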