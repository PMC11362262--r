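#' Pairwise canvas distances within one trial
#'
#' Euclidean distances (in pixels) between the final canvas positions of all
#' object pairs a participant arranged in a single trial.
#'
#' @param records data.frame with columns `object_id`, `x`, `y` for one
#'   participant-trial.
#' @return data.frame with columns `i`, `j` (object ids, `i < j`) and
#'   `distance`.
#' @export
trial_pair_distances <- function(records) {
  if (nrow(records) < 2) stop("a trial needs at least 2 objects", call. = FALSE)
  if (anyDuplicated(records$object_id)) {
    stop("malformed record: duplicate object in trial", call. = FALSE)
  }
  ord <- order(records$object_id)
  ids <- records$object_id[ord]
  xy <- cbind(records$x, records$y)[ord, , drop = FALSE]
  dm <- as.matrix(dist(xy))
  ij <- pair_index(length(ids))
  data.frame(
    i = ids[ij[, 1]], j = ids[ij[, 2]],
    distance = dm[ij]
  )
}

#' Per-participant dissimilarity matrix
#'
#' Averages a participant's within-trial canvas distances into an
#' `n_objects` x `n_objects` symmetric matrix: entry (i, j) is the mean
#' pixel distance over every trial in which objects i and j were shown
#' together. Under a pair-covering design the matrix is complete (no missing
#' entries off the diagonal).
#'
#' @param records data.frame with columns `trial_index`, `object_id`, `x`,
#'   `y` for one participant.
#' @param design the `trial_design` the participant was run under (used for
#'   the roster size and to diagnose missing pairs).
#' @param normalize if `TRUE`, distances are divided by the canvas diagonal
#'   before averaging, yielding unit-free values; default keeps raw pixels.
#' @param canvas canvas width and height in pixels, used only when
#'   `normalize = TRUE`.
#' @return symmetric matrix with zero diagonal and `provenance` attribute.
#' @export
participant_matrix <- function(records, design, normalize = FALSE,
                               canvas = c(1000, 600)) {
  n <- design$n_objects
  sums <- matrix(0, n, n)
  cnts <- matrix(0L, n, n)
  for (tr in split(records, records$trial_index)) {
    pd <- trial_pair_distances(tr)
    ii <- cbind(pd$i, pd$j)
    sums[ii] <- sums[ii] + pd$distance
    cnts[ii] <- cnts[ii] + 1L
  }
  miss <- which(upper.tri(cnts) & cnts == 0L, arr.ind = TRUE)
  if (nrow(miss) > 0) {
    stop(sprintf(
      "pairs never co-displayed (design does not cover them): %s",
      paste(sprintf("(%d,%d)", miss[, 1], miss[, 2]), collapse = " ")
    ), call. = FALSE)
  }
  M <- sums
  M[upper.tri(M)] <- sums[upper.tri(M)] / cnts[upper.tri(M)]
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  diag(M) <- 0
  if (normalize) M <- M / sqrt(sum(canvas^2))
  attr(M, "provenance") <- as.character(records$participant_id[1])
  M
}

#' Group-average dissimilarity matrix
#'
#' Element-wise mean across participants' matrices; the group-level d_ij
#' fed to multidimensional scaling.
#'
#' @param matrices list of equally sized participant matrices.
#' @return symmetric matrix with zero diagonal, `provenance = "group"`.
#' @export
group_matrix <- function(matrices) {
  if (length(matrices) < 1) stop("need at least one matrix", call. = FALSE)
  dims <- vapply(matrices, function(m) dim(m)[1], integer(1))
  if (length(unique(dims)) != 1 ||
    any(vapply(matrices, function(m) dim(m)[1] != dim(m)[2], logical(1)))) {
    stop("all matrices must be square and of identical size", call. = FALSE)
  }
  M <- Reduce(`+`, matrices) / length(matrices)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  attr(M, "provenance") <- "group"
  M
}

#' Build per-participant matrices from an arrangement table
#'
#' @param arrangements data.frame with columns `participant_id`,
#'   `trial_index`, `object_id`, `x`, `y` (one row per placed object).
#' @inheritParams participant_matrix
#' @return named list of participant matrices, in order of first appearance.
#' @export
participant_matrices <- function(arrangements, design, normalize = FALSE,
                                 canvas = c(1000, 600)) {
  ids <- unique(arrangements$participant_id)
  out <- lapply(ids, function(p) {
    participant_matrix(arrangements[arrangements$participant_id == p, ],
      design,
      normalize = normalize, canvas = canvas
    )
  })
  names(out) <- ids
  out
}

#' Read / write arrangement records
#'
#' CSV columns: `participant_id`, `trial_index`, `object_id`, `x`, `y`
#' (pixels; origin top-left, y increasing downward).
#'
#' @param path CSV path.
#' @return data.frame of arrangement records.
#' @export
read_arrangements_csv <- function(path) {
  df <- read.csv(path)
  need <- c("participant_id", "trial_index", "object_id", "x", "y")
  if (!all(need %in% names(df))) {
    stop("arrangements CSV must have columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  df
}

#' @rdname read_arrangements_csv
#' @param arrangements data.frame of arrangement records.
#' @export
write_arrangements_csv <- function(arrangements, path) {
  write.csv(arrangements, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a dissimilarity matrix as CSV
#'
#' N x N numeric CSV with object ids as header row and first column.
#'
#' @param path CSV path.
#' @return symmetric numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  M <- as.matrix(df)
  dimnames(M) <- NULL
  check_dissim(M)
  M
}

#' @rdname read_matrix_csv
#' @param M symmetric matrix.
#' @export
write_matrix_csv <- function(M, path) {
  df <- as.data.frame(M)
  names(df) <- seq_len(ncol(M))
  rownames(df) <- seq_len(nrow(M))
  write.csv(df, path, row.names = TRUE)
  invisible(path)
}
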