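#' Canonicalize naming responses with a synonym map
#'
#' Replaces each listed concept by its canonical form (e.g. "half circle"
#' and "semicircle" both become "semicircle"), drops duplicate canonical
#' concepts within a response, and marks responses that reduce to exactly
#' one canonical concept as single-concept. Unmapped concepts pass through
#' unchanged.
#'
#' @param records data.frame with columns `participant_id`, `object_id`,
#'   `seen_before` ("yes"/"no"), `concepts` (semicolon-separated concept
#'   tokens, possibly empty).
#' @param synonym_map data.frame with columns `variant`, `canonical`, or
#'   `NULL` for no collapsing.
#' @return the records with list-column `coded_concepts` and logical column
#'   `single_concept`.
#' @export
code_responses <- function(records, synonym_map = NULL) {
  lookup <- if (!is.null(synonym_map) && nrow(synonym_map) > 0) {
    stats::setNames(
      trimws(as.character(synonym_map$canonical)),
      trimws(as.character(synonym_map$variant))
    )
  } else {
    character(0)
  }
  coded <- lapply(records$concepts, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) {
      return(character(0))
    }
    toks <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    toks <- toks[nzchar(toks)]
    mapped <- ifelse(toks %in% names(lookup), lookup[toks], toks)
    unique(unname(mapped))
  })
  records$coded_concepts <- coded
  records$single_concept <- lengths(coded) == 1L
  records
}

#' Novelty rate of one object
#'
#' Percentage of participants answering "no" to having seen the object
#' category before.
#'
#' @param records coded naming records for a single object.
#' @return percentage in \[0, 100\].
#' @export
novelty_rate <- function(records) {
  if (nrow(records) == 0) stop("no records for object", call. = FALSE)
  ans <- tolower(trimws(as.character(records$seen_before)))
  100 * mean(ans == "no")
}

#' Identity agreement of one object
#'
#' Share of single-concept responses that used the most popular concept.
#' The denominator is conservatively restricted to single-concept responses
#' (hybrid and no-concept responses are excluded). Ties for the most
#' popular concept are broken lexically and flagged.
#'
#' @param records coded naming records (see [code_responses()]) for one
#'   object.
#' @return list with `top_concept`, `agreement` (percent, `NA` when there
#'   are no single-concept responses), `n_single_concept`, `defined`, `tie`.
#' @export
identity_agreement <- function(records) {
  singles <- records[records$single_concept, , drop = FALSE]
  n_single <- nrow(singles)
  if (n_single == 0) {
    return(list(
      top_concept = NA_character_, agreement = NA_real_,
      n_single_concept = 0L, defined = FALSE, tie = FALSE
    ))
  }
  concepts <- vapply(singles$coded_concepts, `[[`, character(1), 1L)
  counts <- sort(table(concepts), decreasing = TRUE)
  top_n <- counts[counts == max(counts)]
  top <- sort(names(top_n))[1]
  list(
    top_concept = top,
    agreement = 100 * unname(counts[top]) / n_single,
    n_single_concept = n_single, defined = TRUE,
    tie = length(top_n) > 1
  )
}

#' Per-object novelty and naming-agreement scores
#'
#' @param records coded naming records for all objects.
#' @param known_benchmark identity-agreement percentage above which an
#'   object would count as "known" rather than novel (default 85, the
#'   familiar-object naming benchmark).
#' @return data.frame with one row per object: `object_id`, `novelty_rate`,
#'   `n_single_concept`, `top_concept`, `identity_agreement`,
#'   `below_known_benchmark`.
#' @export
novelty_scores <- function(records, known_benchmark = 85) {
  by_obj <- split(records, records$object_id)
  out <- lapply(by_obj, function(r) {
    ia <- identity_agreement(r)
    data.frame(
      object_id = r$object_id[1],
      novelty_rate = novelty_rate(r),
      n_single_concept = ia$n_single_concept,
      top_concept = ia$top_concept,
      identity_agreement = ia$agreement,
      below_known_benchmark = is.na(ia$agreement) || ia$agreement < known_benchmark
    )
  })
  res <- do.call(rbind, out)
  res <- res[order(res$object_id), ]
  rownames(res) <- NULL
  res
}

#' Summary statistics across objects
#'
#' Sample mean, sample SD (n - 1 denominator) and range of a per-object
#' measure, plus flags for objects more than two SDs above the mean (the
#' outlier rule used to single out unusually nameable objects).
#'
#' @param values numeric vector of per-object scores (length >= 2); `NA`s
#'   are dropped.
#' @return list with `mean`, `sd`, `range` (length 2), `outliers` (indices
#'   into `values` exceeding mean + 2 SD).
#' @export
summary_stats <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(v)
  s <- sd(v)
  list(
    mean = m, sd = s, range = range(v),
    outliers = which(!is.na(values) & values > m + 2 * s)
  )
}

#' Spearman rank correlation with t-approximate p value
#'
#' Pearson correlation of average-tie ranks; `df = n - 2`; two-tailed p via
#' the t transform `t = rho * sqrt(df / (1 - rho^2))`.
#'
#' @param x,y equal-length numeric vectors (n >= 4).
#' @return list with `rho`, `df`, `p`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4) {
    stop("x and y must have equal length >= 4", call. = FALSE)
  }
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    stop("undefined: zero rank variance", call. = FALSE)
  }
  rho <- cor(rx, ry)
  df <- length(x) - 2
  p <- if (abs(rho) >= 1) 0 else 2 * pt(-abs(rho * sqrt(df / (1 - rho^2))), df)
  list(rho = rho, df = df, p = p)
}

#' Read naming records / synonym map from CSV
#'
#' `naming.csv` columns: `participant_id`, `object_id`, `seen_before`
#' (yes|no), `concepts` (semicolon-separated, possibly empty);
#' `concept_map.csv` columns: `variant`, `canonical`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_naming_csv <- function(path) {
  df <- read.csv(path)
  need <- c("participant_id", "object_id", "seen_before", "concepts")
  if (!all(need %in% names(df))) {
    stop("naming CSV must have columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  df$concepts <- as.character(df$concepts)
  df$concepts[is.na(df$concepts)] <- ""
  df
}

#' @rdname read_naming_csv
#' @export
read_concept_map_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("variant", "canonical") %in% names(df))) {
    stop("concept map CSV must have columns: variant, canonical", call. = FALSE)
  }
  df
}
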