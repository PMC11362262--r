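#' Assemble a pipeline configuration
#'
#' Collects every stage setting in one validated list. Inputs can be given
#' as in-memory objects (data frames, matrices, a `trial_design`) or file
#' paths; anything left `NULL` falls back to the synthetic preset generated
#' from `seed`.
#'
#' @param seed integer seed; mandatory, drives every stochastic stage.
#' @param design `trial_design`, path to a design CSV, or `NULL` to
#'   generate one (`n_objects`, `block_size`, `design_restarts`).
#' @param arrangements arrangement records (data.frame or CSV path), or
#'   `NULL` to simulate synthetic participants.
#' @param naming naming records (data.frame or CSV path), `NULL` to
#'   simulate, or `NA` to skip the novelty stage.
#' @param synonym_map concept map (data.frame or CSV path) or `NULL`.
#' @param pixel_sets list of `pixel_set`s, a directory of
#'   `object_<id>.png` images, `NULL` to simulate palettes, or `NA` to skip
#'   the color stage.
#' @param world a `latent_world` for the synthetic preset, or `NULL` to
#'   create one from the defaults and `seed`.
#' @param n_objects,block_size,design_restarts design-generation settings.
#' @param n_participants,sigma_place synthetic-behavior settings.
#' @param normalize_coords divide canvas distances by the canvas diagonal
#'   before averaging (default off: raw pixel distances).
#' @param canvas canvas size in pixels.
#' @param dims dimensionality grid for the stress profile.
#' @param stress_replicates SMACOF replicates per dimensionality.
#' @param final_starts random starts for the final configuration.
#' @param k_range cluster-count grid for the distortion elbow.
#' @param kmeans_restarts k-means restarts.
#' @param bootstrap_replicates stability bootstrap replicates.
#' @param fixed_k cluster count for the stability stage; `NULL` uses the
#'   distortion elbow.
#' @param embed_dim embedding dimensionality; `NULL` uses the scree elbow.
#' @param out_dir directory for stage outputs, or `NULL` to keep results
#'   in memory only.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed,
                            design = NULL, arrangements = NULL, naming = NULL,
                            synonym_map = NULL, pixel_sets = NULL, world = NULL,
                            n_objects = 30L, block_size = 16L,
                            design_restarts = 100L,
                            n_participants = 96L, sigma_place = 15,
                            normalize_coords = FALSE, canvas = c(1000, 600),
                            dims = 1:7, stress_replicates = 100L,
                            final_starts = 8L,
                            k_range = 1:15, kmeans_restarts = 50L,
                            bootstrap_replicates = 100L, fixed_k = NULL,
                            embed_dim = NULL, out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory for reproducibility", call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; file-path values are
#' passed through and resolved by [run_pipeline()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

resolve_design <- function(cfg) {
  d <- cfg$design
  if (is.null(d)) {
    minimal_blocks(cfg$n_objects, cfg$block_size,
      restarts = cfg$design_restarts, seed = child_seed(cfg$seed, 11L)
    )$design
  } else if (inherits(d, "trial_design")) {
    d
  } else {
    read_design_csv(d)
  }
}

stage_skipped <- function(x) length(x) == 1 && !is.list(x) && is.na(x)

#' Run the full norming pipeline
#'
#' Executes the analysis end-to-end: design coverage audit, per-participant
#' and group dissimilarity matrices, stress profile and kneedle
#' dimensionality selection, the final multi-start SMACOF configuration,
#' ranked pair table with quartile bins, distortion elbow and dual
#' clustering, the participant-bootstrap stability protocol, the color
#' confound check, and novelty / naming-agreement scoring. Identical
#' configuration and seed give an identical report.
#'
#' @param config a `pipeline_config` (see [pipeline_config()]) or the path
#'   to a YAML file.
#' @return object of class `run_report`: list with the selected
#'   dimensionality and cluster count, the final `mds_fit`, partitions,
#'   the stability report, color correlation, novelty summary, and the
#'   stage inputs used.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else read_pipeline_config(config)
  # validate every file-path input up front, before any compute
  for (field in c("design", "arrangements", "naming", "synonym_map", "pixel_sets")) {
    v <- cfg[[field]]
    if (is.character(v) && !file.exists(v)) {
      stop(sprintf("config validation: %s file not found: %s", field, v),
        call. = FALSE
      )
    }
  }
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  save_csv <- function(obj, name, writer = write.csv) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
    invisible(obj)
  }

  # -- design ----------------------------------------------------------
  design <- resolve_design(cfg)
  cov <- verify_coverage(design)
  if (nrow(cov$uncovered) > 0) {
    stop("stage design: design does not cover all pairs", call. = FALSE)
  }
  if (!is.null(out_dir)) write_design_csv(design, file.path(out_dir, "design.csv"))

  # -- synthetic preset (only for inputs left NULL) --------------------
  world <- cfg$world
  need_world <- is.null(cfg$arrangements) ||
    (is.null(cfg$naming)) || (is.null(cfg$pixel_sets))
  if (is.null(world) && need_world) {
    world <- make_world(
      n_objects = cfg$n_objects,
      seed = child_seed(cfg$seed, 13L)
    )
  }

  # -- matrices --------------------------------------------------------
  arr <- cfg$arrangements
  if (is.null(arr)) {
    arr <- simulate_arrangements(world, design,
      n_participants = cfg$n_participants, sigma_place = cfg$sigma_place,
      canvas = cfg$canvas, seed = child_seed(cfg$seed, 17L)
    )
  } else if (is.character(arr)) {
    arr <- read_arrangements_csv(arr)
  }
  mats <- participant_matrices(arr, design,
    normalize = cfg$normalize_coords, canvas = cfg$canvas
  )
  G <- group_matrix(mats)
  if (!is.null(out_dir)) write_matrix_csv(G, file.path(out_dir, "group_matrix.csv"))

  # -- embedding -------------------------------------------------------
  prof <- stress_profile(G,
    dims = cfg$dims, replicates = cfg$stress_replicates,
    seed = child_seed(cfg$seed, 19L)
  )
  save_csv(prof, "stress_profile.csv", function(o, f) write.csv(o, f, row.names = FALSE))
  sel_dim <- select_dimensionality(prof)
  embed_dim <- if (!is.null(cfg$embed_dim)) {
    cfg$embed_dim
  } else if (!is.na(sel_dim)) {
    sel_dim
  } else {
    stop("stage embedding: no elbow found and no embed_dim configured",
      call. = FALSE
    )
  }
  fit <- smacof_embed(G, embed_dim,
    n_starts = cfg$final_starts,
    seed = child_seed(cfg$seed, 23L)
  )
  pairs <- ranked_pair_table(fit)
  quart <- quartile_bins(pairs)
  save_csv(quart$table, "pairs_ranked.csv", function(o, f) write.csv(o, f, row.names = FALSE))

  # -- clustering ------------------------------------------------------
  elbow <- distortion_elbow(fit$coordinates,
    k_range = cfg$k_range,
    n_restarts = cfg$kmeans_restarts, seed = child_seed(cfg$seed, 29L)
  )
  fixed_k <- if (!is.null(cfg$fixed_k)) {
    cfg$fixed_k
  } else if (!is.na(elbow$k_at_elbow)) {
    elbow$k_at_elbow
  } else {
    stop("stage clustering: no distortion elbow found and no fixed_k configured",
      call. = FALSE
    )
  }
  km <- kmeans_partition(fit$coordinates, fixed_k,
    n_restarts = cfg$kmeans_restarts, seed = child_seed(cfg$seed, 31L)
  )
  wd <- cut_tree(ward_tree(as.matrix(dist(fit$coordinates))), fixed_k)
  save_csv(
    data.frame(
      object_id = seq_along(km$labels),
      kmeans_label = km$labels, ward_label = wd$labels
    ),
    "partitions.csv", function(o, f) write.csv(o, f, row.names = FALSE)
  )

  # -- stability -------------------------------------------------------
  kb <- bootstrap_partitions(mats, "kmeans",
    n_replicates = cfg$bootstrap_replicates, fixed_k = fixed_k,
    embed_dim = embed_dim, seed = child_seed(cfg$seed, 37L)
  )
  wb <- bootstrap_partitions(mats, "ward",
    n_replicates = cfg$bootstrap_replicates, fixed_k = fixed_k,
    embed_dim = embed_dim, seed = child_seed(cfg$seed, 41L)
  )
  stab <- stability_summary(kb, wb, kmeans_original = km, ward_original = wd)

  # -- color confound --------------------------------------------------
  color <- NULL
  if (!stage_skipped(cfg$pixel_sets)) {
    ps <- cfg$pixel_sets
    if (is.null(ps)) {
      ps <- simulate_pixel_sets(world, seed = child_seed(cfg$seed, 43L))
    } else if (is.character(ps)) {
      files <- file.path(ps, sprintf("object_%d.png", seq_len(design$n_objects)))
      missing_f <- files[!file.exists(files)]
      if (length(missing_f) > 0) {
        stop(
          "stage color: missing image files: ",
          paste(basename(missing_f), collapse = ", "),
          call. = FALSE
        )
      }
      ps <- lapply(seq_along(files), function(i) {
        downsample_and_mask(files[i], object_id = i)
      })
    }
    ct <- color_score_table(ps)
    key <- paste(pairs$i, pairs$j)
    ct <- ct[match(key, paste(ct$i, ct$j)), ]
    color <- color_shape_correlation(ct$mean_delta_e, pairs$distance)
    color$scores <- ct
  }

  # -- novelty ---------------------------------------------------------
  novelty <- NULL
  if (!stage_skipped(cfg$naming)) {
    nm <- cfg$naming
    if (is.null(nm)) {
      nm <- simulate_naming(world,
        n_participants = cfg$n_participants,
        seed = child_seed(cfg$seed, 47L)
      )
    } else if (is.character(nm)) {
      nm <- read_naming_csv(nm)
    }
    sm <- cfg$synonym_map
    if (is.character(sm)) sm <- read_concept_map_csv(sm)
    coded <- code_responses(nm, sm)
    scores <- novelty_scores(coded)
    save_csv(scores, "novelty_report.csv", function(o, f) write.csv(o, f, row.names = FALSE))
    novelty <- list(
      scores = scores,
      novelty = summary_stats(scores$novelty_rate),
      agreement = summary_stats(scores$identity_agreement),
      spearman = spearman_rho(scores$novelty_rate, scores$identity_agreement)
    )
  }

  report <- structure(
    list(
      seed = cfg$seed,
      design = design, coverage = cov,
      group_matrix = G, n_participants = length(mats),
      stress_profile = prof, selected_dim = sel_dim, embed_dim = embed_dim,
      fit = fit, ranked_pairs = pairs, quartiles = quart,
      distortion = elbow, selected_k = fixed_k,
      kmeans = km, ward = wd, stability = stab,
      color = color, novelty = novelty,
      world = world
    ),
    class = "run_report"
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      report_summary(report),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  report
}

#' Flat numeric summary of a pipeline run
#'
#' @param report a `run_report`.
#' @return named list of the headline quantities.
#' @export
report_summary <- function(report) {
  out <- list(
    seed = report$seed,
    n_trials = length(report$design$blocks),
    pairs_covered = report$coverage$n_pairs_covered,
    selected_dim = report$selected_dim,
    final_stress = report$fit$stress,
    selected_k = report$selected_k,
    mean_ari_kmeans = report$stability$mean_ari_kmeans,
    mean_ari_ward = report$stability$mean_ari_ward,
    mean_ari_cross = report$stability$mean_ari_cross
  )
  if (!is.null(report$color)) {
    out$color_r <- report$color$r
    out$color_p <- report$color$p
  }
  if (!is.null(report$novelty)) {
    out$novelty_rate_mean <- report$novelty$novelty$mean
    out$novelty_rate_sd <- report$novelty$novelty$sd
    out$identity_agreement_mean <- report$novelty$agreement$mean
    out$identity_agreement_sd <- report$novelty$agreement$sd
    out$spearman_novelty_agreement <- report$novelty$spearman$rho
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  s <- report_summary(x)
  cat("SpAM norming pipeline run\n")
  cat(sprintf(
    "  design: %d trials, %d / %d pairs covered\n",
    s$n_trials, s$pairs_covered, x$coverage$n_pairs_total
  ))
  cat(sprintf(
    "  embedding: selected %s dims (stress %.4g at %d dims)\n",
    ifelse(is.na(s$selected_dim), "?", s$selected_dim), s$final_stress,
    x$embed_dim
  ))
  cat(sprintf("  clustering: k = %d global categories\n", s$selected_k))
  cat(sprintf(
    "  stability (B = %d): k-means %.3f, Ward %.3f, cross %.3f\n",
    x$stability$n_replicates, s$mean_ari_kmeans, s$mean_ari_ward,
    s$mean_ari_cross
  ))
  if (!is.null(x$color)) {
    cat(sprintf(
      "  color confound: r(%d) = %.3f, p = %.3g\n",
      x$color$df, x$color$r, x$color$p
    ))
  }
  if (!is.null(x$novelty)) {
    cat(sprintf(
      "  novelty: mean rate %.2f%% (SD %.2f), mean agreement %.2f%% (SD %.2f)\n",
      s$novelty_rate_mean, s$novelty_rate_sd,
      s$identity_agreement_mean, s$identity_agreement_sd
    ))
    cat(sprintf(
      "  Spearman novelty vs agreement: rho(%d) = %.2f, p = %.3g\n",
      x$novelty$spearman$df, x$novelty$spearman$rho, x$novelty$spearman$p
    ))
  }
  invisible(x)
}
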