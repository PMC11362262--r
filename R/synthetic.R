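#' Default synthetic-world and behavior parameters
#'
#' Single documented block of generator defaults. The world mirrors the
#' study conditions: 30 objects in a 3-dimensional latent shape space with
#' 7 planted clusters of 2-6 objects, 96 participants arranging 6 trials of
#' 16 objects on a 1000 x 600 canvas. Free parameters are fixed here once:
#' cluster centers by greedy maximin in a side-100 hypercube (well-separated
#' categories), within-cluster spread `sigma_within = 4`, placement jitter
#' `sigma_place = 15` px (small relative to the canvas), per-object
#' familiarity uniform on 0.31..0.81 (matching the observed novelty-rate
#' range of roughly 19-69%), naming concentration `kappa = 3`, hybrid- and
#' no-concept response probabilities 0.08 and 0.05.
#'
#' @return named list of defaults.
#' @export
synthetic_defaults <- function() {
  list(
    n_objects = 30L, latent_dim = 3L, n_clusters = 7L,
    cluster_size_range = c(2L, 6L), center_scale = 100, sigma_within = 4,
    familiarity_range = c(0.31, 0.81), kappa = 3,
    n_participants = 96L, canvas = c(1000, 600), margin = 50,
    sigma_place = 15, p_hybrid = 0.08, p_no_concept = 0.05
  )
}

#' Generate a synthetic object world
#'
#' Plants `n_clusters` non-empty clusters (sizes within
#' `cluster_size_range`) of objects in a `latent_dim`-dimensional shape
#' space: cluster centers are placed by greedy maximin sampling in a
#' hypercube of side `center_scale` (so categories are well separated),
#' and object coordinates scatter around their center with isotropic SD
#' `sigma_within`. Each object also gets a familiarity probability, a
#' canonical name, and a color palette drawn independently of the geometry.
#'
#' @param n_objects,latent_dim,n_clusters,cluster_size_range,center_scale,
#'   sigma_within,familiarity_range,kappa see [synthetic_defaults()].
#' @param n_palette_colors colors per object (the stimuli used 3).
#' @param seed integer seed; the world is fully reproducible.
#' @return object of class `latent_world`: list with `coordinates`
#'   (n x latent_dim), `cluster_labels` (planted partition), `centers`,
#'   `familiarity`, `kappa`, `canonical_names`, `palette` (list of 3-color
#'   RGB matrices), and the generating parameters.
#' @export
make_world <- function(n_objects = 30L, latent_dim = 3L, n_clusters = 7L,
                       cluster_size_range = c(2L, 6L), center_scale = 100,
                       sigma_within = 4, familiarity_range = c(0.31, 0.81),
                       kappa = 3, n_palette_colors = 3L, seed = 1L) {
  if (n_clusters > n_objects) {
    stop("cluster count cannot exceed n_objects", call. = FALSE)
  }
  lo <- cluster_size_range[1]
  hi <- cluster_size_range[2]
  if (n_clusters * lo > n_objects || n_clusters * hi < n_objects) {
    stop("cluster_size_range cannot tile n_objects", call. = FALSE)
  }
  with_seed(seed, {
    # random composition of n_objects into n_clusters parts within [lo, hi]
    sizes <- rep(lo, n_clusters)
    while (sum(sizes) < n_objects) {
      open <- which(sizes < hi)
      pick <- if (length(open) == 1L) open else open[sample.int(length(open), 1L)]
      sizes[pick] <- sizes[pick] + 1L
    }
    labels <- sample(rep(seq_len(n_clusters), times = sizes))
    # greedy maximin centers: spread candidates, keep the farthest each time
    centers <- matrix(NA_real_, n_clusters, latent_dim)
    centers[1, ] <- runif(latent_dim, 0, center_scale)
    if (n_clusters > 1) {
      for (c in 2:n_clusters) {
        cand <- matrix(runif(64L * latent_dim, 0, center_scale), 64L, latent_dim)
        dmin <- apply(cand, 1, function(p) {
          min(sqrt(rowSums((centers[seq_len(c - 1), , drop = FALSE] -
            matrix(p, c - 1, latent_dim, byrow = TRUE))^2)))
        })
        centers[c, ] <- cand[which.max(dmin), ]
      }
    }
    coords <- centers[labels, , drop = FALSE] +
      matrix(rnorm(n_objects * latent_dim, 0, sigma_within), n_objects, latent_dim)
    fam <- runif(n_objects, familiarity_range[1], familiarity_range[2])
    palette <- lapply(seq_len(n_objects), function(o) {
      matrix(sample.int(256L, 3L * n_palette_colors, replace = TRUE) - 1L,
        ncol = 3
      )
    })
    structure(
      list(
        coordinates = coords, cluster_labels = labels, centers = centers,
        familiarity = fam, kappa = kappa,
        canonical_names = paste0("concept_", seq_len(n_objects)),
        palette = palette,
        n_objects = as.integer(n_objects), latent_dim = as.integer(latent_dim),
        n_clusters = as.integer(n_clusters), sigma_within = sigma_within,
        center_scale = center_scale, seed = seed
      ),
      class = "latent_world"
    )
  })
}

#' @export
print.latent_world <- function(x, ...) {
  cat(sprintf(
    "Synthetic world: %d objects, %d latent dims, %d planted clusters (sizes %s)\n",
    x$n_objects, x$latent_dim, x$n_clusters,
    paste(sort(as.vector(table(x$cluster_labels))), collapse = "/")
  ))
  invisible(x)
}

#' Latent pairwise distance matrix of a world
#'
#' @param world a `latent_world`.
#' @return symmetric matrix of latent Euclidean distances.
#' @export
latent_distances <- function(world) {
  as.matrix(dist(world$coordinates))
}

#' Simulate participant canvas arrangements
#'
#' Each participant, on each trial of the design, lays the trial's objects
#' out on the canvas so that inter-object distances reflect their latent
#' dissimilarities: a 2-dimensional metric MDS layout of the within-trial
#' latent distances (classical scaling refined by majorization, so the
#' noiseless layout is the deterministic best flat arrangement) is rescaled
#' into the canvas (common scale, centered, with a margin) and isotropic
#' Gaussian jitter of SD `sigma_place` pixels is added to every position
#' before clipping to the canvas. Participants arrange on a 2-D surface
#' whatever the latent dimensionality, so trials are flattened projections;
#' the covering design's cross-trial averaging is what lets the pipeline
#' recover higher-dimensional structure.
#'
#' @param world a `latent_world`.
#' @param design a `trial_design` covering the world's objects.
#' @param n_participants number of simulated participants.
#' @param sigma_place placement jitter SD in pixels (0 = noiseless).
#' @param canvas canvas width and height in pixels.
#' @param margin canvas margin in pixels kept free of object centers
#'   (before jitter).
#' @param seed integer seed.
#' @return data.frame of arrangement records: `participant_id`,
#'   `trial_index`, `object_id`, `x`, `y`.
#' @export
simulate_arrangements <- function(world, design, n_participants = 96L,
                                  sigma_place = 15, canvas = c(1000, 600),
                                  margin = 50, seed = 1L) {
  if (design$n_objects != world$n_objects) {
    stop("design does not cover the world's objects", call. = FALSE)
  }
  DL <- latent_distances(world)
  rows <- vector("list", n_participants * length(design$blocks))
  r <- 0L
  for (p in seq_len(n_participants)) {
    for (t in seq_along(design$blocks)) {
      b <- design$blocks[[t]]
      sub <- DL[b, b, drop = FALSE]
      # classical scaling init + majorization polish: deterministic,
      # recovers 2-d latent layouts exactly at zero jitter
      X0 <- suppressWarnings(stats::cmdscale(sub, k = 2))
      if (ncol(X0) < 2) X0 <- cbind(X0, matrix(0, nrow(X0), 2 - ncol(X0)))
      layout <- smacof_one(sub, X0, max_iter = 150L, tol = 1e-10)$X
      # fit into the canvas: common scale, centered
      layout <- sweep(layout, 2, colMeans(layout))
      span <- apply(layout, 2, function(v) diff(range(v)))
      span[span == 0] <- 1
      sc <- min((canvas - 2 * margin) / span)
      xy <- sweep(layout * sc, 2, canvas / 2, "+")
      xy <- xy + with_seed(
        child_seed(seed, 100003L + (p - 1L) * length(design$blocks) + t),
        matrix(rnorm(length(b) * 2, 0, sigma_place), length(b), 2)
      )
      xy[, 1] <- pmin(pmax(xy[, 1], 0), canvas[1])
      xy[, 2] <- pmin(pmax(xy[, 2], 0), canvas[2])
      r <- r + 1L
      rows[[r]] <- data.frame(
        participant_id = sprintf("p%03d", p), trial_index = t,
        object_id = b, x = xy[, 1], y = xy[, 2]
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate naming and familiarity responses
#'
#' For each participant x object: the yes/no "seen before" answer is
#' Bernoulli in the object's familiarity; the named concept is the object's
#' canonical name with probability `k_eff / (1 + k_eff)` where
#' `k_eff = kappa * familiarity / (1 - familiarity)`, and otherwise an
#' idiosyncratic participant-specific description (all distinct). So
#' `kappa = Inf` makes every participant converge on the same name,
#' `kappa = 0` makes all names distinct, and more familiar objects attract
#' more name agreement — the coupling that produces the negative
#' novelty/agreement correlation seen in human norming. Hybrid (two-concept)
#' and no-concept responses occur with fixed probabilities.
#'
#' @param world a `latent_world`.
#' @param n_participants number of simulated participants.
#' @param p_hybrid probability a response adds a second concept (hybrid, so
#'   not single-concept).
#' @param p_no_concept probability a response carries no codable concept.
#' @param seed integer seed.
#' @return data.frame of naming records: `participant_id`, `object_id`,
#'   `seen_before`, `concepts` (semicolon-separated).
#' @export
simulate_naming <- function(world, n_participants = 96L, p_hybrid = 0.08,
                            p_no_concept = 0.05, seed = 1L) {
  n <- world$n_objects
  with_seed(seed, {
    grid <- expand.grid(
      participant = seq_len(n_participants),
      object = seq_len(n)
    )
    fam <- world$familiarity[grid$object]
    seen <- rbinom(nrow(grid), 1L, fam) == 1L
    k_eff <- world$kappa * fam / pmax(1 - fam, 1e-12)
    p_canon <- if (is.infinite(world$kappa)) {
      rep(1, nrow(grid))
    } else {
      k_eff / (1 + k_eff)
    }
    canon <- runif(nrow(grid)) < p_canon
    none <- runif(nrow(grid)) < p_no_concept
    hybrid <- runif(nrow(grid)) < p_hybrid
    concepts <- character(nrow(grid))
    for (r in seq_len(nrow(grid))) {
      if (none[r]) {
        concepts[r] <- ""
        next
      }
      base <- if (canon[r]) {
        world$canonical_names[grid$object[r]]
      } else {
        sprintf("idio_%d_p%d", grid$object[r], grid$participant[r])
      }
      if (hybrid[r]) {
        other <- sample(setdiff(seq_len(n), grid$object[r]), 1L)
        base <- paste(base, world$canonical_names[other], sep = ";")
      }
      concepts[r] <- base
    }
    out <- data.frame(
      participant_id = sprintf("p%03d", grid$participant),
      object_id = grid$object,
      seen_before = ifelse(seen, "yes", "no"),
      concepts = concepts
    )
    out[order(out$participant_id, out$object_id), ]
  })
}

#' Synthetic pixel sets for the color-confound control
#'
#' Builds each object's low-resolution pixel set directly from its palette
#' (colors were assigned independently of the latent geometry), with
#' per-pixel jitter so pixels within an object vary slightly.
#'
#' @param world a `latent_world`.
#' @param n_pixels retained pixels per object.
#' @param jitter SD of per-pixel RGB jitter (8-bit units).
#' @param seed integer seed.
#' @return list of `pixel_set` objects.
#' @export
simulate_pixel_sets <- function(world, n_pixels = 60L, jitter = 6, seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(world$n_objects), function(o) {
      pal <- world$palette[[o]]
      pick <- pal[sample.int(nrow(pal), n_pixels, replace = TRUE), , drop = FALSE]
      rgb <- pick + matrix(rnorm(n_pixels * 3, 0, jitter), n_pixels, 3)
      rgb <- pmin(pmax(rgb, 0), 255)
      structure(
        list(
          object_id = o, lab = srgb_to_lab(rgb),
          alpha = rep(1, n_pixels), target = NA_integer_
        ),
        class = "pixel_set"
      )
    })
  })
}

#' Write the planted ground truth as JSON
#'
#' @param world a `latent_world`.
#' @param path output path.
#' @export
write_world_json <- function(world, path) {
  jsonlite::write_json(
    list(
      n_objects = world$n_objects, latent_dim = world$latent_dim,
      n_clusters = world$n_clusters,
      cluster_labels = world$cluster_labels,
      familiarity = world$familiarity,
      coordinates = world$coordinates
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
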