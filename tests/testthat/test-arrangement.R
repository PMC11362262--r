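test_that("within-trial pair distances are plain Euclidean pixel distances", {
  rec <- data.frame(object_id = c(1, 2), x = c(0, 3), y = c(0, 4))
  expect_equal(trial_pair_distances(rec)$distance, 5)

  same <- data.frame(object_id = c(4, 9), x = c(10, 10), y = c(7, 7))
  expect_equal(trial_pair_distances(same)$distance, 0)

  full <- data.frame(object_id = 1:16, x = runif(16, 0, 1000), y = runif(16, 0, 600))
  expect_equal(nrow(trial_pair_distances(full)), 120)

  dup <- data.frame(object_id = c(1, 1), x = c(0, 1), y = c(0, 1))
  expect_error(trial_pair_distances(dup), "duplicate")
  expect_error(trial_pair_distances(full[1, ]), "at least 2")
})

test_that("participant matrix averages repeated pairs and is complete under a covering design", {
  # two trials sharing the pair (1,2) at distances 10 and 20
  d <- structure(
    list(
      blocks = list(c(1, 2, 3), c(1, 2, 4), c(3, 4, 1)),
      n_objects = 4L, block_size = 3L, seed = NA
    ),
    class = "trial_design"
  )
  rec <- rbind(
    data.frame(
      participant_id = "p1", trial_index = 1,
      object_id = c(1, 2, 3), x = c(0, 10, 0), y = c(0, 0, 5)
    ),
    data.frame(
      participant_id = "p1", trial_index = 2,
      object_id = c(1, 2, 4), x = c(0, 20, 3), y = c(0, 0, 0)
    ),
    data.frame(
      participant_id = "p1", trial_index = 3,
      object_id = c(3, 4, 1), x = c(0, 6, 0), y = c(0, 0, 8)
    )
  )
  M <- participant_matrix(rec, d)
  expect_equal(M[1, 2], 15) # mean of 10 and 20
  expect_equal(M[1, 4], mean(c(3, 10))) # trials 2 and 3
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  expect_true(all(M[upper.tri(M)] > 0))

  # a non-covering design leaves pairs unmeasured and must fail loudly
  gappy <- structure(
    list(blocks = list(c(1, 2), c(3, 4)), n_objects = 4L, block_size = 2L, seed = NA),
    class = "trial_design"
  )
  expect_error(
    participant_matrix(rec[rec$object_id %in% c(1, 2) & rec$trial_index == 1 |
      rec$object_id %in% c(3, 4) & rec$trial_index == 3, ], gappy),
    "never co-displayed"
  )
})

test_that("the paper-scale design yields all 435 populated pairs", {
  dat <- tiny_pipeline_data(seed = 7, n_participants = 2)
  M <- dat$mats[[1]]
  expect_equal(dim(M), c(30, 30))
  expect_equal(sum(M[upper.tri(M)] > 0), 435)
})

test_that("group matrix is the per-cell mean and participant-order invariant", {
  set.seed(8)
  mk <- function() {
    A <- matrix(runif(25), 5, 5)
    A <- A + t(A)
    diag(A) <- 0
    A
  }
  ms <- list(mk(), mk(), mk())
  G <- group_matrix(ms)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(G[i, j], mean(c(ms[[1]][i, j], ms[[2]][i, j], ms[[3]][i, j])))
    }
  }
  expect_equal(group_matrix(ms[c(3, 1, 2)]), G, ignore_attr = TRUE)
  expect_equal(group_matrix(ms[1]), ms[[1]], ignore_attr = TRUE)
  expect_error(group_matrix(list(mk(), matrix(0, 4, 4))), "identical size")
})

test_that("simple two-value averaging example holds at the group level", {
  A <- matrix(c(0, 10, 10, 0), 2, 2)
  B <- matrix(c(0, 30, 30, 0), 2, 2)
  expect_equal(group_matrix(list(A, B))[1, 2], 20)
})

test_that("normalized mode divides by the canvas diagonal", {
  dat <- tiny_pipeline_data(seed = 9, n_participants = 1)
  raw <- participant_matrix(dat$arr, dat$design, normalize = FALSE)
  nrm <- participant_matrix(dat$arr, dat$design,
    normalize = TRUE, canvas = c(1000, 600)
  )
  expect_equal(nrm, raw / sqrt(1000^2 + 600^2), ignore_attr = TRUE)
  expect_true(all(nrm <= 1))
})

test_that("noiseless arrangements of a 2-d world rank-preserve latent distances within trial", {
  world <- make_world(seed = 21, latent_dim = 2)
  design <- minimal_blocks(30, 16, restarts = 5, seed = 21)$design
  arr <- simulate_arrangements(world, design,
    n_participants = 1,
    sigma_place = 0, seed = 22
  )
  DL <- latent_distances(world)
  for (t in unique(arr$trial_index)) {
    pd <- trial_pair_distances(arr[arr$trial_index == t, ])
    lat <- DL[cbind(pd$i, pd$j)]
    expect_gt(cor(pd$distance, lat, method = "spearman"), 0.999)
  }
  # a 3-d world flattened onto the canvas stays strongly but not perfectly monotone
  world3 <- make_world(seed = 23, latent_dim = 3)
  arr3 <- simulate_arrangements(world3, design,
    n_participants = 1,
    sigma_place = 0, seed = 24
  )
  DL3 <- latent_distances(world3)
  pd3 <- trial_pair_distances(arr3[arr3$trial_index == 1, ])
  expect_gt(cor(pd3$distance, DL3[cbind(pd3$i, pd3$j)], method = "spearman"), 0.7)
})

test_that("arrangement and matrix CSVs round-trip", {
  dat <- tiny_pipeline_data(seed = 10, n_participants = 2)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_arrangements_csv(dat$arr, p1)
  back <- read_arrangements_csv(p1)
  expect_equal(back$x, dat$arr$x)
  expect_equal(back$object_id, dat$arr$object_id)

  G <- group_matrix(dat$mats)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(G, p2)
  expect_equal(read_matrix_csv(p2), G, ignore_attr = TRUE)
})
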