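naming_df <- function(seen, concepts, object_id = 1) {
  data.frame(
    participant_id = sprintf("p%d", seq_along(seen)),
    object_id = object_id, seen_before = seen, concepts = concepts,
    stringsAsFactors = FALSE
  )
}

test_that("synonym collapsing marks single-concept responses correctly", {
  map <- data.frame(variant = "half circle", canonical = "semicircle")
  rec <- naming_df(
    c("yes", "no", "no", "yes"),
    c("half circle", "rainbow;prism", "", "semicircle;half circle")
  )
  coded <- code_responses(rec, map)
  expect_equal(coded$coded_concepts[[1]], "semicircle")
  expect_true(coded$single_concept[1])
  expect_equal(coded$coded_concepts[[2]], c("rainbow", "prism"))
  expect_false(coded$single_concept[2]) # hybrid
  expect_length(coded$coded_concepts[[3]], 0)
  expect_false(coded$single_concept[3]) # no concept
  # duplicates collapse to one canonical concept
  expect_equal(coded$coded_concepts[[4]], "semicircle")
  expect_true(coded$single_concept[4])
})

test_that("novelty rate is the percentage of no answers", {
  rec <- naming_df(rep(c("no", "yes"), each = 4), "")
  expect_equal(novelty_rate(rec), 50)
  expect_equal(novelty_rate(naming_df(rep("yes", 5), "")), 0)
  expect_error(novelty_rate(rec[0, ]), "no records")
})

test_that("identity agreement uses single-concept responses only", {
  rec <- code_responses(naming_df(
    rep("yes", 6),
    c("a", "a", "a", "b", "a;b", "")
  ), NULL)
  ia <- identity_agreement(rec)
  expect_equal(ia$top_concept, "a")
  expect_equal(ia$agreement, 75) # 3 of 4 single-concept responses
  expect_equal(ia$n_single_concept, 4)

  distinct <- code_responses(naming_df(rep("no", 10), paste0("c", 1:10)), NULL)
  expect_equal(identity_agreement(distinct)$agreement, 10)

  tied <- code_responses(naming_df(rep("no", 4), c("b", "b", "a", "a")), NULL)
  ia_t <- identity_agreement(tied)
  expect_true(ia_t$tie)
  expect_equal(ia_t$top_concept, "a") # lexical tie-break

  none <- code_responses(naming_df(rep("no", 3), c("", "x;y", "")), NULL)
  ia_n <- identity_agreement(none)
  expect_false(ia_n$defined)
  expect_true(is.na(ia_n$agreement))
})

test_that("summary statistics use the sample SD and flag >2SD outliers", {
  s <- summary_stats(c(10, 20, 30))
  expect_equal(s$mean, 20)
  expect_equal(s$range, c(10, 30))

  set.seed(1)
  v <- runif(40)
  expect_equal(summary_stats(v)$sd, sd_oracle(v))

  spiked <- c(rep(10, 20), 40)
  st <- summary_stats(spiked)
  expect_equal(st$outliers, 21L)
  expect_error(summary_stats(5), "at least 2")
})

test_that("Spearman correlation handles monotone vectors and ties like the rank oracle", {
  x <- c(1, 2, 3, 4, 5)
  up <- spearman_rho(x, c(2, 4, 9, 16, 30))
  expect_equal(up$rho, 1)
  expect_equal(up$df, 3)
  down <- spearman_rho(x, -x^3)
  expect_equal(down$rho, -1)

  set.seed(2)
  for (r in 1:50) {
    n <- sample(5:15, 1)
    a <- sample(1:5, n, replace = TRUE) # heavy ties
    b <- sample(1:5, n, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman_rho(a, b)$rho, spearman_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 6), 1:6), "zero rank variance")
  expect_error(spearman_rho(1:3, 1:3), "length >= 4")
})

test_that("simulated naming recovers planted familiarity and concentration limits", {
  w <- make_world(seed = 3)
  w$familiarity <- rep(0.5, 30)
  nm <- simulate_naming(w, n_participants = 96, seed = 4)
  coded <- code_responses(nm, NULL)
  rates <- novelty_scores(coded)$novelty_rate
  # exact binomial 99% band around 50% at n = 96, in percent
  band <- 100 * qbinom(c(0.005, 0.995), 96, 0.5) / 96
  expect_gt(mean(rates >= band[1] & rates <= band[2]), 0.9)

  # degenerate limits
  w_inf <- w
  w_inf$kappa <- Inf
  w_inf$familiarity <- rep(1, 30)
  nm_inf <- simulate_naming(w_inf, n_participants = 20, p_hybrid = 0, p_no_concept = 0, seed = 5)
  sc <- novelty_scores(code_responses(nm_inf, NULL))
  expect_true(all(sc$novelty_rate == 0))
  expect_true(all(sc$identity_agreement == 100))

  w0 <- w
  w0$kappa <- 0
  nm0 <- simulate_naming(w0, n_participants = 30, p_hybrid = 0, p_no_concept = 0, seed = 6)
  sc0 <- novelty_scores(code_responses(nm0, NULL))
  expect_equal(sc0$identity_agreement, 100 / sc0$n_single_concept, tolerance = 1e-9)
})

test_that("naming agreement rises with the concentration parameter", {
  med_agreement <- vapply(c(0.3, 3, 30), function(kap) {
    vals <- vapply(1:5, function(s) {
      w <- make_world(seed = 100 + s, kappa = kap)
      nm <- simulate_naming(w, n_participants = 40, seed = 200 + s)
      mean(novelty_scores(code_responses(nm, NULL))$identity_agreement, na.rm = TRUE)
    }, numeric(1))
    median(vals)
  }, numeric(1))
  expect_true(all(diff(med_agreement) > 0))
})

test_that("novelty rate and naming agreement are negatively related in synthetic worlds", {
  w <- make_world(seed = 7)
  nm <- simulate_naming(w, n_participants = 96, seed = 8)
  sc <- novelty_scores(code_responses(nm, NULL))
  res <- spearman_rho(sc$novelty_rate, sc$identity_agreement)
  expect_lt(res$rho, 0)
})

test_that("naming and concept-map CSVs load with validation", {
  nm <- simulate_naming(make_world(seed = 9), n_participants = 3, seed = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(nm, path, row.names = FALSE)
  back <- read_naming_csv(path)
  expect_equal(back$concepts, nm$concepts)

  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_naming_csv(bad), "must have columns")
  expect_error(read_concept_map_csv(bad), "variant")
})

test_that("the shipped example naming data score as documented", {
  nm <- read_naming_csv(system.file("extdata", "example_naming.csv",
    package = "spamkit"
  ))
  map <- read_concept_map_csv(system.file("extdata", "example_concept_map.csv",
    package = "spamkit"
  ))
  sc <- novelty_scores(code_responses(nm, map))
  expect_equal(sc$object_id, c(1, 2))
  # object 1: 5 of 6 said "no"; object 2: 2 of 6
  expect_equal(sc$novelty_rate, c(100 * 5 / 6, 100 * 2 / 6))
  # object 1 singles: rainbow x2, curve x2 (arch mapped) -> lexical tie
  expect_equal(sc$top_concept[1], "curve")
  expect_equal(sc$identity_agreement[1], 50)
  # object 2 singles: house x5 (hut mapped), semicircle x1
  expect_equal(sc$top_concept[2], "house")
  expect_equal(sc$identity_agreement[2], 100 * 5 / 6)
  expect_true(all(sc$below_known_benchmark == c(TRUE, TRUE)))
})
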