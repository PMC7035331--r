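test_that("envelope bounds are exact order statistics of the simulations", {
  pts <- fixture_points(40, seed = 201)
  cfg <- estimator_config(r = c(3, 6, 12, 20))
  null <- null_model_spec("csr", n_sim = 39, rank = 4, seed = 5)
  env <- run_envelope(pts, "g", null, cfg)
  for (k in seq_along(env$r)) {
    srt <- sort(env$sims[, k]) # independent full sort
    expect_identical(env$lower[k], srt[4])
    expect_identical(env$upper[k], srt[39 + 1 - 4])
  }
  # classification consistent with bounds
  expect_true(all(
    (env$observed > env$upper) == (env$classification == "above")))
  expect_true(all(env$lower <= env$upper))
})

test_that("n_sim = 19 with rank 1 uses the simulation min and max", {
  pts <- fixture_points(30, seed = 202)
  cfg <- estimator_config(r = c(5, 10))
  env <- run_envelope(pts, "g",
                      null_model_spec("csr", n_sim = 19, rank = 1,
                                      seed = 6), cfg)
  expect_equal(env$lower, apply(env$sims, 2, min))
  expect_equal(env$upper, apply(env$sims, 2, max))
})

test_that("increasing rank never widens the envelope", {
  pts <- fixture_points(35, seed = 203)
  cfg <- estimator_config(r = c(4, 8, 16))
  env2 <- run_envelope(pts, "g",
                       null_model_spec("csr", 39, rank = 2, seed = 7), cfg)
  env5 <- run_envelope(pts, "g",
                       null_model_spec("csr", 39, rank = 5, seed = 7), cfg)
  expect_true(all(env5$lower >= env2$lower))
  expect_true(all(env5$upper <= env2$upper))
})

test_that("random labelling permutes marks without touching coordinates", {
  pts <- fixture_points(50, seed = 204)
  lab <- null_random_labelling(pts, 20, seed = 8)
  expect_identical(lab$points, pts) # coordinate multiset conserved
  expect_equal(sum(lab$dead), 20)
  expect_equal(sum(null_random_labelling(pts, 0, seed = 9)$dead), 0)
  expect_equal(sum(null_random_labelling(pts, 50, seed = 10)$dead), 50)
  expect_error(null_random_labelling(pts, 51), "out of range")
})

test_that("random labelling draws all mark subsets uniformly", {
  pts <- fixture_points(6, seed = 205)
  combos <- utils::combn(6, 2)
  keys <- apply(combos, 2, paste, collapse = "-")
  seen <- table(vapply(1:10000, function(i) {
    d <- which(null_random_labelling(pts, 2, seed = 20000 + i)$dead)
    paste(d, collapse = "-")
  }, ""))
  expect_setequal(names(seen), keys)
  # each of the 15 subsets at frequency 1/15 ~ 0.0667; 5 SE ~ 0.0125
  expect_true(all(abs(seen / 10000 - 1 / 15) < 0.0125))
})

test_that("toroidal shift is an isometry and identity at zero", {
  pts <- fixture_points(12, seed = 206)
  expect_equal(toroidal_shift(pts, c(100, 100), 0, 0), pts)
  shifted <- toroidal_shift(pts, c(100, 100), 33.3, 71.7)
  tor_dist <- function(p) {
    dx <- abs(outer(p[, 1], p[, 1], "-"))
    dy <- abs(outer(p[, 2], p[, 2], "-"))
    sqrt(pmin(dx, 100 - dx)^2 + pmin(dy, 100 - dy)^2)
  }
  expect_equal(tor_dist(shifted), tor_dist(pts), tolerance = 1e-9)
})

test_that("independence null preserves counts and CSR-ness", {
  p1 <- fixture_points(60, seed = 207)
  p2 <- fixture_points(40, seed = 208)
  d <- null_independence(p1, p2, c(100, 100), "csr_both", seed = 11)
  expect_equal(nrow(d$points1), 60)
  expect_equal(nrow(d$points2), 40)
  expect_false(identical(d$points1, p1))
  d2 <- null_independence(p1, p2, c(100, 100), "toroidal_shift", seed = 12)
  expect_identical(d2$points1, p1) # pattern 1 untouched in shift mode
  # g11 of simulated pattern 1 under csr_both is ~1 on average
  cfg <- estimator_config(r = c(5, 15))
  vals <- vapply(1:60, function(i) {
    s <- null_independence(p1, p2, c(100, 100), "csr_both",
                           seed = 30000 + i)
    pcf_univariate(s$points1, c(100, 100), cfg)$value
  }, numeric(2))
  expect_true(all(abs(rowMeans(vals) - 1) < 0.08))
})

test_that("fast random-labelling path equals the generic recomputation", {
  sm <- fixture_stem_map(n = 40, n_dead = 15, seed = 209)
  cfg <- estimator_config(r = c(3, 7, 14, 21))
  null <- null_model_spec("random_labelling", n_sim = 25, rank = 2,
                          seed = 13)
  fast <- run_envelope(sm, "P", null, cfg, use_fast = TRUE)
  slow <- run_envelope(sm, "P", null, cfg, use_fast = FALSE)
  expect_equal(fast$observed, slow$observed, tolerance = 1e-12)
  expect_equal(fast$sims, slow$sims, tolerance = 1e-12)
  expect_identical(fast$classification, slow$classification)
})

test_that("the mortality test rejects degenerate plots", {
  sm_dead <- generate_stage_plot("dead", seed = 14)
  expect_error(random_mortality_test(sm_dead), "test undefined")
})

test_that("incompatible statistic/null pairs are refused", {
  pts <- fixture_points(20, seed = 210)
  expect_error(run_envelope(pts, "g", null_model_spec("random_labelling")),
               "csr")
  sm <- fixture_stem_map(n = 20, n_dead = 5, seed = 211)
  expect_error(run_envelope(sm, "P", null_model_spec("csr")),
               "random_labelling")
  expect_error(run_envelope(sm, "g12", null_model_spec("csr")),
               "independence")
})

test_that("GoF rank test: p = 1 when the observed equals the null mean", {
  pts <- fixture_points(30, seed = 212)
  cfg <- estimator_config(r = c(4, 9, 18))
  env <- run_envelope(pts, "g", null_model_spec("csr", 19, 1, seed = 15),
                      cfg)
  env$observed <- colMeans(env$sims)
  expect_equal(gof_rank_test(env)$p_value, 1)
  expect_error(gof_rank_test(env, c(60, 80)), "no defined")
})

test_that("GoF p-values are approximately uniform under the null", {
  cfg <- estimator_config(r = c(4, 10, 18))
  ps <- vapply(1:150, function(i) {
    pts <- simulate_csr(n = 40, seed = 40000 + i)
    env <- run_envelope(pts, "g",
                        null_model_spec("csr", 19, 1,
                                        seed = child_seed(50000, i)), cfg)
    gof_rank_test(env)$p_value
  }, 0)
  expect_true(all(ps >= 1 / 20 & ps <= 1))
  expect_lt(abs(mean(ps) - 0.525), 0.08) # E[p] = (1 + 1/20)/2 under null
  expect_gt(mean(ps <= 0.5), 0.3)
  expect_lt(mean(ps <= 0.5), 0.65)
})

test_that("GoF test has power against strong clustering", {
  ps <- vapply(1:25, function(i) {
    th <- simulate_thomas(0.002, 10, 2, seed = 60000 + i)
    if (nrow(th) < 20) return(NA_real_)
    env <- run_envelope(th, "g",
                        null_model_spec("csr", 99, 1,
                                        seed = child_seed(70000, i)),
                        estimator_config(r = seq(1, 10, 1)))
    gof_rank_test(env)$p_value
  }, 0)
  ps <- ps[!is.na(ps)]
  expect_gt(mean(ps <= 0.01), 0.95)
})

test_that("classification strings compress runs the way results are read", {
  env <- structure(list(
    r = 1:10,
    classification = c("above", "above", "above", "above", rep("within", 6)),
    statistic = "g"), class = "envelope_result")
  expect_match(classification_string(env), "aggregated at 1-4 m")
  env$classification <- rep("within", 10)
  expect_equal(classification_string(env), "random at all scales")
  env$classification <- rep("undefined", 10)
  expect_equal(classification_string(env), "(undefined)")
})
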