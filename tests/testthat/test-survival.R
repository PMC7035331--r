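test_that("exact binomial tails match enumeration and binom.test", {
  # hand-derived: P(X >= 19 | n = 22, p = 1/2) = 1794/2^22
  expect_equal(exact_binomial(19, 22, 0.5, "greater"), 1794 / 4194304,
               tolerance = 1e-15)
  expect_equal(exact_binomial(19, 22, 0.5, "two_sided"), 3588 / 4194304,
               tolerance = 1e-15)
  expect_equal(exact_binomial(22, 22, 0.5, "two_sided"), 2 / 4194304,
               tolerance = 1e-15)
  expect_equal(exact_binomial(11, 22, 0.5, "two_sided"), 1)
  expect_equal(exact_binomial(0, 1, 0.5, "greater"), 1)
  # full enumeration oracle across n, k and p0
  for (n in c(5, 12, 20)) {
    for (k in c(0, 2, n %/% 2, n)) {
      for (p0 in c(0.3, 0.5, 0.8)) {
        for (alt in c("two_sided", "greater", "less")) {
          expect_equal(exact_binomial(k, n, p0, alt),
                       oracle_binomial(k, n, p0, alt), tolerance = 1e-12)
        }
        # independent cross-check against the stats implementation
        alt_map <- c(two_sided = "two.sided", greater = "greater")
        expect_equal(exact_binomial(k, n, p0, "greater"),
                     stats::binom.test(k, n, p0, "greater")$p.value,
                     tolerance = 1e-12)
      }
      # minimum-likelihood two-sided rule agrees with binom.test
      expect_equal(exact_binomial(k, n, 0.3, "two_sided"),
                   stats::binom.test(k, n, 0.3)$p.value, tolerance = 1e-12)
    }
  }
  expect_error(exact_binomial(5, 3), "k <= n")
  expect_error(exact_binomial(1, 3, 0), "p0")
})

test_that("two-sided p at p0 = 0.5 is symmetric in k", {
  for (n in c(7, 16, 30)) {
    for (k in 0:n) {
      expect_equal(exact_binomial(k, n, 0.5, "two_sided"),
                   exact_binomial(n - k, n, 0.5, "two_sided"),
                   tolerance = 1e-14)
    }
  }
})

test_that("binomial median test counts strict exceedances and ties", {
  dead <- c(1, 2, 3, 4, 5) # median 3
  live <- c(3, 3, 4, 5, 6, 7) # 4 above, 2 ties
  res <- binomial_median_test(live, dead)
  expect_equal(res$k, 4)
  expect_equal(res$n, 6)
  expect_equal(res$ties, 2)
  expect_equal(res$median_dead, 3)
  expect_equal(res$p_value, exact_binomial(4, 6, 0.5, "two_sided"))
  # the small-live-sample situation: 19 of 22 live above the dead median
  live22 <- c(rep(10, 19), rep(1, 3))
  dead_many <- c(rep(3, 83), rep(5, 82)) # median 3: three live stems fail
  res2 <- binomial_median_test(live22, dead_many)
  expect_equal(res2$k, 19)
  expect_equal(round(res2$p_value, 3), 0.001)
  expect_error(binomial_median_test(numeric(0), dead), "non-empty")
})

test_that("logistic fit recovers a known survival slope", {
  set.seed(31)
  pts <- simulate_csr(n = 5000, seed = 32)
  tr <- assign_sizes(pts, 3, 1.5, seed = 33)
  sm <- apply_mortality(tr, mortality_config("size_dependent", beta0 = -1,
                                             beta_height = 0.97, seed = 34))
  fit <- fit_survival(sm, survival_design("height", grouping = FALSE))
  est <- fit$coefficients$estimate[fit$coefficients$term == "height"]
  se <- fit$coefficients$std_error[fit$coefficients$term == "height"]
  expect_lt(abs(est - 0.97), 4 * se)
  expect_equal(fit$method, "glm")
  expect_true(fit$converged)
  # z = estimate / SE by construction
  expect_equal(fit$coefficients$z,
               fit$coefficients$estimate / fit$coefficients$std_error)
})

test_that("a pure-noise covariate is rejected at roughly the nominal rate", {
  rejections <- vapply(1:100, function(i) {
    pts <- simulate_csr(n = 500, seed = 80000 + i)
    tr <- assign_sizes(pts, 3, 1.5, seed = 81000 + i)
    sm <- apply_mortality(tr, mortality_config("random",
                                               death_fraction = 0.4,
                                               seed = 82000 + i))
    fit <- fit_survival(sm, survival_design("height", grouping = FALSE))
    abs(fit$coefficients$z[2]) > 1.96
  }, TRUE)
  expect_lt(mean(rejections), 0.12) # ~5% nominal, 100 seeds
})

test_that("degenerate and ill-posed designs raise informative errors", {
  sm <- fixture_stem_map(n = 15, n_dead = 0, seed = 301)
  expect_error(fit_survival(sm, survival_design("height")),
               "degenerate response.*alive")
  sm2 <- fixture_stem_map(n = 20, n_dead = 5, seed = 302)
  # duplicate covariate via distance within a single plot: constant column
  expect_error(fit_survival(sm2, survival_design(c("height", "distance"),
                                                 grouping = FALSE)),
               "singular|collinear")
})

test_that("complete separation is flagged with finite ridge estimates", {
  md <- plot_metadata("sep", "mature", 979, 1.51)
  n <- 40
  h <- round(seq(2, 12, length.out = n), 2)
  trees <- data.frame(tree_id = sprintf("s%02d", 1:n),
                      x = round(seq(1, 99, length.out = n), 1),
                      y = rep(50, n), height = h,
                      dbh = round(1.2 * h^1.5, 1),
                      basal_diameter = NA_real_,
                      vitality = ifelse(h > 7, "healthy", "dead"))
  sm <- stem_map(trees, md)
  expect_warning(
    fit <- fit_survival(sm, survival_design("height", grouping = FALSE)),
    "separation")
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$coefficients$estimate)))
  expect_true(all(fit$coefficients$std_error > 0))
})

test_that("grouped fits use a plot random intercept when identifiable", {
  sms <- lapply(1:3, function(i) {
    pts <- simulate_csr(n = 300, seed = 90000 + i)
    tr <- assign_sizes(pts, 3, 1.5, seed = 91000 + i)
    sm <- apply_mortality(tr, mortality_config("size_dependent",
                                               beta0 = -1 + 0.4 * i,
                                               beta_height = 0.8,
                                               seed = 92000 + i))
    sm$metadata$plot_id <- paste0("plot", i)
    sm
  })
  fit <- fit_survival(sms, survival_design("height", grouping = TRUE))
  expect_equal(fit$method, "glmer")
  expect_equal(fit$n_groups, 3)
  expect_false(is.na(fit$ranef_var))
  # with a plot-constant covariate and few plots the intercept is dropped
  for (i in 1:3) sms[[i]]$metadata$distance_river <- c(0.4, 1.5, 5.7)[i]
  fit2 <- fit_survival(sms, survival_design(c("height", "distance")))
  expect_equal(fit2$method, "glm")
  expect_match(paste(fit2$notes, collapse = " "), "random intercept dropped")
})

test_that("per-plot fits mirror the staged findings and skip untestable plots", {
  pts <- simulate_thomas(0.02, 38, 2, window = c(100, 100), seed = 41,
                         n_total = 2000)
  tr <- assign_sizes(pts, 1.5, 0.8, seed = 42)
  juv <- apply_mortality(tr, mortality_config("size_dependent", beta0 = -2,
                                              beta_height = 1.5,
                                              seed = 43),
                         plot_metadata("juvenile_synth", "juvenile", 975,
                                       0.41))
  dead_plot <- generate_stage_plot("dead", seed = 44)
  tab <- per_plot_fits(list(juv, dead_plot), covariates = "height")
  expect_equal(unique(tab$plot_id), "juvenile_synth")
  h_p <- tab$p[tab$covariate == "height"]
  expect_lt(h_p, 0.001)
  expect_equal(tab$signif[tab$covariate == "height"], "***")
  skipped <- attr(tab, "skipped")
  expect_match(skipped[["dead_plot"]], "no live trees")
})

test_that("per-plot p-values are calibrated when survival ignores size", {
  ps <- vapply(1:60, function(i) {
    pts <- simulate_csr(n = 500, seed = 95000 + i)
    tr <- assign_sizes(pts, 3, 1.5, seed = 96000 + i)
    sm <- apply_mortality(tr, mortality_config("random",
                                               death_fraction = 0.35,
                                               seed = 97000 + i))
    tab <- per_plot_fits(sm, covariates = "height")
    tab$p[1]
  }, 0)
  # roughly uniform: quartile occupancy within generous Monte-Carlo bands
  expect_gt(min(ps), 0)
  expect_lt(abs(mean(ps < 0.5) - 0.5), 0.2)
  expect_lt(mean(ps < 0.05), 0.15)
})
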