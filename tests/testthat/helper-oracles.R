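# Independent brute-force reference implementations: plain double loops in
# R, written directly from the estimator definitions, never calling the
# package's computational path.  Used to pin down the production estimators
# on small fixtures.

oracle_edge_weight <- function(dx, dy, wx, wy, translation) {
  if (!translation) return(1)
  (wx * wy) / ((wx - abs(dx)) * (wy - abs(dy)))
}

# univariate ring-mode pcf: sum over ordered pairs of e_ij 1{d in ring},
# divided by lambda-hat * n * ring area
oracle_pcf <- function(pts, window, r, w = 1, translation = TRUE) {
  n <- nrow(pts)
  A <- window[1] * window[2]
  hw <- w / 2
  vapply(r, function(rk) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      dx <- pts[i, 1] - pts[j, 1]
      dy <- pts[i, 2] - pts[j, 2]
      d <- sqrt(dx^2 + dy^2)
      if (d > rk - hw && d <= rk + hw) {
        s <- s + oracle_edge_weight(dx, dy, window[1], window[2],
                                    translation)
      }
    }
    s / ((n / A) * n * pi * ((rk + hw)^2 - (rk - hw)^2))
  }, 0)
}

oracle_pcf_cross <- function(p1, p2, window, r, w = 1, translation = TRUE) {
  n1 <- nrow(p1)
  n2 <- nrow(p2)
  A <- window[1] * window[2]
  hw <- w / 2
  vapply(r, function(rk) {
    s <- 0
    for (i in seq_len(n1)) for (j in seq_len(n2)) {
      dx <- p1[i, 1] - p2[j, 1]
      dy <- p1[i, 2] - p2[j, 2]
      d <- sqrt(dx^2 + dy^2)
      if (d > rk - hw && d <= rk + hw) {
        s <- s + oracle_edge_weight(dx, dy, window[1], window[2],
                                    translation)
      }
    }
    s / ((n2 / A) * n1 * pi * ((rk + hw)^2 - (rk - hw)^2))
  }, 0)
}

# survival probability with reference = joined: weighted live neighbours
# over weighted all neighbours, self excluded; NA when the denominator is 0
oracle_survival_prob <- function(dead, live, window, r, w = 1,
                                 translation = TRUE) {
  joined <- rbind(dead, live)
  is_live <- c(rep(FALSE, nrow(dead)), rep(TRUE, nrow(live)))
  n <- nrow(joined)
  hw <- w / 2
  vapply(r, function(rk) {
    num <- den <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      dx <- joined[i, 1] - joined[j, 1]
      dy <- joined[i, 2] - joined[j, 2]
      d <- sqrt(dx^2 + dy^2)
      if (d > rk - hw && d <= rk + hw) {
        e <- oracle_edge_weight(dx, dy, window[1], window[2], translation)
        den <- den + e
        if (is_live[j]) num <- num + e
      }
    }
    if (den > 0) num / den else NA_real_
  }, 0)
}

# exact binomial p-value by full enumeration of the sample space with the
# minimum-likelihood two-sided rule
oracle_binomial <- function(k, n, p0, alternative) {
  pmf <- vapply(0:n, function(j) choose(n, j) * p0^j * (1 - p0)^(n - j), 0)
  switch(alternative,
         greater = sum(pmf[(k + 1):(n + 1)]),
         less = sum(pmf[1:(k + 1)]),
         two_sided = sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)]))
}

# deterministic small fixtures --------------------------------------------

fixture_points <- function(n, window = c(100, 100), seed = 11) {
  set.seed(seed)
  cbind(x = round(runif(n, 0, window[1]), 1),
        y = round(runif(n, 0, window[2]), 1))
}

fixture_stem_map <- function(n = 20, n_dead = 6, seed = 7,
                             window = c(100, 100)) {
  set.seed(seed)
  h <- round(c(runif(5, 0.3, 1.3), runif(n - 5, 1.4, 12)), 2)
  trees <- data.frame(
    tree_id = sprintf("t%03d", 1:n),
    x = round(runif(n, 0, window[1] - 0.1), 1),
    y = round(runif(n, 0, window[2] - 0.1), 1),
    height = h,
    dbh = ifelse(h > 1.3, round(1.2 * h^1.5, 1), NA_real_),
    basal_diameter = ifelse(h <= 1.3, round(1.5 * h, 1), NA_real_),
    vitality = c(rep("dead", n_dead),
                 sample(c("healthy", "low_stress", "high_stress", "dying"),
                        n - n_dead, replace = TRUE)),
    stringsAsFactors = FALSE)
  stem_map(trees, plot_metadata("fixture", "mature", 979, 1.51, window))
}
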