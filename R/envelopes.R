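#' Specification of a Monte-Carlo null model for simulation envelopes
#'
#' With the defaults (199 simulations, rank 5) the envelope bounds are the
#' 5th-lowest and 5th-highest simulated values at every distance, i.e. the
#' band leaves the five highest simulation values above the upper envelope
#' and the five lowest below the lower one, a pointwise two-sided level of
#' `2 * rank / (n_sim + 1) = 0.05`.
#'
#' @param kind null model: `"csr"` (complete spatial randomness conditioned
#'   on the observed count), `"independence_csr_both"` (both patterns
#'   replaced by CSR), `"independence_toroidal"` (pattern 2 toroidally
#'   shifted, keeping its internal structure) or `"random_labelling"`
#'   (marks permuted over fixed locations).
#' @param n_sim number of simulations (>= 19).
#' @param rank order of the extreme simulated values used as bounds
#'   (`1 <= rank <= n_sim / 2`).
#' @param seed optional integer seed.
#' @return an object of class `null_model_spec`.
#' @export
null_model_spec <- function(kind = c("csr", "independence_csr_both",
                                     "independence_toroidal",
                                     "random_labelling"),
                            n_sim = 199, rank = 5, seed = NULL) {
  kind <- match.arg(kind)
  if (n_sim < 19) stop("`n_sim` must be at least 19")
  if (rank < 1 || rank > n_sim / 2) {
    stop("`rank` must satisfy 1 <= rank <= n_sim / 2")
  }
  structure(list(kind = kind, n_sim = as.integer(n_sim),
                 rank = as.integer(rank), seed = seed),
            class = "null_model_spec")
}

#' CSR null draw conditioned on the observed count
#'
#' @param n number of points (>= 1).
#' @param window window side lengths in metres.
#' @param seed optional integer seed.
#' @return two-column coordinate matrix.
#' @export
null_csr <- function(n, window = c(100, 100), seed = NULL) {
  if (n < 1) stop("`n` must be at least 1")
  simulate_csr(n = n, window = window, seed = seed)
}

#' Shift a pattern by a fixed toroidal translation
#'
#' An isometry of the torus: all intra-pattern toroidal distances are
#' preserved; shifting by `(0, 0)` is the identity.
#'
#' @param points two-column coordinate matrix.
#' @param window window side lengths in metres.
#' @param dx,dy shift components in metres.
#' @return shifted coordinate matrix.
#' @export
toroidal_shift <- function(points, window = c(100, 100), dx = 0, dy = 0) {
  pts <- as_points(points)
  window <- as_window(window)
  cbind(x = (pts[, 1] + dx) %% window[1],
        y = (pts[, 2] + dy) %% window[2])
}

#' Independence null draw for a pair of patterns
#'
#' `"csr_both"` (default) replaces both patterns by CSR with their counts
#' preserved; `"toroidal_shift"` keeps both patterns' internal structure
#' and displaces pattern 2 by a uniform toroidal vector.
#'
#' @param points1,points2 two-column coordinate matrices (non-empty).
#' @param window window side lengths in metres.
#' @param mode `"csr_both"` or `"toroidal_shift"`.
#' @param seed optional integer seed.
#' @return list with elements `points1`, `points2`.
#' @export
null_independence <- function(points1, points2, window = c(100, 100),
                              mode = c("csr_both", "toroidal_shift"),
                              seed = NULL) {
  mode <- match.arg(mode)
  p1 <- as_points(points1)
  p2 <- as_points(points2)
  if (nrow(p1) == 0 || nrow(p2) == 0) stop("patterns must be non-empty")
  window <- as_window(window)
  with_seed(seed, {
    if (mode == "csr_both") {
      list(points1 = simulate_csr(n = nrow(p1), window = window),
           points2 = simulate_csr(n = nrow(p2), window = window))
    } else {
      list(points1 = p1,
           points2 = toroidal_shift(p2, window,
                                    runif(1, 0, window[1]),
                                    runif(1, 0, window[2])))
    }
  })
}

#' Random-labelling null draw over a fixed joined pattern
#'
#' Positions are untouched; exactly `n_dead` trees chosen uniformly without
#' replacement get the mark dead.
#'
#' @param points two-column coordinate matrix of the joined pattern.
#' @param n_dead number of dead marks (`0 <= n_dead <= n`).
#' @param seed optional integer seed.
#' @return list with `points` (unchanged) and logical vector `dead`.
#' @export
null_random_labelling <- function(points, n_dead, seed = NULL) {
  pts <- as_points(points)
  n <- nrow(pts)
  if (n_dead < 0 || n_dead > n) stop("`n_dead` out of range [0, n]")
  with_seed(seed, {
    dead <- rep(FALSE, n)
    if (n_dead > 0) dead[sample.int(n, n_dead)] <- TRUE
    list(points = pts, dead = dead)
  })
}

interpretation_labels <- function(statistic) {
  switch(statistic,
         g = c(above = "aggregated", within = "random", below = "regular"),
         g12 = c(above = "positive", within = "independent",
                 below = "negative"),
         P = c(above = "survival_above", within = "consistent",
               below = "survival_below"),
         c(above = "above", within = "within", below = "below"))
}

# assemble an envelope_result from observed + simulated statistic vectors
build_envelope <- function(r, observed, obs_defined, sims, sims_defined,
                           statistic, null, config = NULL) {
  n_sim <- nrow(sims)
  rank <- null$rank
  nr <- length(r)
  lower <- upper <- null_mean <- rep(NA_real_, nr)
  classification <- rep("undefined", nr)
  for (k in seq_len(nr)) {
    vals <- sims[sims_defined[, k], k]
    if (length(vals) < n_sim / 2) next   # too sparse at this r
    srt <- sort(vals)
    lower[k] <- srt[rank]
    upper[k] <- srt[length(srt) + 1 - rank]
    null_mean[k] <- mean(vals)
    if (!obs_defined[k]) next
    classification[k] <- if (observed[k] > upper[k]) "above"
      else if (observed[k] < lower[k]) "below" else "within"
  }
  labels <- interpretation_labels(statistic)
  interpretation <- ifelse(classification == "undefined", "undefined",
                           labels[classification])
  structure(list(r = r, observed = observed, lower = lower, upper = upper,
                 null_mean = null_mean, classification = classification,
                 interpretation = unname(interpretation),
                 statistic = statistic, n_sim = n_sim, rank = rank,
                 sims = sims, sims_defined = sims_defined,
                 obs_defined = obs_defined, null_kind = null$kind,
                 seed = null$seed, config = config),
            class = "envelope_result")
}

#' @exportS3Method base::print
print.envelope_result <- function(x, ...) {
  cat(sprintf(
    "rank envelope for %s(r) under %s null (%d simulations, rank %d)\n",
    x$statistic, x$null_kind, x$n_sim, x$rank))
  cat("  ", classification_string(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.envelope_result <- function(x, ...) {
  data.frame(r = x$r, observed = x$observed, lower = x$lower,
             upper = x$upper, null_mean = x$null_mean,
             classification = x$classification,
             interpretation = x$interpretation)
}

#' Rank simulation envelope for a summary statistic under a null model
#'
#' Simulates `null$n_sim` datasets under the requested null model,
#' recomputes the statistic on each, and returns the rank-`rank` lower and
#' `n_sim + 1 - rank` upper order statistics of the simulated values at
#' every distance, together with the per-distance classification of the
#' observed statistic (above / within / below, with a statistic-specific
#' interpretation label).  Distances at which a simulated statistic is
#' undefined are dropped from the ranking there; a distance where more than
#' half the simulations are undefined is reported undefined.
#'
#' @param x the data: a two-column coordinate matrix (statistic `"g"`),
#'   a list of two matrices (`"g12"`), or a [stem_map()] (any statistic;
#'   `pattern` selects the sub-pattern for `"g"`).
#' @param statistic `"g"`, `"g12"` or `"P"`.
#' @param null a [null_model_spec()] compatible with the statistic:
#'   `csr` for `"g"`, one of the independence kinds for `"g12"`,
#'   `random_labelling` for `"P"`.
#' @param config an [estimator_config()].
#' @param window window side lengths (taken from the stem map when given).
#' @param pattern sub-pattern for `"g"` on a stem map.
#' @param reference reference pattern for `"P"` (see
#'   [survival_probability()]).
#' @param use_fast use the precomputed-degree fast path for random
#'   labelling with the joined reference (identical results; set FALSE to
#'   force the generic path).
#' @return an object of class `envelope_result`.
#' @export
run_envelope <- function(x, statistic = c("g", "g12", "P"),
                         null = null_model_spec(),
                         config = estimator_config(),
                         window = c(100, 100),
                         pattern = c("all", "live", "dead"),
                         reference = "joined", use_fast = TRUE) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(null, "null_model_spec"))
  if (inherits(x, "stem_map")) window <- x$metadata$window
  window <- as_window(window)
  n_sim <- null$n_sim
  seeds <- if (is.null(null$seed)) vector("list", n_sim) else
    lapply(seq_len(n_sim), function(i) child_seed(null$seed, i))

  if (statistic == "g") {
    if (null$kind != "csr") {
      stop("statistic 'g' requires the 'csr' null model")
    }
    pts <- if (inherits(x, "stem_map")) {
      stem_points(x, match.arg(pattern))
    } else as_points(x)
    if (nrow(pts) < 2) stop("need at least 2 points")
    obs <- pcf_univariate(pts, window, config)
    vals <- vapply(seq_len(n_sim), function(i) {
      p <- null_csr(nrow(pts), window, seeds[[i]])
      pcf_univariate(p, window, config)$value
    }, numeric(length(config$r)))
    sims <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1)
    return(build_envelope(config$r, obs$value, obs$defined, sims,
                          matrix(TRUE, n_sim, length(config$r)),
                          "g", null, config))
  }

  if (statistic == "g12") {
    if (!null$kind %in% c("independence_csr_both",
                          "independence_toroidal")) {
      stop("statistic 'g12' requires an independence null model")
    }
    if (inherits(x, "stem_map")) {
      p1 <- stem_points(x, "live")
      p2 <- stem_points(x, "dead")
    } else {
      p1 <- as_points(x[[1]])
      p2 <- as_points(x[[2]])
    }
    if (nrow(p1) == 0 || nrow(p2) == 0) {
      stop("both patterns must be non-empty")
    }
    mode <- if (null$kind == "independence_toroidal") "toroidal_shift"
      else "csr_both"
    obs <- pcf_bivariate(p1, p2, window, config)
    vals <- vapply(seq_len(n_sim), function(i) {
      d <- null_independence(p1, p2, window, mode, seeds[[i]])
      pcf_bivariate(d$points1, d$points2, window, config)$value
    }, numeric(length(config$r)))
    sims <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1)
    return(build_envelope(config$r, obs$value, obs$defined, sims,
                          matrix(TRUE, n_sim, length(config$r)),
                          "g12", null, config))
  }

  # statistic == "P"
  if (null$kind != "random_labelling") {
    stop("statistic 'P' requires the 'random_labelling' null model")
  }
  if (inherits(x, "stem_map")) {
    dp <- stem_points(x, "dead")
    lp <- stem_points(x, "live")
  } else {
    dp <- as_points(x$dead)
    lp <- as_points(x$live)
  }
  n_dead <- nrow(dp)
  n_live <- nrow(lp)
  n <- n_dead + n_live
  if (n < 2) stop("the joined pattern must hold at least 2 points")
  nr <- length(config$r)

  if (identical(reference, "joined") && use_fast) {
    # positions are fixed under random labelling, so the weighted ring
    # degree of every tree is computed once; each relabelling is then a
    # mark-vector product:  P(r) = m' D(., r) / colsum D(., r)
    joined <- rbind(dp, lp)
    kk <- config_kernel(config)
    D <- cpp_ring_degree(joined[, 1], joined[, 2], window[1], window[2],
                         config$r, kk$hw, kk$code,
                         config$edge_correction == "translation")
    den <- colSums(D)
    defined <- den > 0
    m_obs <- c(rep(0, n_dead), rep(1, n_live))
    obs_val <- ifelse(defined, as.vector(crossprod(m_obs, D)) / den,
                      NA_real_)
    M <- matrix(0, n_sim, n)
    for (i in seq_len(n_sim)) {
      lab <- null_random_labelling(joined, n_dead, seeds[[i]])
      M[i, ] <- as.numeric(!lab$dead)
    }
    sims <- (M %*% D) / rep(den, each = n_sim)
    sims[, !defined] <- NA_real_
    return(build_envelope(config$r, obs_val, defined, sims,
                          matrix(defined, n_sim, nr, byrow = TRUE),
                          "P", null, config))
  }

  joined <- rbind(dp, lp)
  obs <- survival_probability(dp, lp, window, config, reference)
  sims <- matrix(NA_real_, n_sim, nr)
  sims_defined <- matrix(FALSE, n_sim, nr)
  for (i in seq_len(n_sim)) {
    lab <- null_random_labelling(joined, n_dead, seeds[[i]])
    est <- survival_probability(lab$points[lab$dead, , drop = FALSE],
                                lab$points[!lab$dead, , drop = FALSE],
                                window, config, reference)
    sims[i, ] <- est$value
    sims_defined[i, ] <- est$defined
  }
  build_envelope(config$r, obs$value, obs$defined, sims, sims_defined,
                 "P", null, config)
}

#' Test of the random mortality hypothesis
#'
#' Builds the rank envelope of the survival-probability statistic P(r)
#' under random labelling of the live/dead marks over the fixed tree
#' locations.  Distances at which the observed P(r) exits the envelope
#' indicate non-random mortality (below: depressed survival near dead
#' trees, the signature of density-dependent mortality at small scales).
#' The test is undefined on all-live or all-dead plots.
#'
#' @param x a [stem_map()] with at least one live and one dead tree.
#' @param config an [estimator_config()].
#' @param null a [null_model_spec()] of kind `random_labelling`.
#' @param reference see [survival_probability()].
#' @return an `envelope_result` for the statistic `"P"`.
#' @export
random_mortality_test <- function(x, config = estimator_config(),
                                  null = null_model_spec("random_labelling"),
                                  reference = "joined") {
  stopifnot(inherits(x, "stem_map"))
  n_live <- sum(x$trees$alive)
  n_dead <- sum(!x$trees$alive)
  if (n_live == 0 || n_dead == 0) {
    stop(sprintf(
      "random mortality test undefined: plot has %d live and %d dead trees (both classes required)",
      n_live, n_dead))
  }
  if (null$kind != "random_labelling") {
    stop("the random mortality test uses the random_labelling null")
  }
  run_envelope(x, "P", null, config, reference = reference)
}

#' Goodness-of-fit rank test over a distance interval
#'
#' Reduces the simultaneous-inference problem of reading a pointwise
#' envelope at many distances to one scalar: the summed squared deviation
#' of each statistic vector from the simulation mean over the interval.
#' The p-value is the rank of the observed deviation among the simulated
#' ones, `p = (1 + #\{u_sim >= u_obs\}) / (n_sim + 1)`; by exchangeability
#' it is uniform on `\{1/(n+1), ..., 1\}` under the null.
#'
#' @param envelope an `envelope_result` (its stored simulations are
#'   reused, keeping observed and simulated statistics exchangeable).
#' @param r_interval length-2 numeric range of distances to aggregate
#'   over; defaults to the full grid.
#' @return list with elements `p_value`, `u_obs`, `n_sim`.
#' @export
gof_rank_test <- function(envelope, r_interval = NULL) {
  stopifnot(inherits(envelope, "envelope_result"))
  r_interval <- r_interval %||% range(envelope$r)
  keep <- envelope$r >= r_interval[1] & envelope$r <= r_interval[2] &
    envelope$obs_defined & colSums(envelope$sims_defined) == envelope$n_sim
  if (!any(keep)) {
    stop("`r_interval` selects no defined distances on the r grid")
  }
  S <- envelope$sims[, keep, drop = FALSE]
  mu <- colMeans(S)
  u_obs <- sum((envelope$observed[keep] - mu)^2)
  u_sim <- colSums((t(S) - mu)^2)
  p <- (1 + sum(u_sim >= u_obs)) / (envelope$n_sim + 1)
  list(p_value = p, u_obs = u_obs, n_sim = envelope$n_sim)
}

#' Pointwise coverage of the rank envelope under a true CSR null
#'
#' Calibration experiment: repeatedly generate a CSR pattern as the
#' "observed" data, build its g(r) envelope from `n_sim` CSR simulations,
#' and record whether the observed g at a single distance lies within the
#' bounds.  With 199 simulations and rank 5 the expected coverage is 95%.
#'
#' @param n_rep number of outer replicates.
#' @param n_points points per pattern.
#' @param window window side lengths in metres.
#' @param r0 evaluation distance in metres.
#' @param ring_width ring width in metres.
#' @param n_sim,rank envelope parameters.
#' @param seed integer seed for the whole experiment.
#' @return list with `coverage_percent`, `n_rep`, `n_within`.
#' @export
envelope_coverage_experiment <- function(n_rep = 400, n_points = 50,
                                         window = c(100, 100), r0 = 5,
                                         ring_width = 1, n_sim = 199,
                                         rank = 5, seed = 1) {
  config <- estimator_config(r = r0, ring_width = ring_width)
  within <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    s <- child_seed(seed, i)
    obs_pts <- simulate_csr(n = n_points, window = window, seed = s)
    env <- run_envelope(obs_pts, "g",
                        null_model_spec("csr", n_sim = n_sim, rank = rank,
                                        seed = child_seed(s, 1)),
                        config, window)
    within[i] <- env$classification == "within"
  }
  list(coverage_percent = 100 * mean(within), n_rep = n_rep,
       n_within = sum(within))
}

#' Compress per-distance classifications into a scale-range string
#'
#' Reports maximal runs of consecutive grid distances sharing a
#' non-baseline classification, e.g. `"aggregated at 1-4 m, random
#' elsewhere"`; an all-within envelope gives `"random at all scales"` (with
#' the baseline label of the statistic), and an envelope with no defined
#' distances gives `"(undefined)"`.
#'
#' @param envelope an `envelope_result`.
#' @return a single character string.
#' @export
classification_string <- function(envelope) {
  labels <- interpretation_labels(envelope$statistic)
  cl <- envelope$classification
  ok <- cl != "undefined"
  if (!any(ok)) return("(undefined)")
  r <- envelope$r
  dev <- ok & cl != "within"
  if (!any(dev)) {
    return(paste0(labels["within"], " at all scales"))
  }
  runs <- rle(paste0(cl, ifelse(ok, "", "_na")))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  parts <- character(0)
  for (j in seq_along(runs$values)) {
    v <- runs$values[j]
    if (!v %in% c("above", "below")) next
    a <- r[starts[j]]
    b <- r[ends[j]]
    rng <- if (a == b) sprintf("%g m", a) else sprintf("%g-%g m", a, b)
    parts <- c(parts, paste0(labels[v], " at ", rng))
  }
  out <- paste(parts, collapse = ", ")
  if (any(ok & cl == "within")) {
    out <- paste0(out, ", ", labels["within"], " elsewhere")
  }
  out
}

#' Write an envelope result as CSV
#'
#' @param x an `envelope_result`.
#' @param path output path.
#' @return `x`, invisibly.
#' @export
write_envelope <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(x)
}
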