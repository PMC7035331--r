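#' Simulate complete spatial randomness (homogeneous Poisson) in a window
#'
#' Either a fixed number of points (a binomial process, used for
#' conditional-on-n null models) or a Poisson number with the given
#' intensity.
#'
#' @param n fixed number of points, or NULL to use `intensity`.
#' @param intensity points per square metre (ignored when `n` is given).
#' @param window window side lengths in metres.
#' @param seed optional integer seed; NULL continues the current RNG stream.
#' @return two-column matrix of coordinates.
#' @export
simulate_csr <- function(n = NULL, intensity = NULL, window = c(100, 100),
                         seed = NULL) {
  window <- as_window(window)
  with_seed(seed, {
    if (is.null(n)) {
      if (is.null(intensity) || intensity < 0) {
        stop("need `n` >= 0 or `intensity` >= 0")
      }
      n <- rpois(1, intensity * prod(window))
    }
    if (n < 0) stop("`n` must be non-negative")
    cbind(x = runif(n, 0, window[1]), y = runif(n, 0, window[2]))
  })
}

#' Simulate a Thomas cluster process
#'
#' Poisson(kappa * A) parents; each parent spawns a Poisson(mu) number of
#' offspring displaced by an isotropic Gaussian of standard deviation
#' `sigma`; only offspring are returned.  With `boundary = "wrap"`
#' (default) offspring are wrapped toroidally, which keeps the process
#' stationary and its intensity exactly `kappa * mu`; with `"discard"`,
#' parents are laid in a window buffered by 4 sigma and offspring falling
#' outside the window are dropped.  With `n_total` given, exactly that many
#' offspring are generated and assigned to the Poisson-drawn parents
#' uniformly at random (the cluster process conditioned on its total
#' count), always with toroidal wrapping.
#'
#' @param kappa parent intensity per square metre.
#' @param mu mean offspring per parent.
#' @param sigma dispersal standard deviation in metres (> 0).
#' @param window window side lengths in metres.
#' @param seed optional integer seed.
#' @param boundary `"wrap"` or `"discard"`.
#' @param n_total optional fixed total number of offspring.
#' @return two-column matrix of coordinates.
#' @export
simulate_thomas <- function(kappa, mu, sigma, window = c(100, 100),
                            seed = NULL, boundary = c("wrap", "discard"),
                            n_total = NULL) {
  boundary <- match.arg(boundary)
  window <- as_window(window)
  if (kappa < 0 || mu < 0) stop("`kappa` and `mu` must be non-negative")
  if (sigma <= 0) stop("`sigma` must be positive")
  with_seed(seed, {
    if (!is.null(n_total)) {
      if (n_total == 0) return(cbind(x = numeric(0), y = numeric(0)))
      n_par <- max(1L, rpois(1, kappa * prod(window)))
      px <- runif(n_par, 0, window[1])
      py <- runif(n_par, 0, window[2])
      idx <- sample.int(n_par, n_total, replace = TRUE)
      ox <- px[idx] + rnorm(n_total, 0, sigma)
      oy <- py[idx] + rnorm(n_total, 0, sigma)
      return(cbind(x = ox %% window[1], y = oy %% window[2]))
    }
    buffer <- if (boundary == "discard") 4 * sigma else 0
    lo <- -buffer
    hix <- window[1] + buffer
    hiy <- window[2] + buffer
    n_par <- rpois(1, kappa * (hix - lo) * (hiy - lo))
    if (n_par == 0) return(cbind(x = numeric(0), y = numeric(0)))
    px <- runif(n_par, lo, hix)
    py <- runif(n_par, lo, hiy)
    n_off <- rpois(n_par, mu)
    idx <- rep.int(seq_len(n_par), n_off)
    m <- length(idx)
    if (m == 0) return(cbind(x = numeric(0), y = numeric(0)))
    ox <- px[idx] + rnorm(m, 0, sigma)
    oy <- py[idx] + rnorm(m, 0, sigma)
    if (boundary == "wrap") {
      cbind(x = ox %% window[1], y = oy %% window[2])
    } else {
      keep <- ox >= 0 & ox < window[1] & oy >= 0 & oy < window[2]
      cbind(x = ox[keep], y = oy[keep])
    }
  })
}

# parent (mu, sigma) of a zero-truncated normal whose post-truncation mean
# and sd equal the targets; solved by quasi-Newton on the closed-form
# truncated moments.  Requires sd/mean < 1 (always true for tree heights).
truncnorm_params <- function(mean, sd) {
  if (sd == 0) return(c(mu = mean, sigma = 0))
  if (mean <= 0) stop("height mean must be positive")
  if (sd / mean >= 1) {
    stop("cannot match sd/mean >= 1 with a zero-truncated normal")
  }
  moments <- function(mu, sigma) {
    a <- -mu / sigma
    z <- pnorm(a, lower.tail = FALSE)
    lam <- exp(dnorm(a, log = TRUE) - log(z))
    m <- mu + sigma * lam
    v <- sigma^2 * (1 + a * lam - lam^2)
    c(m, sqrt(max(v, 0)))
  }
  obj <- function(p) {
    mm <- moments(p[1], exp(p[2]))
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# draw from a normal truncated at zero by inverse-CDF (exact, vectorised)
r_truncnorm <- function(n, mu, sigma) {
  if (sigma == 0) return(rep(mu, n))
  p0 <- pnorm(0, mu, sigma)
  qnorm(p0 + runif(n) * (1 - p0), mu, sigma)
}

#' Default allometric height-to-DBH rule
#'
#' Monotone power law giving the median DBH (cm) of a tree of height h (m);
#' multiplicative log-normal noise is added by [assign_sizes()].
#'
#' @param height heights in metres.
#' @return median DBH in cm.
#' @export
default_dbh_rule <- function(height) 1.2 * height^1.5

#' Assign heights and diameters to a point set
#'
#' Heights are drawn from a normal truncated at zero whose post-truncation
#' mean and sd equal the stated values (the parent parameters are solved
#' numerically), so the realised height distribution reproduces the stand
#' moments it is asked for.  DBH is assigned only to trees taller than
#' 1.3 m through a monotone height-to-DBH rule with multiplicative
#' log-normal noise; shorter stems receive a basal diameter by an analogous
#' rule.
#'
#' @param points two-column coordinate matrix.
#' @param height_mean,height_sd target height moments in metres
#'   (`height_sd = 0` gives every tree the mean height).
#' @param dbh_rule function mapping height (m) to median DBH (cm).
#' @param noise_sd standard deviation of the log-normal diameter noise.
#' @param seed optional integer seed.
#' @return data frame of tree records (without vitality marks).
#' @export
assign_sizes <- function(points, height_mean, height_sd,
                         dbh_rule = default_dbh_rule, noise_sd = 0.15,
                         seed = NULL) {
  if (height_sd < 0) stop("`height_sd` must be non-negative")
  pts <- as_points(points)
  n <- nrow(pts)
  with_seed(seed, {
    pars <- truncnorm_params(height_mean, height_sd)
    h <- r_truncnorm(n, pars["mu"], pars["sigma"])
    h <- round(pmax(h, 0.01), 2) # 0.01 m measurement resolution
    tall <- h > 1.3
    dbh <- rep(NA_real_, n)
    basal <- rep(NA_real_, n)
    if (any(tall)) {
      dbh[tall] <- pmax(
        dbh_rule(h[tall]) * exp(rnorm(sum(tall), 0, noise_sd)), 0.1)
    }
    if (any(!tall)) {
      basal[!tall] <- pmax(
        1.5 * h[!tall]^1.2 * exp(rnorm(sum(!tall), 0, noise_sd)), 0.1)
    }
    data.frame(tree_id = sprintf("t%04d", seq_len(n)),
               x = pts[, 1], y = pts[, 2], height = h,
               dbh = dbh, basal_diameter = basal,
               stringsAsFactors = FALSE)
  })
}

#' Mortality model configuration
#'
#' Three marking mechanisms over a fixed tree pattern: `random` (each tree
#' dies independently with `death_fraction`, or a uniformly random subset of
#' exactly `death_count` trees in fixed-count mode), `density_dependent`
#' (logit of death probability increases with the number of neighbours
#' within `radius` metres at slope `alpha`; the intercept is either given
#' or solved so the expected dead share equals `death_fraction`) and
#' `size_dependent` (logit of survival is
#' `beta0 + beta_height * height + beta_dbh * dbh + beta_distance *
#' distance`, missing DBH entering as 0).
#'
#' @param model one of `"random"`, `"density_dependent"`, `"size_dependent"`.
#' @param death_fraction target dead share in `[0, 1]`.
#' @param death_count optional exact number of deaths (fixed-count mode).
#' @param radius neighbourhood radius in metres (density-dependent).
#' @param alpha slope on the neighbour count (density-dependent).
#' @param intercept optional logit intercept (density-dependent); solved
#'   from `death_fraction` when NULL.
#' @param beta0,beta_height,beta_dbh,beta_distance survival-logit
#'   coefficients (size-dependent).
#' @param seed optional integer seed.
#' @return an object of class `mortality_config`.
#' @export
mortality_config <- function(model = c("random", "density_dependent",
                                       "size_dependent"),
                             death_fraction = 0.3, death_count = NULL,
                             radius = 2, alpha = 0.3, intercept = NULL,
                             beta0 = -1, beta_height = 0.97, beta_dbh = 0,
                             beta_distance = 0, seed = NULL) {
  model <- match.arg(model)
  if (death_fraction < 0 || death_fraction > 1) {
    stop("`death_fraction` must lie in [0, 1]")
  }
  if (model == "density_dependent" && radius <= 0) {
    stop("`radius` must be positive")
  }
  structure(list(model = model, death_fraction = death_fraction,
                 death_count = death_count, radius = radius, alpha = alpha,
                 intercept = intercept, beta0 = beta0,
                 beta_height = beta_height, beta_dbh = beta_dbh,
                 beta_distance = beta_distance, seed = seed),
            class = "mortality_config")
}

# solve the logit intercept so that mean death probability hits the target
solve_intercept <- function(eta, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  uniroot(function(a) mean(plogis(a + eta)) - target,
          lower = -50, upper = 50, tol = 1e-10)$root
}

# stage-specific cosmetic stress-class shares among live trees
stress_shares <- function(stage) {
  switch(stage,
         juvenile = c(0.10, 0.20, 0.25, 0.45),
         mature = c(0.25, 0.35, 0.30, 0.10),
         dying = c(0.00, 0.00, 0.50, 0.50),
         dead = c(0.25, 0.25, 0.25, 0.25),
         c(0.25, 0.25, 0.25, 0.25))
}

# monotone latent drought score (shorter trees more stressed) cut into the
# four live classes at the stage shares; cosmetic only, never used by
# inference
assign_stress <- function(height, shares) {
  n <- length(height)
  if (n == 0) return(character(0))
  score <- -as.numeric(scale(height)) + rnorm(n)
  if (any(!is.finite(score))) score <- rnorm(n)
  q <- rank(score, ties.method = "first") / n
  cuts <- cumsum(shares) / sum(shares)
  lab <- c("healthy", "low_stress", "high_stress", "dying")
  lab[pmax(1L, findInterval(q, c(0, cuts), left.open = TRUE,
                            rightmost.closed = TRUE))]
}

#' Apply a mortality model to a set of tree records
#'
#' Marks trees dead according to the configured mechanism and assigns the
#' surviving trees a stress class (a cosmetic monotone function of a
#' height-linked latent drought score).
#'
#' @param trees data frame of tree records as produced by [assign_sizes()].
#' @param config a [mortality_config()].
#' @param metadata optional [plot_metadata()]; a generic synthetic plot is
#'   used when omitted.
#' @return a validated [stem_map()] with vitality marks.
#' @export
apply_mortality <- function(trees, config, metadata = NULL) {
  stopifnot(inherits(config, "mortality_config"))
  if (is.null(metadata)) {
    metadata <- plot_metadata("synthetic", "juvenile", NA, 0.41)
  }
  n <- nrow(trees)
  with_seed(config$seed, {
    dead <- rep(FALSE, n)
    if (n > 0) {
      if (config$model == "random") {
        if (!is.null(config$death_count)) {
          k <- config$death_count
          if (k < 0 || k > n) stop("`death_count` out of range")
          dead[sample.int(n, k)] <- TRUE
        } else {
          dead <- runif(n) < config$death_fraction
        }
      } else {
        if (config$model == "density_dependent") {
          cnt <- cpp_neighbour_counts(trees$x, trees$y, config$radius)
          eta <- config$alpha * cnt
        } else {
          dbh0 <- ifelse(is.na(trees$dbh), 0, trees$dbh)
          dist <- metadata$distance_river %||% 0
          eta <- -(config$beta0 + config$beta_height * trees$height +
                     config$beta_dbh * dbh0 + config$beta_distance * dist)
        }
        if (!is.null(config$death_count)) {
          k <- config$death_count
          if (k < 0 || k > n) stop("`death_count` out of range")
          a <- config$intercept %||% solve_intercept(eta, k / n)
          p <- plogis(a + eta)
          dead[sample.int(n, k, prob = pmin(pmax(p, 1e-12), 1))] <- TRUE
        } else {
          a <- config$intercept %||%
            solve_intercept(eta, config$death_fraction)
          dead <- runif(n) < plogis(a + eta)
        }
      }
    }
    vit <- rep("dead", n)
    if (any(!dead)) {
      vit[!dead] <- assign_stress(trees$height[!dead],
                                  stress_shares(metadata$stage))
    }
    tr <- trees
    tr$vitality <- vit
    # snap to the 0.1 m recording resolution inside the half-open window
    w <- metadata$window
    tr$x <- pmin(pmax(round(tr$x, 1), 0), w[1] - 0.1)
    tr$y <- pmin(pmax(round(tr$y, 1), 0), w[2] - 0.1)
    stem_map(tr, metadata)
  })
}

#' Table of stage presets for the four forest plots
#'
#' Per-stage expected live/dead densities (stems per ha in a 1-ha window),
#' pooled height moments, plot metadata and clustering/mortality settings.
#' The juvenile stage uses density-dependent mortality over a strongly
#' clustered recruitment pattern; mature, dying and dead stages use random
#' mortality over mildly clustered patterns.
#'
#' @param stage one of `"juvenile"`, `"mature"`, `"dying"`, `"dead"`.
#' @return a list of preset parameters.
#' @export
stage_preset <- function(stage = c("juvenile", "mature", "dying", "dead")) {
  stage <- match.arg(stage)
  presets <- list(
    juvenile = list(elevation = 975, distance_river = 0.41,
                    live = 5316, dead = 2277, height_mean = 1.1,
                    height_sd = 0.8, kappa = 0.02, sigma = 2,
                    mortality = "density_dependent", radius = 2,
                    alpha = 0.3),
    mature = list(elevation = 979, distance_river = 1.51,
                  live = 186, dead = 30, height_mean = 9.7,
                  height_sd = 4.23, kappa = 0.003, sigma = 3,
                  mortality = "random"),
    dying = list(elevation = 984, distance_river = 5.86,
                 live = 22, dead = 165, height_mean = 2.4,
                 height_sd = 2.2, kappa = 0.003, sigma = 3,
                 mortality = "random"),
    dead = list(elevation = 984, distance_river = 5.67,
                live = 0, dead = 194, height_mean = 1.6,
                height_sd = 1.5, kappa = 0.003, sigma = 3,
                mortality = "random"))
  c(list(stage = stage), presets[[stage]])
}

#' Generate a synthetic stand for a developmental stage
#'
#' Composes the cluster-process location generator, the size generator and
#' the mortality model into one seeded stem map whose expected live/dead
#' densities and height moments match the stage preset.  In `"fixed"` mode
#' (default) the live and dead counts are hit exactly; in `"poisson"` mode
#' the total count is Poisson and deaths are independent Bernoulli draws.
#'
#' @param stage one of `"juvenile"`, `"mature"`, `"dying"`, `"dead"`.
#' @param seed integer seed (expanded into per-component child seeds).
#' @param mode `"fixed"` (exact preset counts) or `"poisson"`.
#' @param window window side lengths in metres.
#' @return a [stem_map()].
#' @export
generate_stage_plot <- function(stage, seed = 1,
                                mode = c("fixed", "poisson"),
                                window = c(100, 100)) {
  preset <- stage_preset(stage)
  mode <- match.arg(mode)
  window <- as_window(window)
  area_ha <- prod(window) / 1e4
  md <- plot_metadata(paste0(stage, "_plot"), stage, preset$elevation,
                      preset$distance_river, window)
  n_live <- preset$live * area_ha
  n_dead <- preset$dead * area_ha
  n_total <- n_live + n_dead
  mu <- n_total / (preset$kappa * prod(window))
  if (mode == "fixed") {
    pts <- simulate_thomas(preset$kappa, mu, preset$sigma, window,
                           seed = child_seed(seed, 1),
                           n_total = round(n_total))
  } else {
    pts <- simulate_thomas(preset$kappa, mu, preset$sigma, window,
                           seed = child_seed(seed, 1), boundary = "wrap")
  }
  # snap to the 0.1 m recording resolution inside the half-open window
  pts <- round(pts, 1)
  pts[, 1] <- pmin(pts[, 1], window[1] - 0.1)
  pts[, 2] <- pmin(pts[, 2], window[2] - 0.1)
  trees <- assign_sizes(pts, preset$height_mean, preset$height_sd,
                        seed = child_seed(seed, 2))
  frac <- if (n_total > 0) n_dead / n_total else 0
  cfg <- if (preset$mortality == "density_dependent") {
    mortality_config("density_dependent", death_fraction = frac,
                     death_count = if (mode == "fixed") round(n_dead),
                     radius = preset$radius, alpha = preset$alpha,
                     seed = child_seed(seed, 3))
  } else {
    mortality_config("random", death_fraction = frac,
                     death_count = if (mode == "fixed") round(n_dead),
                     seed = child_seed(seed, 3))
  }
  apply_mortality(trees, cfg, md)
}
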