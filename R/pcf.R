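#' Configuration of the second-order summary estimators
#'
#' @param r increasing vector of distances in metres (default 0.5 to 50 m
#'   in steps of 0.5 m, matching the scales over which stand analyses are
#'   usually read).
#' @param mode `"ring"` (indicator over a distance ring, default) or
#'   `"kernel"` (smoothing kernel around each r).
#' @param ring_width ring width w in metres; the ring at r is the half-open
#'   interval `(r - w/2, r + w/2]`, so distance ties at ring boundaries are
#'   resolved deterministically and adjacent rings of width equal to the
#'   grid step partition distance.
#' @param bandwidth kernel half-width h in metres (kernel mode); defaults
#'   to `ring_width / 2`.
#' @param kernel `"epanechnikov"` (default) or `"box"`; the box kernel with
#'   `bandwidth = w/2` reproduces ring mode exactly.
#' @param edge_correction `"translation"` (exact closed form on rectangles,
#'   default) or `"none"`.
#' @return an object of class `estimator_config`.
#' @export
estimator_config <- function(r = seq(0.5, 50, by = 0.5),
                             mode = c("ring", "kernel"),
                             ring_width = 1, bandwidth = NULL,
                             kernel = c("epanechnikov", "box"),
                             edge_correction = c("translation", "none")) {
  mode <- match.arg(mode)
  kernel <- match.arg(kernel)
  edge_correction <- match.arg(edge_correction)
  r <- as.numeric(r)
  if (length(r) == 0 || any(r <= 0) || is.unsorted(r, strictly = TRUE)) {
    stop("`r` must be a strictly increasing vector of positive distances")
  }
  if (ring_width <= 0) stop("`ring_width` must be positive")
  bandwidth <- bandwidth %||% (ring_width / 2)
  if (bandwidth <= 0) stop("`bandwidth` must be positive")
  structure(list(r = r, mode = mode, ring_width = ring_width,
                 bandwidth = bandwidth, kernel = kernel,
                 edge_correction = edge_correction),
            class = "estimator_config")
}

# resolve (half-width, C++ mode code) for a config
config_kernel <- function(config) {
  if (config$mode == "ring") {
    list(hw = config$ring_width / 2, code = 0L)
  } else {
    list(hw = config$bandwidth,
         code = if (config$kernel == "epanechnikov") 1L else 2L)
  }
}

check_window_r <- function(config, window) {
  if (max(config$r) > min(window) / 2) {
    stop(sprintf(
      "r_max = %g m too large for the window: must be at most half the shorter side (%g m)",
      max(config$r), min(window) / 2))
  }
}

function_estimate <- function(statistic, r, value, defined, n1,
                              n2 = NA_integer_, config = NULL) {
  structure(list(statistic = statistic, r = r, value = value,
                 defined = defined, n1 = n1, n2 = n2, config = config),
            class = "function_estimate")
}

#' @exportS3Method base::print
print.function_estimate <- function(x, ...) {
  cat(sprintf("%s(r) estimate on %d distances (r in [%g, %g] m), n1 = %d%s\n",
              x$statistic, length(x$r), min(x$r), max(x$r), x$n1,
              if (!is.na(x$n2)) sprintf(", n2 = %d", x$n2) else ""))
  invisible(x)
}

#' @export
as.data.frame.function_estimate <- function(x, ...) {
  data.frame(r = x$r, statistic = x$statistic, value = x$value,
             n1 = x$n1, n2 = x$n2, defined = x$defined)
}

#' Univariate pair correlation function
#'
#' Ring-mode estimator
#' \deqn{\hat g(r) = \frac{\sum_{i \ne j} e_{ij}\, 1\{d_{ij} \in (r-w/2,\, r+w/2]\}}
#'                        {\hat\lambda \, n \, a(r)}}
#' with ring area \eqn{a(r) = \pi[(r+w/2)^2 - (r-w/2)^2]}, intensity
#' \eqn{\hat\lambda = n/A} and translation edge-correction weights
#' \eqn{e_{ij} = A / ((W_x - |\Delta x_{ij}|)(W_y - |\Delta y_{ij}|))}.
#' Kernel mode replaces the indicator with an Epanechnikov (or box) kernel
#' and the ring area with \eqn{2\pi r}.  Under complete spatial randomness
#' the expectation is approximately 1 at every r.
#'
#' @param points two-column coordinate matrix (>= 2 points).
#' @param window window side lengths in metres.
#' @param config an [estimator_config()].
#' @return a `function_estimate` with statistic label `"g"`.
#' @export
pcf_univariate <- function(points, window = c(100, 100),
                           config = estimator_config()) {
  pts <- as_points(points)
  window <- as_window(window)
  check_window_r(config, window)
  n <- nrow(pts)
  if (n < 2) stop("need at least 2 points to estimate g(r)")
  kk <- config_kernel(config)
  sums <- cpp_pair_sums(pts[, 1], pts[, 2], window[1], window[2],
                        config$r, kk$hw, kk$code,
                        config$edge_correction == "translation")
  A <- prod(window)
  denom <- if (config$mode == "ring") {
    (n / A) * n * pi * ((config$r + kk$hw)^2 - (config$r - kk$hw)^2)
  } else {
    (n / A) * n * 2 * pi * config$r
  }
  function_estimate("g", config$r, sums / denom,
                    defined = rep(TRUE, length(config$r)),
                    n1 = n, config = config)
}

#' Bivariate (cross-type) pair correlation function
#'
#' Same estimator over ordered pairs with i from pattern 1 and j from
#' pattern 2, normalised by the pattern-2 intensity and the pattern-1
#' count; approximately 1 at all r under independence of the two patterns.
#'
#' @param points1,points2 two-column coordinate matrices (non-empty).
#' @param window window side lengths in metres.
#' @param config an [estimator_config()].
#' @return a `function_estimate` with statistic label `"g12"`.
#' @export
pcf_bivariate <- function(points1, points2, window = c(100, 100),
                          config = estimator_config()) {
  p1 <- as_points(points1)
  p2 <- as_points(points2)
  window <- as_window(window)
  check_window_r(config, window)
  if (nrow(p1) == 0 || nrow(p2) == 0) {
    stop("both patterns must be non-empty to estimate g12(r)")
  }
  kk <- config_kernel(config)
  sums <- cpp_cross_sums(p1[, 1], p1[, 2], p2[, 1], p2[, 2],
                         window[1], window[2], config$r, kk$hw, kk$code,
                         config$edge_correction == "translation",
                         integer(0), integer(0))
  A <- prod(window)
  n1 <- nrow(p1)
  n2 <- nrow(p2)
  denom <- if (config$mode == "ring") {
    (n2 / A) * n1 * pi * ((config$r + kk$hw)^2 - (config$r - kk$hw)^2)
  } else {
    (n2 / A) * n1 * 2 * pi * config$r
  }
  function_estimate("g12", config$r, sums / denom,
                    defined = rep(TRUE, length(config$r)),
                    n1 = n1, n2 = n2, config = config)
}

#' Survival probability at distance r
#'
#' The mark-connection-type statistic giving the probability that a tree
#' found at distance r from a reference tree is alive:
#' \deqn{\hat P(r) = \frac{\sum_{i \in \mathrm{ref}} \#\{\text{live neighbours
#' of } i \text{ in the ring at } r\}}{\sum_{i \in \mathrm{ref}}
#' \#\{\text{all neighbours of } i \text{ in the ring at } r\}}}
#' with each tree excluded from its own neighbourhood and neighbours
#' weighted by the configured edge correction.  With the default reference
#' (`"joined"`, all trees) this is algebraically identical to
#' \eqn{\lambda_2 \hat g_{a2}(r) / (\lambda_a \hat g_{aa}(r))} where a is
#' the joined pattern and 2 the live one.  Under random mortality the
#' statistic is flat at the overall live share at every r.  Values are in
#' `[0, 1]`; distances where the denominator is zero are flagged undefined
#' (never reported as 0).
#'
#' @param dead_points,live_points two-column coordinate matrices; the
#'   joined pattern must hold at least 2 points.
#' @param window window side lengths in metres.
#' @param config an [estimator_config()].
#' @param reference reference pattern: `"joined"` (default), `"live"` or
#'   `"dead"`.
#' @return a `function_estimate` with statistic label `"P"` (`n1` dead
#'   count, `n2` live count).
#' @export
survival_probability <- function(dead_points, live_points,
                                 window = c(100, 100),
                                 config = estimator_config(),
                                 reference = c("joined", "live", "dead")) {
  reference <- match.arg(reference)
  dp <- as_points(dead_points)
  lp <- as_points(live_points)
  window <- as_window(window)
  check_window_r(config, window)
  n_dead <- nrow(dp)
  n_live <- nrow(lp)
  if (n_dead + n_live < 2) {
    stop("the joined pattern must hold at least 2 points")
  }
  joined <- rbind(dp, lp)
  alive <- c(rep(FALSE, n_dead), rep(TRUE, n_live))
  ids <- seq_len(n_dead + n_live)
  ref_idx <- switch(reference, joined = ids, live = ids[alive],
                    dead = ids[!alive])
  if (length(ref_idx) == 0) stop("reference pattern is empty")
  kk <- config_kernel(config)
  translation <- config$edge_correction == "translation"
  num <- cpp_cross_sums(joined[ref_idx, 1], joined[ref_idx, 2],
                        joined[alive, 1], joined[alive, 2],
                        window[1], window[2], config$r, kk$hw, kk$code,
                        translation, ref_idx, ids[alive])
  den <- cpp_cross_sums(joined[ref_idx, 1], joined[ref_idx, 2],
                        joined[, 1], joined[, 2],
                        window[1], window[2], config$r, kk$hw, kk$code,
                        translation, ref_idx, ids)
  defined <- den > 0
  value <- ifelse(defined, num / den, NA_real_)
  function_estimate("P", config$r, value, defined,
                    n1 = n_dead, n2 = n_live, config = config)
}
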