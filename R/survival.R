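#' Design of a tree-level survival model
#'
#' @param covariates subset of `"height"` (m), `"dbh"` (cm),
#'   `"distance"` (km from the river; constant within a plot).
#' @param grouping add a plot-level random intercept when possible.
#' @param standardize centre and scale covariates before fitting.
#' @return an object of class `survival_design`.
#' @export
survival_design <- function(covariates = c("height", "distance"),
                            grouping = TRUE, standardize = FALSE) {
  covariates <- match.arg(covariates, c("height", "dbh", "distance"),
                          several.ok = TRUE)
  structure(list(covariates = covariates, grouping = grouping,
                 standardize = standardize), class = "survival_design")
}

# assemble the tree-level modelling frame from one or more stem maps
survival_frame <- function(stem_maps) {
  if (inherits(stem_maps, "stem_map")) stem_maps <- list(stem_maps)
  do.call(rbind, lapply(stem_maps, function(sm) {
    tr <- sm$trees
    data.frame(plot_id = sm$metadata$plot_id, tree_id = tr$tree_id,
               alive = as.integer(tr$alive), height = tr$height,
               dbh = tr$dbh, distance = sm$metadata$distance_river,
               stringsAsFactors = FALSE)
  }))
}

# minimal ridge-penalised IRLS fallback for separated logistic fits
ridge_logit <- function(X, y, lambda = 1e-3, maxit = 200, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  pen <- diag(lambda, ncol(X))
  pen[1, 1] <- 0 # intercept unpenalised
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X, X * w) + pen
    beta_new <- solve(H, crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  se <- sqrt(diag(solve(H)))
  list(coef = drop(beta), se = se)
}

#' Logistic survival model over one or more plots
#'
#' Fits individual survival (live = 1, dead = 0) on the requested
#' covariates by maximum-likelihood logistic regression (iteratively
#' reweighted least squares).  When grouping is requested, at least two
#' plots are present and the design is identifiable, a plot-level random
#' intercept is added (Laplace approximation via `lme4::glmer`); when a
#' plot-constant covariate (distance) is included with four or fewer
#' plots, the random intercept is dropped with a note, since so few groups
#' cannot identify both the group effect and a group-level slope.  Trees
#' with missing DBH are excluded from models that use DBH.  Complete
#' separation is detected and handled by a ridge-penalised refit, flagged
#' with a warning.
#'
#' @param stem_maps a [stem_map()] or list of them.
#' @param design a [survival_design()].
#' @return an object of class `survival_fit`: coefficient table
#'   (`term`, `estimate`, `std_error`, `z`, `p`), counts, method, notes.
#' @export
fit_survival <- function(stem_maps, design = survival_design()) {
  stopifnot(inherits(design, "survival_design"))
  df <- survival_frame(stem_maps)
  covs <- design$covariates
  if ("dbh" %in% covs) {
    n_drop <- sum(is.na(df$dbh))
    df <- df[!is.na(df$dbh), , drop = FALSE]
  } else n_drop <- 0L
  for (cv in covs) {
    if (all(is.na(df[[cv]]))) stop("covariate entirely missing: ", cv)
  }
  if (length(unique(df$alive)) < 2) {
    stop("degenerate response: all trees are ",
         if (all(df$alive == 1)) "alive" else "dead")
  }
  if (design$standardize) {
    for (cv in covs) df[[cv]] <- as.numeric(scale(df[[cv]]))
  }
  X <- stats::model.matrix(as.formula(paste("~", paste(covs, collapse = "+"))),
                           df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design: collinear column(s) ",
         paste(bad, collapse = ", "))
  }
  n_plots <- length(unique(df$plot_id))
  notes <- character(0)
  if (n_drop > 0) {
    notes <- c(notes, sprintf(
      "%d trees without DBH excluded from the DBH model", n_drop))
  }
  use_ranef <- design$grouping && n_plots >= 2 &&
    !("distance" %in% covs && n_plots <= 4)
  if (design$grouping && !use_ranef && n_plots >= 2) {
    notes <- c(notes, paste(
      "plot random intercept dropped: a plot-constant covariate with",
      n_plots, "plots is not identifiable alongside a group effect"))
  }

  fml <- paste("alive ~", paste(covs, collapse = " + "))
  separation <- FALSE
  ranef_var <- NA_real_
  converged <- TRUE
  if (use_ranef) {
    fit <- lme4::glmer(as.formula(paste(fml, "+ (1 | plot_id)")),
                       data = df, family = binomial())
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                        std_error = sm[, 2], z = sm[, 3], p = sm[, 4],
                        stringsAsFactors = FALSE)
    ranef_var <- as.numeric(lme4::VarCorr(fit)$plot_id[1])
    converged <- length(fit@optinfo$conv$lme4) == 0
    method <- "glmer"
  } else {
    warn_sep <- FALSE
    fit <- withCallingHandlers(
      glm(as.formula(fml), data = df, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          warn_sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (warn_sep || any(abs(coef(fit)) > 15, na.rm = TRUE)) {
      separation <- TRUE
      warning("possible complete separation; reporting ridge-penalised estimates")
      rf <- ridge_logit(X, df$alive)
      est <- rf$coef
      se <- rf$se
      method <- "glm+ridge"
    } else {
      est <- coef(fit)
      se <- sqrt(diag(vcov(fit)))
      converged <- fit$converged
      method <- "glm"
    }
    z <- est / se
    coefs <- data.frame(term = names(est) %||% colnames(X), estimate = est,
                        std_error = se, z = z,
                        p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  }
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs, n = nrow(df), n_groups = n_plots,
                 method = method, converged = converged,
                 ranef_var = ranef_var, separation = separation,
                 notes = notes, design = design),
            class = "survival_fit")
}

#' @exportS3Method base::print
print.survival_fit <- function(x, ...) {
  cat(sprintf("logistic survival fit (%s): n = %d trees, %d plot(s)\n",
              x$method, x$n, x$n_groups))
  printed <- x$coefficients
  printed$signif <- significance_code(printed$p)
  print(printed, row.names = FALSE, digits = 4)
  if (!is.na(x$ranef_var)) {
    cat(sprintf("  plot random-intercept variance: %.4g\n", x$ranef_var))
  }
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

#' Significance codes used in the per-plot tables
#'
#' `***` p < 0.001; `**` 0.001 <= p < 0.01; `*` 0.01 <= p < 0.05; `NS`
#' otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of codes.
#' @export
significance_code <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS"))))
}

#' Per-plot logistic fits of survival on size
#'
#' One logistic fit per plot with the requested size covariates (jointly
#' by default, or one model per covariate), reporting per-covariate Wald
#' p-values with significance codes.  Plots failing the preconditions (no
#' live or no dead trees, or no measured covariate values) are skipped
#' with a logged reason.
#'
#' @param stem_maps list of [stem_map()] objects.
#' @param covariates size covariates, default DBH and height.
#' @param joint fit the covariates jointly (default) or separately.
#' @return data frame with one row per plot x covariate (`plot_id`,
#'   `covariate`, `estimate`, `p`, `signif`); skipped plots are recorded
#'   in the `"skipped"` attribute as named reasons.
#' @export
per_plot_fits <- function(stem_maps, covariates = c("dbh", "height"),
                          joint = TRUE) {
  if (inherits(stem_maps, "stem_map")) stem_maps <- list(stem_maps)
  rows <- list()
  skipped <- character(0)
  for (sm in stem_maps) {
    pid <- sm$metadata$plot_id
    tr <- sm$trees
    if (sum(tr$alive) == 0 || sum(!tr$alive) == 0) {
      skipped[pid] <- sprintf("no %s trees: survival model untestable",
                              if (sum(tr$alive) == 0) "live" else "dead")
      next
    }
    fit_one <- function(covs) {
      fit <- try(suppressWarnings(
        fit_survival(sm, survival_design(covs, grouping = FALSE))),
        silent = TRUE)
      if (inherits(fit, "try-error")) return(NULL)
      fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    }
    tab <- if (joint) fit_one(covariates) else
      do.call(rbind, lapply(covariates, fit_one))
    if (is.null(tab)) {
      skipped[pid] <- "model could not be fitted"
      next
    }
    rows[[pid]] <- data.frame(plot_id = pid, covariate = tab$term,
                              estimate = tab$estimate, p = tab$p,
                              signif = significance_code(tab$p),
                              stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(plot_id = character(0), covariate = character(0),
               estimate = numeric(0), p = numeric(0),
               signif = character(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Exact binomial tail probability
#'
#' Direct summation of the binomial probability mass function.  The
#' two-sided p-value doubles the smaller tail when `p0 = 0.5` (where this
#' coincides with the minimum-likelihood rule by symmetry) and sums all
#' outcomes no more likely than the observed one when `p0 != 0.5`.
#'
#' @param k number of successes (`0 <= k <= n`).
#' @param n number of trials.
#' @param p0 null success probability in (0, 1).
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @return the exact p-value.
#' @export
exact_binomial <- function(k, n, p0 = 0.5,
                           alternative = c("two_sided", "greater",
                                           "less")) {
  alternative <- match.arg(alternative)
  if (n < 0 || k < 0 || k > n || k != round(k) || n != round(n)) {
    stop("need integers 0 <= k <= n")
  }
  if (p0 <= 0 || p0 >= 1) stop("`p0` must lie strictly in (0, 1)")
  pmf <- dbinom(0:n, n, p0)
  upper <- sum(pmf[(k + 1):(n + 1)])
  lower <- sum(pmf[1:(k + 1)])
  switch(alternative,
         greater = upper,
         less = lower,
         two_sided = {
           if (p0 == 0.5) {
             min(1, 2 * min(lower, upper))
           } else {
             sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
           }
         })
}

#' Binomial median test of live versus dead tree sizes
#'
#' Counts how many live-tree values strictly exceed the median of the
#' dead-tree values (ties with the median are not successes and are
#' reported) and tests that count against Binomial(n_live, 1/2) with the
#' exact two-sided binomial test.  Designed for the situation where one
#' mark class is too small for a regression but can be compared against
#' the other class's median.
#'
#' @param values_live,values_dead non-empty numeric vectors (e.g. DBH or
#'   height of live and dead trees).
#' @return an object of class `binomial_test_result` with elements `k`,
#'   `n`, `ties`, `p0`, `alternative`, `p_value`, `median_dead`.
#' @export
binomial_median_test <- function(values_live, values_dead) {
  values_live <- values_live[!is.na(values_live)]
  values_dead <- values_dead[!is.na(values_dead)]
  if (length(values_live) == 0 || length(values_dead) == 0) {
    stop("both value lists must be non-empty")
  }
  med <- median(values_dead)
  k <- sum(values_live > med)
  n <- length(values_live)
  structure(list(k = k, n = n, ties = sum(values_live == med), p0 = 0.5,
                 alternative = "two_sided",
                 p_value = exact_binomial(k, n, 0.5, "two_sided"),
                 median_dead = med),
            class = "binomial_test_result")
}

#' @exportS3Method base::print
print.binomial_test_result <- function(x, ...) {
  cat(sprintf(
    "binomial median test: %d of %d live values above the dead median (%g)%s\n",
    x$k, x$n, x$median_dead,
    if (x$ties) sprintf(" [%d tie(s)]", x$ties) else ""))
  cat(sprintf("  exact two-sided p = %.4g\n", x$p_value))
  invisible(x)
}
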