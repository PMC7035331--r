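#' Build a run configuration for the full analysis pipeline
#'
#' @param plots list of plot sources; each element is either
#'   `list(stage = "<stage>")` for a synthetic stand or
#'   `list(stem_map = "<csv>", metadata = "<csv>")` for field data.
#' @param analyses analyses to run, any of `"summary"`, `"univariate"`,
#'   `"association"`, `"mortality_test"`, `"survival"`, `"binomial"`.
#' @param estimator an [estimator_config()] (or list of its arguments).
#' @param null a [null_model_spec()] (or list of its arguments; the
#'   `seed` field is always derived from the global seed).
#' @param seed global integer seed; expanded per component.
#' @param out_dir output directory for the CSV/JSON bundle.
#' @param dbh_bins optional DBH breakpoints for the stand summaries.
#' @return an object of class `run_config`.
#' @export
run_config <- function(plots, analyses = c("summary", "univariate",
                                           "association", "mortality_test",
                                           "survival", "binomial"),
                       estimator = estimator_config(),
                       null = null_model_spec(), seed = 1,
                       out_dir = tempfile("standspat_run_"),
                       dbh_bins = NULL) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  if (is.list(estimator) && !inherits(estimator, "estimator_config")) {
    estimator <- do.call(estimator_config, estimator)
  }
  if (is.list(null) && !inherits(null, "null_model_spec")) {
    null <- do.call(null_model_spec, null)
  }
  if (length(plots) == 0) stop("at least one plot is required")
  structure(list(plots = plots, analyses = analyses, estimator = estimator,
                 null = null, seed = seed, out_dir = out_dir,
                 dbh_bins = dbh_bins),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file holds the fields of [run_config()]; `estimator` and `null` are
#' given as parameter maps.  A configuration written with
#' [write_run_config()] reads back equal.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(plots = y$plots,
             analyses = y$analyses %||% c("summary", "univariate",
                                          "association", "mortality_test",
                                          "survival", "binomial"),
             estimator = y$estimator %||% estimator_config(),
             null = y$null %||% null_model_spec(),
             seed = y$seed %||% 1,
             out_dir = y$out_dir %||% tempfile("standspat_run_"),
             dbh_bins = y$dbh_bins)
}

#' Write a run configuration to YAML
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return `config`, invisibly.
#' @export
write_run_config <- function(config, path) {
  y <- list(plots = config$plots, analyses = config$analyses,
            estimator = list(r = config$estimator$r,
                             mode = config$estimator$mode,
                             ring_width = config$estimator$ring_width,
                             bandwidth = config$estimator$bandwidth,
                             kernel = config$estimator$kernel,
                             edge_correction = config$estimator$edge_correction),
            null = list(kind = config$null$kind,
                        n_sim = config$null$n_sim, rank = config$null$rank),
            seed = config$seed, out_dir = config$out_dir,
            dbh_bins = config$dbh_bins)
  yaml::write_yaml(y, path)
  invisible(config)
}

log_line <- function(log, stage, msg) {
  line <- sprintf("[%s] %s: %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
  message(line)
  c(log, line)
}

#' Run the full analysis pipeline over one or more plots
#'
#' For every plot: stand summary, univariate g(r) envelopes of the live
#' and the dead pattern under CSR, the live-dead association envelope
#' under the independence null, and the random-mortality test; across
#' plots: a pooled logistic survival table (height + distance, with dying
#' and dead stage plots merged into one distance stratum) and per-plot
#' size fits; per plot with both mark classes, binomial median tests on
#' DBH and height.  Analyses whose preconditions fail are skipped with a
#' logged reason (e.g. the mortality test on an all-dead plot).  All
#' results are written as CSV plus a machine-readable JSON manifest, and
#' the run is fully determined by the global seed.
#'
#' @param config a [run_config()] (or YAML path).
#' @return (invisibly) the report bundle: a list with `summaries`,
#'   `envelopes`, `mortality`, `survival`, `per_plot`, `binomial`,
#'   `skipped`, `manifest`, `log`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  log <- character(0)
  skipped <- list()
  seed <- config$seed

  # ---- load or generate plots -------------------------------------------
  stem_maps <- list()
  for (i in seq_along(config$plots)) {
    p <- config$plots[[i]]
    sm <- if (!is.null(p$stage)) {
      generate_stage_plot(p$stage, seed = child_seed(seed, 100 + i))
    } else {
      read_stem_map(p$stem_map, p$metadata)
    }
    stem_maps[[sm$metadata$plot_id]] <- sm
    log <- log_line(log, "load",
                    sprintf("plot '%s': %d trees (%d live, %d dead)",
                            sm$metadata$plot_id, n_trees(sm),
                            sum(sm$trees$alive), sum(!sm$trees$alive)))
  }

  est <- config$estimator
  summaries <- list()
  envelopes <- list()
  mortality <- list()
  binomial <- list()

  for (i in seq_along(stem_maps)) {
    sm <- stem_maps[[i]]
    pid <- sm$metadata$plot_id
    if ("summary" %in% config$analyses) {
      s <- summarize_stand(sm, config$dbh_bins)
      summaries[[pid]] <- s
      write_stand_summary(s, file.path(out_dir,
                                       paste0(pid, "_summary.csv")))
      log <- log_line(log, "summary", pid)
    }
    if ("univariate" %in% config$analyses) {
      for (pat in c("live", "dead")) {
        pts <- stem_points(sm, pat)
        key <- paste0(pid, "_g_", pat)
        if (nrow(pts) < 2) {
          skipped[[key]] <- sprintf(
            "univariate g(r) of %s trees skipped: fewer than 2 points", pat)
          log <- log_line(log, "skip", skipped[[key]])
          next
        }
        env <- run_envelope(pts, "g",
                            null_model_spec("csr", config$null$n_sim,
                                            config$null$rank,
                                            child_seed(seed, 200 + 10 * i +
                                                         (pat == "dead"))),
                            est, sm$metadata$window)
        envelopes[[key]] <- env
        write_envelope(env, file.path(out_dir, paste0(key, ".csv")))
        log <- log_line(log, "envelope",
                        paste0(key, ": ", classification_string(env)))
      }
    }
    if ("association" %in% config$analyses) {
      key <- paste0(pid, "_g12")
      if (sum(sm$trees$alive) == 0 || sum(!sm$trees$alive) == 0) {
        skipped[[key]] <-
          "live-dead association skipped: one pattern is empty"
        log <- log_line(log, "skip", skipped[[key]])
      } else {
        env <- run_envelope(sm, "g12",
                            null_model_spec("independence_csr_both",
                                            config$null$n_sim,
                                            config$null$rank,
                                            child_seed(seed, 300 + i)),
                            est)
        envelopes[[key]] <- env
        write_envelope(env, file.path(out_dir, paste0(key, ".csv")))
        log <- log_line(log, "envelope",
                        paste0(key, ": ", classification_string(env)))
      }
    }
    if ("mortality_test" %in% config$analyses) {
      key <- paste0(pid, "_mortality")
      if (sum(sm$trees$alive) == 0 || sum(!sm$trees$alive) == 0) {
        skipped[[key]] <- sprintf(
          "random mortality test on '%s' skipped: test undefined without both live and dead trees",
          pid)
        log <- log_line(log, "skip", skipped[[key]])
      } else {
        env <- random_mortality_test(
          sm, est, null_model_spec("random_labelling", config$null$n_sim,
                                   config$null$rank,
                                   child_seed(seed, 400 + i)))
        mortality[[pid]] <- env
        write_envelope(env, file.path(out_dir, paste0(key, ".csv")))
        log <- log_line(log, "mortality-test",
                        paste0(pid, ": ", classification_string(env)))
      }
    }
    if ("binomial" %in% config$analyses &&
          sum(sm$trees$alive) > 0 && sum(!sm$trees$alive) > 0) {
      tr <- sm$trees
      tests <- list()
      for (var in c("dbh", "height")) {
        vl <- tr[[var]][tr$alive]
        vd <- tr[[var]][!tr$alive]
        if (sum(!is.na(vl)) > 0 && sum(!is.na(vd)) > 0) {
          tests[[var]] <- binomial_median_test(vl, vd)
        }
      }
      if (length(tests)) {
        binomial[[pid]] <- tests
        btab <- do.call(rbind, lapply(names(tests), function(v) {
          t <- tests[[v]]
          data.frame(variable = v, k = t$k, n = t$n, ties = t$ties,
                     median_dead = t$median_dead, p_value = t$p_value)
        }))
        write.csv(btab, file.path(out_dir, paste0(pid, "_binomial.csv")),
                  row.names = FALSE, quote = FALSE)
        log <- log_line(log, "binomial", pid)
      }
    }
  }

  # ---- pooled and per-plot survival models ------------------------------
  survival_fit <- NULL
  per_plot <- NULL
  if ("survival" %in% config$analyses) {
    pooled <- stem_maps
    # dying + dead stage plots form one distance stratum
    stages <- vapply(pooled, function(s) s$metadata$stage, "")
    merge_idx <- which(stages %in% c("dying", "dead"))
    if (length(merge_idx) > 1) {
      for (j in merge_idx) {
        pooled[[j]]$metadata$plot_id <- "dying_dead_stratum"
      }
      log <- log_line(log, "survival",
                      "dying and dead plots pooled as one distance stratum")
    }
    alive_all <- unlist(lapply(pooled, function(s) s$trees$alive))
    if (length(unique(alive_all)) < 2) {
      skipped[["survival_pooled"]] <-
        "pooled survival model skipped: degenerate response"
      log <- log_line(log, "skip", skipped[["survival_pooled"]])
    } else {
      survival_fit <- fit_survival(pooled,
                                   survival_design(c("height", "distance")))
      for (note in survival_fit$notes) log <- log_line(log, "survival", note)
      tab <- survival_fit$coefficients
      tab$signif <- significance_code(tab$p)
      write.csv(tab, file.path(out_dir, "survival_pooled.csv"),
                row.names = FALSE, quote = FALSE)
      log <- log_line(log, "survival", "pooled height+distance model fitted")
    }
    per_plot <- per_plot_fits(stem_maps)
    for (pid in names(attr(per_plot, "skipped"))) {
      key <- paste0(pid, "_per_plot_fit")
      skipped[[key]] <- paste0("per-plot fit on '", pid, "' skipped: ",
                               attr(per_plot, "skipped")[[pid]])
      log <- log_line(log, "skip", skipped[[key]])
    }
    if (nrow(per_plot)) {
      write.csv(per_plot, file.path(out_dir, "survival_per_plot.csv"),
                row.names = FALSE, quote = FALSE)
    }
  }

  manifest <- list(
    package_version = as.character(packageVersion("standspat")),
    seed = seed,
    analyses = config$analyses,
    estimator = list(r_min = min(est$r), r_max = max(est$r),
                     n_r = length(est$r), mode = est$mode,
                     ring_width = est$ring_width,
                     edge_correction = est$edge_correction),
    null = list(n_sim = config$null$n_sim, rank = config$null$rank),
    plots = lapply(stem_maps, function(s) {
      list(plot_id = s$metadata$plot_id, stage = s$metadata$stage,
           n_live = sum(s$trees$alive), n_dead = sum(!s$trees$alive))
    }),
    skipped = skipped,
    outputs = list.files(out_dir, pattern = "\\.csv$"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log, file.path(out_dir, "run.log"))

  invisible(structure(
    list(stem_maps = stem_maps, summaries = summaries,
         envelopes = envelopes, mortality = mortality,
         binomial = binomial, survival = survival_fit,
         per_plot = per_plot, skipped = skipped, manifest = manifest,
         log = log, out_dir = out_dir),
    class = "report_bundle"))
}

#' Render a report bundle as human-readable text tables
#'
#' Produces per-plot stand-structure tables, per-scale classification
#' strings for every envelope (e.g. `"aggregated at 1-4 m, random
#' elsewhere"`) and the survival coefficient tables.
#'
#' @param bundle a report bundle from [run_pipeline()].
#' @return character vector of report lines (also printed).
#' @export
report_tables <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  out <- character(0)
  add <- function(...) out <<- c(out, sprintf(...))
  for (pid in names(bundle$summaries)) {
    s <- bundle$summaries[[pid]]
    add("== Stand summary: %s ==", pid)
    add("  %d stems, live %.0f /ha, dead %.0f /ha, height %.1f +/- %.1f m",
        s$n, s$live_density, s$dead_density, s$height_mean,
        ifelse(is.na(s$height_sd), 0, s$height_sd))
    for (j in seq_len(nrow(s$table))) {
      if (s$table$count[j] > 0) {
        add("  %-28s %-12s %6d  (%.1f%%)", s$table$class[j],
            s$table$vitality[j], s$table$count[j],
            100 * s$table$proportion[j])
      }
    }
  }
  for (key in names(bundle$envelopes)) {
    add("%s: %s", key, classification_string(bundle$envelopes[[key]]))
  }
  for (pid in names(bundle$mortality)) {
    add("%s mortality: %s", pid,
        classification_string(bundle$mortality[[pid]]))
  }
  if (!is.null(bundle$survival)) {
    add("== Pooled survival model (%s) ==", bundle$survival$method)
    cf <- bundle$survival$coefficients
    for (j in seq_len(nrow(cf))) {
      add("  %-12s est %8.4f  se %7.4f  z %7.3f  p %.3g %s", cf$term[j],
          cf$estimate[j], cf$std_error[j], cf$z[j], cf$p[j],
          significance_code(cf$p[j]))
    }
  }
  if (!is.null(bundle$per_plot) && nrow(bundle$per_plot)) {
    add("== Per-plot size effects ==")
    pp <- bundle$per_plot
    for (j in seq_len(nrow(pp))) {
      add("  %-16s %-8s p = %.3g %s", pp$plot_id[j], pp$covariate[j],
          pp$p[j], pp$signif[j])
    }
  }
  for (key in names(bundle$skipped)) {
    add("skipped: %s", bundle$skipped[[key]])
  }
  cat(paste(out, collapse = "\n"), "\n")
  invisible(out)
}
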