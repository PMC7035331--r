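#' Vitality classes of mapped stems
#'
#' Five ordered vitality labels based on crown and branch losses: `healthy`
#' (intact tree form), `low_stress` (< 10% loss), `high_stress` (10% to
#' two-thirds loss), `dying` (more than two-thirds loss) and `dead`
#' (standing dead trees and fallen logs).  Only `dead` maps to
#' `alive = FALSE`; `dying` trees count as alive in every spatial analysis.
#'
#' @return character vector of the five labels, in order of increasing stress.
#' @export
vitality_levels <- function() {
  c("healthy", "low_stress", "high_stress", "dying", "dead")
}

#' Plot metadata for a mapped stand
#'
#' @param plot_id character identifier.
#' @param stage developmental stage, one of `"juvenile"`, `"mature"`,
#'   `"dying"`, `"dead"`.
#' @param elevation plot elevation in metres.
#' @param distance_river distance from the river channel in km (>= 0).
#' @param window window side lengths in metres, default `c(100, 100)`.
#' @return an object of class `plot_metadata`.
#' @export
plot_metadata <- function(plot_id, stage, elevation = NA_real_,
                          distance_river = 0, window = c(100, 100)) {
  stage <- match.arg(stage, c("juvenile", "mature", "dying", "dead"))
  window <- as_window(window)
  distance_river <- as.numeric(distance_river)
  if (!is.finite(distance_river) || distance_river < 0) {
    stop("`distance_river` must be a finite non-negative number of km")
  }
  structure(
    list(plot_id = as.character(plot_id), stage = stage,
         elevation = as.numeric(elevation),
         distance_river = distance_river, window = window),
    class = "plot_metadata")
}

# snap measured quantities to their recording resolution
snap_trees <- function(trees) {
  trees$x <- round(trees$x, 1)
  trees$y <- round(trees$y, 1)
  trees$height <- round(trees$height, 2)
  trees$dbh <- round(trees$dbh, 1)
  trees$basal_diameter <- round(trees$basal_diameter, 1)
  trees
}

tree_columns <- c("tree_id", "x", "y", "height", "dbh",
                  "basal_diameter", "vitality")

#' Construct a validated stem map
#'
#' A stem map is a marked point pattern: one row per mapped stem with
#' coordinates (metres from the plot origin, bottom-left corner, recorded to
#' 0.1 m), height (m), DBH (cm, measured at 1.3 m and therefore present
#' exactly when height > 1.3 m), basal diameter (cm, for stems of height
#' <= 1.3 m such as stumps and failed root suckers) and a vitality class.
#' Coordinates live in the half-open window `[0, wx) x [0, wy)` so boundary
#' points are never double-counted.  Fallen logs are represented by their
#' trunk-base coordinates with vitality `dead`.
#'
#' @param trees data frame with columns `tree_id`, `x`, `y`, `height`,
#'   `dbh`, `basal_diameter`, `vitality` (`dbh`/`basal_diameter` may be NA).
#' @param metadata a [plot_metadata()] object.
#' @return an object of class `stem_map` with elements `metadata` and
#'   `trees` (the validated data frame, plus a derived logical `alive`).
#' @export
stem_map <- function(trees, metadata) {
  if (!inherits(metadata, "plot_metadata")) {
    stop("`metadata` must be a plot_metadata object")
  }
  trees <- as.data.frame(trees)
  if (nrow(trees) == 0 && !all(tree_columns %in% names(trees))) {
    trees <- data.frame(tree_id = character(0), x = numeric(0),
                        y = numeric(0), height = numeric(0),
                        dbh = numeric(0), basal_diameter = numeric(0),
                        vitality = character(0))
  }
  missing_cols <- setdiff(tree_columns, names(trees))
  if (length(missing_cols)) {
    stop("stem-map table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  trees <- trees[, tree_columns]
  trees$tree_id <- as.character(trees$tree_id)
  for (col in c("x", "y", "height", "dbh", "basal_diameter")) {
    v <- trees[[col]]
    if (is.character(v)) v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & v != "")
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at row %d: '%s'",
                   col, bad[1], as.character(v[bad[1]])))
    }
    trees[[col]] <- num
  }
  trees$vitality <- as.character(trees$vitality)
  trees <- snap_trees(trees)

  w <- metadata$window
  if (nrow(trees)) {
    bad <- which(!is.finite(trees$x) | !is.finite(trees$y) |
                   trees$x < 0 | trees$x >= w[1] |
                   trees$y < 0 | trees$y >= w[2])
    if (length(bad)) {
      stop(sprintf(
        "tree '%s' (row %d) lies outside the %g x %g m window: (%g, %g)",
        trees$tree_id[bad[1]], bad[1], w[1], w[2],
        trees$x[bad[1]], trees$y[bad[1]]))
    }
    bad <- which(!(trees$vitality %in% vitality_levels()))
    if (length(bad)) {
      stop(sprintf(
        "tree '%s' (row %d) has unknown vitality '%s'; allowed labels: %s",
        trees$tree_id[bad[1]], bad[1], trees$vitality[bad[1]],
        paste(vitality_levels(), collapse = ", ")))
    }
    dup <- trees$tree_id[duplicated(trees$tree_id)]
    if (length(dup)) {
      stop("duplicate tree_id within plot: ", dup[1])
    }
    bad <- which(!is.finite(trees$height) | trees$height <= 0)
    if (length(bad)) {
      stop(sprintf("tree '%s' (row %d) has non-positive height",
                   trees$tree_id[bad[1]], bad[1]))
    }
    bad <- which(trees$height <= 1.3 & !is.na(trees$dbh))
    if (length(bad)) {
      stop(sprintf(
        "tree '%s' (row %d): height <= 1.3 m but dbh is recorded (stems at or below breast height carry basal_diameter only)",
        trees$tree_id[bad[1]], bad[1]))
    }
    bad <- which(trees$height > 1.3 & is.na(trees$dbh))
    if (length(bad)) {
      stop(sprintf(
        "tree '%s' (row %d): height > 1.3 m but dbh is missing",
        trees$tree_id[bad[1]], bad[1]))
    }
    bad <- which(!is.na(trees$dbh) & trees$dbh < 0)
    if (length(bad)) stop("negative dbh at row ", bad[1])
    bad <- which(!is.na(trees$basal_diameter) & trees$basal_diameter < 0)
    if (length(bad)) stop("negative basal_diameter at row ", bad[1])
  }
  trees$alive <- trees$vitality != "dead"
  rownames(trees) <- NULL
  structure(list(metadata = metadata, trees = trees), class = "stem_map")
}

#' @exportS3Method base::print
print.stem_map <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("stem map '%s' (%s stage): %d trees (%d live, %d dead)\n",
              m$plot_id, m$stage, nrow(x$trees), sum(x$trees$alive),
              sum(!x$trees$alive)))
  cat(sprintf("  window %g x %g m, %.2f km from river\n",
              m$window[1], m$window[2], m$distance_river))
  invisible(x)
}

#' Number of trees in a stem map
#' @param x a `stem_map`.
#' @return integer count.
#' @export
n_trees <- function(x) nrow(x$trees)

#' Extract coordinates of a sub-pattern from a stem map
#'
#' @param x a `stem_map`.
#' @param pattern which stems to return: all, live only or dead only.
#' @return two-column matrix of coordinates.
#' @export
stem_points <- function(x, pattern = c("all", "live", "dead")) {
  pattern <- match.arg(pattern)
  tr <- x$trees
  keep <- switch(pattern, all = rep(TRUE, nrow(tr)), live = tr$alive,
                 dead = !tr$alive)
  as_points(tr[keep, c("x", "y"), drop = FALSE])
}

#' Read a stem map from CSV files
#'
#' Expects a stem table with columns
#' `tree_id,x_m,y_m,height_m,dbh_cm,basal_diameter_cm,vitality` and a
#' one-row metadata table with columns
#' `plot_id,stage,elevation_m,distance_river_km,window_x_m,window_y_m`.
#' Missing diameters are empty fields, never 0.
#'
#' @param path path to the stem-map CSV.
#' @param metadata_path path to the plot-metadata CSV.
#' @return a validated [stem_map()].
#' @export
read_stem_map <- function(path, metadata_path) {
  meta_raw <- read.csv(metadata_path, stringsAsFactors = FALSE)
  need <- c("plot_id", "stage", "elevation_m", "distance_river_km",
            "window_x_m", "window_y_m")
  missing_cols <- setdiff(need, names(meta_raw))
  if (length(missing_cols)) {
    stop("metadata CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  md <- plot_metadata(meta_raw$plot_id[1], meta_raw$stage[1],
                      meta_raw$elevation_m[1], meta_raw$distance_river_km[1],
                      c(meta_raw$window_x_m[1], meta_raw$window_y_m[1]))
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("tree_id", "x_m", "y_m", "height_m", "dbh_cm",
            "basal_diameter_cm", "vitality")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("stem-map CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  trees <- data.frame(tree_id = raw$tree_id, x = raw$x_m, y = raw$y_m,
                      height = raw$height_m, dbh = raw$dbh_cm,
                      basal_diameter = raw$basal_diameter_cm,
                      vitality = raw$vitality, stringsAsFactors = FALSE)
  stem_map(trees, md)
}

#' Write a stem map (and optionally its metadata) to CSV
#'
#' The writer is the inverse of [read_stem_map()]: coordinates are written
#' with one decimal (0.1 m resolution), heights with two, diameters with
#' one, and missing diameters as empty fields, so a write/read round trip
#' reproduces the stem map exactly and repeated writes are byte-stable.
#'
#' @param x a `stem_map`.
#' @param path output path for the stem table CSV.
#' @param metadata_path optional output path for the metadata CSV.
#' @return `x`, invisibly.
#' @export
write_stem_map <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "stem_map"))
  tr <- x$trees
  out <- data.frame(
    tree_id = tr$tree_id,
    x_m = fmt_num(tr$x, 1), y_m = fmt_num(tr$y, 1),
    height_m = fmt_num(tr$height, 2),
    dbh_cm = fmt_num(tr$dbh, 1),
    basal_diameter_cm = fmt_num(tr$basal_diameter, 1),
    vitality = tr$vitality, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(metadata_path)) {
    m <- x$metadata
    md <- data.frame(plot_id = m$plot_id, stage = m$stage,
                     elevation_m = m$elevation,
                     distance_river_km = m$distance_river,
                     window_x_m = m$window[1], window_y_m = m$window[2])
    write.csv(md, metadata_path, row.names = FALSE, quote = FALSE)
  }
  invisible(x)
}

#' Stand-structure summary of a stem map
#'
#' Cross-tabulates stems by vitality class and size class (height <= 1.3 m
#' versus taller; taller stems optionally subdivided by DBH bins) and
#' reports live/dead stem densities per hectare and the height mean and sd
#' pooled over live and dead stems.
#'
#' @param x a `stem_map`.
#' @param dbh_bins optional numeric breakpoints (cm) subdividing the
#'   height > 1.3 m class by DBH.
#' @return an object of class `stand_summary`: a list with the long-format
#'   `table` (`class`, `vitality`, `count`, `proportion`), densities per
#'   hectare, height moments and plot area.
#' @export
summarize_stand <- function(x, dbh_bins = NULL) {
  stopifnot(inherits(x, "stem_map"))
  tr <- x$trees
  area_ha <- prod(x$metadata$window) / 1e4
  n <- nrow(tr)
  if (n == 0) {
    size_class <- character(0)
  } else if (is.null(dbh_bins)) {
    size_class <- ifelse(tr$height <= 1.3, "H<=1.3m", "H>1.3m")
  } else {
    breaks <- sort(unique(c(0, dbh_bins, Inf)))
    lab <- paste0("H>1.3m,DBH(", head2(breaks), "-", tail2(breaks), "]")
    size_class <- ifelse(tr$height <= 1.3, "H<=1.3m",
                         lab[findInterval(tr$dbh, breaks,
                                          rightmost.closed = TRUE,
                                          left.open = TRUE)])
  }
  classes <- if (is.null(dbh_bins)) c("H<=1.3m", "H>1.3m") else
    c("H<=1.3m", sort(unique(size_class[size_class != "H<=1.3m"])))
  tab <- expand.grid(class = classes, vitality = vitality_levels(),
                     stringsAsFactors = FALSE)
  tab$count <- mapply(function(cl, vi) {
    sum(size_class == cl & tr$vitality == vi)
  }, tab$class, tab$vitality)
  tab$proportion <- if (n > 0) tab$count / n else 0
  structure(
    list(table = tab, n = n, area_ha = area_ha,
         live_density = sum(tr$alive) / area_ha,
         dead_density = sum(!tr$alive) / area_ha,
         height_mean = if (n) mean(tr$height) else NA_real_,
         height_sd = if (n > 1) sd(tr$height) else NA_real_),
    class = "stand_summary")
}

head2 <- function(b) b[-length(b)]
tail2 <- function(b) b[-1]

#' @exportS3Method base::print
print.stand_summary <- function(x, ...) {
  cat(sprintf(
    "stand summary: %d stems on %.2f ha (live %.0f /ha, dead %.0f /ha)\n",
    x$n, x$area_ha, x$live_density, x$dead_density))
  if (x$n) {
    cat(sprintf("  height %.2f +/- %.2f m\n", x$height_mean,
                x$height_sd %||% NA))
  }
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a stand summary as long-format CSV
#'
#' @param x a `stand_summary`.
#' @param path output path.
#' @return `x`, invisibly.
#' @export
write_stand_summary <- function(x, path) {
  stopifnot(inherits(x, "stand_summary"))
  write.csv(x$table, path, row.names = FALSE, quote = FALSE)
  invisible(x)
}
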