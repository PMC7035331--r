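#' Derive a reproducible child seed from a global seed
#'
#' One global integer seed is expanded into per-component seeds by a fixed
#' affine map modulo the largest 32-bit prime, so partial reruns of a
#' pipeline reuse identical streams per component.
#'
#' @param seed integer global seed.
#' @param k integer component index (>= 0).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k))
  m <- 2147483647
  as.integer((as.double(seed) %% m * 7919 + as.double(k) * 104729 + 1) %% m)
}

# run code with a locally set seed (NULL seed = use current stream)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# fixed-decimal formatting that writes "" for NA (byte-stable CSV fields)
fmt_num <- function(x, digits) {
  out <- ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
  sub("^-0(\\.0+)?$", "0\\1", out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce a window specification to c(wx, wy)
as_window <- function(window) {
  w <- as.numeric(window)
  if (length(w) == 1L) w <- c(w, w)
  if (length(w) != 2L || any(!is.finite(w)) || any(w <= 0)) {
    stop("`window` must be one or two positive side lengths in metres")
  }
  w
}

# coerce points input (matrix/data.frame with x,y) to a 2-column matrix
as_points <- function(p) {
  if (is.null(p)) return(cbind(x = numeric(0), y = numeric(0)))
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
  if (is.matrix(p) && ncol(p) >= 2) {
    m <- p[, 1:2, drop = FALSE]
    colnames(m) <- c("x", "y")
    storage.mode(m) <- "double"
    return(m)
  }
  stop("points must be a two-column matrix or a data frame with x and y")
}
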