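# Internal helpers shared across modules.

#' @importFrom rlang %||% .data abort
#' @importFrom stats dist rnorm rpois runif
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `code` under a fixed RNG state when `seed` is given, leaving the
# caller's RNG untouched; pass seed = NULL to use the ambient RNG stream.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Derive `n` reproducible 31-bit sub-seeds from one master seed.
derive_seeds <- function(seed, n) {
  with_seed_(seed, sample.int(.Machine$integer.max, n))
}

# Coerce a data frame (or 2-column matrix) of waypoints to an n x 2 matrix.
as_points_matrix <- function(points) {
  if (is.matrix(points)) {
    if (ncol(points) != 2) abort("`points` matrix must have two columns (x, y).")
    m <- points
  } else if (is.data.frame(points)) {
    if (!all(c("x", "y") %in% names(points))) {
      abort("`points` must have numeric `x` and `y` columns.")
    }
    m <- cbind(points$x, points$y)
  } else {
    abort("`points` must be a data frame or a two-column matrix.")
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("`points` must not contain missing coordinates.")
  dimnames(m) <- NULL
  m
}

dist_matrix <- function(pts) {
  as.matrix(stats::dist(pts))
}

check_permutation <- function(order, n) {
  order <- as.integer(order)
  if (length(order) != n || anyNA(order) || !setequal(order, seq_len(n))) {
    abort(sprintf(
      "`order` must be a permutation of 1..%d (got %d indices).", n, length(order)
    ))
  }
  order
}

# Closed-tour length from a precomputed distance matrix (Eq.-(4)-style objective).
closed_length_dm <- function(dm, order) {
  n <- length(order)
  if (n < 2) return(0)
  nxt <- order[c(2:n, 1)]
  sum(dm[cbind(order, nxt)])
}

open_length_dm <- function(dm, order) {
  n <- length(order)
  if (n < 2) return(0)
  sum(dm[cbind(order[-n], order[-1])])
}

# Closed lengths for a population of tours (rows of `popm`), vectorised.
population_lengths <- function(dm, popm) {
  n <- ncol(popm)
  nxt <- popm[, c(2:n, 1), drop = FALSE]
  rowSums(matrix(dm[cbind(as.vector(popm), as.vector(nxt))], nrow = nrow(popm)))
}
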