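# Tour objective and the deterministic route constructors.

# Build the tidy tour object: one row per visited waypoint, lengths and
# provenance in attributes.
new_tour <- function(points, order, planner, params = list()) {
  pts <- as_points_matrix(points)
  n <- nrow(pts)
  order <- check_permutation(order, n)
  dm <- if (n >= 2) dist_matrix(pts) else matrix(0, 1, 1)
  out <- tibble::tibble(
    step = seq_len(n), idx = order,
    x = pts[order, 1], y = pts[order, 2]
  )
  structure(
    out,
    planner = planner,
    closed_length = closed_length_dm(dm, order),
    open_length = open_length_dm(dm, order),
    params = params,
    class = c("rose_tour", class(out))
  )
}

#' @export
print.rose_tour <- function(x, ...) {
  cat(sprintf(
    "<rose_tour> %s, %d waypoint(s), closed length %.4g, open length %.4g\n",
    attr(x, "planner"), nrow(x), attr(x, "closed_length"), attr(x, "open_length")
  ))
  NextMethod()
}

#' Tour accessors
#'
#' @param tour A `rose_tour`.
#' @param closed Return the closed-loop length (with the return edge to the
#'   start) or the open path length.
#' @return `tour_order()` the integer visiting order; `tour_len()` the
#'   requested length.
#' @export
tour_order <- function(tour) as.integer(tour$idx)

#' @rdname tour_order
#' @export
tour_len <- function(tour, closed = TRUE) {
  attr(tour, if (closed) "closed_length" else "open_length")
}

#' @method glance rose_tour
#' @export
glance.rose_tour <- function(x, ...) {
  tibble::tibble(
    planner = attr(x, "planner"), n = nrow(x),
    closed_length = attr(x, "closed_length"),
    open_length = attr(x, "open_length")
  )
}

#' Euclidean tour length
#'
#' The picking-path objective: the sum of consecutive Euclidean distances
#' along the visiting order, plus — for a closed tour — the return edge from
#' the final target back to the first, closing the harvesting loop. A single
#' point has length 0; an empty point set is an error.
#'
#' @param points Data frame with `x`, `y`.
#' @param order Permutation of `1:nrow(points)`; defaults to file order.
#' @param closed Include the closing edge (default `TRUE`).
#' @return The length in coordinate units.
#' @examples
#' tri <- data.frame(x = c(0, 3, 0), y = c(0, 0, 4))
#' tour_length(tri)                 # 3 + 5 + 4 = 12
#' tour_length(tri, closed = FALSE) # 3 + 5 = 8
#' @export
tour_length <- function(points, order = seq_len(nrow(pts_df(points))), closed = TRUE) {
  pts <- as_points_matrix(points)
  n <- nrow(pts)
  if (n == 0) abort("Cannot measure a tour over zero points.")
  order <- check_permutation(order, n)
  if (n == 1) return(0)
  dm <- dist_matrix(pts)
  if (closed) closed_length_dm(dm, order) else open_length_dm(dm, order)
}

pts_df <- function(points) {
  if (is.matrix(points)) as.data.frame(points) else points
}

#' Reciprocating (boustrophedon) traversal
#'
#' Reduces planning to sorting: points are bucketed into horizontal bands of
#' `band_height` by their y coordinate, bands are visited top to bottom, and
#' within each band points are sorted by x with the sweep direction
#' alternating between consecutive non-empty bands (a serpentine). Runs in
#' O(n log n). By default the vertical extent of the points is split into
#' ten bands (a field-row traversal); pass `band_height` to control it.
#'
#' @param points Data frame with `x`, `y` (n >= 1).
#' @param band_height Band height in pixels (> 0), or `NULL` for the
#'   ten-band default.
#' @return A `rose_tour`; its closed length is used for cross-planner
#'   comparison, the open length is also recorded.
#' @examples
#' sq <- data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
#' tour_order(reciprocating_tour(sq, band_height = 0.5))
#' @export
reciprocating_tour <- function(points, band_height = NULL) {
  pts <- as_points_matrix(points)
  n <- nrow(pts)
  if (n == 0) abort("Cannot plan an empty scene.")
  if (!is.null(band_height) && band_height <= 0) {
    abort("`band_height` must be positive.")
  }
  if (n == 1) {
    return(new_tour(points, 1L, "reciprocating",
                    list(band_height = band_height)))
  }
  y <- pts[, 2]
  span <- diff(range(y))
  if (is.null(band_height)) {
    band_height <- if (span > 0) span / 10 else 1
  }
  band <- floor((y - min(y)) / band_height)
  ord <- order(band, pts[, 1], seq_len(n)) # stable: band, then x, then input order
  bands <- split(ord, band[ord])
  dir_flip <- FALSE
  visit <- integer(0)
  for (b in bands) {
    visit <- c(visit, if (dir_flip) rev(b) else b)
    dir_flip <- !dir_flip
  }
  new_tour(points, visit, "reciprocating", list(band_height = band_height))
}

#' Nearest-neighbour construction
#'
#' Greedy tour: from the start point, repeatedly hop to the closest
#' unvisited point; distance ties are broken towards the lowest index, so
#' the construction is deterministic.
#'
#' @param points Data frame with `x`, `y` (n >= 1).
#' @param start Index of the starting waypoint.
#' @return A `rose_tour`.
#' @export
nearest_neighbor_tour <- function(points, start = 1L) {
  pts <- as_points_matrix(points)
  n <- nrow(pts)
  if (n == 0) abort("Cannot plan an empty scene.")
  if (length(start) != 1 || is.na(start) || start < 1 || start > n) {
    abort("`start` must index a waypoint.")
  }
  order <- nn_order(dist_matrix(pts), as.integer(start))
  new_tour(points, order, "nearest_neighbor", list(start = as.integer(start)))
}

nn_order <- function(dm, start) {
  n <- nrow(dm)
  visited <- logical(n)
  order <- integer(n)
  cur <- start
  visited[cur] <- TRUE
  order[1] <- cur
  for (k in seq_len(n - 1)) {
    d <- dm[cur, ]
    d[visited] <- Inf
    cur <- which.min(d) # ties: lowest index
    visited[cur] <- TRUE
    order[k + 1] <- cur
  }
  order
}

# First-improvement 2-opt on the closed tour; inner loop vectorised over the
# second cut point. Stagnation tolerance avoids float churn.
two_opt_order <- function(dm, ord, tol = 1e-9, max_passes = 1000) {
  n <- length(ord)
  if (n < 4) return(ord)
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    i <- 1L
    while (i <= n - 1L) {
      a <- ord[if (i == 1L) n else i - 1L]
      b <- ord[i]
      js <- (i + 1L):n
      if (i == 1L) js <- js[js < n] # same (wrap) edge: no move
      if (!length(js)) { i <- i + 1L; next }
      cs <- ord[js]
      ds <- ord[ifelse(js == n, 1L, js + 1L)]
      delta <- dm[cbind(a, cs)] + dm[cbind(b, ds)] -
        dm[a, b] - dm[cbind(cs, ds)]
      k <- which(delta < -tol)
      if (length(k)) {
        j <- js[k[1]]
        ord[i:j] <- ord[j:i]
        improved <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!improved) break
  }
  ord
}

#' 2-opt local search
#'
#' Repeated first-improvement segment reversals on the closed tour until no
#' 2-opt move shortens it. The output is never longer than the input and is
#' 2-opt-locally optimal; on Euclidean instances the resulting tour has no
#' pair of properly crossing edges.
#'
#' @param points Data frame with `x`, `y`.
#' @param order Starting order: an integer permutation, a `rose_tour`, or
#'   `NULL` for file order.
#' @return A `rose_tour`.
#' @export
two_opt <- function(points, order = NULL) {
  pts <- as_points_matrix(points)
  n <- nrow(pts)
  if (inherits(order, "rose_tour")) order <- tour_order(order)
  if (is.null(order)) order <- seq_len(n)
  order <- check_permutation(order, n)
  if (n < 2) return(new_tour(points, order, "two_opt"))
  dm <- dist_matrix(pts)
  new_tour(points, two_opt_order(dm, order), "two_opt")
}

#' Exact optimum by enumeration
#'
#' Brute-force oracle for small instances: enumerates the `(n-1)!/2`
#' distinct closed tours (first city fixed, reflections removed) and returns
#' a minimum-length one. Guarded to `2 <= n <= 9`.
#'
#' @param points Data frame with `x`, `y`.
#' @return A `rose_tour` of minimum closed length.
#' @export
brute_force_optimal <- function(points) {
  pts <- as_points_matrix(points)
  n <- nrow(pts)
  if (n < 2 || n > 9) abort("`brute_force_optimal` handles 2 <= n <= 9 only.")
  if (n == 2) return(new_tour(points, 1:2, "brute_force"))
  perms <- permutations_of(2:n)
  keep <- perms[, 1] < perms[, ncol(perms)] # remove reflections
  perms <- perms[keep, , drop = FALSE]
  orders <- cbind(1L, perms)
  dm <- dist_matrix(pts)
  lens <- population_lengths(dm, orders)
  new_tour(points, orders[which.min(lens), ], "brute_force")
}

permutations_of <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- permutations_of(v[-i])
    out[[i]] <- cbind(v[i], sub)
  }
  do.call(rbind, out)
}

# Strict orientation-based proper-intersection test for two segments.
segments_cross <- function(p, q, r, s) {
  orient <- function(a, b, c) {
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  }
  o1 <- orient(p, q, r); o2 <- orient(p, q, s)
  o3 <- orient(r, s, p); o4 <- orient(r, s, q)
  o1 != o2 && o3 != o4 && o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0
}

#' Count properly crossing edge pairs of a closed tour
#'
#' Diagnostic used to verify 2-opt geometry: a 2-opt-locally-optimal
#' Euclidean tour contains no pair of edges that cross at an interior point
#' of both. Edge pairs sharing an endpoint (including coincident waypoints)
#' are not counted.
#'
#' @param points Data frame with `x`, `y`.
#' @param order Visiting order (permutation) or a `rose_tour`.
#' @return Integer count of properly crossing pairs.
#' @export
tour_crossings <- function(points, order) {
  pts <- as_points_matrix(points)
  if (inherits(order, "rose_tour")) order <- tour_order(order)
  n <- nrow(pts)
  order <- check_permutation(order, n)
  if (n < 4) return(0L)
  nxt <- order[c(2:n, 1)]
  crossings <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next # adjacent edges
      if (segments_cross(pts[order[i], ], pts[nxt[i], ],
                         pts[order[j], ], pts[nxt[j], ])) {
        crossings <- crossings + 1L
      }
    }
  }
  crossings
}
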