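# Ant-system baseline planner (benchmark comparison only).

#' Ant-colony configuration
#'
#' Standard ant-system settings for the baseline planner. Defaults
#' (`ant_count = n`, 100 iterations, alpha 1, beta 3, evaporation 0.5) are a
#' conventional benchmark parameterisation, not a statement about any
#' particular deployment.
#'
#' @param ant_count Ants per iteration, or `NULL` for one per waypoint.
#' @param iterations Number of colony iterations.
#' @param alpha Pheromone exponent (>= 0).
#' @param beta Heuristic (inverse-distance) exponent (>= 0).
#' @param evaporation Evaporation rate in (0, 1).
#' @param q Deposit constant (each ant deposits `q / length` on its edges).
#' @param seed Default RNG seed.
#' @return An `aco_config` list.
#' @export
aco_config <- function(ant_count = NULL, iterations = 100,
                       alpha = 1, beta = 3, evaporation = 0.5,
                       q = 1, seed = NULL) {
  if (evaporation <= 0 || evaporation >= 1) {
    abort("`evaporation` must lie strictly between 0 and 1.")
  }
  if (iterations < 1 || (!is.null(ant_count) && ant_count < 1)) {
    abort("Counts must be positive.")
  }
  if (alpha < 0 || beta < 0) abort("`alpha` and `beta` must be non-negative.")
  structure(
    list(ant_count = ant_count, iterations = as.integer(iterations),
         alpha = alpha, beta = beta, evaporation = evaporation,
         q = q, seed = seed),
    class = "aco_config"
  )
}

#' Ant-system tour planner
#'
#' Classic ant system on the closed-tour objective: ants construct tours by
#' sampling the next city with probability proportional to
#' `pheromone^alpha * (1/d)^beta` over unvisited cities; after each
#' iteration pheromone evaporates globally and every ant deposits
#' `q / length` on its edges. Ant k starts at city `((k-1) mod n) + 1`, so
#' with `alpha = 0` and a large `beta` the first ant reproduces the
#' nearest-neighbour construction from city 1. The best-so-far tour is
#' returned; runs are deterministic for a fixed seed.
#'
#' @param points Data frame with `x`, `y` (n >= 2).
#' @param cfg An [aco_config()].
#' @param seed RNG seed (takes precedence over `cfg$seed`).
#' @return A `rose_tour`.
#' @export
aco_tour <- function(points, cfg = aco_config(), seed = NULL) {
  pts <- as_points_matrix(points)
  n <- nrow(pts)
  if (n < 2) abort("The ant-system planner needs at least two waypoints.")
  dm <- dist_matrix(pts)
  m <- cfg$ant_count %||% n
  eff_seed <- seed %||% cfg$seed

  order_best <- with_seed_(eff_seed, {
    nn_len <- closed_length_dm(dm, nn_order(dm, 1L))
    tau <- matrix(1 / (n * nn_len), n, n)
    eta_b <- (1 / pmax(dm, 1e-12))^cfg$beta
    diag(eta_b) <- 0
    best_order <- NULL
    best_len <- Inf
    for (it in seq_len(cfg$iterations)) {
      tours <- matrix(0L, m, n)
      lens <- numeric(m)
      for (k in seq_len(m)) {
        cur <- ((k - 1L) %% n) + 1L
        visited <- logical(n)
        visited[cur] <- TRUE
        ordk <- integer(n)
        ordk[1] <- cur
        for (s in 2:n) {
          w <- (tau[cur, ]^cfg$alpha) * eta_b[cur, ]
          w[visited] <- 0
          if (!any(w > 0)) w[!visited] <- 1 # degenerate weights: uniform
          cur <- sample.int(n, 1, prob = w)
          visited[cur] <- TRUE
          ordk[s] <- cur
        }
        tours[k, ] <- ordk
        lens[k] <- closed_length_dm(dm, ordk)
      }
      tau <- (1 - cfg$evaporation) * tau
      for (k in seq_len(m)) {
        e1 <- tours[k, ]
        e2 <- tours[k, c(2:n, 1)]
        dep <- cfg$q / max(lens[k], 1e-12)
        tau[cbind(e1, e2)] <- tau[cbind(e1, e2)] + dep
        tau[cbind(e2, e1)] <- tau[cbind(e2, e1)] + dep
      }
      ib <- which.min(lens)
      if (lens[ib] < best_len) {
        best_len <- lens[ib]
        best_order <- tours[ib, ]
      }
    }
    best_order
  })

  new_tour(points, order_best, "aco",
           params = list(ant_count = m, iterations = cfg$iterations,
                         alpha = cfg$alpha, beta = cfg$beta,
                         evaporation = cfg$evaporation, seed = eff_seed))
}
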