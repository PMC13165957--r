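# Hybrid genetic planner: greedy + random initialization, elitism,
# tournament selection, order crossover, adaptive inversion mutation,
# periodic 2-opt polish and stagnation-based early stopping.

#' Genetic-planner configuration
#'
#' All knobs of the hybrid GA. `population_size` (N) and `max_generations`
#' (G) default to the adaptive schedule of [dynamic_ga_params()]; keeping
#' them clamped constants keeps total planner work O(G N n), i.e. O(n^2)
#' overall. The mutation probability decays linearly from `mutation_start`
#' to `mutation_end` over the generations; stopping is triggered after
#' `stagnation_patience` consecutive generations (default ten) without an
#' improvement of the best closed length (absolute tolerance 1e-9, so float
#' churn does not reset the counter).
#'
#' The ablation switches `adaptive_mutation` and `use_two_opt`, together
#' with `greedy_seed_fraction = 0`, turn the hybrid GA into the plain GA
#' baseline used by the benchmark harness.
#'
#' @param population_size,max_generations Positive counts, or `NULL` for the
#'   adaptive schedule.
#' @param elite_count Individuals copied unchanged each generation
#'   (< population size).
#' @param tournament_size Tournament size for parent selection.
#' @param crossover_rate Probability of order crossover (else the first
#'   parent is cloned).
#' @param mutation_start,mutation_end Endpoints of the linear mutation-rate
#'   decay (`mutation_start >= mutation_end >= 0`).
#' @param mutation_op `"inversion"` (segment reversal, pairing naturally
#'   with 2-opt neighbourhoods) or `"swap"`.
#' @param greedy_seed_fraction Fraction of the initial population built by
#'   nearest-neighbour construction from distinct starts (0 disables greedy
#'   seeding; remainder is uniform random permutations).
#' @param stagnation_patience Generations without improvement before early
#'   stop.
#' @param two_opt_every Apply 2-opt to the generation best every this many
#'   generations (final best is always polished when `use_two_opt`).
#' @param adaptive_mutation Linear decay on (`TRUE`) or constant
#'   `mutation_start` (`FALSE`).
#' @param use_two_opt Enable the 2-opt local search.
#' @param seed Default RNG seed (overridable per call).
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = NULL, max_generations = NULL,
                      elite_count = 2, tournament_size = 3,
                      crossover_rate = 0.9,
                      mutation_start = 0.20, mutation_end = 0.02,
                      mutation_op = c("inversion", "swap"),
                      greedy_seed_fraction = 0.2,
                      stagnation_patience = 10, two_opt_every = 5,
                      adaptive_mutation = TRUE, use_two_opt = TRUE,
                      seed = NULL) {
  if (!is.null(population_size) && elite_count >= population_size) {
    abort("`elite_count` must be smaller than `population_size`.")
  }
  if (mutation_start < mutation_end || mutation_end < 0) {
    abort("Need `mutation_start` >= `mutation_end` >= 0.")
  }
  if (greedy_seed_fraction < 0 || greedy_seed_fraction > 1) {
    abort("`greedy_seed_fraction` must lie in [0, 1].")
  }
  structure(
    list(
      population_size = population_size, max_generations = max_generations,
      elite_count = as.integer(elite_count),
      tournament_size = as.integer(tournament_size),
      crossover_rate = crossover_rate,
      mutation_start = mutation_start, mutation_end = mutation_end,
      mutation_op = match.arg(mutation_op),
      greedy_seed_fraction = greedy_seed_fraction,
      stagnation_patience = as.integer(stagnation_patience),
      two_opt_every = as.integer(two_opt_every),
      adaptive_mutation = isTRUE(adaptive_mutation),
      use_two_opt = isTRUE(use_two_opt),
      seed = seed
    ),
    class = "ga_config"
  )
}

#' Linearly decaying mutation rate
#'
#' `mutation_start - (mutation_start - mutation_end) * g / (G - 1)` for
#' 0-based generation `g`; a single-generation run returns
#' `mutation_start`.
#'
#' @param generation 0-based generation index, `0 <= generation < G`.
#' @param cfg A [ga_config()] with `max_generations` set.
#' @return The mutation probability at that generation.
#' @examples
#' cfg <- ga_config(population_size = 20, max_generations = 101)
#' mutation_rate(50, cfg) # midpoint of 0.20 -> 0.02 is 0.11
#' @export
mutation_rate <- function(generation, cfg) {
  G <- cfg$max_generations
  if (is.null(G)) abort("`cfg$max_generations` must be set.")
  if (any(generation < 0) || any(generation >= G)) {
    abort("`generation` must satisfy 0 <= generation < max_generations.")
  }
  if (G == 1) return(rep(cfg$mutation_start, length(generation)))
  cfg$mutation_start -
    (cfg$mutation_start - cfg$mutation_end) * generation / (G - 1)
}

#' Adaptive GA budget from the target count
#'
#' Dynamic parameter schedule: the population size and generation budget
#' grow with the number of detected targets but are clamped to small
#' constants so the planner stays inside its real-time complexity envelope:
#' `N = clamp(4 n, 20, 120)`, `G = clamp(10 n, 50, 400)`.
#'
#' @param n Number of waypoints (>= 1).
#' @return A one-row tibble with `population_size` and `max_generations`.
#' @examples
#' dynamic_ga_params(25) # N = 100, G = 250
#' @export
dynamic_ga_params <- function(n) {
  if (any(n < 1)) abort("`n` must be >= 1.")
  tibble::tibble(
    population_size = as.integer(clamp(4 * n, 20, 120)),
    max_generations = as.integer(clamp(10 * n, 50, 400))
  )
}

mutate_order <- function(ord, op) {
  n <- length(ord)
  ij <- sort(sample.int(n, 2))
  if (op == "inversion") {
    ord[ij[1]:ij[2]] <- ord[ij[2]:ij[1]]
  } else {
    ord[ij] <- ord[rev(ij)]
  }
  ord
}

# Order crossover (OX): copy a segment of p1, fill the rest in p2's order.
ox_crossover <- function(p1, p2) {
  n <- length(p1)
  cut <- sort(sample.int(n, 2))
  seg <- p1[cut[1]:cut[2]]
  child <- integer(n)
  child[cut[1]:cut[2]] <- seg
  child[-(cut[1]:cut[2])] <- p2[!(p2 %in% seg)]
  child
}

#' Hybrid genetic tour planner
#'
#' Order-based GA on the closed-tour objective. The initial population mixes
#' nearest-neighbour constructions from distinct starts
#' (`greedy_seed_fraction`), any caller-supplied `seed_tours` (the pipeline
#' passes the reciprocating and nearest-neighbour tours, which — through
#' elitism — guarantees the result never exceeds them), and uniform random
#' permutations. Each generation: the `elite_count` best are copied
#' unchanged, parents are chosen by size-`tournament_size` tournaments,
#' children are produced by order crossover and mutated at the (linearly
#' decaying) rate, and every `two_opt_every` generations the generation best
#' is polished by 2-opt. The best closed length is monotonically
#' non-increasing across generations, and the run stops early after
#' `stagnation_patience` generations without improvement. Fully
#' deterministic for a fixed `seed`.
#'
#' @param points Data frame with `x`, `y` (n >= 2).
#' @param cfg A [ga_config()].
#' @param seed RNG seed (takes precedence over `cfg$seed`; if both are
#'   `NULL` the ambient RNG stream is used).
#' @param seed_tours Optional list of permutations injected into the initial
#'   population.
#' @return A `rose_tour`; `attr(, "history")` holds the best closed length
#'   per generation and `attr(, "params")` the budgets actually used.
#' @export
ga_tour <- function(points, cfg = ga_config(), seed = NULL, seed_tours = NULL) {
  pts <- as_points_matrix(points)
  n <- nrow(pts)
  if (n < 2) abort("The genetic planner needs at least two waypoints.")
  dyn <- dynamic_ga_params(n)
  N <- cfg$population_size %||% dyn$population_size
  G <- cfg$max_generations %||% dyn$max_generations
  if (cfg$elite_count >= N) abort("`elite_count` must be smaller than N.")
  cfg$population_size <- N
  cfg$max_generations <- G
  dm <- dist_matrix(pts)
  eff_seed <- seed %||% cfg$seed

  res <- with_seed_(eff_seed, {
    ## --- initial population -------------------------------------------
    k_greedy <- min(n, round(cfg$greedy_seed_fraction * N))
    greedy <- if (k_greedy > 0) {
      starts <- sample.int(n, k_greedy)
      t(vapply(starts, function(s) nn_order(dm, s), integer(n)))
    } else NULL
    seeded <- NULL
    if (length(seed_tours)) {
      seed_tours <- lapply(seed_tours, check_permutation, n = n)
      seeded <- do.call(rbind, seed_tours)
    }
    fixed <- rbind(greedy, seeded)
    if (!is.null(fixed) && nrow(fixed) > N - 1) {
      fixed <- fixed[seq_len(N - 1), , drop = FALSE] # keep >= 1 random slot
    }
    n_rand <- N - if (is.null(fixed)) 0 else nrow(fixed)
    rand <- t(vapply(seq_len(n_rand), function(i) sample.int(n), integer(n)))
    popm <- rbind(fixed, rand)
    len <- population_lengths(dm, popm)

    best_i <- which.min(len)
    best_order <- popm[best_i, ]
    best_len <- len[best_i]
    history <- numeric(0)
    stall <- 0L
    gens_run <- 0L

    for (g in seq_len(G) - 1L) {
      gens_run <- g + 1L
      pm <- if (cfg$adaptive_mutation) mutation_rate(g, cfg) else cfg$mutation_start
      rank <- order(len)
      elites <- popm[rank[seq_len(cfg$elite_count)], , drop = FALSE]
      n_child <- N - cfg$elite_count
      ## tournament selection, argmin length, ties to the first candidate
      cand <- matrix(sample.int(N, 2 * n_child * cfg$tournament_size,
                                replace = TRUE),
                     ncol = cfg$tournament_size)
      win <- cand[cbind(seq_len(nrow(cand)),
                        max.col(-matrix(len[cand], ncol = cfg$tournament_size),
                                ties.method = "first"))]
      p1 <- win[seq_len(n_child)]
      p2 <- win[n_child + seq_len(n_child)]
      do_cx <- runif(n_child) < cfg$crossover_rate
      do_mut <- runif(n_child) < pm
      children <- matrix(0L, n_child, n)
      for (i in seq_len(n_child)) {
        ch <- if (do_cx[i]) ox_crossover(popm[p1[i], ], popm[p2[i], ])
              else popm[p1[i], ]
        if (do_mut[i]) ch <- mutate_order(ch, cfg$mutation_op)
        children[i, ] <- ch
      }
      popm <- rbind(elites, children)
      len <- population_lengths(dm, popm)
      if (cfg$use_two_opt && cfg$two_opt_every > 0 &&
          g %% cfg$two_opt_every == 0) {
        bi <- which.min(len)
        imp <- two_opt_order(dm, popm[bi, ])
        popm[bi, ] <- imp
        len[bi] <- closed_length_dm(dm, imp)
      }
      gen_best_i <- which.min(len)
      if (len[gen_best_i] < best_len - 1e-9) {
        best_len <- len[gen_best_i]
        best_order <- popm[gen_best_i, ]
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      history <- c(history, best_len)
      if (stall >= cfg$stagnation_patience) break
    }
    if (cfg$use_two_opt) {
      polished <- two_opt_order(dm, best_order)
      pl <- closed_length_dm(dm, polished)
      if (pl < best_len) {
        best_order <- polished
        best_len <- pl
      }
    }
    list(order = best_order, history = history, gens_run = gens_run)
  })

  out <- new_tour(points, res$order, "genetic",
                  params = list(population_size = N, max_generations = G,
                                generations_run = res$gens_run,
                                seed = eff_seed, config = cfg))
  attr(out, "history") <- res$history
  out
}
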