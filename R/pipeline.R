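# End-to-end adaptive planner and the benchmark harness.

#' Plan a picking tour adaptively
#'
#' The full adaptive pipeline for one harvest category of a scene: compute
#' the scene statistics and complexity score, select a planner with the
#' decision-tree gate, and run it. When the genetic planner is selected its
#' budgets come from [dynamic_ga_params()] unless an explicit [ga_config()]
#' is given, and the initial population always contains the reciprocating
#' and nearest-neighbour tours — elitism then guarantees the returned closed
#' length never exceeds either construction. A single-waypoint scene
#' returns the trivial tour. The result is fully reproducible from
#' `(scene, configs, seed)`.
#'
#' @param scene A [rose_scene][new_scene].
#' @param category `"bloom"`, `"bud"` or `"combined"`.
#' @param gate_cfg A [gate_config()].
#' @param ga_cfg A [ga_config()], or `NULL` for the adaptive budgets.
#' @param band_height Band height for the reciprocating traversal, or
#'   `NULL` for one tenth of the image height.
#' @param seed RNG seed (used only when the genetic planner runs).
#' @return A `rose_plan` object: the complexity report, the tour, the
#'   planner provenance and the wall-clock runtime (informational only).
#'   Supports [tidy()], [glance()], [ggplot2::autoplot()].
#' @export
rose_plan <- function(scene, category = c("combined", "bloom", "bud"),
                      gate_cfg = gate_config(), ga_cfg = NULL,
                      band_height = NULL, seed = 1L) {
  category <- match.arg(category)
  points <- scene_points(scene, category)
  if (nrow(points) == 0) abort(sprintf("Scene has no '%s' waypoints.", category))
  dims <- scene_dims(scene)
  if (is.null(band_height)) band_height <- dims[["height"]] / 10
  report <- assess_scene(scene, category, gate_cfg)

  t0 <- proc.time()[["elapsed"]]
  recip <- reciprocating_tour(points, band_height)
  ga_params <- NULL
  if (report$selected == "genetic") {
    nn <- nearest_neighbor_tour(points, 1L)
    cfg <- ga_cfg %||% ga_config()
    tour <- ga_tour(points, cfg, seed = seed,
                    seed_tours = list(tour_order(recip), tour_order(nn)))
    ga_params <- attr(tour, "params")
  } else {
    tour <- recip
  }
  runtime <- proc.time()[["elapsed"]] - t0

  structure(
    list(category = category, report = report, tour = tour,
         planner_used = report$selected, ga_params = ga_params,
         reciprocating_length = tour_len(recip),
         runtime = runtime, seed = seed),
    class = "rose_plan"
  )
}

#' @export
print.rose_plan <- function(x, ...) {
  cat(sprintf(
    paste0("<rose_plan> %s: n = %d, c = %.3f -> %s planner\n",
           "  closed length %.2f px (reciprocating %.2f px), %.4f s\n"),
    x$category, x$report$n, x$report$c, x$planner_used,
    tour_len(x$tour), x$reciprocating_length, x$runtime
  ))
  invisible(x)
}

#' @method tidy rose_plan
#' @export
tidy.rose_plan <- function(x, ...) {
  tibble::as_tibble(x$tour)
}

#' @method glance rose_plan
#' @export
glance.rose_plan <- function(x, ...) {
  tibble::tibble(
    category = x$category, n = x$report$n, rho = x$report$rho,
    d_bar = x$report$d_bar, c = x$report$c,
    planner = x$planner_used,
    closed_length = tour_len(x$tour),
    open_length = tour_len(x$tour, closed = FALSE),
    reciprocating_length = x$reciprocating_length,
    runtime = x$runtime, seed = x$seed
  )
}

#' Plot a planned path over its scene
#'
#' Numbered waypoints joined by the visiting order; the closing edge back to
#' the start is dashed. An optional raster (e.g. from [png::readPNG()]) is
#' drawn underneath.
#'
#' @param scene A [rose_scene][new_scene] (provides image bounds and class
#'   colouring).
#' @param plan A `rose_plan` or `rose_tour` planned on this scene's points
#'   (matching `scene_points(scene, category)`).
#' @param category Category the tour was planned on.
#' @param image Optional raster array used as background.
#' @return A ggplot object.
#' @export
plot_path <- function(scene, plan, category = NULL, image = NULL) {
  if (inherits(plan, "rose_plan")) {
    category <- plan$category
    tour <- plan$tour
  } else {
    tour <- plan
    category <- category %||% "combined"
  }
  pts <- scene_points(scene, category)
  if (nrow(tour) != nrow(pts) ||
      !isTRUE(all.equal(unname(as.matrix(tour[order(tour$idx), c("x", "y")])),
                        unname(as.matrix(pts[sort(tour$idx), ])),
                        tolerance = 1e-8))) {
    abort("Tour does not index this scene's waypoints.")
  }
  dims <- scene_dims(scene)
  seq_df <- tibble::as_tibble(tour)
  close_df <- seq_df[c(nrow(seq_df), 1), ]
  cls <- scene$class[if (category == "combined") tour$idx else
    which(scene$class == category)[tour$idx]]
  seq_df$class <- cls
  p <- ggplot2::ggplot(seq_df, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(image)) {
    p <- p + ggplot2::annotation_raster(image, 0, dims[["width"]],
                                        -dims[["height"]], 0)
  }
  p +
    ggplot2::geom_path(colour = "grey30") +
    ggplot2::geom_path(data = close_df, colour = "grey30", linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$step),
                       size = 2.5, vjust = -1) +
    ggplot2::scale_y_reverse(limits = c(dims[["height"]], 0)) +
    ggplot2::scale_x_continuous(limits = c(0, dims[["width"]])) +
    ggplot2::scale_colour_manual(
      values = c(bloom = "#D6604D", bud = "#4393C3"), drop = TRUE
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot rose_plan
#' @export
autoplot.rose_plan <- function(object, ...) {
  seq_df <- tibble::as_tibble(object$tour)
  close_df <- seq_df[c(nrow(seq_df), 1), ]
  ggplot2::ggplot(seq_df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "grey30") +
    ggplot2::geom_path(data = close_df, colour = "grey30", linetype = "dashed") +
    ggplot2::geom_point(colour = "#D6604D", size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$step), size = 2.5, vjust = -1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s planner, closed length %.1f px",
                      object$planner_used, tour_len(object$tour)),
      x = "x (px)", y = "y (px)"
    ) +
    ggplot2::theme_minimal()
}

plan_with_strategy <- function(points, strategy, band_height, seed) {
  n <- nrow(points)
  if (n == 1) {
    return(list(length = 0, planner = strategy))
  }
  tour <- switch(strategy,
    reciprocating = reciprocating_tour(points, band_height),
    aco = aco_tour(points, aco_config(), seed = seed),
    # standard-GA baseline: conventional fixed budgets, none of the hybrid
    # planner's additions (greedy seeding, 2-opt, mutation decay, adaptive
    # budgets, early stopping)
    ga_plain = ga_tour(
      points,
      ga_config(population_size = 50, max_generations = 200,
                greedy_seed_fraction = 0, use_two_opt = FALSE,
                adaptive_mutation = FALSE, stagnation_patience = 200),
      seed = seed
    ),
    abort(sprintf("Unknown strategy '%s'.", strategy))
  )
  list(length = tour_len(tour), planner = attr(tour, "planner"))
}

#' Benchmark planning strategies over a scene set
#'
#' Mirrors a planner-comparison design: every strategy plans the same
#' scenes (identical detection-point totals), blooms and buds are planned
#' as separate tours per scene, and per-scene closed lengths are summed and
#' aggregated per strategy. `"rose"` is the full adaptive pipeline;
#' `"ga_plain"` is the ablated plain-GA baseline (no greedy seeding, no
#' 2-opt, constant mutation rate); `"reciprocating"` and `"aco"` are the
#' traversal and ant-system baselines. Deterministic for a fixed seed.
#'
#' @param scenes List of [rose_scene][new_scene] objects (>= 1).
#' @param strategies Subset of
#'   `c("reciprocating", "aco", "ga_plain", "rose")`.
#' @param gate_cfg A [gate_config()] (used by `"rose"`).
#' @param seed Master RNG seed; per-scene/strategy sub-seeds are derived
#'   from it.
#' @return A `rose_benchmark` object: `$summary` (one row per strategy:
#'   scene count, bud/bloom totals, mean runtime, mean closed length) and
#'   `$per_scene` (per-scene audit rows). Supports [tidy()], [glance()],
#'   [ggplot2::autoplot()].
#' @export
run_benchmark <- function(scenes,
                          strategies = c("reciprocating", "ga_plain", "rose"),
                          gate_cfg = gate_config(), seed = 1L) {
  if (!length(scenes)) abort("Need at least one scene.")
  known <- c("reciprocating", "aco", "ga_plain", "rose")
  bad <- setdiff(strategies, known)
  if (length(bad)) abort(sprintf("Unknown strategy name(s): %s.",
                                 paste(bad, collapse = ", ")))
  n_s <- length(scenes)
  seeds <- matrix(derive_seeds(seed, n_s * length(strategies) * 2),
                  nrow = n_s)
  rows <- list()
  for (si in seq_len(n_s)) {
    sc <- scenes[[si]]
    dims <- scene_dims(sc)
    band <- dims[["height"]] / 10
    for (ki in seq_along(strategies)) {
      strat <- strategies[ki]
      for (ci in 1:2) {
        cat_name <- c("bloom", "bud")[ci]
        pts <- scene_points(sc, cat_name)
        if (nrow(pts) == 0) next
        sub_seed <- seeds[si, (ki - 1) * 2 + ci]
        t0 <- proc.time()[["elapsed"]]
        if (strat == "rose") {
          pl <- rose_plan(sc, cat_name, gate_cfg = gate_cfg, seed = sub_seed)
          len <- tour_len(pl$tour)
          planner <- pl$planner_used
        } else {
          res <- plan_with_strategy(pts, strat, band, sub_seed)
          len <- res$length
          planner <- res$planner
        }
        rt <- proc.time()[["elapsed"]] - t0
        rows[[length(rows) + 1]] <- tibble::tibble(
          scene_id = si, strategy = strat, category = cat_name,
          n = nrow(pts), closed_length = len, runtime = rt,
          planner_used = planner
        )
      }
    }
  }
  per_scene <- dplyr::bind_rows(rows)
  totals <- per_scene |>
    dplyr::filter(.data$strategy == strategies[1]) |>
    dplyr::summarise(
      n_bud = sum(.data$n[.data$category == "bud"]),
      n_bloom = sum(.data$n[.data$category == "bloom"])
    )
  summary <- per_scene |>
    dplyr::group_by(.data$strategy, .data$scene_id) |>
    dplyr::summarise(
      scene_length = sum(.data$closed_length),
      scene_runtime = sum(.data$runtime), .groups = "drop_last"
    ) |>
    dplyr::summarise(
      n_scenes = dplyr::n(),
      mean_runtime = mean(.data$scene_runtime),
      mean_closed_length = mean(.data$scene_length), .groups = "drop"
    ) |>
    dplyr::mutate(n_bud = totals$n_bud, n_bloom = totals$n_bloom) |>
    dplyr::select("strategy", "n_scenes", "n_bud", "n_bloom",
                  "mean_runtime", "mean_closed_length") |>
    dplyr::arrange(match(.data$strategy, known))
  structure(list(summary = summary, per_scene = per_scene, seed = seed),
            class = "rose_benchmark")
}

#' @export
print.rose_benchmark <- function(x, ...) {
  cat(sprintf("<rose_benchmark> %d scene(s), %d strategy(ies)\n",
              length(unique(x$per_scene$scene_id)), nrow(x$summary)))
  print(x$summary)
  invisible(x)
}

#' @method tidy rose_benchmark
#' @export
tidy.rose_benchmark <- function(x, ...) x$per_scene

#' @method glance rose_benchmark
#' @export
glance.rose_benchmark <- function(x, ...) x$summary

#' @method autoplot rose_benchmark
#' @export
autoplot.rose_benchmark <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = stats::reorder(.data$strategy, .data$mean_closed_length),
                 y = .data$mean_closed_length)
  ) +
    ggplot2::geom_col(fill = "#4393C3") +
    ggplot2::labs(x = NULL, y = "mean closed tour length (px)") +
    ggplot2::theme_minimal()
}
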