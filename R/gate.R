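# Scene-complexity model and the decision-tree planner gate.

#' Gate configuration
#'
#' Parameters of the scene-complexity score and the decision tree that
#' switches between the reciprocating traversal and the genetic planner.
#' The score is
#' \deqn{c = w_{time} \frac{\rho}{1+\rho} + w_{dist} \frac{\bar d}{1+\bar d}}
#' with target density \eqn{\rho} and (normalized) mean pairwise distance
#' \eqn{\bar d}; both saturating terms lie in \[0, 1) so \eqn{c} does too.
#'
#' Density is measured per reference tile rather than per raw pixel: with the
#' default `density_ref_frac = 0.01` (one percent of the image area),
#' \eqn{\rho} is the number of targets per 1%-tile, i.e. `n / 100` for any
#' image size, which keeps the saturating term in a useful range. A fixed
#' tile in pixels squared can be set via `density_ref_area` instead. The mean
#' pairwise distance is divided by the image diagonal before entering the
#' score (`distance_norm = "diagonal"`), again to avoid saturation; raw
#' pixels are available with `"none"`.
#'
#' @param w_time,w_distance Score weights (must sum to 1). Defaults 0.6 / 0.4.
#' @param n_low Below this count the reciprocating planner is always chosen
#'   (default 3, i.e. the rule `n < 3`).
#' @param n_high Above this count the genetic planner is always chosen
#'   (default 20, i.e. the rule `n > 20`).
#' @param c_threshold Score threshold for the mid-range rule `c <= 0.4`.
#' @param bud_density_threshold Density threshold of the bud override
#'   (`rho > 0.5` forces the genetic planner for bud scenes in mid range).
#' @param density_ref_frac Reference tile as a fraction of the image area.
#' @param density_ref_area Reference tile in pixels squared; overrides
#'   `density_ref_frac` when non-`NULL`.
#' @param distance_norm `"diagonal"` or `"none"`.
#' @param pair_method `"all_pairs"` (mean over all unordered pairs, the
#'   default reading of average Euclidean distance) or
#'   `"nearest_neighbor"` (mean nearest-neighbour distance).
#' @return A `gate_config` list.
#' @export
gate_config <- function(w_time = 0.6, w_distance = 0.4,
                        n_low = 3, n_high = 20,
                        c_threshold = 0.4, bud_density_threshold = 0.5,
                        density_ref_frac = 0.01, density_ref_area = NULL,
                        distance_norm = c("diagonal", "none"),
                        pair_method = c("all_pairs", "nearest_neighbor")) {
  if (abs(w_time + w_distance - 1) > 1e-12) {
    abort("`w_time` + `w_distance` must equal 1.")
  }
  if (any(c(n_low, n_high, c_threshold, bud_density_threshold,
            density_ref_frac) <= 0)) {
    abort("Gate thresholds must be positive.")
  }
  structure(
    list(
      w_time = w_time, w_distance = w_distance,
      n_low = n_low, n_high = n_high,
      c_threshold = c_threshold,
      bud_density_threshold = bud_density_threshold,
      density_ref_frac = density_ref_frac,
      density_ref_area = density_ref_area,
      distance_norm = match.arg(distance_norm),
      pair_method = match.arg(pair_method)
    ),
    class = "gate_config"
  )
}

#' Read / write a gate configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg A [gate_config()].
#' @return `read_gate_config()` a `gate_config`; `write_gate_config()` the
#'   path, invisibly.
#' @export
read_gate_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(gate_config, vals)
}

#' @rdname read_gate_config
#' @export
write_gate_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Scene statistics feeding the complexity score
#'
#' Computes the waypoint count `n`, the density `rho` (targets per reference
#' tile), the mean pairwise Euclidean distance `d_bar` in coordinate units
#' (0 when `n < 2`), and its normalized version `d_norm` that enters the
#' score.
#'
#' @param points Data frame with `x`, `y` columns.
#' @param image_width,image_height Workspace dimensions in pixels.
#' @param cfg A [gate_config()].
#' @return A one-row tibble: `n`, `rho`, `d_bar`, `d_norm`,
#'   `density_ref_area`.
#' @examples
#' scene_stats(data.frame(x = c(0, 3), y = c(0, 4)), 100, 100)
#' @export
scene_stats <- function(points, image_width, image_height, cfg = gate_config()) {
  if (image_width <= 0 || image_height <= 0) {
    abort("Image dimensions must be positive.")
  }
  pts <- as_points_matrix(points)
  n <- nrow(pts)
  area <- image_width * image_height
  ref_area <- cfg$density_ref_area %||% (cfg$density_ref_frac * area)
  rho <- n / (area / ref_area)
  d_bar <- if (n < 2) 0 else {
    d <- stats::dist(pts)
    if (cfg$pair_method == "all_pairs") {
      mean(d)
    } else {
      dm <- as.matrix(d)
      diag(dm) <- Inf
      mean(apply(dm, 1, min))
    }
  }
  d_norm <- switch(cfg$distance_norm,
    diagonal = d_bar / sqrt(image_width^2 + image_height^2),
    none = d_bar
  )
  tibble::tibble(n = n, rho = rho, d_bar = d_bar, d_norm = d_norm,
                 density_ref_area = ref_area)
}

#' Scene-complexity score
#'
#' `w_time * rho/(1+rho) + w_distance * d/(1+d)`: a weighted sum of two
#' saturating transforms, dimensionless, strictly increasing in each
#' argument and bounded in \[0, 1). `d_bar` is expected on the normalized
#' scale produced by [scene_stats()] (`d_norm`).
#'
#' @param rho Density (non-negative; vectorized).
#' @param d_bar Normalized mean pairwise distance (non-negative; vectorized).
#' @param cfg A [gate_config()] supplying the weights.
#' @return Numeric score(s) in \[0, 1).
#' @examples
#' complexity_score(1, 1) # 0.6 * 0.5 + 0.4 * 0.5 = 0.5
#' @export
complexity_score <- function(rho, d_bar, cfg = gate_config()) {
  if (any(rho < 0) || any(d_bar < 0)) {
    abort("`rho` and `d_bar` must be non-negative.")
  }
  cfg$w_time * rho / (1 + rho) + cfg$w_distance * d_bar / (1 + d_bar)
}

#' Decision-tree planner selection
#'
#' Transcribes the gating pseudocode literally: scenes with `n < n_low`
#' always take the reciprocating traversal; scenes with `n > n_high` always
#' take the genetic planner; in between the score decides
#' (`reciprocating` iff `c <= c_threshold`), except that bud scenes with
#' `rho > bud_density_threshold` are forced to the genetic planner. Boundary
#' semantics follow the operators exactly (`<`, `>`, `<=`, `>`). Every
#' admissible input maps to exactly one planner.
#'
#' @param n Waypoint count (>= 1; vectorized).
#' @param c Complexity score (vectorized).
#' @param rho Density on the configured reference scale (vectorized).
#' @param category `"bloom"` or `"bud"` (recycled).
#' @param cfg A [gate_config()].
#' @return Character vector, `"reciprocating"` or `"genetic"`.
#' @export
select_algorithm <- function(n, c, rho, category = "bloom", cfg = gate_config()) {
  if (any(n < 1)) abort("Planning is undefined for an empty scene (`n` >= 1).")
  args <- vctrs_recycle(n = n, c = c, rho = rho, category = category)
  mid_initial <- ifelse(args$c <= cfg$c_threshold, "reciprocating", "genetic")
  mid <- ifelse(args$category == "bud" & args$rho > cfg$bud_density_threshold,
                "genetic", mid_initial)
  ifelse(args$n < cfg$n_low, "reciprocating",
         ifelse(args$n > cfg$n_high, "genetic", mid))
}

# Minimal common-length recycling for the vectorized gate.
vctrs_recycle <- function(...) {
  args <- list(...)
  len <- max(lengths(args))
  lapply(args, function(a) rep_len(a, len))
}

#' Assess a scene: statistics, score and planner choice
#'
#' Convenience wrapper producing the full complexity report for one harvest
#' category of a scene.
#'
#' @param scene A [rose_scene][new_scene].
#' @param category `"bloom"`, `"bud"` or `"combined"` (the override only
#'   applies when the category is `"bud"`).
#' @param cfg A [gate_config()].
#' @return A one-row tibble: `category`, `n`, `rho`, `d_bar`, `d_norm`, `c`,
#'   `selected`, `density_ref_area`.
#' @export
assess_scene <- function(scene, category = c("combined", "bloom", "bud"),
                         cfg = gate_config()) {
  category <- match.arg(category)
  pts <- scene_points(scene, category)
  if (nrow(pts) == 0) abort(sprintf("Scene has no '%s' waypoints.", category))
  dims <- scene_dims(scene)
  st <- scene_stats(pts, dims[["width"]], dims[["height"]], cfg)
  score <- complexity_score(st$rho, st$d_norm, cfg)
  sel <- select_algorithm(st$n, score, st$rho, category, cfg)
  tibble::tibble(
    category = category, n = st$n, rho = st$rho,
    d_bar = st$d_bar, d_norm = st$d_norm, c = score,
    selected = sel, density_ref_area = st$density_ref_area
  )
}
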