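# Synthetic flower-field scenes: uniform blooms, Thomas-clustered buds.

#' Synthetic scene specification
#'
#' Describes one simulated flower field. Blooms follow a uniform Poisson
#' process over the image; buds follow a Thomas cluster process (uniform
#' Poisson parents, Gaussian-scattered offspring), matching the field
#' structure of rose stands where buds are small, numerous and tightly
#' clustered while open blooms are sparser. The default expected counts
#' (21 buds, 6 blooms per image) follow the per-image averages implied by a
#' 288-image validation survey of detected targets (6114 buds, 1816
#' blooms); buds outnumber blooms by default.
#'
#' @param image_width,image_height Scene dimensions in pixels.
#' @param bloom_count_mean,bud_count_mean Expected (Poisson) counts per
#'   scene; `bud_count_mean >= bloom_count_mean` expected by default.
#' @param bud_cluster_count Expected number of cluster parents (>= 1 parent
#'   is forced whenever buds are drawn).
#' @param bud_cluster_sd Within-cluster Gaussian spread in pixels.
#' @param min_separation Minimum pairwise distance between generated points
#'   in pixels (enforced by bounded rejection; infeasible packings error).
#' @param seed Default RNG seed.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(image_width = 640, image_height = 640,
                       bloom_count_mean = 6, bud_count_mean = 21,
                       bud_cluster_count = 4, bud_cluster_sd = 25,
                       min_separation = 4, seed = NULL) {
  if (image_width <= 0 || image_height <= 0) {
    abort("Scene dimensions must be positive.")
  }
  if (bloom_count_mean < 0 || bud_count_mean < 0 || min_separation < 0 ||
      bud_cluster_count < 1 || bud_cluster_sd <= 0) {
    abort("Invalid scene_spec parameter.")
  }
  structure(
    list(image_width = image_width, image_height = image_height,
         bloom_count_mean = bloom_count_mean, bud_count_mean = bud_count_mean,
         bud_cluster_count = bud_cluster_count, bud_cluster_sd = bud_cluster_sd,
         min_separation = min_separation, seed = seed),
    class = "scene_spec"
  )
}

# Place `k` points by a position sampler (called with the point index),
# rejecting draws out of bounds or closer than min_sep to any accepted
# point. Errors when packing fails.
place_points <- function(k, sampler, width, height, min_sep, max_tries = 200) {
  if (k == 0) return(matrix(numeric(0), 0, 2))
  acc <- matrix(NA_real_, k, 2)
  n_acc <- 0L
  for (i in seq_len(k)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- sampler(i)
      if (p[1] < 0 || p[1] > width || p[2] < 0 || p[2] > height) next
      if (n_acc > 0 && min_sep > 0) {
        d2 <- (acc[seq_len(n_acc), 1] - p[1])^2 + (acc[seq_len(n_acc), 2] - p[2])^2
        if (min(d2) < min_sep^2) next
      }
      n_acc <- n_acc + 1L
      acc[n_acc, ] <- p
      placed <- TRUE
      break
    }
    if (!placed) {
      abort(sprintf(
        "Could not place point %d of %d with min_separation %g after %d tries.",
        i, k, min_sep, max_tries
      ))
    }
  }
  acc
}

#' Generate a synthetic detection scene
#'
#' Draws bloom and bud waypoints from the scene specification's point processes,
#' rejection-resampled to stay inside the image and respect
#' `min_separation`. Synthetic bounding boxes get fixed extents (30 x 30 px
#' blooms, 14 x 14 px buds) purely so the scene round-trips through YOLO
#' label files; planning uses centers only. Deterministic per seed.
#'
#' @param spec A [scene_spec()].
#' @param seed RNG seed (takes precedence over `spec$seed`).
#' @return A [rose_scene][new_scene].
#' @export
generate_scene <- function(spec = scene_spec(), seed = NULL) {
  eff_seed <- seed %||% spec$seed
  W <- spec$image_width
  H <- spec$image_height
  with_seed_(eff_seed, {
    n_bloom <- rpois(1, spec$bloom_count_mean)
    blooms <- place_points(
      n_bloom, function(i) c(runif(1, 0, W), runif(1, 0, H)),
      W, H, spec$min_separation
    )
    n_bud <- rpois(1, spec$bud_count_mean)
    buds <- matrix(numeric(0), 0, 2)
    if (n_bud > 0) {
      n_par <- max(1L, rpois(1, spec$bud_cluster_count))
      parents <- cbind(runif(n_par, 0, W), runif(n_par, 0, H))
      assign_par <- sample.int(n_par, n_bud, replace = TRUE)
      buds <- place_points(
        n_bud,
        function(i) {
          # resamples reuse bud i's assigned parent
          parents[assign_par[i], ] + rnorm(2, 0, spec$bud_cluster_sd)
        },
        W, H, spec$min_separation
      )
    }
    det <- dplyr::bind_rows(
      tibble::tibble(class = "bloom",
                     x = blooms[, 1], y = blooms[, 2], w = 30, h = 30),
      tibble::tibble(class = "bud",
                     x = buds[, 1], y = buds[, 2], w = 14, h = 14)
    )
    # boxes must renormalize to [0, 1]; shrink those overhanging the border
    det$w <- pmin(det$w, 2 * pmin(det$x, W - det$x) + 1e-9, W)
    det$h <- pmin(det$h, 2 * pmin(det$y, H - det$y) + 1e-9, H)
    det$w <- pmax(det$w, 1e-6)
    det$h <- pmax(det$h, 1e-6)
    new_scene(det, W, H)
  })
}

#' Named scene-suite profiles
#'
#' Preset parameterisations spanning the planner's operating range
#' (n from 2 to ~200):
#' `"sparse"` (few targets, n < 10 guaranteed by truncated resampling),
#' `"dense"` (many overlapping targets), `"clustered_buds"` (tight bud
#' clusters, sparse blooms), `"large_scene"` (bigger workspace, up to ~200
#' targets), and `"gate_boundary"` (fixed counts 2, 3, 20, 21 plus
#' mid-range sparse/dense scenes straddling the score threshold).
#'
#' @param profile Profile name.
#' @param count Number of scenes (>= 1).
#' @param seed RNG seed for the whole suite.
#' @return A list of [rose_scene][new_scene] objects.
#' @export
scene_suite <- function(profile = c("sparse", "dense", "clustered_buds",
                                    "large_scene", "gate_boundary"),
                        count = 10, seed = 1) {
  profile <- match.arg(profile)
  if (count < 1) abort("`count` must be >= 1.")
  seeds <- derive_seeds(seed, count)
  purrr::map(seq_len(count), function(i) {
    generate_profile_scene(profile, i, seeds[i])
  })
}

generate_profile_scene <- function(profile, i, seed) {
  switch(profile,
    sparse = {
      sp <- scene_spec(bloom_count_mean = 2, bud_count_mean = 3,
                       bud_cluster_count = 2, bud_cluster_sd = 60)
      # preset contract: sparse scenes keep 2 <= n < 10 (truncated resampling)
      for (try in seq_len(100)) {
        sc <- generate_scene(sp, seed = (seed + try - 1) %% .Machine$integer.max)
        if (nrow(sc) >= 2 && nrow(sc) < 10) return(sc)
      }
      abort("sparse profile: could not draw a scene with 2 <= n < 10.")
    },
    dense = generate_scene(
      scene_spec(bloom_count_mean = 10, bud_count_mean = 40,
                 bud_cluster_count = 6, bud_cluster_sd = 18),
      seed = seed
    ),
    clustered_buds = generate_scene(
      scene_spec(bloom_count_mean = 4, bud_count_mean = 45,
                 bud_cluster_count = 3, bud_cluster_sd = 12),
      seed = seed
    ),
    large_scene = generate_scene(
      scene_spec(image_width = 1280, image_height = 960,
                 bloom_count_mean = 25, bud_count_mean = 100,
                 bud_cluster_count = 8, bud_cluster_sd = 30),
      seed = seed
    ),
    gate_boundary = {
      # cycle through fixed-count scenes hitting every decision branch
      kinds <- list(
        list(n_bud = 2, n_bloom = 0, sd = 120),   # n < 3
        list(n_bud = 3, n_bloom = 0, sd = 120),   # lower mid boundary
        list(n_bud = 0, n_bloom = 20, sd = NA),   # upper mid boundary
        list(n_bud = 21, n_bloom = 0, sd = 20),   # n > 20
        list(n_bud = 0, n_bloom = 10, sd = NA),   # mid, sparse blooms
        list(n_bud = 10, n_bloom = 0, sd = 10)    # mid, tight bud cluster
      )
      k <- kinds[[(i - 1) %% length(kinds) + 1]]
      fixed_count_scene(k$n_bud, k$n_bloom, k$sd, seed)
    }
  )
}

# Exact-count scene used for gate-boundary coverage: blooms uniform, buds in
# one Gaussian cluster of the given sd (uniform if sd is NA).
fixed_count_scene <- function(n_bud, n_bloom, sd, seed,
                              width = 640, height = 640) {
  with_seed_(seed, {
    blooms <- cbind(runif(n_bloom, 0, width), runif(n_bloom, 0, height))
    buds <- if (n_bud > 0) {
      if (is.na(sd)) {
        cbind(runif(n_bud, 0, width), runif(n_bud, 0, height))
      } else {
        ctr <- c(runif(1, width * 0.3, width * 0.7),
                 runif(1, height * 0.3, height * 0.7))
        m <- cbind(rnorm(n_bud, ctr[1], sd), rnorm(n_bud, ctr[2], sd))
        m[, 1] <- clamp(m[, 1], 0, width)
        m[, 2] <- clamp(m[, 2], 0, height)
        m
      }
    } else matrix(numeric(0), 0, 2)
    det <- dplyr::bind_rows(
      tibble::tibble(class = "bloom", x = blooms[, 1], y = blooms[, 2],
                     w = 30, h = 30),
      tibble::tibble(class = "bud", x = buds[, 1], y = buds[, 2],
                     w = 14, h = 14)
    )
    det$w <- pmax(pmin(det$w, 2 * pmin(det$x, width - det$x) + 1e-9), 1e-6)
    det$h <- pmax(pmin(det$h, 2 * pmin(det$y, height - det$y) + 1e-9), 1e-6)
    new_scene(det, width, height)
  })
}

#' Mixed benchmark suite
#'
#' The default scene set for planner comparisons: a fixed mixture of the
#' named profiles (72 sparse, 72 dense, 96 clustered-bud, 36 large-scene and
#' 12 gate-boundary scenes for the default 288 — matching the size of the
#' validation survey the planners are benchmarked against; other totals are
#' split proportionally).
#'
#' @param n_scenes Total number of scenes (>= 5).
#' @param seed RNG seed.
#' @return A list of [rose_scene][new_scene] objects.
#' @export
benchmark_suite <- function(n_scenes = 288, seed = 1) {
  if (n_scenes < 5) abort("`n_scenes` must be >= 5.")
  frac <- c(sparse = 72, dense = 72, clustered_buds = 96,
            large_scene = 36, gate_boundary = 12) / 288
  counts <- pmax(round(frac * n_scenes), 1)
  seeds <- derive_seeds(seed, length(counts))
  out <- purrr::imap(counts, function(k, prof) {
    scene_suite(prof, count = k, seed = seeds[match(prof, names(counts))])
  })
  unlist(unname(out), recursive = FALSE)
}

#' Clark–Evans aggregation index
#'
#' Ratio of the observed mean nearest-neighbour distance to the expectation
#' `0.5 / sqrt(n / area)` under complete spatial randomness. Values below 1
#' indicate clustering, near 1 randomness. Used as a distributional sanity
#' check on the generator (clustered bud patterns score < 1, uniform bloom
#' patterns near 1).
#'
#' @param points Data frame with `x`, `y` (n >= 2).
#' @param image_width,image_height Workspace dimensions in pixels.
#' @return The index (single number).
#' @export
clark_evans_index <- function(points, image_width, image_height) {
  pts <- as_points_matrix(points)
  n <- nrow(pts)
  if (n < 2) abort("Need at least two points.")
  dm <- dist_matrix(pts)
  diag(dm) <- Inf
  mean_nn <- mean(apply(dm, 1, min))
  expected <- 0.5 / sqrt(n / (image_width * image_height))
  mean_nn / expected
}

#' Export a scene as a YOLO label file with a JSON sidecar
#'
#' Writes the `.txt` label file plus `<path>.json` carrying the image
#' dimensions (and any generator parameters passed in `meta`), so synthetic
#' scenes round-trip through the same reader as real detector output.
#'
#' @param scene A [rose_scene][new_scene].
#' @param path Label-file path (`.txt`).
#' @param meta Optional named list stored in the sidecar.
#' @return `path`, invisibly.
#' @export
export_scene <- function(scene, path, meta = list()) {
  write_yolo_labels(scene, path)
  dims <- scene_dims(scene)
  sidecar <- c(list(image_width = dims[["width"]],
                    image_height = dims[["height"]]), meta)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
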