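# Reading detector outputs and the optional image-rescaling pre-step.

#' Read a YOLO label file into a scene
#'
#' Parses the one-object-per-line YOLO label format
#' `<class_id> <cx> <cy> <w> <h>` (normalized floats in \[0, 1\]) and
#' denormalizes the box centers into pixel waypoints: a detection centred at
#' `(cx, cy)` becomes the picking waypoint `(cx * image_width,
#' cy * image_height)`. Empty and whitespace-only lines are skipped;
#' `source_line` records each detection's original line number.
#'
#' @param path Path to the `.txt` label file.
#' @param image_width,image_height Dimensions of the image the labels refer
#'   to, in pixels.
#' @param class_map Named character vector mapping class ids (as written in
#'   the file) to `"bloom"` / `"bud"`.
#' @return A [rose_scene][new_scene] tibble.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines("0 0.5 0.5 0.1 0.1", f)
#' read_yolo_labels(f, 100, 100)
#' @export
read_yolo_labels <- function(path, image_width, image_height,
                             class_map = c("0" = "bloom", "1" = "bud")) {
  if (!file.exists(path)) abort(sprintf("Label file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  rows <- lapply(keep, function(i) {
    fields <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(fields) != 5) {
      abort(sprintf("Line %d of %s: expected 5 fields, got %d.",
                    i, path, length(fields)))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      abort(sprintf("Line %d of %s: non-numeric field.", i, path))
    }
    if (any(vals[2:5] < 0) || any(vals[2:5] > 1)) {
      abort(sprintf("Line %d of %s: normalized fields must lie in [0, 1].", i, path))
    }
    id <- fields[[1]]
    if (!id %in% names(class_map)) {
      abort(sprintf("Line %d of %s: class id '%s' absent from `class_map`.",
                    i, path, id))
    }
    tibble::tibble(
      class = unname(class_map[[id]]),
      x = vals[2] * image_width, y = vals[3] * image_height,
      w = vals[4] * image_width, h = vals[5] * image_height,
      source_line = i
    )
  })
  det <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(class = character(), x = double(), y = double(),
                   w = double(), h = double(), source_line = integer())
  new_scene(det, image_width, image_height)
}

#' Write a scene back to a YOLO label file
#'
#' Inverse of [read_yolo_labels()]: centers and extents are re-normalized by
#' the scene's image dimensions. Round-tripping a parsed file reproduces the
#' same scene.
#'
#' @param scene A `rose_scene`.
#' @param path Output path.
#' @param class_map Same mapping as in [read_yolo_labels()]; inverted here.
#' @param digits Significant digits written per field.
#' @return `path`, invisibly.
#' @export
write_yolo_labels <- function(scene, path,
                              class_map = c("0" = "bloom", "1" = "bud"),
                              digits = 10) {
  dims <- scene_dims(scene)
  inv <- stats::setNames(names(class_map), class_map)
  w <- ifelse(is.na(scene$w), 0, scene$w)
  h <- ifelse(is.na(scene$h), 0, scene$h)
  lines <- sprintf(
    "%s %s %s %s %s",
    inv[scene$class],
    formatC(scene$x / dims[["width"]], digits = digits, format = "g"),
    formatC(scene$y / dims[["height"]], digits = digits, format = "g"),
    formatC(w / dims[["width"]], digits = digits, format = "g"),
    formatC(h / dims[["height"]], digits = digits, format = "g")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON detection document into a scene
#'
#' Expected schema: an object with numeric `image_width` and `image_height`
#' and a `detections` array of records `{label, bbox}` where `bbox` is
#' `[x_min, y_min, x_max, y_max]` in pixels. Waypoints are box midpoints.
#' An optional per-record `score` is carried through as a column but ignored
#' by all planning (tours are planned on every detected center). Records with
#' identical boxes yield coincident waypoints; nothing is deduplicated.
#'
#' @param path Path to the JSON file.
#' @param class_map Named character vector mapping `label` values to
#'   `"bloom"` / `"bud"`; labels already equal to `"bloom"`/`"bud"` pass
#'   through unmapped.
#' @return A [rose_scene][new_scene] tibble.
#' @export
read_json_detections <- function(path, class_map = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$image_width) || is.null(doc$image_height)) {
    abort("JSON detections must carry `image_width` and `image_height`.")
  }
  dets <- doc$detections %||% list()
  rows <- lapply(seq_along(dets), function(i) {
    d <- dets[[i]]
    bb <- unlist(d$bbox)
    if (is.null(d$label) || length(bb) != 4 || anyNA(suppressWarnings(as.numeric(bb)))) {
      abort(sprintf("Detection %d: need `label` and 4-number `bbox`.", i))
    }
    bb <- as.numeric(bb)
    if (bb[3] <= bb[1] || bb[4] <= bb[2]) {
      abort(sprintf("Detection %d: malformed bbox (x_max <= x_min or y_max <= y_min).", i))
    }
    lab <- as.character(d$label)
    if (!is.null(class_map) && lab %in% names(class_map)) lab <- class_map[[lab]]
    tibble::tibble(
      class = lab,
      x = (bb[1] + bb[3]) / 2, y = (bb[2] + bb[4]) / 2,
      w = bb[3] - bb[1], h = bb[4] - bb[2],
      source_line = i,
      score = if (is.null(d$score)) NA_real_ else as.numeric(d$score)
    )
  })
  det <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(class = character(), x = double(), y = double(),
                   w = double(), h = double(), source_line = integer(),
                   score = double())
  new_scene(det, doc$image_width, doc$image_height)
}

#' Pixel-budget rescaling record
#'
#' Large captures (e.g. 4160 x 3120 phone images) are shrunk before
#' processing by a pixel-count-based dynamic scaling rule: when the pixel
#' count exceeds `pixel_budget`, both dimensions are multiplied by
#' `sqrt(pixel_budget / pixel_count)` so the working image holds about
#' `pixel_budget` pixels; images already under budget pass through with
#' factor 1 (the rule is idempotent). The record retains the original
#' dimensions so planned paths can be calibrated back to original pixel
#' coordinates via [scale_points()].
#'
#' @param image_width,image_height Original dimensions in pixels.
#' @param pixel_budget Maximum working pixel count (default 1 megapixel,
#'   `2^20`).
#' @return A one-row tibble with `original_width`, `original_height`,
#'   `working_width`, `working_height`, `factor`, `pixel_budget`.
#' @examples
#' rescale_for_processing(4160, 3120)
#' @export
rescale_for_processing <- function(image_width, image_height,
                                   pixel_budget = 2^20) {
  if (image_width <= 0 || image_height <= 0 || pixel_budget <= 0) {
    abort("Dimensions and `pixel_budget` must be positive.")
  }
  px <- image_width * image_height
  factor <- if (px <= pixel_budget) 1 else sqrt(pixel_budget / px)
  tibble::tibble(
    original_width = image_width, original_height = image_height,
    working_width = round(image_width * factor),
    working_height = round(image_height * factor),
    factor = factor, pixel_budget = pixel_budget
  )
}

#' Map points between original and working coordinates
#'
#' @param points Data frame with `x`, `y` columns.
#' @param record A record from [rescale_for_processing()].
#' @param to `"working"` multiplies by the factor, `"original"` divides.
#' @return `points` with rescaled `x`, `y` (other columns untouched).
#' @export
scale_points <- function(points, record, to = c("working", "original")) {
  to <- match.arg(to)
  f <- if (to == "working") record$factor else 1 / record$factor
  points$x <- points$x * f
  points$y <- points$y * f
  points
}

# Lanczos-3 kernel, vanishing outside |x| < a.
lanczos_kernel <- function(x, a = 3) {
  out <- numeric(length(x))
  nz <- abs(x) < a & x != 0
  out[x == 0] <- 1
  out[nz] <- a * sin(pi * x[nz]) * sin(pi * x[nz] / a) / (pi^2 * x[nz]^2)
  out
}

# Row-resampling weight matrix (n_out x n_in), rows normalized to sum 1.
lanczos_weights <- function(n_in, n_out, a = 3) {
  scale <- n_in / n_out
  centers <- (seq_len(n_out) - 0.5) * scale + 0.5 # input-space sample positions
  support <- a * max(1, scale)
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- max(1L, floor(centers[i] - support))
    hi <- min(n_in, ceiling(centers[i] + support))
    idx <- lo:hi
    w <- lanczos_kernel((idx - centers[i]) / max(1, scale), a)
    s <- sum(w)
    if (s != 0) W[i, idx] <- w / s
  }
  W
}

#' Resize an image array with Lanczos interpolation
#'
#' Separable Lanczos-3 resampling of a numeric image (matrix or
#' height x width x channels array, values on any scale). Used for the
#' optional raw-image leg of the rescaling pre-step; waypoint coordinates are
#' rescaled in closed form by [scale_points()] and do not pass through here.
#'
#' @param img Numeric matrix or 3-d array (H x W or H x W x C).
#' @param factor Resize factor (> 0); output dims are `round(dim * factor)`.
#' @param a Kernel support (default 3, the classical Lanczos-3 window).
#' @return Resized array of the same arity as `img`.
#' @export
resize_image_lanczos <- function(img, factor, a = 3) {
  if (factor <= 0) abort("`factor` must be positive.")
  d <- dim(img)
  if (is.null(d) || !length(d) %in% c(2, 3)) {
    abort("`img` must be a matrix or an H x W x C array.")
  }
  h_out <- max(1L, round(d[1] * factor))
  w_out <- max(1L, round(d[2] * factor))
  Wh <- lanczos_weights(d[1], h_out, a)
  Ww <- lanczos_weights(d[2], w_out, a)
  resize_plane <- function(m) Wh %*% m %*% t(Ww)
  if (length(d) == 2) {
    resize_plane(img)
  } else {
    out <- array(0, c(h_out, w_out, d[3]))
    for (k in seq_len(d[3])) out[, , k] <- resize_plane(img[, , k])
    out
  }
}
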