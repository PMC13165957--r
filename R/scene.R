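#' Construct a detection scene
#'
#' A scene is the planner's input universe: an image-sized workspace together
#' with the picking waypoints extracted from class-labelled detections. It is
#' stored as a tibble with one row per detection (columns `class`, `x`, `y`,
#' `w`, `h`, `source_line`) and the image geometry kept in attributes, so it
#' pipes through dplyr verbs like any other data frame.
#'
#' Coordinates are continuous pixels with the origin at the top-left corner,
#' x increasing rightwards and y downwards. Coincident duplicate detections
#' are retained: downstream planners tolerate zero-length edges.
#'
#' @param detections Data frame with at least `class`, `x`, `y`; optional
#'   `w`, `h` box extents (pixels), `source_line`, `score`. Row order is
#'   preserved.
#' @param image_width,image_height Image dimensions in pixels (positive).
#' @param scale_applied Dimensionless resize factor already applied to the
#'   coordinates (1 if none); see [rescale_for_processing()].
#' @return A `rose_scene` tibble.
#' @examples
#' sc <- new_scene(
#'   data.frame(class = c("bloom", "bud"), x = c(50, 150), y = c(25, 75)),
#'   image_width = 200, image_height = 100
#' )
#' scene_area(sc)
#' @export
new_scene <- function(detections, image_width, image_height, scale_applied = 1) {
  if (!is.numeric(image_width) || !is.numeric(image_height) ||
      length(image_width) != 1 || length(image_height) != 1 ||
      is.na(image_width) || is.na(image_height) ||
      image_width <= 0 || image_height <= 0) {
    abort("`image_width` and `image_height` must be single positive numbers.")
  }
  det <- tibble::as_tibble(detections)
  if (nrow(det) == 0 && !all(c("class", "x", "y") %in% names(det))) {
    det <- tibble::tibble(
      class = character(), x = double(), y = double(),
      w = double(), h = double(), source_line = integer()
    )
  }
  if (!all(c("class", "x", "y") %in% names(det))) {
    abort("`detections` must have `class`, `x` and `y` columns.")
  }
  bad <- !det$class %in% c("bloom", "bud")
  if (any(bad)) {
    abort(sprintf("Unknown class label(s): %s.",
                  paste(unique(det$class[bad]), collapse = ", ")))
  }
  if (!"w" %in% names(det)) det$w <- NA_real_
  if (!"h" %in% names(det)) det$h <- NA_real_
  if (!"source_line" %in% names(det)) det$source_line <- seq_len(nrow(det))
  if (any(det$x < 0 | det$x > image_width | det$y < 0 | det$y > image_height)) {
    abort("All waypoints must lie inside [0, image_width] x [0, image_height].")
  }
  if (any(!is.na(det$w) & det$w <= 0) || any(!is.na(det$h) & det$h <= 0)) {
    abort("Box extents `w` and `h` must be positive where present.")
  }
  structure(
    det,
    image_width = as.numeric(image_width),
    image_height = as.numeric(image_height),
    scale_applied = as.numeric(scale_applied),
    class = c("rose_scene", class(det))
  )
}

#' @export
print.rose_scene <- function(x, ...) {
  cat(sprintf(
    "<rose_scene> %g x %g px, %d bloom(s), %d bud(s)%s\n",
    attr(x, "image_width"), attr(x, "image_height"),
    sum(x$class == "bloom"), sum(x$class == "bud"),
    if (isTRUE(all.equal(attr(x, "scale_applied"), 1))) ""
    else sprintf(", scale %.4g", attr(x, "scale_applied"))
  ))
  NextMethod()
}

#' Scene geometry accessors
#'
#' @param scene A `rose_scene`.
#' @return `scene_area()` the workspace area in pixels squared;
#'   `scene_dims()` a named numeric vector `c(width, height)`.
#' @export
scene_area <- function(scene) {
  prod(scene_dims(scene))
}

#' @rdname scene_area
#' @export
scene_dims <- function(scene) {
  w <- attr(scene, "image_width")
  h <- attr(scene, "image_height")
  if (is.null(w) || is.null(h)) abort("Not a rose_scene: missing image dimensions.")
  c(width = w, height = h)
}

#' Extract the waypoints of one harvest category
#'
#' Blooms and buds are harvested for different uses and planned as separate
#' tours by default; `"combined"` merges both classes into one waypoint set.
#'
#' @param scene A `rose_scene`.
#' @param category `"bloom"`, `"bud"` or `"combined"`.
#' @return A tibble with columns `x`, `y` (file order preserved).
#' @export
scene_points <- function(scene, category = c("combined", "bloom", "bud")) {
  category <- match.arg(category)
  pts <- if (category == "combined") scene else scene[scene$class == category, ]
  tibble::tibble(x = pts$x, y = pts$y)
}
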