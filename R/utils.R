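# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so generators are pure functions of
#' (parameters, seed) and do not disturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_param("`%s` must be a single positive finite number", name)
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop_param("`%s` must be a single non-negative finite number", name)
  }
  invisible(x)
}

#' Derive a deterministic child seed from a root seed
#'
#' Used by the pipeline so stages can be re-run in isolation with the same
#' stream. Kept below 2^31 - 1 (R integers are 32-bit).
#' @noRd
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * index) %% 2147483647)
}

#' Field-of-view specification
#'
#' A rectangular imaging field: physical size in micrometers, the pixel size
#' of the camera, and an optional RNG seed used as the default by the
#' synthetic-data generators. The default pixel size (0.078 um) corresponds
#' to the higher-magnification camera setting; 0.119 um is the other common
#' value.
#'
#' Coordinate convention (used throughout the package): origin at the center
#' of the top-left pixel, x rightward, y downward, 0-based pixel indices;
#' pixel (row r, col c) has center (c * pixel_size, r * pixel_size) um.
#'
#' @param width,height Field extent in micrometers.
#' @param pixel_size Pixel size in micrometers per pixel.
#' @param seed Optional integer seed; generators default to it.
#' @return An object of class `field_spec`.
#' @examples
#' field_spec(50, 50)
#' @export
field_spec <- function(width, height, pixel_size = 0.078, seed = NULL) {
  check_positive(width, "width")
  check_positive(height, "height")
  check_positive(pixel_size, "pixel_size")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(width = width, height = height, pixel_size = pixel_size, seed = seed),
    class = "field_spec"
  )
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("<field_spec> %g x %g um, %g um/pixel%s\n",
              x$width, x$height, x$pixel_size,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

is_field_spec <- function(x) inherits(x, "field_spec")

assert_field <- function(field) {
  if (!is_field_spec(field)) stop_param("`field` must be a field_spec object")
  invisible(field)
}

#' Area of the convex hull of a point set (shoelace formula)
#' @noRd
convex_hull_area <- function(points) {
  h <- grDevices::chull(points[, 1], points[, 2])
  xs <- points[h, 1]; ys <- points[h, 2]
  n <- length(h)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(xs[j] * ys - xs * ys[j])) / 2
}
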