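# Network representations: snakes (ordered, intensity-bearing filament
# traces), junctions (filament crossover points) and the editing rules
# applied to traced networks before architecture metrics are computed.

#' Construct a snake (filament/cable trace)
#'
#' @param points Matrix or data.frame with columns x, y (um) and optionally
#'   intensity (counts/pixel; defaults to 0).
#' @param id Snake identifier.
#' @param closed Is the contour closed?
#' @param multiplicity Number of bundled filaments represented (used by the
#'   renderer; 1 for a single filament).
#' @param ground_truth Optional generator parameters.
#' @return A `snake` object: list(id, points, closed, multiplicity).
#' @export
snake <- function(points, id = "s1", closed = FALSE, multiplicity = 1,
                  ground_truth = NULL) {
  points <- as.matrix(points)
  if (ncol(points) == 2) points <- cbind(points, 0)
  if (ncol(points) < 3) stop_param("snake points need columns x, y[, intensity]")
  points <- points[, 1:3, drop = FALSE]
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "intensity")
  if (nrow(points) < 2) stop_param("a snake needs at least 2 points")
  seg <- diff(points[, 1:2, drop = FALSE])
  if (any(rowSums(seg^2) == 0)) stop_param("consecutive snake points must be distinct")
  if (any(points[, 3] < 0)) stop_param("snake intensities must be >= 0")
  structure(list(id = as.character(id), points = points,
                 closed = isTRUE(closed), multiplicity = multiplicity,
                 ground_truth = ground_truth),
            class = "snake")
}

#' @export
print.snake <- function(x, ...) {
  cat(sprintf("<snake %s> %d points, length %.3g um%s\n", x$id,
              nrow(x$points), snake_length(x),
              if (x$closed) ", closed" else ""))
  invisible(x)
}

#' Contour length of a snake (um)
#' @param sn A [snake()].
#' @export
snake_length <- function(sn) {
  p <- sn$points[, 1:2, drop = FALSE]
  if (sn$closed) p <- rbind(p, p[1, ])
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Construct a network model
#'
#' Snakes plus junction centroids for one field of view, with the arc-length
#' sampling distance `c` (default 0.625 um = 8 pixels at 0.078 um/pixel)
#' that the curvature and junction-fusion rules are expressed in.
#'
#' @param snakes List of [snake()] objects.
#' @param junctions data.frame with columns x, y (um) and optionally
#'   junction_id, incident_snakes (list column of snake ids).
#' @param field A [field_spec()].
#' @param c_sample Sampling distance c (um).
#' @return A `network_model` object.
#' @export
network_model <- function(snakes = list(), junctions = NULL, field,
                          c_sample = 0.625) {
  assert_field(field)
  check_positive(c_sample, "c_sample")
  junctions <- normalize_junctions(junctions)
  if (anyDuplicated(junctions$junction_id)) stop_param("junction ids must be unique")
  if (nrow(junctions) > 0) {
    inside <- junctions$x >= 0 & junctions$x <= field$width &
              junctions$y >= 0 & junctions$y <= field$height
    if (!all(inside)) stop_param("junction centroids must lie inside the field")
  }
  structure(list(snakes = snakes, junctions = junctions, field = field,
                 c_sample = c_sample),
            class = "network_model")
}

normalize_junctions <- function(junctions) {
  if (is.null(junctions) || (is.data.frame(junctions) && nrow(junctions) == 0) ||
      (is.matrix(junctions) && nrow(junctions) == 0)) {
    return(data.frame(junction_id = character(0), x = numeric(0), y = numeric(0),
                      incident_snakes = I(list())))
  }
  j <- as.data.frame(junctions)
  if (!all(c("x", "y") %in% names(j))) stop_param("junctions need columns x, y")
  if (is.null(j$junction_id)) j$junction_id <- sprintf("j%d", seq_len(nrow(j)))
  if (is.null(j$incident_snakes)) {
    j$incident_snakes <- I(replicate(nrow(j), character(0), simplify = FALSE))
  }
  j[, c("junction_id", "x", "y", "incident_snakes")]
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d snakes, %d junctions, c = %g um, %g x %g um field\n",
              length(x$snakes), nrow(x$junctions), x$c_sample,
              x$field$width, x$field$height))
  invisible(x)
}

#' Junction centroids of a network as a point pattern
#' @param net A [network_model()].
#' @return A [point_pattern()].
#' @export
junction_pattern <- function(net) {
  point_pattern(as.matrix(net$junctions[, c("x", "y")]), net$field)
}

#' Resample a polyline at constant arc-length spacing
#'
#' Linear interpolation along the cumulative arc length; the first vertex is
#' always kept and the last resampled point never overshoots the contour.
#'
#' @param points n x 2 coordinate matrix.
#' @param spacing Arc-length spacing (um).
#' @return Matrix of resampled (x, y).
#' @export
resample_polyline <- function(points, spacing) {
  check_positive(spacing, "spacing")
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  seg <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total < spacing) return(points[c(1L, nrow(points)), , drop = FALSE])
  target <- seq(0, total, by = spacing)
  cbind(x = stats::approx(s, points[, 1], xout = target, ties = "ordered")$y,
        y = stats::approx(s, points[, 2], xout = target, ties = "ordered")$y)
}

# ---------------------------------------------------------------------------
# SOAX-dialect result files

#' Parse a SOAX-style network result file
#'
#' Reads the text output of filament-tracing software: marker-prefixed
#' header lines (`#`-prefixed, or `key value` parameter lines), per-point
#' records `snake_index point_index x y z intensity` (comma- or
#' whitespace-delimited), and a trailing junction coordinate block opened by
#' a line containing "junction" (e.g. `#junctions` or `[junctions]`).
#' Coordinates are in pixels in the file and converted to micrometers.
#'
#' @param path Path to the result file.
#' @param pixel_size Pixel size (um/pixel) used for the conversion.
#' @param field Optional [field_spec()]; inferred from the coordinate extent
#'   when absent.
#' @param c_sample Sampling distance c (um) to record on the model.
#' @return A [network_model()].
#' @examples
#' path <- system.file("extdata", "example_soax.txt", package = "netarch")
#' net <- parse_soax(path, pixel_size = 0.078)
#' net
#' fuse_junctions(net)   # merges the two junctions < 1.2c apart
#' @export
parse_soax <- function(path, pixel_size = 0.078, field = NULL,
                       c_sample = 0.625) {
  if (!file.exists(path)) stop_param("file not found: %s", path)
  check_positive(pixel_size, "pixel_size")
  lines <- readLines(path, warn = FALSE)
  in_junctions <- FALSE
  pts <- list(); jct <- list()
  z_seen <- FALSE
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (raw == "") next
    if (grepl("junction", raw, ignore.case = TRUE)) { in_junctions <- TRUE; next }
    if (startsWith(raw, "#") || startsWith(raw, "[")) next
    tok <- strsplit(gsub(",", " ", raw), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(tok))
    if (is.na(num[1])) next  # header / column-name line ("key value", "s p x y ...")
    if (any(is.na(num))) {
      stop_param("malformed record at line %d of %s: '%s'", ln, path, raw)
    }
    if (in_junctions) {
      if (length(num) < 2) stop_param("malformed junction at line %d of %s", ln, path)
      jct[[length(jct) + 1L]] <- num[1:2]
      if (length(num) >= 3 && num[3] != 0) z_seen <- TRUE
    } else {
      if (length(num) < 4) stop_param("malformed snake record at line %d of %s", ln, path)
      # snake_index point_index x y [z [intensity]]
      rec <- c(num[1], num[3], num[4],
               if (length(num) >= 6) num[6] else 0)
      if (length(num) >= 5 && num[5] != 0) z_seen <- TRUE
      pts[[length(pts) + 1L]] <- rec
    }
  }
  if (z_seen) warning("nonzero z coordinates ignored (2-D analysis)")
  if (length(pts) == 0L) {
    warning("no snake records found in ", path)
    if (!in_junctions) warning("no junction block found in ", path)
    fld <- field %||% field_spec(1, 1, pixel_size)
    return(network_model(list(), NULL, fld, c_sample))
  }
  m <- do.call(rbind, pts)
  snakes <- lapply(split(seq_len(nrow(m)), m[, 1]), function(i) {
    snake(cbind(m[i, 2] * pixel_size, m[i, 3] * pixel_size, m[i, 4]),
          id = sprintf("s%g", m[i[1], 1]))
  })
  names(snakes) <- NULL
  junctions <- if (length(jct)) {
    jm <- do.call(rbind, jct) * pixel_size
    data.frame(x = jm[, 1], y = jm[, 2])
  } else {
    warning("no junction block found in ", path)
    NULL
  }
  if (is.null(field)) {
    allx <- c(unlist(lapply(snakes, function(s) s$points[, 1])),
              if (!is.null(junctions)) junctions$x)
    ally <- c(unlist(lapply(snakes, function(s) s$points[, 2])),
              if (!is.null(junctions)) junctions$y)
    field <- field_spec(max(allx) + pixel_size, max(ally) + pixel_size, pixel_size)
  }
  net <- network_model(snakes, junctions, field, c_sample)
  if (nrow(net$junctions) > 0 &&
      all(lengths(net$junctions$incident_snakes) == 0)) {
    net <- link_junctions(net)
  }
  net
}

#' Recompute junction-snake incidence geometrically
#'
#' A snake is incident to a junction when its polyline passes within
#' `c_sample / 2` of the junction centroid.
#' @param net A [network_model()].
#' @return The model with `incident_snakes` filled in.
#' @export
link_junctions <- function(net) {
  if (nrow(net$junctions) == 0) return(net)
  lim <- net$c_sample / 2
  dense <- lapply(net$snakes, function(s) {
    resample_polyline(s$points[, 1:2, drop = FALSE], min(lim / 2, net$c_sample / 4))
  })
  inc <- lapply(seq_len(nrow(net$junctions)), function(i) {
    cx <- net$junctions$x[i]; cy <- net$junctions$y[i]
    hits <- vapply(dense, function(p) {
      min(sqrt((p[, 1] - cx)^2 + (p[, 2] - cy)^2)) <= lim
    }, logical(1))
    vapply(net$snakes[hits], `[[`, character(1), "id")
  })
  net$junctions$incident_snakes <- I(inc)
  net
}

# ---------------------------------------------------------------------------
# Editing rules

#' Fuse neighboring junctions
#'
#' Junction pairs closer than `factor * c` are merged: the distance relation
#' is closed transitively (single-link connected components), each group is
#' replaced by the unweighted centroid of its members, and incident snake
#' lists are unioned. The merge is repeated until no two centroids are
#' within the threshold, which makes the operation idempotent; junctions are
#' re-ordered by centroid coordinates so the result is independent of input
#' order.
#'
#' @param net A [network_model()].
#' @param factor Threshold in units of the sampling distance c (merge when
#'   separation < `factor * c`); default 1.2.
#' @return The edited [network_model()].
#' @export
fuse_junctions <- function(net, factor = 1.2) {
  check_positive(factor, "factor")
  thresh <- factor * net$c_sample
  j <- net$junctions
  if (nrow(j) < 2) return(net)
  repeat {
    comp <- single_link_components(as.matrix(j[, c("x", "y")]), thresh)
    if (max(comp) == nrow(j)) break
    j <- merge_junction_groups(j, comp)
  }
  ord <- order(j$x, j$y)
  j <- j[ord, , drop = FALSE]
  j$junction_id <- sprintf("j%d", seq_len(nrow(j)))
  rownames(j) <- NULL
  net$junctions <- j
  net
}

#' Single-link connected components under a distance threshold
#'
#' Union-find over all point pairs with separation strictly below `thresh`.
#' @param points n x 2 matrix.
#' @param thresh Distance threshold.
#' @return Integer component labels (1..k, k = number of components).
#' @export
single_link_components <- function(points, thresh) {
  n <- nrow(points)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  d <- as.matrix(stats::dist(points))
  for (i in seq_len(n - 1L)) {
    for (k in which(d[i, (i + 1L):n] < thresh)) {
      a <- find(i); b <- find(i + k)
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

merge_junction_groups <- function(j, comp) {
  groups <- split(seq_len(nrow(j)), comp)
  out <- lapply(groups, function(i) {
    data.frame(junction_id = j$junction_id[i[1]],
               x = mean(j$x[i]), y = mean(j$y[i]),
               incident_snakes = I(list(sort(unique(unlist(j$incident_snakes[i]))))))
  })
  do.call(rbind, out)
}

#' Remove spurious snakes
#'
#' Drops snakes shorter than `min_length` or with mean per-point intensity
#' below `min_mean_intensity`. Junctions are never touched here. The ids of
#' removed snakes are recorded in the `pruned` attribute of the result.
#'
#' @param net A [network_model()].
#' @param min_length Minimum contour length (um).
#' @param min_mean_intensity Minimum mean intensity (counts/pixel).
#' @return The edited [network_model()] (attribute `pruned`: removed ids).
#' @export
prune_snakes <- function(net, min_length = 0, min_mean_intensity = 0) {
  check_nonnegative(min_length, "min_length")
  check_nonnegative(min_mean_intensity, "min_mean_intensity")
  keep <- vapply(net$snakes, function(s) {
    snake_length(s) >= min_length && mean(s$points[, 3]) >= min_mean_intensity
  }, logical(1))
  pruned <- vapply(net$snakes[!keep], `[[`, character(1), "id")
  net$snakes <- net$snakes[keep]
  attr(net, "pruned") <- pruned
  net
}

# ---------------------------------------------------------------------------
# Internal JSON network format (schema-versioned, full double precision)

#' Write a network model to the internal JSON format
#' @param net A [network_model()].
#' @param path Output path.
#' @export
write_network_json <- function(net, path) {
  obj <- list(
    schema = "netarch/network/1",
    field = net$field[c("width", "height", "pixel_size")],
    c_sample = net$c_sample,
    snakes = lapply(net$snakes, function(s) {
      list(id = s$id, closed = s$closed, multiplicity = s$multiplicity,
           x = s$points[, 1], y = s$points[, 2], intensity = s$points[, 3])
    }),
    junctions = list(
      junction_id = net$junctions$junction_id,
      x = net$junctions$x, y = net$junctions$y,
      incident_snakes = lapply(net$junctions$incident_snakes, as.character)
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a network model from the internal JSON format
#' @param path Path written by [write_network_json()].
#' @return A [network_model()].
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "netarch/network/1")) {
    stop_param("unrecognized network JSON schema in %s", path)
  }
  fld <- field_spec(obj$field$width, obj$field$height, obj$field$pixel_size)
  num <- function(x) vapply(x, as.numeric, numeric(1))
  snakes <- lapply(obj$snakes, function(s) {
    snake(cbind(num(s$x), num(s$y), num(s$intensity)), id = s$id,
          closed = isTRUE(s$closed), multiplicity = s$multiplicity %||% 1)
  })
  jx <- obj$junctions
  junctions <- if (length(jx$x)) {
    data.frame(junction_id = vapply(jx$junction_id, as.character, character(1)),
               x = num(jx$x), y = num(jx$y),
               incident_snakes = I(lapply(jx$incident_snakes, function(v) {
                 vapply(v, as.character, character(1))
               })))
  } else NULL
  network_model(snakes, junctions, fld, obj$c_sample)
}
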