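# Fixtures are built in code at test time; nothing binary is stored.

# A small SOAX-dialect result file: two snakes, one junction, pixel units.
write_soax_fixture <- function(path, with_junctions = TRUE,
                               intensities = c(500, 510, 520, 400, 410, 420)) {
  lines <- c(
    "# SOAX result file (synthetic fixture)",
    "ridge-threshold 0.01",
    "s p x y z intensity",
    sprintf("1 1 10 10 0 %g", intensities[1]),
    sprintf("1 2 20 10 0 %g", intensities[2]),
    sprintf("1 3 30 10 0 %g", intensities[3]),
    sprintf("2 1 20, 0, 0, %g", intensities[4]),   # comma-delimited on purpose
    sprintf("2 2 20 10 0 %g", intensities[5]),
    sprintf("2 3 20 20 0 %g", intensities[6])
  )
  if (with_junctions) {
    lines <- c(lines, "#junctions", "20 10 0")
  }
  writeLines(lines, path)
  path
}

# straight horizontal snake of given length/intensity
straight_snake <- function(length_um = 10, intensity = 500, id = "s1",
                           y = 5, n = 21, multiplicity = 1) {
  x <- seq(0, length_um, length.out = n)
  snake(cbind(x, y, intensity), id = id, multiplicity = multiplicity)
}

# circle snake of radius r sampled finely
circle_snake <- function(r = 5, center = c(10, 10), n = 400, id = "circ") {
  th <- seq(0, 2 * pi, length.out = n)[-n]
  snake(cbind(center[1] + r * cos(th), center[2] + r * sin(th), 0), id = id)
}

# junction fusion oracle: brute-force connected components (igraph) merged
# to centroids, repeated until no pair is below the threshold
fuse_oracle_centroids <- function(xy, thresh) {
  repeat {
    d <- as.matrix(dist(xy))
    adj <- d < thresh
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    if (max(comp) == nrow(xy)) break
    xy <- t(sapply(split(seq_len(nrow(xy)), comp), function(i) {
      colMeans(xy[i, , drop = FALSE])
    }))
  }
  xy[order(xy[, 1], xy[, 2]), , drop = FALSE]
}

# naive O(N^2) randomness-index oracle (independent of the package path)
randomness_oracle <- function(pattern) {
  pts <- pattern$points
  n <- nrow(pts)
  r_nn <- vapply(seq_len(n), function(i) {
    d <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)
    min(d[-i])
  }, numeric(1))
  sigma <- n / (pattern$field$width * pattern$field$height)
  mean(r_nn) / (1 / (2 * sqrt(sigma)))
}
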