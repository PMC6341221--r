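# Architecture descriptors of a traced network: junction density sigma,
# nearest-neighbor statistics, the randomness index R, cable intensity Q
# and its skewness S, curvature K, and worm-like-chain persistence length.

#' Junction (point) density
#'
#' @param pattern A [point_pattern()].
#' @param area_mode `"field"` (full field of view, default) or `"hull"`
#'   (area of the convex hull of the points, for cropped fields).
#' @return Density in points per square micrometer, with attribute
#'   `area_mode`.
#' @export
junction_density <- function(pattern, area_mode = c("field", "hull")) {
  area_mode <- match.arg(area_mode)
  n <- n_points(pattern)
  if (n < 1) stop_param("density is undefined for an empty pattern")
  area <- switch(area_mode,
    field = pattern$field$width * pattern$field$height,
    hull = convex_hull_area(pattern$points))
  if (area <= 0) stop_param("degenerate area (collinear or coincident points in hull mode)")
  structure(n / area, area_mode = area_mode)
}

#' Mean nearest-neighbor distance R_NN
#'
#' Each point's nearest-neighbor distance r_NN is the minimum over all its
#' interpoint distances; R_NN is their arithmetic mean over the N observed
#' values.
#'
#' @param pattern A [point_pattern()].
#' @param edge_margin Guard-zone width (um): points within this margin of
#'   the border are excluded as NN *sources* but kept as *targets*. The
#'   default 0 applies no edge handling (border points then have a small
#'   upward distance bias).
#' @return List with `R_NN` (mean, um), `r_NN` (per-source distances) and
#'   `N` (number of distances).
#' @export
mean_nn_distance <- function(pattern, edge_margin = 0) {
  if (n_points(pattern) < 2) stop_param("need at least 2 points for R_NN")
  sources <- if (edge_margin > 0) interior_indices(pattern, edge_margin) else NULL
  if (!is.null(sources) && length(sources) == 0L) {
    stop_param("guard zone excluded every point; reduce `edge_margin`")
  }
  r <- nn_distances(pattern$points, sources = sources)
  list(R_NN = mean(r), r_NN = r, N = length(r))
}

#' Poisson nearest-neighbor reference distance
#'
#' Expected mean nearest-neighbor distance of a homogeneous Poisson pattern
#' at density sigma: `r_rand = 1 / (2 * sqrt(sigma))`.
#'
#' @param sigma Point density (points/um^2).
#' @return r_rand in micrometers.
#' @export
random_reference <- function(sigma) {
  check_positive(sigma, "sigma")
  1 / (2 * sqrt(sigma))
}

#' Randomness index R of a point pattern
#'
#' `R = R_NN / r_rand`: approximately 0 for an aggregated pattern (points
#' coalesce), 1 for a random (Poisson) pattern, and up to the hexagonal
#' maximum `2 * sqrt(2 / sqrt(3))` (about 2.15) for an optimally spaced
#' triangular lattice.
#'
#' @inheritParams mean_nn_distance
#' @param area_mode Area convention for the density (see
#'   [junction_density()]).
#' @param sigma Optional known density (points/um^2); when `NULL` the
#'   density is estimated from the pattern.
#' @return R (dimensionless) with attribute `provenance` recording R_NN,
#'   r_rand, sigma, N and the edge handling used.
#' @export
randomness_index <- function(pattern, area_mode = c("field", "hull"),
                             sigma = NULL, edge_margin = 0) {
  area_mode <- match.arg(area_mode)
  nn <- mean_nn_distance(pattern, edge_margin = edge_margin)
  if (is.null(sigma)) sigma <- as.numeric(junction_density(pattern, area_mode))
  rr <- random_reference(sigma)
  structure(nn$R_NN / rr,
            provenance = list(R_NN = nn$R_NN, r_rand = rr, sigma = sigma,
                              N = nn$N, area_mode = area_mode,
                              edge_margin = edge_margin))
}

#' Cable intensity Q
#'
#' Mean snake intensity in detector counts per pixel: either the mean of
#' the per-point intensities stored on each snake, or — when an image is
#' supplied — the mean of image pixels sampled along the snake path.
#' Optionally background-subtracted.
#'
#' @param net A [network_model()].
#' @param image Optional `netarch_image` to sample instead of stored
#'   intensities.
#' @param background Constant background (counts/pixel) subtracted from
#'   every Q.
#' @return List with `Q` (named per-snake values) and `Q_mean`.
#' @export
cable_intensity <- function(net, image = NULL, background = 0) {
  check_nonnegative(background, "background")
  if (length(net$snakes) == 0L) return(list(Q = numeric(0), Q_mean = NaN))
  q <- vapply(net$snakes, function(s) {
    if (is.null(image)) {
      mean(s$points[, 3])
    } else {
      ps <- attr(image, "pixel_size")
      p <- resample_polyline(s$points[, 1:2, drop = FALSE], ps)
      cc <- round(p[, 1] / ps) + 1L
      rr <- round(p[, 2] / ps) + 1L
      if (any(cc < 1 | cc > ncol(image) | rr < 1 | rr > nrow(image))) {
        stop_param("snake %s extends outside the image", s$id)
      }
      mean(image[cbind(rr, cc)])
    }
  }, numeric(1)) - background
  names(q) <- vapply(net$snakes, `[[`, character(1), "id")
  list(Q = q, Q_mean = mean(q))
}

#' Skewness S of an intensity distribution
#'
#' Adjusted Fisher-Pearson sample skewness (the spreadsheet SKEW
#' definition): `S = n / ((n-1)(n-2)) * sum(((x - mean) / sd)^3)` with the
#' n-1 sample standard deviation. S = 0 for a symmetric distribution with
#' mean = mode.
#'
#' @param q_values Numeric sample (>= 3 values, nonzero variance).
#' @return S (dimensionless).
#' @export
intensity_skewness <- function(q_values) {
  q_values <- as.numeric(q_values)
  n <- length(q_values)
  if (n < 3) stop_param("skewness needs at least 3 values")
  s <- stats::sd(q_values)
  if (s == 0) stop_param("skewness is undefined for a constant sample")
  n / ((n - 1) * (n - 2)) * sum(((q_values - mean(q_values)) / s)^3)
}

#' Mean curvature K of a snake
#'
#' The snake is resampled at arc-length spacing `delta_s`; the tangent
#' difference dT between consecutive chords is the unsigned turning angle in
#' [0, pi], and `K = mean(dT) / delta_s` (rad/um). Curvature sign is
#' discarded because the worm-like-chain curvature density is a density on
#' magnitude.
#'
#' @param sn A [snake()].
#' @param delta_s Sampling distance (um); the natural default is the model
#'   sampling distance c = 0.625 um.
#' @return List with `K` (rad/um), `dT` (unsigned tangent differences, rad)
#'   and `delta_s`; `NULL` (with a warning) when the contour is shorter than
#'   `2 * delta_s`.
#' @export
snake_curvature <- function(sn, delta_s = 0.625) {
  check_positive(delta_s, "delta_s")
  if (snake_length(sn) < 2 * delta_s) {
    warning(sprintf("snake %s shorter than 2*delta_s; skipped", sn$id))
    return(NULL)
  }
  p <- resample_polyline(sn$points[, 1:2, drop = FALSE], delta_s)
  seg <- diff(p)
  ang <- atan2(seg[, 2], seg[, 1])
  dT <- abs(diff(ang))
  dT <- pmin(dT, 2 * pi - dT)  # wrap to [0, pi]
  list(K = mean(dT) / delta_s, dT = dT, delta_s = delta_s)
}

#' Persistence length from curvature samples
#'
#' Maximum-likelihood fit of the worm-like-chain half-normal curvature
#' density `P(K) = sqrt(2 l_p c / pi) * exp(-l_p c K^2 / 2)` for K >= 0:
#' the MLE is `l_p = 1 / (c * mean(K^2))`. A Kolmogorov-Smirnov statistic
#' against the fitted density is returned as the goodness of fit. The raw
#' MLE is reported without bias correction (on traced filaments it is known
#' to underestimate; `provenance$bias_corrected` records this).
#'
#' @param curvatures Per-segment curvature magnitudes K (rad/um), e.g.
#'   `dT / delta_s` pooled from [snake_curvature()].
#' @param c_sample Sampling distance c (um) at which the curvatures were
#'   measured.
#' @return Object of class `lp_fit`: list(l_p, n, ks_stat, ks_p, c_sample,
#'   provenance).
#' @export
fit_persistence_length <- function(curvatures, c_sample = 0.625) {
  check_positive(c_sample, "c_sample")
  k <- as.numeric(curvatures)
  k <- k[is.finite(k)]
  if (length(k) < 10) stop_param("need at least 10 curvature samples")
  m2 <- mean(k^2)
  if (m2 == 0) stop_param("all curvatures are zero: straight filaments imply infinite l_p")
  l_p <- 1 / (c_sample * m2)
  # half-normal CDF with variance 1/(l_p c): |Z|, Z ~ N(0, 1/(l_p c))
  sd_k <- sqrt(1 / (l_p * c_sample))
  ks <- suppressWarnings(stats::ks.test(k, function(q) 2 * stats::pnorm(q, 0, sd_k) - 1))
  structure(list(l_p = l_p, n = length(k), ks_stat = unname(ks$statistic),
                 ks_p = ks$p.value, c_sample = c_sample,
                 provenance = list(bias_corrected = FALSE)),
            class = "lp_fit")
}

#' @export
print.lp_fit <- function(x, ...) {
  cat(sprintf("Worm-like-chain persistence length (half-normal curvature MLE)\n"))
  cat(sprintf("  l_p = %.4g um  (n = %d, c = %g um, KS D = %.3g)\n",
              x$l_p, x$n, x$c_sample, x$ks_stat))
  invisible(x)
}

#' Sample curvature magnitudes from the worm-like-chain density
#'
#' Draws K from `P(K) = sqrt(2 l_p c / pi) exp(-l_p c K^2 / 2)` (half-normal
#' with variance `1 / (l_p c)`); the sampling counterpart of
#' [fit_persistence_length()], used for recovery tests.
#'
#' @param n Number of samples.
#' @param l_p Persistence length (um).
#' @param c_sample Sampling distance (um).
#' @param seed Integer seed.
#' @return Numeric vector of curvatures (rad/um).
#' @export
sample_wlc_curvatures <- function(n, l_p, c_sample = 0.625, seed = NULL) {
  check_positive(l_p, "l_p")
  check_positive(c_sample, "c_sample")
  with_seed(seed, abs(stats::rnorm(n, 0, sqrt(1 / (l_p * c_sample)))))
}

#' Architecture summary for one field of view
#'
#' Convenience wrapper computing the full descriptor set: junction density
#' sigma, R_NN, r_rand, randomness index R, mean cable intensity Q, its
#' skewness S, mean curvature K and the persistence length l_p.
#'
#' @param net A [network_model()].
#' @param image Optional image for Q sampling (see [cable_intensity()]).
#' @param background Background subtracted from Q.
#' @param delta_s Curvature sampling distance (um); defaults to the model c.
#' @param area_mode,edge_margin Passed to [randomness_index()].
#' @return Object of class `architecture_summary` (a list of the named
#'   descriptors; descriptors whose preconditions fail are `NA`).
#' @export
summarize_architecture <- function(net, image = NULL, background = 0,
                                   delta_s = net$c_sample,
                                   area_mode = "field", edge_margin = 0) {
  pat <- junction_pattern(net)
  sigma <- R_NN <- r_rand <- R <- NA_real_
  if (n_points(pat) >= 1) sigma <- as.numeric(junction_density(pat, area_mode))
  if (n_points(pat) >= 2) {
    nn <- mean_nn_distance(pat, edge_margin = edge_margin)
    R_NN <- nn$R_NN
    r_rand <- random_reference(sigma)
    R <- R_NN / r_rand
  }
  qres <- cable_intensity(net, image = image, background = background)
  S <- if (length(qres$Q) >= 3 && stats::sd(qres$Q) > 0) {
    intensity_skewness(qres$Q)
  } else NA_real_
  curv <- lapply(net$snakes, function(s) {
    suppressWarnings(snake_curvature(s, delta_s))
  })
  curv <- curv[!vapply(curv, is.null, logical(1))]
  K_mean <- if (length(curv)) mean(vapply(curv, `[[`, numeric(1), "K")) else NA_real_
  dT <- unlist(lapply(curv, `[[`, "dT"))
  l_p <- if (length(dT) >= 10 && any(dT > 0)) {
    fit_persistence_length(dT / delta_s, c_sample = delta_s)$l_p
  } else NA_real_
  structure(list(sigma = sigma, R_NN = R_NN, r_rand = r_rand, R = R,
                 Q = qres$Q_mean, S = S, K_mean = K_mean, l_p = l_p,
                 delta_s = delta_s, n_junctions = n_points(pat),
                 n_snakes = length(net$snakes)),
            class = "architecture_summary")
}

#' @export
print.architecture_summary <- function(x, ...) {
  cat("Network architecture summary\n")
  cat(sprintf("  junctions: %d (sigma = %.4g /um^2)\n", x$n_junctions, x$sigma))
  cat(sprintf("  R_NN = %.4g um, r_rand = %.4g um, R = %.4g\n",
              x$R_NN, x$r_rand, x$R))
  cat(sprintf("  snakes: %d, Q = %.4g counts/pixel, S = %.4g\n",
              x$n_snakes, x$Q, x$S))
  cat(sprintf("  K = %.4g rad/um (delta_s = %g um), l_p = %.4g um\n",
              x$K_mean, x$delta_s, x$l_p))
  invisible(x)
}
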