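# Synthetic-data generators: every input the analysis pipeline consumes,
# with ground-truth parameters recorded alongside, so parameter-recovery
# tests need no external bookkeeping. All generators are pure functions of
# (parameters, seed): the same seed reproduces the output bit-for-bit and
# the caller's RNG stream is left untouched.

#' Homogeneous Poisson point pattern
#'
#' Junction positions where every location is equally likely and points are
#' independent — the reference ("random") architecture against which the
#' randomness index is calibrated.
#'
#' @param density Expected points per square micrometer.
#' @param field A [field_spec()].
#' @param seed Integer seed; defaults to `field$seed`.
#' @return A [point_pattern()] with ground truth
#'   `list(pattern_kind = "poisson", density = density)`.
#' @examples
#' p <- gen_poisson_pattern(0.25, field_spec(40, 40, seed = 1))
#' @export
gen_poisson_pattern <- function(density, field, seed = field$seed) {
  check_positive(density, "density")
  assert_field(field)
  with_seed(seed, {
    n <- stats::rpois(1, density * field$width * field$height)
    pts <- cbind(x = stats::runif(n, 0, field$width),
                 y = stats::runif(n, 0, field$height))
    point_pattern(pts, field,
                  ground_truth = list(pattern_kind = "poisson",
                                      density = density, seed = seed))
  })
}

#' Thomas-process clustered point pattern
#'
#' Aggregated junction architecture: Poisson parent centers, each with a
#' Poisson number of offspring displaced by an isotropic Gaussian. As
#' `cluster_sd` shrinks the points coalesce (randomness index toward 0); as
#' it grows the pattern approaches Poisson (index toward 1). Parents are
#' simulated on a buffer extending 4 cluster standard deviations beyond the
#' field so the in-field intensity is stationary; only offspring inside the
#' field are returned.
#'
#' @param parent_density Parent centers per square micrometer.
#' @param mean_offspring Mean offspring per parent.
#' @param cluster_sd Isotropic Gaussian displacement SD (um).
#' @inheritParams gen_poisson_pattern
#' @return A [point_pattern()]; expected in-field intensity is
#'   `parent_density * mean_offspring`.
#' @export
gen_clustered_pattern <- function(parent_density, mean_offspring, cluster_sd,
                                  field, seed = field$seed) {
  check_positive(parent_density, "parent_density")
  check_positive(mean_offspring, "mean_offspring")
  check_positive(cluster_sd, "cluster_sd")
  assert_field(field)
  with_seed(seed, {
    buf <- 4 * cluster_sd
    w <- field$width + 2 * buf
    h <- field$height + 2 * buf
    n_par <- stats::rpois(1, parent_density * w * h)
    px <- stats::runif(n_par, -buf, field$width + buf)
    py <- stats::runif(n_par, -buf, field$height + buf)
    n_off <- stats::rpois(n_par, mean_offspring)
    cx <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, cluster_sd)
    cy <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, cluster_sd)
    keep <- cx >= 0 & cx <= field$width & cy >= 0 & cy <= field$height
    point_pattern(cbind(x = cx[keep], y = cy[keep]), field,
                  ground_truth = list(pattern_kind = "clustered",
                                      parent_density = parent_density,
                                      mean_offspring = mean_offspring,
                                      cluster_sd = cluster_sd,
                                      density = parent_density * mean_offspring,
                                      seed = seed))
  })
}

#' Hexagonally packed (triangular-lattice) point pattern
#'
#' The optimally spaced architecture: points on a triangular lattice with
#' spacing `a = sqrt(2 / (sqrt(3) * density))`, optionally jittered by an
#' isotropic Gaussian. Jitter-free, every interior point has six nearest
#' neighbors at exactly distance `a`.
#'
#' @param density Target points per square micrometer.
#' @param jitter_sd Gaussian jitter SD (um); 0 for the perfect lattice.
#' @inheritParams gen_poisson_pattern
#' @return A [point_pattern()]; ground truth records the lattice `spacing`
#'   and the exact lattice density `density_lattice = 2 / (sqrt(3) spacing^2)`.
#' @export
gen_hexagonal_pattern <- function(density, jitter_sd = 0, field,
                                  seed = field$seed) {
  check_positive(density, "density")
  check_nonnegative(jitter_sd, "jitter_sd")
  assert_field(field)
  a <- sqrt(2 / (sqrt(3) * density))
  dy <- a * sqrt(3) / 2
  n_rows <- floor(field$height / dy) + 1L
  if (n_rows < 2) stop_param("field too small for >= 2 lattice rows at this density")
  rows <- seq(0, by = dy, length.out = n_rows)
  pts <- do.call(rbind, lapply(seq_along(rows), function(i) {
    off <- if (i %% 2 == 0) a / 2 else 0
    xs <- seq(off, field$width, by = a)
    cbind(x = xs, y = rows[i])
  }))
  with_seed(seed, {
    if (jitter_sd > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), 0, jitter_sd), ncol = 2)
    }
    keep <- pts[, 1] >= 0 & pts[, 1] <= field$width &
            pts[, 2] >= 0 & pts[, 2] <= field$height
    point_pattern(pts[keep, , drop = FALSE], field,
                  ground_truth = list(pattern_kind = "hexagonal",
                                      density = density,
                                      spacing = a,
                                      density_lattice = 2 / (sqrt(3) * a^2),
                                      jitter_sd = jitter_sd, seed = seed))
  })
}

#' Worm-like-chain filament ("snake")
#'
#' Discrete 2-D worm-like chain: tangent-angle increments between successive
#' steps are i.i.d. Gaussian with variance `step / l_p`, giving a filament
#' whose curvature magnitudes follow the half-normal density used by the
#' persistence-length estimator. Contour length is `n_steps * step`.
#'
#' @param l_p Persistence length (um).
#' @param step Arc-length step (um); the natural choice is the analysis
#'   sampling distance c (0.625 um).
#' @param n_steps Number of segments (>= 2).
#' @param field A [field_spec()] (start point is uniform in the field).
#' @param seed Integer seed.
#' @param start,angle0 Optional fixed start point (um) and initial tangent
#'   angle (rad); random if `NULL`.
#' @param multiplicity Number of bundled filaments the snake represents
#'   (scales rendered intensity).
#' @return A `snake` object (see [snake()]) with ground truth attached.
#' @export
gen_wlc_snake <- function(l_p, step, n_steps, field, seed = field$seed,
                          start = NULL, angle0 = NULL, multiplicity = 1) {
  check_positive(l_p, "l_p")
  check_positive(step, "step")
  if (n_steps < 2) stop_param("`n_steps` must be >= 2")
  assert_field(field)
  with_seed(seed, {
    if (is.null(start)) {
      start <- c(stats::runif(1, 0, field$width), stats::runif(1, 0, field$height))
    }
    if (is.null(angle0)) angle0 <- stats::runif(1, 0, 2 * pi)
    dtheta <- stats::rnorm(n_steps - 1L, 0, sqrt(step / l_p))
    theta <- angle0 + c(0, cumsum(dtheta))
    x <- start[1] + c(0, cumsum(step * cos(theta)))
    y <- start[2] + c(0, cumsum(step * sin(theta)))
    snake(cbind(x = x, y = y, intensity = 0), id = "wlc",
          multiplicity = multiplicity,
          ground_truth = list(l_p = l_p, step = step, n_steps = n_steps,
                              seed = seed))
  })
}

#' Render a filament network into a fluorescence image
#'
#' Each snake is traced at sub-pixel arc-length steps and splatted with a
#' normalized Gaussian point-spread function; deposited counts are
#' `intensity_per_filament * multiplicity` per micrometer of contour, so
#' bundle intensity is additive (no quenching) and exactly linear in
#' multiplicity. A constant background is added and, optionally, Poisson
#' shot noise applied.
#'
#' @param snakes List of [snake()] objects (each may carry a `multiplicity`).
#' @param psf_sd PSF standard deviation (um).
#' @param intensity_per_filament Counts deposited per um of a single filament.
#' @param background Constant background (counts/pixel).
#' @param field A [field_spec()] defining the pixel grid.
#' @param noise Apply Poisson noise? (`FALSE` gives the noise-free render.)
#' @param seed Integer seed (used only when `noise = TRUE`).
#' @return A `netarch_image`: numeric matrix (rows = y, cols = x) with
#'   `pixel_size` attribute.
#' @export
render_network_image <- function(snakes, psf_sd, intensity_per_filament = 1000,
                                 background = 100, field, noise = TRUE,
                                 seed = field$seed) {
  check_positive(psf_sd, "psf_sd")
  check_nonnegative(background, "background")
  assert_field(field)
  ps <- field$pixel_size
  nc <- max(2L, round(field$width / ps))
  nr <- max(2L, round(field$height / ps))
  img <- matrix(0, nr, nc)
  # Gaussian kernel in pixel units, normalized to unit sum
  spx <- psf_sd / ps
  half <- ceiling(4 * spx)
  kx <- stats::dnorm(-half:half, 0, spx)
  kern <- outer(kx, kx)
  kern <- kern / sum(kern)
  ds <- ps / 3
  clipped <- FALSE
  for (sn in snakes) {
    pts <- resample_polyline(sn$points[, 1:2, drop = FALSE], ds)
    amp <- intensity_per_filament * (sn$multiplicity %||% 1) * ds
    col0 <- round(pts[, 1] / ps)
    row0 <- round(pts[, 2] / ps)
    inside <- col0 >= 0 & col0 < nc & row0 >= 0 & row0 < nr
    if (any(!inside)) clipped <- TRUE
    for (i in which(inside)) {
      r <- row0[i] + 1L; c0 <- col0[i] + 1L
      rr <- max(1L, r - half):min(nr, r + half)
      cc <- max(1L, c0 - half):min(nc, c0 + half)
      img[rr, cc] <- img[rr, cc] +
        amp * kern[rr - r + half + 1L, cc - c0 + half + 1L]
    }
  }
  if (clipped) warning("snake points outside the field were clipped")
  img <- img + background
  if (noise) {
    img <- with_seed(seed, matrix(stats::rpois(length(img), img), nr, nc))
  }
  structure(img, pixel_size = ps, class = c("netarch_image", "matrix", "array"))
}

#' @export
print.netarch_image <- function(x, ...) {
  cat(sprintf("<netarch_image> %d x %d pixels, %g um/pixel, counts %g-%g\n",
              nrow(x), ncol(x), attr(x, "pixel_size"), min(x), max(x)))
  invisible(x)
}

#' Single-molecule dwell times from an exponential mixture
#'
#' Draws exact exponential (or mixture-of-exponentials) durations,
#' quantizes them to whole camera frames by the ceiling rule (a molecule
#' visible during any part of a frame counts that frame), and right-censors
#' records at the observation window. The default frame interval is 0.05 s
#' (20 frames/s video).
#'
#' @param components Two-column matrix or data.frame (amplitude, rate 1/s),
#'   or a list of c(amplitude, rate) pairs. Amplitudes must be >= 0 and sum
#'   to 1 (small deviations are renormalized with a warning).
#' @param n Number of dwells.
#' @param frame_interval Camera frame interval (s).
#' @param window Observation window (s); dwells running past it are censored.
#' @param seed Integer seed.
#' @return A `dwell_set`: data.frame (frames, duration, censored) with
#'   attributes `frame_interval`, `threshold_frames` (6) and `ground_truth`.
#' @export
gen_dwell_times <- function(components, n, frame_interval = 0.05,
                            window = 60, seed = NULL) {
  comp <- as_mixture(components)
  check_positive(n, "n")
  check_positive(frame_interval, "frame_interval")
  check_positive(window, "window")
  with_seed(seed, {
    which_comp <- sample.int(nrow(comp), n, replace = TRUE, prob = comp[, 1])
    t_true <- stats::rexp(n, rate = comp[which_comp, 2])
    m_window <- floor(window / frame_interval)
    frames <- ceiling(t_true / frame_interval)
    frames[frames < 1L] <- 1L
    censored <- frames > m_window
    frames[censored] <- m_window
    dwell_set(frames, frame_interval, censored,
              ground_truth = list(amplitudes = comp[, 1], rates = comp[, 2],
                                  window = window, seed = seed,
                                  t_true = NULL))
  })
}

as_mixture <- function(components) {
  if (is.list(components) && !is.data.frame(components)) {
    components <- do.call(rbind, components)
  }
  comp <- as.matrix(components)
  if (ncol(comp) != 2) stop_param("`components` must be (amplitude, rate) pairs")
  if (any(comp[, 1] < 0) || any(comp[, 2] <= 0)) {
    stop_param("amplitudes must be >= 0 and rates > 0")
  }
  s <- sum(comp[, 1])
  if (s <= 0) stop_param("amplitudes must not all be zero")
  if (abs(s - 1) > 1e-6) {
    if (abs(s - 1) > 0.05) {
      stop_param("amplitudes must sum to 1 (got %.3f)", s)
    }
    warning(sprintf("amplitudes sum to %.3f; renormalizing", s))
  }
  comp[, 1] <- comp[, 1] / s
  colnames(comp) <- c("amplitude", "rate")
  comp
}

#' Construct a dwell-time set
#'
#' @param frames Integer dwell lengths in camera frames.
#' @param frame_interval Frame interval (s).
#' @param censored Logical right-censoring flags (dwell still present when
#'   the record ended).
#' @param location Optional location class per dwell
#'   ("junction", "cable", "g_actin", "unknown").
#' @param threshold_frames Detection ("bound") threshold in frames.
#' @param ground_truth Optional generator parameters.
#' @return A `dwell_set` data.frame with columns frames, duration (s),
#'   censored, location.
#' @export
dwell_set <- function(frames, frame_interval, censored = FALSE,
                      location = "unknown", threshold_frames = 6L,
                      ground_truth = NULL) {
  frames <- as.integer(frames)
  if (any(frames < 1L)) stop_param("dwell lengths must be >= 1 frame")
  check_positive(frame_interval, "frame_interval")
  d <- data.frame(frames = frames,
                  duration = frames * frame_interval,
                  censored = rep_len(as.logical(censored), length(frames)),
                  location = rep_len(location, length(frames)))
  structure(d, frame_interval = frame_interval,
            threshold_frames = as.integer(threshold_frames),
            ground_truth = ground_truth,
            class = c("dwell_set", "data.frame"))
}

#' Brownian single-particle tracks with localization noise
#'
#' 2-D Brownian motion sampled at the camera frame interval: per-axis
#' increments have variance `2 * D * frame_interval`, so the ensemble MSD is
#' `4 D dT` plus a `4 * loc_noise_sd^2` offset from independent Gaussian
#' localization error at each frame.
#'
#' @param D Diffusion coefficient (um^2/s); may be 0.
#' @param n_tracks,n_frames Number of tracks and frames per track.
#' @param frame_interval Frame interval (s).
#' @param loc_noise_sd Localization error SD (um).
#' @param field A [field_spec()] (start positions uniform in the field).
#' @param seed Integer seed.
#' @return A `track_set`: data.frame (track_id, frame, x, y, intensity) with
#'   attributes `frame_interval` and `ground_truth`.
#' @export
gen_tracks <- function(D, n_tracks, n_frames, frame_interval = 0.05,
                       loc_noise_sd = 0, field, seed = field$seed) {
  check_nonnegative(D, "D")
  check_positive(n_tracks, "n_tracks")
  if (n_frames < 2) stop_param("`n_frames` must be >= 2")
  check_positive(frame_interval, "frame_interval")
  check_nonnegative(loc_noise_sd, "loc_noise_sd")
  assert_field(field)
  with_seed(seed, {
    sd_step <- sqrt(2 * D * frame_interval)
    make1 <- function(id) {
      x0 <- stats::runif(1, 0, field$width)
      y0 <- stats::runif(1, 0, field$height)
      x <- x0 + c(0, cumsum(stats::rnorm(n_frames - 1L, 0, sd_step)))
      y <- y0 + c(0, cumsum(stats::rnorm(n_frames - 1L, 0, sd_step)))
      if (loc_noise_sd > 0) {
        x <- x + stats::rnorm(n_frames, 0, loc_noise_sd)
        y <- y + stats::rnorm(n_frames, 0, loc_noise_sd)
      }
      data.frame(track_id = id, frame = seq_len(n_frames) - 1L,
                 x = x, y = y, intensity = 1)
    }
    tr <- do.call(rbind, lapply(seq_len(n_tracks), make1))
    track_set(tr, frame_interval,
              ground_truth = list(D = D, loc_noise_sd = loc_noise_sd,
                                  n_tracks = n_tracks, n_frames = n_frames,
                                  seed = seed))
  })
}

#' Construct a track set
#'
#' @param tracks data.frame with columns track_id, frame, x, y and
#'   optionally intensity.
#' @param frame_interval Frame interval (s).
#' @param ground_truth Optional generator parameters.
#' @return A `track_set` data.frame.
#' @export
track_set <- function(tracks, frame_interval, ground_truth = NULL) {
  need <- c("track_id", "frame", "x", "y")
  if (!all(need %in% names(tracks))) {
    stop_param("tracks need columns %s", paste(need, collapse = ", "))
  }
  if (is.null(tracks$intensity)) tracks$intensity <- NA_real_
  check_positive(frame_interval, "frame_interval")
  ord <- order(tracks$track_id, tracks$frame)
  tracks <- tracks[ord, , drop = FALSE]
  rownames(tracks) <- NULL
  bad <- tapply(tracks$frame, tracks$track_id, function(f) any(diff(f) <= 0))
  if (any(unlist(bad))) stop_param("frame indices must be strictly increasing within a track")
  structure(tracks, frame_interval = frame_interval,
            ground_truth = ground_truth,
            class = c("track_set", "data.frame"))
}

#' Synthetic image of fluorescent foci
#'
#' Gaussian intensity blobs on a constant background. For each blob the
#' analytic area above half its peak, `pi * 2 * log(2) * sd^2`, is recorded
#' in the ground truth so segmentation tests have an exact reference; an
#' overlap flag marks blob pairs whose half-max disks intersect.
#'
#' @param foci_true data.frame with columns x, y (um), sd (Gaussian radius
#'   parameter, um) and peak (counts above background).
#' @param background Constant background (counts/pixel).
#' @param field A [field_spec()].
#' @param noise Apply Poisson noise?
#' @param seed Integer seed.
#' @return A `netarch_image` with `ground_truth` attribute (count, centers,
#'   half-max areas in um^2, overlap flag).
#' @export
gen_foci_image <- function(foci_true, background = 50, field, noise = FALSE,
                           seed = field$seed) {
  assert_field(field)
  check_nonnegative(background, "background")
  foci_true <- as.data.frame(foci_true)
  need <- c("x", "y", "sd", "peak")
  if (nrow(foci_true) > 0 && !all(need %in% names(foci_true))) {
    stop_param("foci_true needs columns %s", paste(need, collapse = ", "))
  }
  if (nrow(foci_true) > 0 && any(foci_true$sd <= 0)) {
    stop_param("focus radii (sd) must be > 0")
  }
  ps <- field$pixel_size
  nc <- max(2L, round(field$width / ps))
  nr <- max(2L, round(field$height / ps))
  xs <- (seq_len(nc) - 1L) * ps
  ys <- (seq_len(nr) - 1L) * ps
  img <- matrix(background, nr, nc)
  for (i in seq_len(nrow(foci_true))) {
    gx <- stats::dnorm(xs, foci_true$x[i], foci_true$sd[i])
    gy <- stats::dnorm(ys, foci_true$y[i], foci_true$sd[i])
    scale <- foci_true$peak[i] / stats::dnorm(0, 0, foci_true$sd[i])^2
    img <- img + scale * outer(gy, gx)
  }
  overlap <- FALSE
  if (nrow(foci_true) > 1) {
    r_half <- foci_true$sd * sqrt(2 * log(2))
    d <- as.matrix(stats::dist(foci_true[, c("x", "y")]))
    lim <- outer(r_half, r_half, `+`)
    diag(d) <- Inf
    overlap <- any(d < lim)
  }
  if (noise) {
    img <- with_seed(seed, matrix(stats::rpois(length(img), img), nr, nc))
  }
  structure(img, pixel_size = ps,
            ground_truth = list(
              count = nrow(foci_true),
              centers = foci_true[, intersect(c("x", "y"), names(foci_true))],
              half_max_area_um2 = if (nrow(foci_true)) pi * 2 * log(2) * foci_true$sd^2 else numeric(0),
              peak = foci_true$peak, background = background,
              overlap = overlap),
            class = c("netarch_image", "matrix", "array"))
}
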