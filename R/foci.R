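# Myosin-driven compaction: segmentation of fluorescent foci, the paper's
# area/intensity filters, integrated foci intensity, foci spacing
# statistics, and fits to the compaction time courses.

#' Otsu threshold of an image
#'
#' Histogram-based threshold maximizing between-class variance; used as the
#' automatic intensity threshold for focus segmentation.
#'
#' @param image Numeric matrix.
#' @param n_bins Histogram bins.
#' @return Threshold on the intensity scale of the image.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  rng <- range(v)
  if (rng[1] == rng[2]) stop_param("cannot auto-threshold a constant image")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

#' Connected-component labeling of a binary mask
#'
#' Breadth-first flood fill with 8- (default) or 4-connectivity.
#'
#' @param mask Logical matrix.
#' @param connectivity 8 or 4.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop_param("connectivity must be 4 or 8")
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8L) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  current <- 0L
  todo <- which(mask)
  for (s in todo) {
    if (lab[s] != 0L) next
    current <- current + 1L
    lab[s] <- current
    frontier <- s
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      cc <- (frontier - 1L) %/% nr + 1L
      nbr_r <- rep(r, each = nrow(offs)) + offs[, 1]
      nbr_c <- rep(cc, each = nrow(offs)) + offs[, 2]
      ok <- nbr_r >= 1 & nbr_r <= nr & nbr_c >= 1 & nbr_c <= nc
      idx <- unique((nbr_c[ok] - 1L) * nr + nbr_r[ok])
      idx <- idx[mask[idx] & lab[idx] == 0L]
      lab[idx] <- current
      frontier <- idx
    }
  }
  lab
}

#' Detect fluorescent foci
#'
#' Particle-analysis style segmentation: binarize at an intensity threshold,
#' label connected components (8-connected by default), and keep components
#' whose area strictly exceeds `min_area` (the >50 um^2 rule). Per-focus
#' statistics are measured on the *original* image using the binarized
#' component as a mask: intensity-weighted centroid, area (pixel^2 and
#' um^2), and mean intensity Q_foci.
#'
#' @param image A `netarch_image` or numeric matrix.
#' @param intensity_threshold Numeric threshold (counts), or `"otsu"` for
#'   the automatic choice.
#' @param min_area Minimum focus area in um^2 (strict inequality).
#' @param pixel_size Pixel size (um); taken from the image attribute when
#'   absent.
#' @param connectivity 8 (default) or 4.
#' @return A `foci_table`: data.frame (focus_id, x, y, area_px, area_um2,
#'   q_foci) with attributes `pixel_size` and `provenance` (threshold used,
#'   how chosen).
#' @export
detect_foci <- function(image, intensity_threshold = "otsu", min_area = 50,
                        pixel_size = attr(image, "pixel_size"),
                        connectivity = 8L) {
  if (is.null(pixel_size)) stop_param("`pixel_size` is required")
  check_positive(pixel_size, "pixel_size")
  check_nonnegative(min_area, "min_area")
  auto <- identical(intensity_threshold, "otsu")
  thr <- if (auto) otsu_threshold(image) else as.numeric(intensity_threshold)
  mask <- unclass(image) > thr
  lab <- label_components(mask, connectivity)
  tab <- empty_foci_table()
  if (any(mask)) {
    px_area <- pixel_size^2
    rows <- lapply(seq_len(max(lab)), function(k) {
      idx <- which(lab == k)
      area_um2 <- length(idx) * px_area
      if (area_um2 <= min_area) return(NULL)
      r <- (idx - 1L) %% nrow(lab) + 1L
      cc <- (idx - 1L) %/% nrow(lab) + 1L
      w <- as.numeric(image)[idx]
      data.frame(focus_id = NA_integer_,
                 x = sum((cc - 1L) * w) / sum(w) * pixel_size,
                 y = sum((r - 1L) * w) / sum(w) * pixel_size,
                 area_px = length(idx), area_um2 = area_um2,
                 q_foci = mean(w))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) {
      tab <- do.call(rbind, rows)
      tab$focus_id <- seq_len(nrow(tab))
    }
  }
  structure(tab, pixel_size = pixel_size,
            provenance = list(threshold = thr,
                              threshold_mode = if (auto) "otsu" else "manual",
                              min_area = min_area, connectivity = connectivity),
            class = c("foci_table", "data.frame"))
}

empty_foci_table <- function() {
  data.frame(focus_id = integer(0), x = numeric(0), y = numeric(0),
             area_px = integer(0), area_um2 = numeric(0), q_foci = numeric(0))
}

#' Integrated foci intensity
#'
#' `sum over foci of A_foci (pixel^2) * Q_foci (counts/pixel)` — the total
#' fluorescence gathered into segmented foci, the compaction readout.
#'
#' @param table A `foci_table` from [detect_foci()].
#' @return Total counts (0 for an empty table).
#' @export
sum_Q_foci <- function(table) {
  if (nrow(table) == 0L) return(0)
  sum(table$area_px * table$q_foci)
}

#' Spacing randomness index of segmented foci
#'
#' Delegates to [randomness_index()] on the foci centroids: the same
#' nearest-neighbor statistic used for filament junctions, applied to the
#' compacted foci.
#'
#' @param table A `foci_table`.
#' @param field A [field_spec()].
#' @param ... Passed to [randomness_index()].
#' @return R (dimensionless).
#' @export
foci_spacing_index <- function(table, field, ...) {
  if (nrow(table) < 2) stop_param("need at least 2 foci for a spacing index")
  randomness_index(point_pattern(table[, c("x", "y")], field), ...)
}

#' Fit compaction time courses
#'
#' Linear least-squares fit of the foci spacing index R(t) and a
#' zero-intercept saturating-exponential fit of the integrated intensity,
#' `Q(t) = Q_inf * (1 - exp(-t / tau))` (compaction starts at perfusion, so
#' Q(0) = 0).
#'
#' @param times Time points (strictly increasing; s or min — the fitted
#'   rate is in the reciprocal unit).
#' @param R Spacing index per time point (>= 3 values), or `NULL` to skip.
#' @param Q Integrated foci intensity per time point (>= 4 values), or
#'   `NULL` to skip.
#' @return Object of class `timecourse_fit`: list(R_fit = list(slope,
#'   intercept, residuals), Q_fit = list(Q_inf, tau, residuals)).
#' @export
fit_timecourses <- function(times, R = NULL, Q = NULL) {
  if (is.unsorted(times, strictly = TRUE)) {
    stop_param("`times` must be strictly increasing")
  }
  R_fit <- NULL
  if (!is.null(R)) {
    if (length(R) < 3) stop_param("linear R(t) fit needs >= 3 time points")
    fit <- stats::lm(R ~ times)
    R_fit <- list(slope = unname(stats::coef(fit)[2]),
                  intercept = unname(stats::coef(fit)[1]),
                  residuals = unname(stats::residuals(fit)))
  }
  Q_fit <- NULL
  if (!is.null(Q)) {
    if (length(Q) < 4) stop_param("exponential Q(t) fit needs >= 4 time points")
    Q_inf0 <- max(Q) * 1.05
    half <- times[which.min(abs(Q - Q_inf0 / 2))]
    tau0 <- max(half / log(2), diff(range(times)) / 20)
    fit <- tryCatch(
      stats::nls(Q ~ Q_inf * (1 - exp(-times / tau)),
                 start = list(Q_inf = Q_inf0, tau = tau0),
                 control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
      error = function(e) {
        stop_param("exponential fit did not converge: %s (starts Q_inf = %.3g, tau = %.3g)",
                   conditionMessage(e), Q_inf0, tau0)
      })
    co <- stats::coef(fit)
    Q_fit <- list(Q_inf = unname(co["Q_inf"]), tau = unname(co["tau"]),
                  residuals = unname(stats::residuals(fit)),
                  # tau outside the resolvable window: longer than 10x the
                  # observation span, or shorter than the sampling interval
                  degenerate_tau = unname(co["tau"]) > 10 * diff(range(times)) ||
                    unname(co["tau"]) < min(diff(times)))
  }
  structure(list(R_fit = R_fit, Q_fit = Q_fit, times = times),
            class = "timecourse_fit")
}

#' @export
print.timecourse_fit <- function(x, ...) {
  cat("Compaction time-course fits\n")
  if (!is.null(x$R_fit)) {
    cat(sprintf("  R(t): slope %.4g per time unit, intercept %.4g\n",
                x$R_fit$slope, x$R_fit$intercept))
  }
  if (!is.null(x$Q_fit)) {
    cat(sprintf("  Q(t) = Q_inf (1 - exp(-t/tau)): Q_inf = %.4g, tau = %.4g%s\n",
                x$Q_fit$Q_inf, x$Q_fit$tau,
                if (isTRUE(x$Q_fit$degenerate_tau)) " [tau >> observation span]" else ""))
  }
  invisible(x)
}
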