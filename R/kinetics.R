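# Single-molecule kinetics: dwell-time extraction and bound fraction,
# censored exponential survival fits (mono and bi), mean-square-displacement
# diffusion estimation, and kymographs.

#' Extract dwell times and the bound fraction from tracks
#'
#' A dwell is a contiguous run of frames in which a molecule is present.
#' Runs touching the first or last frame of the observation window are
#' right-censored (the true dwell is at least the observed one). The bound
#' fraction is the proportion of dwells longer than `threshold_frames`
#' (default 6 frames = 0.3 s at 20 frames/s).
#'
#' @param tracks A [track_set()].
#' @param threshold_frames Detection ("bound") threshold in frames.
#' @param window_frames Frame range of the record, as c(first, last);
#'   defaults to the range observed across all tracks.
#' @param net Optional [network_model()]: each dwell is classified
#'   `"junction"` when the track centroid lies within the sampling distance
#'   c of a junction, else `"cable"`.
#' @return List with `dwells` (a [dwell_set()]) and `bound_fraction`.
#' @export
extract_dwells <- function(tracks, threshold_frames = 6L, window_frames = NULL,
                           net = NULL) {
  if (nrow(tracks) == 0L) stop_param("`tracks` is empty")
  dt <- attr(tracks, "frame_interval")
  if (is.null(window_frames)) window_frames <- range(tracks$frame)
  runs <- lapply(split(tracks, tracks$track_id), function(tr) {
    f <- tr$frame
    brk <- c(0L, which(diff(f) > 1L), length(f))
    out <- lapply(seq_len(length(brk) - 1L), function(i) {
      seg <- (brk[i] + 1L):brk[i + 1L]
      loc <- "unknown"
      if (!is.null(net) && nrow(net$junctions) > 0) {
        cx <- mean(tr$x[seg]); cy <- mean(tr$y[seg])
        dmin <- min(sqrt((net$junctions$x - cx)^2 + (net$junctions$y - cy)^2))
        loc <- if (dmin < net$c_sample) "junction" else "cable"
      }
      data.frame(frames = length(seg),
                 censored = f[seg[1]] <= window_frames[1] ||
                            f[seg[length(seg)]] >= window_frames[2],
                 location = loc)
    })
    do.call(rbind, out)
  })
  runs <- do.call(rbind, runs)
  d <- dwell_set(runs$frames, dt, censored = runs$censored,
                 location = runs$location,
                 threshold_frames = threshold_frames)
  list(dwells = d, bound_fraction = mean(runs$frames > threshold_frames))
}

#' Fit an exponential survival model to dwell times
#'
#' Maximum-likelihood fit of a mono- or bi-exponential dwell-time
#' distribution with left truncation at the detection threshold and right
#' censoring at the observation window. Frame-quantized dwells (the normal
#' case: camera frames, ceiling rule) use the exact discrete likelihood —
#' an uncensored dwell of m frames contributes `S((m-1) dt) - S(m dt)`, a
#' censored one `S(m dt)`, both conditioned on survival past the threshold.
#' For unquantized durations (`frame_interval = NULL` and a numeric input)
#' the continuous likelihood is used, whose mono MLE is the closed form
#' (number uncensored) / (total excess time).
#'
#' The bi-exponential fit runs deterministic-seeded multi-start
#' optimization (log-rate / logit-amplitude parameterization); rates are
#' reported in descending order. AIC is returned for model comparison.
#'
#' @param dwells A [dwell_set()], or a numeric vector of durations (s).
#' @param model `"mono"` or `"bi"`.
#' @param threshold_frames Left-truncation threshold in frames; defaults to
#'   the dwell-set attribute (6). Dwells of at most this many frames are
#'   discarded and the likelihood conditions on exceeding it.
#' @param frame_interval Frame interval (s); taken from the dwell set. Set
#'   `NULL` with a numeric input for the continuous-time likelihood.
#' @param censored Logical vector for numeric input (default none).
#' @param n_starts Random restarts for the bi-exponential optimizer.
#' @return Object of class `survival_fit`: list(model, rates (1/s,
#'   descending), amplitudes, loglik, aic, n, n_censored, threshold_frames,
#'   frame_interval).
#' @export
fit_survival <- function(dwells, model = c("mono", "bi"),
                         threshold_frames = NULL, frame_interval = NULL,
                         censored = NULL, n_starts = 10L) {
  model <- match.arg(model)
  if (inherits(dwells, "dwell_set")) {
    frame_interval <- frame_interval %||% attr(dwells, "frame_interval")
    threshold_frames <- threshold_frames %||% attr(dwells, "threshold_frames")
    frames <- dwells$frames
    cens <- dwells$censored
  } else {
    t_obs <- as.numeric(dwells)
    cens <- censored %||% rep(FALSE, length(t_obs))
    if (!is.null(frame_interval)) {
      frames <- as.integer(round(t_obs / frame_interval))
    } else {
      frames <- NULL
    }
  }
  threshold_frames <- as.integer(threshold_frames %||% 0L)

  if (!is.null(frame_interval)) {
    keep <- frames > threshold_frames
    frames <- frames[keep]; cens <- cens[keep]
    n_unc <- sum(!cens)
    if (model == "mono" && n_unc < 20) stop_param("mono fit needs >= 20 uncensored dwells")
    if (model == "bi" && n_unc < 100) stop_param("bi fit needs >= 100 uncensored dwells")
    if (stats::var(frames) == 0) stop_param("degenerate likelihood: all dwells equal")
    fit <- fit_exp_discrete(frames, cens, frame_interval, threshold_frames,
                            model, n_starts)
  } else {
    t0 <- threshold_frames  # threshold in the same (continuous) time unit: 0 unless given
    keep <- t_obs > t0
    t_obs <- t_obs[keep]; cens <- cens[keep]
    n_unc <- sum(!cens)
    if (model == "mono" && n_unc < 20) stop_param("mono fit needs >= 20 uncensored dwells")
    if (model == "bi" && n_unc < 100) stop_param("bi fit needs >= 100 uncensored dwells")
    if (stats::var(t_obs) == 0) stop_param("degenerate likelihood: all dwells equal")
    fit <- fit_exp_continuous(t_obs, cens, t0, model, n_starts)
  }
  structure(c(fit, list(model = model, n = length(cens), n_censored = sum(cens),
                        threshold_frames = threshold_frames,
                        frame_interval = frame_interval)),
            class = "survival_fit")
}

# survival function of an exponential mixture
mix_surv <- function(t, amp, rate) {
  drop(exp(-outer(t, rate)) %*% amp)
}

# discrete (frame-quantized) negative log-likelihood, truncated at m0 frames
nll_discrete <- function(amp, rate, m, cens, dt, m0) {
  # aggregate over unique (m, cens) for speed
  key <- m * 2L + as.integer(cens)
  agg <- rowsum(rep(1, length(key)), key)
  u <- as.integer(rownames(agg))
  um <- u %/% 2L; uc <- (u %% 2L) == 1L
  s_thr <- mix_surv(m0 * dt, amp, rate)
  s_hi <- mix_surv((um - 1L) * dt, amp, rate)
  s_lo <- mix_surv(um * dt, amp, rate)
  ll <- numeric(length(u))
  ll[!uc] <- log(pmax(s_hi[!uc] - s_lo[!uc], 1e-300))
  ll[uc] <- log(pmax(s_lo[uc], 1e-300))
  -sum(agg * (ll - log(s_thr)))
}

fit_exp_discrete <- function(m, cens, dt, m0, model, n_starts) {
  x <- m - m0
  if (model == "mono") {
    # geometric closed form with censoring:
    # q = P(survive one more frame); S = total "failure-free" frames
    S <- sum(x[!cens] - 1L) + sum(x[cens])
    U <- sum(!cens)
    q <- S / (S + U)
    k <- -log(q) / dt
    nll <- nll_discrete(1, k, m, cens, dt, m0)
    return(list(rates = k, amplitudes = 1, loglik = -nll, aic = 2 * nll + 2))
  }
  k0 <- -log(max(sum(x[!cens] - 1L) + sum(x[cens]), 1) /
             (sum(x[!cens] - 1L) + sum(x[cens]) + sum(!cens))) / dt
  obj <- function(th) {
    a <- stats::plogis(th[1]); k <- exp(th[2:3])
    nll_discrete(c(a, 1 - a), k, m, cens, dt, m0)
  }
  best <- multistart_optim(obj, k0, n_starts)
  a <- stats::plogis(best$par[1]); k <- exp(best$par[2:3])
  pack_bi(a, k, -best$value)
}

fit_exp_continuous <- function(t_obs, cens, t0, model, n_starts) {
  ex <- t_obs - t0
  if (model == "mono") {
    k <- sum(!cens) / sum(ex)
    ll <- sum(log(k) - k * ex[!cens]) + sum(-k * ex[cens])
    return(list(rates = k, amplitudes = 1, loglik = ll, aic = -2 * ll + 2))
  }
  k0 <- sum(!cens) / sum(ex)
  obj <- function(th) {
    a <- stats::plogis(th[1]); k <- exp(th[2:3])
    amp <- c(a, 1 - a)
    s_thr <- mix_surv(t0, amp, k)
    f <- drop(exp(-outer(t_obs[!cens], k)) %*% (amp * k))
    s <- mix_surv(t_obs[cens], amp, k)
    -(sum(log(pmax(f, 1e-300))) + sum(log(pmax(s, 1e-300))) -
        length(t_obs) * log(s_thr))
  }
  best <- multistart_optim(obj, k0, n_starts)
  a <- stats::plogis(best$par[1]); k <- exp(best$par[2:3])
  pack_bi(a, k, -best$value)
}

multistart_optim <- function(obj, k0, n_starts) {
  ratios <- c(0.2, 1, 5, 25, 100)
  mixes <- c(0.3, 0.5, 0.7)
  starts <- list()
  for (r in ratios) for (a in mixes) {
    starts[[length(starts) + 1L]] <- c(stats::qlogis(a),
                                       log(k0 * sqrt(r)), log(k0 / sqrt(r)))
  }
  starts <- starts[seq_len(min(length(starts), max(n_starts, 2L)))]
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) stop_param("bi-exponential fit failed to converge; try model = 'mono'")
  best
}

pack_bi <- function(a, k, ll) {
  amp <- c(a, 1 - a)
  ord <- order(k, decreasing = TRUE)
  k <- k[ord]; amp <- amp[ord]
  if (min(amp) < 1e-4 || k[1] / k[2] < 1 + 1e-6) {
    stop_param("bi-exponential mixture collapsed to a boundary; use model = 'mono'")
  }
  list(rates = k, amplitudes = amp, loglik = ll, aic = -2 * ll + 2 * 3)
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("%s-exponential dwell-time fit (n = %d, %d censored)\n",
              x$model, x$n, x$n_censored))
  for (i in seq_along(x$rates)) {
    cat(sprintf("  component %d: amplitude %.3f, k_off = %.4g 1/s\n",
                i, x$amplitudes[i], x$rates[i]))
  }
  cat(sprintf("  logLik %.2f, AIC %.2f\n", x$loglik, x$aic))
  invisible(x)
}

#' Select between mono- and bi-exponential dwell models
#'
#' Both models are fitted and compared by BIC (the stronger `log(n)`
#' complexity penalty keeps a one-component truth from being overfitted by
#' the three-parameter mixture). A bi fit that collapses to a boundary
#' falls back to mono.
#'
#' @param dwells A [dwell_set()].
#' @param ... Passed to [fit_survival()].
#' @return The winning `survival_fit`; attribute `bic_table` holds both
#'   BIC values.
#' @export
select_survival_model <- function(dwells, ...) {
  mono <- fit_survival(dwells, model = "mono", ...)
  bi <- tryCatch(fit_survival(dwells, model = "bi", ...), error = function(e) NULL)
  bic <- function(fit) {
    if (is.null(fit)) return(NA_real_)
    k <- 2 * length(fit$rates) - 1
    -2 * fit$loglik + k * log(fit$n)
  }
  tab <- c(mono = bic(mono), bi = bic(bi))
  if (is.null(bi) || tab["mono"] <= tab["bi"]) {
    structure(mono, bic_table = tab)
  } else {
    structure(bi, bic_table = tab)
  }
}

#' Ensemble mean-square displacement of a track set
#'
#' Time-averaged MSD per track over all start points, pooled across tracks
#' with per-lag pair weighting: `msd(lag) = sum of squared displacements /
#' number of pairs` over every frame pair separated by exactly `lag` frames.
#'
#' @param tracks A [track_set()].
#' @param max_lag Largest lag in frames; truncated with a warning when no
#'   track is long enough.
#' @return Object of class `msd_curve`: data.frame (lag, dT, msd, n_pairs)
#'   with attribute `frame_interval`.
#' @export
msd_curve <- function(tracks, max_lag = 10L) {
  dt <- attr(tracks, "frame_interval")
  by_track <- split(tracks[, c("frame", "x", "y")], tracks$track_id)
  longest <- max(vapply(by_track, function(tr) diff(range(tr$frame)), numeric(1)))
  if (max_lag > longest) {
    warning(sprintf("max_lag truncated from %d to %d (longest track)", max_lag, longest))
    max_lag <- longest
  }
  if (max_lag < 1) stop_param("no usable lags: need a track with >= 2 localizations")
  ss <- numeric(max_lag); np <- numeric(max_lag)
  for (tr in by_track) {
    f <- tr$frame
    for (lag in seq_len(max_lag)) {
      j <- match(f + lag, f)
      ok <- !is.na(j)
      if (!any(ok)) next
      dx <- tr$x[j[ok]] - tr$x[ok]
      dy <- tr$y[j[ok]] - tr$y[ok]
      ss[lag] <- ss[lag] + sum(dx^2 + dy^2)
      np[lag] <- np[lag] + sum(ok)
    }
  }
  keep <- np > 0
  structure(data.frame(lag = which(keep), dT = which(keep) * dt,
                       msd = ss[keep] / np[keep], n_pairs = np[keep]),
            frame_interval = dt,
            class = c("msd_curve", "data.frame"))
}

#' Lateral diffusion coefficient from an MSD curve
#'
#' Weighted least-squares line through the first `fit_lags` lags (weights =
#' pair counts): in 2-D, `D_lat = slope / 4`; the intercept is retained as
#' the localization-noise floor (approximately `4 sigma_loc^2`).
#'
#' @param curve An [msd_curve()].
#' @param fit_lags Number of initial lags to fit (>= 2).
#' @return Object of class `dlat_fit`: list(D_lat (um^2/s), offset (um^2),
#'   slope, fit_lags, clamped).
#' @export
fit_dlat <- function(curve, fit_lags = 4L) {
  if (fit_lags < 2) stop_param("`fit_lags` must be >= 2")
  if (fit_lags > nrow(curve)) stop_param("`fit_lags` exceeds available lags")
  d <- curve[seq_len(fit_lags), ]
  fit <- stats::lm(msd ~ dT, data = d, weights = d$n_pairs)
  slope <- unname(stats::coef(fit)[2])
  offset <- unname(stats::coef(fit)[1])
  clamped <- slope < 0
  if (clamped) warning("negative MSD slope; reporting D_lat = 0")
  structure(list(D_lat = max(slope, 0) / 4, offset = offset, slope = slope,
                 fit_lags = fit_lags, clamped = clamped),
            class = "dlat_fit")
}

#' @export
print.dlat_fit <- function(x, ...) {
  cat(sprintf("MSD line fit (first %d lags): D_lat = %.4g um^2/s, offset = %.4g um^2%s\n",
              x$fit_lags, x$D_lat, x$offset,
              if (x$clamped) " [slope clamped at 0]" else ""))
  invisible(x)
}

#' Kymograph along a polyline
#'
#' For each frame of an image stack, the intensity profile along a polyline
#' (resampled at pixel spacing), taking the maximum over an odd transverse
#' width; profiles are stacked into a time x arc-length image.
#'
#' @param stack 3-D numeric array (rows y, cols x, frames) or a list of
#'   `netarch_image` frames.
#' @param polyline Matrix of (x, y) vertices in micrometers.
#' @param width Transverse width in pixels (odd).
#' @param pixel_size Pixel size (um); taken from attributes when absent.
#' @return Matrix (frames x arc-length samples) of class `kymograph` with
#'   attributes `pixel_size` and `spacing`.
#' @export
kymograph <- function(stack, polyline, width = 1L, pixel_size = NULL) {
  if (is.list(stack)) {
    pixel_size <- pixel_size %||% attr(stack[[1]], "pixel_size")
    stack <- simplify2array(lapply(stack, unclass))
  }
  pixel_size <- pixel_size %||% attr(stack, "pixel_size")
  if (is.null(pixel_size)) stop_param("`pixel_size` is required")
  if (width %% 2 == 0) stop_param("`width` must be odd")
  nr <- dim(stack)[1]; nc <- dim(stack)[2]; nt <- dim(stack)[3]
  path <- resample_polyline(as.matrix(polyline), pixel_size)
  seg <- diff(path)
  tang <- rbind(seg, seg[nrow(seg), , drop = FALSE])
  tang <- tang / sqrt(rowSums(tang^2))
  normal <- cbind(-tang[, 2], tang[, 1])
  offs <- (-(width - 1L) / 2):((width - 1L) / 2)
  samp <- lapply(offs, function(o) {
    px <- path[, 1] + o * pixel_size * normal[, 1]
    py <- path[, 2] + o * pixel_size * normal[, 2]
    cc <- round(px / pixel_size) + 1L
    rr <- round(py / pixel_size) + 1L
    if (any(cc < 1 | cc > nc | rr < 1 | rr > nr)) {
      stop_param("polyline (with transverse width) extends outside the image")
    }
    cbind(rr, cc)
  })
  ky <- matrix(0, nt, nrow(path))
  for (t in seq_len(nt)) {
    fr <- stack[, , t]
    prof <- do.call(pmax, lapply(samp, function(s) fr[s]))
    ky[t, ] <- prof
  }
  structure(ky, pixel_size = pixel_size, spacing = pixel_size,
            class = c("kymograph", "matrix", "array"))
}
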