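# Dwell times, bound fraction, survival fits, MSD/diffusion, kymographs.

test_that("extract_dwells counts runs, censors ends, computes bound fraction", {
  dt <- 0.05
  tr <- rbind(
    data.frame(track_id = "a", frame = 10:19, x = 1, y = 1, intensity = 1),  # 10 frames
    data.frame(track_id = "b", frame = 30:32, x = 2, y = 2, intensity = 1),  # 3 frames
    data.frame(track_id = "c", frame = 51:100, x = 3, y = 3, intensity = 1)  # touches end
  )
  ts <- track_set(tr, dt)
  res <- extract_dwells(ts, threshold_frames = 6, window_frames = c(0, 100))
  d <- res$dwells
  expect_equal(sort(d$frames), c(3, 10, 50))
  expect_equal(d$censored[order(d$frames)], c(FALSE, FALSE, TRUE))
  expect_equal(d$duration[order(d$frames)][2], 0.5)  # 10 frames at 20 fps
  expect_equal(res$bound_fraction, 2 / 3)
  # bound fraction monotone non-increasing in the threshold
  bf <- sapply(c(2, 6, 20, 60), function(th) {
    extract_dwells(ts, threshold_frames = th, window_frames = c(0, 100))$bound_fraction
  })
  expect_true(all(diff(bf) <= 0))
})

test_that("dwells split at gaps and classify junction vs cable locations", {
  dt <- 0.05
  tr <- data.frame(track_id = "a", frame = c(1:5, 10:14), x = c(rep(1, 5), rep(9, 5)),
                   y = 1, intensity = 1)
  net <- network_model(list(), data.frame(x = 1, y = 1), field_spec(20, 20),
                       c_sample = 0.625)
  res <- extract_dwells(track_set(tr, dt), window_frames = c(0, 20), net = net)
  expect_equal(nrow(res$dwells), 2)
  expect_setequal(res$dwells$location, c("junction", "cable"))
})

test_that("mono fit: closed form equals likelihood optimum, recovers rates", {
  # continuous likelihood: MLE is exactly 1 / mean
  set.seed(81)
  t_cont <- rexp(500, 1.7)
  fit_c <- fit_survival(t_cont, "mono", frame_interval = NULL)
  expect_equal(fit_c$rates, 1 / mean(t_cont), tolerance = 1e-10)
  # iterative route on the same data (bi with near-equal start collapses is
  # not used here; compare against optimize() on the continuous loglik)
  nll <- function(k) -sum(dexp(t_cont, k, log = TRUE))
  k_opt <- optimize(nll, c(0.01, 20))$minimum
  expect_equal(fit_c$rates, k_opt, tolerance = 1e-6)
  # discrete likelihood on frame-quantized data is unbiased at 20 fps
  d <- gen_dwell_times(cbind(1, 2.55), 1200, frame_interval = 0.05,
                       window = 60, seed = 82)
  fit_d <- fit_survival(d, "mono", threshold_frames = 0)
  expect_lt(abs(fit_d$rates - 2.55) / 2.55, 0.05)
  expect_error(fit_survival(dwell_set(rep(5, 50), 0.05), "mono",
                            threshold_frames = 0), "degenerate")
})

test_that("censoring is handled: heavy censoring does not bias k_off up", {
  d <- gen_dwell_times(cbind(1, 0.06), 3000, frame_interval = 0.05,
                       window = 20, seed = 83)  # mean dwell ~ window
  expect_gt(mean(d$censored), 0.2)
  fit <- fit_survival(d, "mono", threshold_frames = 0)
  expect_lt(abs(fit$rates - 0.06) / 0.06, 0.08)
})

test_that("survival fits are invariant to time-unit rescaling", {
  d <- gen_dwell_times(rbind(c(0.5, 1.0), c(0.5, 0.1)), 2000,
                       frame_interval = 0.05, window = 120, seed = 84)
  fit_s <- fit_survival(d, "bi", threshold_frames = 3)
  d_ms <- dwell_set(d$frames, 50, censored = d$censored)  # same frames, ms units
  fit_ms <- fit_survival(d_ms, "bi", threshold_frames = 3)
  expect_equal(fit_ms$rates * 1000, fit_s$rates, tolerance = 1e-4)
  expect_equal(fit_ms$amplitudes, fit_s$amplitudes, tolerance = 1e-5)
})

test_that("bi-exponential fit recovers well-separated mixtures", {
  d <- gen_dwell_times(rbind(c(0.43, 1.2), c(0.56, 0.06)), 5000,
                       frame_interval = 0.05, window = 60, seed = 85) |>
    suppressWarnings()
  fit <- fit_survival(d, "bi", threshold_frames = 6)
  expect_lt(abs(fit$rates[1] - 1.2) / 1.2, 0.15)
  expect_lt(abs(fit$rates[2] - 0.06) / 0.06, 0.15)
  expect_lt(abs(fit$amplitudes[1] - 0.43 / 0.99), 0.1)
  expect_true(all(diff(fit$rates) < 0))  # reported descending
})

test_that("model selection prefers the true model", {
  picks <- sapply(1:100, function(s) {
    mono_d <- gen_dwell_times(cbind(1, 0.8), 400, frame_interval = 0.05,
                              window = 60, seed = 9000 + s)
    bi_d <- gen_dwell_times(rbind(c(0.5, 2.0), c(0.5, 0.2)), 400,
                            frame_interval = 0.05, window = 60, seed = 9500 + s)
    c(mono = select_survival_model(mono_d, threshold_frames = 0)$model,
      bi = select_survival_model(bi_d, threshold_frames = 0)$model)
  })
  expect_gte(mean(picks["mono", ] == "mono"), 0.95)
  expect_gte(mean(picks["bi", ] == "bi"), 0.95)
})

test_that("MSD estimator matches the Brownian closed form", {
  f <- field_spec(50, 50)
  tr <- gen_tracks(0.25, 150, 60, frame_interval = 0.05, field = f, seed = 86)
  curve <- msd_curve(tr, max_lag = 8)
  expect_equal(curve$msd, 4 * 0.25 * curve$dT, tolerance = 0.05)
  expect_true(all(diff(curve$n_pairs) < 0))
  # translation invariance
  tr2 <- tr; tr2$x <- tr2$x + 100; tr2$y <- tr2$y - 40
  attr(tr2, "frame_interval") <- 0.05
  expect_equal(msd_curve(tr2, 8)$msd, curve$msd, tolerance = 1e-9)
  expect_warning(msd_curve(gen_tracks(0.1, 3, 10, field = f, seed = 87),
                           max_lag = 50), "truncated")
})

test_that("fit_dlat: exact line, noise offset, negative-slope clamp", {
  lags <- 1:6
  exact <- structure(data.frame(lag = lags, dT = lags * 0.05,
                                msd = 4 * 0.25 * lags * 0.05,
                                n_pairs = rep(100, 6)),
                     frame_interval = 0.05,
                     class = c("msd_curve", "data.frame"))
  expect_equal(fit_dlat(exact)$D_lat, 0.25, tolerance = 1e-12)
  # D = 0 with localization noise: plateau ~ 4 sigma^2, D ~ 0
  f <- field_spec(50, 50)
  tr <- gen_tracks(0, 300, 40, loc_noise_sd = 0.03, field = f, seed = 88)
  dl <- suppressWarnings(fit_dlat(msd_curve(tr, 6)))
  expect_lt(dl$D_lat, 0.0005)
  expect_equal(dl$offset, 4 * 0.03^2, tolerance = 0.15)
  # recovery at the post-treatment diffusivity
  tr2 <- gen_tracks(0.37, 200, 100, frame_interval = 0.05,
                    loc_noise_sd = 0.02, field = f, seed = 89)
  dl2 <- fit_dlat(msd_curve(tr2, 10))
  expect_lt(abs(dl2$D_lat - 0.37) / 0.37, 0.05)
})

test_that("kymograph streaks encode presence duration and speed", {
  f <- field_spec(10, 10, pixel_size = 0.1)
  nt <- 40
  mk_frame <- function(spots) {
    img <- matrix(10, 100, 100)
    for (s in spots) {
      cc <- round(s[1] / 0.1) + 1L; rr <- round(s[2] / 0.1) + 1L
      img[rr, cc] <- 1000
    }
    structure(img, pixel_size = 0.1, class = c("netarch_image", "matrix", "array"))
  }
  # static spot on the line, present frames 10..29 (20 frames = 1.0 s at 20 fps)
  stack <- lapply(seq_len(nt), function(t) {
    mk_frame(if (t >= 10 && t <= 29) list(c(5, 5)) else list())
  })
  ky <- kymograph(stack, polyline = cbind(c(1, 9), c(5, 5)), width = 3)
  col <- round(4 / 0.1) + 1L  # arc-length sample at x = 5 starts at x = 1
  streak <- which(ky[, col] > 500)
  expect_equal(range(streak), c(10, 29))
  expect_equal(length(streak) * 0.05, 1.0)
  # moving spot: slope of the streak = speed
  speed <- 0.15  # um/frame
  stack2 <- lapply(seq_len(nt), function(t) mk_frame(list(c(1 + speed * (t - 1), 5))))
  ky2 <- kymograph(stack2, polyline = cbind(c(1, 9), c(5, 5)), width = 3)
  pos <- apply(ky2, 1, which.max)
  fitted_speed <- coef(lm(pos ~ seq_len(nt)))[2] * 0.1  # um/frame
  expect_equal(unname(fitted_speed), speed, tolerance = 0.1 / 2)
  expect_error(kymograph(stack, polyline = cbind(c(1, 20), c(5, 5)), width = 3),
               "outside")
  expect_error(kymograph(stack, polyline = cbind(c(1, 9), c(5, 5)), width = 2),
               "odd")
})
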