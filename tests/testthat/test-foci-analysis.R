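# Focus segmentation, the area/intensity filters, integrated intensity and
# compaction time-course fits.

make_foci_field <- function() field_spec(80, 80, pixel_size = 0.25)

test_that("detect_foci applies the strict >min_area filter", {
  f <- make_foci_field()
  # half-max areas 2*pi*log(2)*sd^2: sd 3.7 -> 59.6 um^2 (kept),
  # sd 3.0 -> 39.2 um^2 (dropped by the > 50 rule)
  foci <- data.frame(x = c(20, 60), y = c(20, 60), sd = c(3.7, 3.0),
                     peak = c(1000, 1000))
  img <- gen_foci_image(foci, background = 0, field = f)
  tab <- detect_foci(img, intensity_threshold = 500, min_area = 50)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$x, 20, tolerance = f$pixel_size)
  expect_equal(tab$y, 20, tolerance = f$pixel_size)
  # with a permissive area filter both are found, centroids at blob centers
  tab2 <- detect_foci(img, intensity_threshold = 500, min_area = 10)
  expect_equal(nrow(tab2), 2)
  expect_equal(tab2$x, c(20, 60), tolerance = f$pixel_size)
  # blank image -> empty table; constant image cannot be auto-thresholded
  blank <- gen_foci_image(data.frame(), background = 10, field = f)
  expect_equal(nrow(detect_foci(blank, intensity_threshold = 50)), 0)
  expect_error(detect_foci(blank, intensity_threshold = "otsu"), "constant")
})

test_that("segmented area and Q match the analytic blob geometry", {
  f <- make_foci_field()
  img <- gen_foci_image(data.frame(x = 40, y = 40, sd = 4, peak = 1000),
                        background = 0, field = f)
  gt <- attr(img, "ground_truth")
  tab <- detect_foci(img, intensity_threshold = 500, min_area = 50)
  expect_equal(nrow(tab), 1)
  # pixel-counted area above half max vs analytic pi*2*log(2)*sd^2
  expect_equal(tab$area_um2, gt$half_max_area_um2, tolerance = 0.03)
  # mean intensity over the half-max disk of a Gaussian:
  # (peak - peak/2) / log(2) = 721.3 for peak 1000
  expect_equal(tab$q_foci, 500 / log(2), tolerance = 10)
})

test_that("detect_foci is monotone in its thresholds", {
  f <- make_foci_field()
  set.seed(51)
  foci <- data.frame(x = runif(6, 15, 65), y = runif(6, 15, 65),
                     sd = runif(6, 2, 5), peak = runif(6, 600, 1200))
  img <- gen_foci_image(foci, background = 50, field = f, noise = TRUE,
                        seed = 52)
  n_at <- function(thr, area) nrow(detect_foci(img, thr, min_area = area))
  expect_true(all(diff(sapply(c(200, 400, 600, 800), n_at, area = 5)) <= 0))
  expect_true(all(diff(sapply(c(5, 20, 50, 80), function(a) n_at(300, a))) <= 0))
})

test_that("sum_Q_foci implements sum(A * Q) and is additive", {
  tab <- structure(data.frame(focus_id = 1:3, x = 1:3, y = 1:3,
                              area_px = c(100, 200, 50),
                              area_um2 = c(6.25, 12.5, 3.125),
                              q_foci = c(10, 5, 40)),
                   class = c("foci_table", "data.frame"))
  expect_equal(sum_Q_foci(tab), 100 * 10 + 200 * 5 + 50 * 40)
  expect_equal(sum_Q_foci(tab[0, ]), 0)
  expect_equal(sum_Q_foci(tab[1:2, ]) + sum_Q_foci(tab[3, ]), sum_Q_foci(tab))
})

test_that("sum_Q_foci is translation-invariant and gain-linear", {
  f <- make_foci_field()
  foci <- data.frame(x = c(25, 50), y = c(30, 55), sd = c(4, 4.5),
                     peak = c(1000, 900))
  img1 <- gen_foci_image(foci, background = 0, field = f)
  shift <- foci; shift$x <- shift$x + 5; shift$y <- shift$y - 5
  img2 <- gen_foci_image(shift, background = 0, field = f)
  q1 <- sum_Q_foci(detect_foci(img1, 400, min_area = 30))
  q2 <- sum_Q_foci(detect_foci(img2, 400, min_area = 30))
  expect_equal(q1, q2, tolerance = 0.01)
  gained <- structure(unclass(img1) * 3, pixel_size = f$pixel_size,
                      class = class(img1))
  q3 <- sum_Q_foci(detect_foci(gained, 1200, min_area = 30))
  expect_equal(q3, 3 * q1, tolerance = 1e-6)
})

test_that("foci spacing index reproduces the lattice and Poisson endpoints", {
  f <- field_spec(100, 100, pixel_size = 0.25)
  hex <- gen_hexagonal_pattern(0.04, 0, f, seed = 61)
  tab <- data.frame(focus_id = seq_len(nrow(hex$points)),
                    x = hex$points[, 1], y = hex$points[, 2],
                    area_px = 1, area_um2 = 1, q_foci = 1)
  a <- hex$ground_truth$spacing
  R_hex <- foci_spacing_index(tab, f, sigma = hex$ground_truth$density_lattice,
                              edge_margin = 2 * a)
  expect_equal(as.numeric(R_hex), 2 * sqrt(2 / sqrt(3)), tolerance = 0.01)
  po <- gen_poisson_pattern(0.05, f, seed = 62)
  tabp <- data.frame(focus_id = seq_len(nrow(po$points)),
                     x = po$points[, 1], y = po$points[, 2],
                     area_px = 1, area_um2 = 1, q_foci = 1)
  expect_equal(as.numeric(foci_spacing_index(tabp, f)), 1, tolerance = 0.15)
  expect_error(foci_spacing_index(tabp[1, ], f), "at least 2")
})

test_that("time-course fits recover linear R and saturating-exponential Q", {
  t <- seq(0, 12, by = 1)
  fit <- fit_timecourses(t, R = 0.5 + 0.04 * t)
  expect_equal(fit$R_fit$slope, 0.04, tolerance = 1e-12)
  expect_equal(fit$R_fit$intercept, 0.5, tolerance = 1e-12)
  set.seed(71)
  Q <- 1000 * (1 - exp(-t / 3)) * (1 + rnorm(length(t), 0, 0.05))
  fit2 <- fit_timecourses(t, Q = Q)
  expect_lt(abs(fit2$Q_fit$Q_inf - 1000) / 1000, 0.10)
  expect_lt(abs(fit2$Q_fit$tau - 3) / 3, 0.10)
  # constant series: zero slope, degenerate tau flagged
  fit3 <- fit_timecourses(t, R = rep(2, length(t)),
                          Q = rep(500, length(t)) + c(1e-9, rep(0, 12)))
  expect_equal(fit3$R_fit$slope, 0, tolerance = 1e-9)
  expect_true(is.null(fit3$Q_fit) || isTRUE(fit3$Q_fit$degenerate_tau))
  expect_error(fit_timecourses(c(1, 2), R = c(1, 2)), ">= 3")
})

test_that("end-to-end: noise-free render recovers the generator ground truth", {
  f <- make_foci_field()
  foci <- data.frame(x = c(20, 45, 62), y = c(55, 25, 60),
                     sd = c(4, 3.8, 4.4), peak = c(900, 1100, 1000))
  img <- gen_foci_image(foci, background = 40, field = f)
  gt <- attr(img, "ground_truth")
  tab <- detect_foci(img, intensity_threshold = "otsu", min_area = 50)
  expect_equal(nrow(tab), gt$count)
  ord <- order(tab$x)
  expect_equal(tab$x[ord], sort(foci$x), tolerance = 2 * f$pixel_size)
  # Eq. 4 hand computation on the segmented table
  expect_equal(sum_Q_foci(tab), sum(tab$area_px * tab$q_foci))
})
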