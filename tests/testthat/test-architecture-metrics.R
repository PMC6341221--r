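# Junction spatial statistics, cable intensity, skewness, curvature and
# persistence length.

test_that("density, R_NN and r_rand follow their definitions", {
  f <- field_spec(10, 10)
  set.seed(1)
  p <- point_pattern(cbind(runif(100, 0, 10), runif(100, 0, 10)), f)
  expect_equal(as.numeric(junction_density(p, "field")), 1.0)
  expect_gte(as.numeric(junction_density(p, "hull")),
             as.numeric(junction_density(p, "field")))
  # two points 1 um apart
  p2 <- point_pattern(cbind(c(0, 1), c(0, 0)), f)
  expect_equal(mean_nn_distance(p2)$R_NN, 1.0)
  # collinear 0, 1, 3: r_NN = (1, 1, 2)
  p3 <- point_pattern(cbind(c(0, 1, 3), c(0, 0, 0)), f)
  nn <- mean_nn_distance(p3)
  expect_equal(sort(nn$r_NN), c(1, 1, 2))
  expect_equal(nn$R_NN, 4 / 3)
  # duplicates give zero distances
  p4 <- point_pattern(cbind(c(0, 0, 3), c(0, 0, 0)), f)
  expect_equal(sort(mean_nn_distance(p4)$r_NN), c(0, 0, 3))
  # Eq. 5 substitutions
  expect_equal(random_reference(0.25), 1.0)
  expect_equal(random_reference(1.0), 0.5)
  expect_equal(random_reference(4.0), 0.25)
  expect_error(random_reference(0), "positive")
  expect_error(mean_nn_distance(point_pattern(cbind(1, 1), f)), "at least 2")
})

test_that("randomness index is invariant to rigid motion and rescaling", {
  f <- field_spec(30, 30)
  p <- gen_poisson_pattern(0.5, f, seed = 77)
  R0 <- as.numeric(randomness_index(p))
  # rotate by 90 degrees about the field center (square field -> same frame)
  rot <- cbind(30 - p$points[, 2], p$points[, 1])
  expect_equal(as.numeric(randomness_index(point_pattern(rot, f))), R0,
               tolerance = 1e-12)
  # translate within a padded field, hull mode (density from the same hull)
  big <- field_spec(60, 60)
  sh <- point_pattern(p$points + 10, big)
  expect_equal(as.numeric(randomness_index(sh, area_mode = "hull")),
               as.numeric(randomness_index(point_pattern(p$points, big),
                                           area_mode = "hull")),
               tolerance = 1e-12)
  # uniform rescaling: R_NN and r_rand scale identically
  f2 <- field_spec(90, 90)
  expect_equal(as.numeric(randomness_index(point_pattern(p$points * 3, f2))),
               R0, tolerance = 1e-12)
})

test_that("randomness index matches the naive O(N^2) oracle", {
  set.seed(2024)
  for (i in 1:25) {
    n <- sample(10:500, 1)
    f <- field_spec(runif(1, 5, 30), runif(1, 5, 30))
    p <- point_pattern(cbind(runif(n, 0, f$width), runif(n, 0, f$height)), f)
    expect_equal(as.numeric(randomness_index(p)), randomness_oracle(p),
                 tolerance = 1e-9)
  }
})

test_that("ordering: clustered < Poisson < hexagonal at matched density", {
  Rs <- sapply(1:20, function(s) {
    f <- field_spec(60, 60)
    c(cl = as.numeric(randomness_index(
        gen_clustered_pattern(0.025, 10, 0.4, f, seed = s))),
      po = as.numeric(randomness_index(
        gen_poisson_pattern(0.25, f, seed = 1000 + s))),
      hx = as.numeric(randomness_index(
        gen_hexagonal_pattern(0.25, 0.3, f, seed = 2000 + s))))
  })
  m <- rowMeans(Rs)
  expect_lt(m["cl"], m["po"])
  expect_lt(m["po"], m["hx"])
})

test_that("default (uncorrected) R has a small positive boundary bias", {
  # border points lack neighbors beyond the field, inflating their r_NN;
  # the guard-zone option removes the bias
  rs <- sapply(1:10, function(s) {
    p <- gen_poisson_pattern(1, field_spec(50, 50), seed = 300 + s)
    c(raw = as.numeric(randomness_index(p)),
      guarded = as.numeric(randomness_index(p, edge_margin = 1)))
  })
  expect_gt(mean(rs["raw", ]), mean(rs["guarded", ]))
  expect_lt(abs(mean(rs["guarded", ]) - 1), 0.02)
})

test_that("cable intensity Q: stored, image-sampled, background-subtracted", {
  f <- field_spec(10, 10, pixel_size = 0.1)
  sn <- straight_snake(6, intensity = 500, y = 5)
  net <- network_model(list(sn), NULL, f)
  expect_equal(cable_intensity(net)$Q_mean, 500)
  expect_equal(cable_intensity(net, background = 100)$Q_mean, 400)
  # renderer linearity seen through image-sampled Q
  s1 <- straight_snake(6, y = 3, id = "m1", multiplicity = 1)
  s2 <- straight_snake(6, y = 7, id = "m2", multiplicity = 2)
  img <- render_network_image(list(s1, s2), psf_sd = 0.15, background = 0,
                              field = f, noise = FALSE)
  q <- cable_intensity(network_model(list(s1, s2), NULL, f), image = img)$Q
  expect_equal(unname(q["m2"] / q["m1"]), 2, tolerance = 0.02)
  out <- snake(cbind(c(2, 50), c(5, 5), 0), id = "stray")
  expect_error(
    cable_intensity(network_model(list(out), NULL, field_spec(100, 10, 0.1)),
                    image = img),
    "stray")
})

test_that("skewness is the adjusted Fisher-Pearson (spreadsheet) statistic", {
  sym <- c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1)  # mirror pairs
  expect_equal(intensity_skewness(sym), 0, tolerance = 1e-12)
  set.seed(10)
  x <- rexp(2e5)
  expect_equal(intensity_skewness(x), 2, tolerance = 0.1)
  # frozen hand computation of the n/((n-1)(n-2)) sum(z^3) formula
  # S = 1.5 * sum(z^3) with z = (x - 3)/sqrt(7): 1.5 * 0.972 = 1.458
  expect_equal(intensity_skewness(c(1, 2, 6)), 1.458, tolerance = 1e-3)
  expect_error(intensity_skewness(c(3, 3, 3)), "constant")
  expect_error(intensity_skewness(c(1, 2)), "at least 3")
})

test_that("curvature: straight lines, circles and the WLC variance law", {
  st <- straight_snake(10)
  expect_equal(snake_curvature(st, 0.625)$K, 0)
  circ <- circle_snake(r = 5)
  expect_equal(snake_curvature(circ, 0.25)$K, 1 / 5, tolerance = 0.01)
  f <- field_spec(1000, 1000)
  sn <- gen_wlc_snake(8, 0.625, 8000, f, seed = 21)
  cv <- snake_curvature(sn, 0.625)
  m2 <- mean(cv$dT^2)
  se <- m2 * sqrt(2 / length(cv$dT))
  expect_lt(abs(m2 - 0.625 / 8), 3 * se)
  tiny <- snake(cbind(c(0, 0.2), c(0, 0), 0), id = "tiny")
  expect_warning(res <- snake_curvature(tiny, 0.625), "skipped")
  expect_null(res)
})

test_that("persistence-length MLE recovers truth and is scale-consistent", {
  k <- sample_wlc_curvatures(10000, l_p = 10, c_sample = 0.625, seed = 31)
  fit <- fit_persistence_length(k, 0.625)
  expect_lt(abs(fit$l_p - 10) / 10, 0.10)
  expect_gt(fit$ks_p, 0.01)
  # l_p c = 6.25 parameterization
  k2 <- sample_wlc_curvatures(10000, l_p = 6.25, c_sample = 1, seed = 32)
  expect_lt(abs(fit_persistence_length(k2, 1)$l_p - 6.25) / 6.25, 0.10)
  expect_error(fit_persistence_length(rep(0, 100)), "infinite")
  expect_error(fit_persistence_length(k[1:5]), "at least 10")
  # estimate invariant to the resampling distance for delta_s << l_p, when
  # the underlying chain is sampled much more finely than delta_s (chord
  # resampling at a spacing comparable to the generation step biases the
  # tangent variance, which is why the contour is generated at step
  # delta_s/8 here)
  f <- field_spec(1e4, 1e4)
  sn <- gen_wlc_snake(10, 0.625 / 8, 60000, f, seed = 33)
  lp_fine <- fit_persistence_length(
    snake_curvature(sn, 0.625)$dT / 0.625, 0.625)$l_p
  lp_coarse <- fit_persistence_length(
    snake_curvature(sn, 1.25)$dT / 1.25, 1.25)$l_p
  expect_lt(abs(lp_fine - lp_coarse) / lp_fine, 0.15)
})

test_that("summarize_architecture assembles all descriptors", {
  f <- field_spec(60, 60)
  set.seed(41)
  snakes <- lapply(1:12, function(i) {
    gen_wlc_snake(10, 0.625, 60, f, seed = 500 + i,
                  start = c(runif(1, 10, 50), runif(1, 10, 50)))
  })
  snakes <- lapply(seq_along(snakes), function(i) {
    s <- snakes[[i]]; s$id <- sprintf("s%d", i)
    s$points[, 3] <- 400 + 20 * i
    s
  })
  pat <- gen_poisson_pattern(0.2, f, seed = 42)
  net <- network_model(snakes, data.frame(x = pat$points[, 1],
                                          y = pat$points[, 2]), f)
  s <- summarize_architecture(net)
  expect_s3_class(s, "architecture_summary")
  expect_equal(s$r_rand, 1 / (2 * sqrt(s$sigma)))
  expect_equal(s$R, s$R_NN / s$r_rand)
  expect_equal(s$Q, mean(400 + 20 * (1:12)))
  expect_false(is.na(s$S))
  expect_gt(s$l_p, 2)
  expect_output(print(s), "Network architecture summary")
})
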