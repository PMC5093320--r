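test_that("axial Von Mises fit handles canonical histograms", {
  # uniform weights: completely unaligned, sigma = 90
  expect_equal(fit_axial_von_mises(angular_histogram(rep(1, 45)))$sigma, 90)

  # all weight in one bin: mu at the bin centre, sigma below the bin width
  w <- numeric(45); w[12] <- 3   # bin centred at 46 deg with 4-deg bins
  f <- fit_axial_von_mises(angular_histogram(w, bin_width = 4))
  expect_equal(f$mu, 46)
  expect_lt(f$sigma, 4)

  # empty histogram: unaligned sentinel
  f0 <- fit_axial_von_mises(angular_histogram(numeric(180)))
  expect_true(is.na(f0$mu))
  expect_equal(f0$sigma, 90)
  expect_error(fit_axial_von_mises(angular_histogram(c(rep(1, 44), -1))),
               "negative|non-negative")
})

test_that("fit inverts a wrapped-normal generator", {
  set.seed(42)
  for (s in c(22, 30, 40)) {
    ang <- rnorm(1e6, 77, s) %% 180
    f <- fit_axial_von_mises(bin_directions(ang, bin_width = 1))
    expect_equal(f$sigma, s, tolerance = 1 / s)
    expect_lt(axial_diff(f$mu, 77), 0.5)
  }
})

test_that("fit is invariant to rotation and weight rescaling", {
  set.seed(7)
  w <- bin_directions(rnorm(2e4, 40, 25) %% 180, bin_width = 1)
  base <- fit_axial_von_mises(w)
  for (delta in c(10, 90, 137)) {
    shifted <- angular_histogram(
      w$weights[((seq_len(180) - 1 - delta) %% 180) + 1], bin_width = 1)
    f <- fit_axial_von_mises(shifted)
    expect_lt(axial_diff(f$mu, (base$mu + delta) %% 180), 1e-6)
    expect_equal(f$sigma, base$sigma, tolerance = 1e-12)
  }
  f3 <- fit_axial_von_mises(angular_histogram(w$weights * 17.3, bin_width = 1))
  expect_equal(f3$sigma, base$sigma, tolerance = 1e-12)
})

test_that("mtdev is the acute axial difference", {
  expect_equal(mtdev(47, 47), 0)
  expect_equal(mtdev(5, 175), 10)
  expect_equal(mtdev(100, 10), 90)
  expect_equal(mtdev(179, 1), 2)
})

test_that("shared-vs-separate linear fit test behaves at both extremes", {
  d <- data.frame(x = 1:10, y = 2 + 3 * (1:10))
  r <- compare_linear_fits(list(d, d))
  expect_lt(r$F, 1e-8)
  expect_gt(r$p_value, 0.999)

  d1 <- data.frame(x = 1:10, y = 1:10 + rnorm(10, 0, 1e-8))
  d2 <- data.frame(x = 1:10, y = 2 * (1:10) + rnorm(10, 0, 1e-8))
  r2 <- compare_linear_fits(list(d1, d2))
  expect_lt(r2$p_value, 1e-6)

  expect_error(compare_linear_fits(list(d)), "two datasets")
  expect_error(
    compare_linear_fits(list(d, data.frame(x = rep(1, 5), y = 1:5))),
    "degenerate")
})

test_that("shared fit is rarely rejected under the null", {
  set.seed(11)
  p <- replicate(100, {
    ds <- lapply(1:3, function(i)
      data.frame(x = runif(8), y = NA))
    ds <- lapply(ds, function(d) { d$y <- 1 + 2 * d$x + rnorm(8, 0, 0.05); d })
    compare_linear_fits(ds)$p_value
  })
  expect_gte(mean(p > 0.5), 0.45)     # median of the null p is 0.5
  expect_gte(mean(p > 0.05), 0.90)    # rejection rate near nominal 5%
})

test_that("one-phase decay recovers parameters", {
  x <- seq(0, 2, length.out = 30)
  y <- (60 - 5) * exp(-4 * x) + 5
  f <- fit_one_phase_decay(x, y)
  expect_true(f$converged)
  expect_equal(f$y0, 60, tolerance = 1e-6)
  expect_equal(f$plateau, 5, tolerance = 1e-6)
  expect_equal(f$k, 4, tolerance = 1e-6)

  fc <- fit_one_phase_decay(x, rep(3, 30))
  expect_false(fc$converged)
  expect_equal(fc$plateau, 3)
  expect_true(is.na(fc$k))

  set.seed(5)
  ok <- replicate(20, {
    xs <- runif(50, 0, 2)
    ys <- (60 - 5) * exp(-4 * xs) + 5 + rnorm(50, 0, 1)
    fk <- fit_one_phase_decay(xs, ys)
    fk$converged && abs(fk$k - 4) / 4 < 0.2
  })
  expect_gte(mean(ok), 0.9)
})

test_that("histograms validate their construction", {
  expect_error(angular_histogram(rep(1, 45), bin_width = 7), "divide")
  expect_error(angular_histogram(rep(1, 10), bin_width = 4), "bins")
  h <- bin_directions(c(0, 45, 90, 135, 179.9), bin_width = 4,
                      normalized = TRUE)
  expect_equal(sum(h$weights), 1)
  # binning respects the 180-degree wrap
  h2 <- bin_directions(c(181, 361), bin_width = 1)
  expect_equal(h2$weights[2], 2)
})
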