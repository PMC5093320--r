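test_that("dimensionalization reproduces the per-second rate table", {
  d <- dimensionalize(sim_params())
  expect_equal(d$R, 0.15 * 1000 / (1000 * 8.2), tolerance = 1e-12)
  expect_equal(signif(d$R, 4), 0.01829)
  rates <- setNames(d$rates$per_second, d$rates$rate)
  expect_equal(unname(rates["alpha"]), 18.29, tolerance = 1e-3)
  expect_equal(unname(rates["beta"]), 64.02, tolerance = 1e-3)
  expect_equal(unname(rates["beta_prime"]), 0.01829, tolerance = 1e-3)
  expect_equal(signif(d$seconds(10), 2), 550)
  expect_error(dimensionalize(sim_params(growth_speed_um_s = -1)),
               "growth speed|rates")
})

test_that("collision outcome law matches the printed probabilities", {
  set.seed(1)
  n <- 2e4
  u <- runif(n)
  for (a in c(5, 15, 25)) {
    p_exp <- a / 30 * 0.01
    out <- resolve_collision(rep(a, n), "microtubule", "angle_dependent", u)
    se <- sqrt(p_exp * (1 - p_exp) / n)
    expect_lt(abs(mean(out == "catastrophe") - p_exp), 3 * se + 1e-12)
    expect_true(all(out %in% c("catastrophe", "zip")))
    outb <- resolve_collision(rep(a, n), "boundary", "angle_dependent", u)
    expect_identical(out == "catastrophe", outb == "catastrophe")
  }
  for (a in c(45, 75)) {
    out <- resolve_collision(rep(a, n), "microtubule", "angle_dependent", u)
    se <- sqrt(0.01 * 0.99 / n)
    expect_lt(abs(mean(out == "catastrophe") - 0.01), 3 * se)
    expect_true(all(out %in% c("catastrophe", "cross")))
    expect_true(all(resolve_collision(rep(a, 50), "boundary",
                                      "angle_dependent") == "catastrophe"))
  }
  # theta exactly at theta_critical goes to the steep branch
  expect_equal(unique(resolve_collision(rep(30, 50), "boundary",
                                        "angle_dependent")), "catastrophe")
  # deterministic rule sets
  expect_equal(resolve_collision(40, "boundary", "stabilize_no_cross"),
               "stabilize")
  expect_equal(resolve_collision(40, "microtubule", "stabilize_no_cross"),
               "catastrophe")
  expect_equal(resolve_collision(40, "microtubule", "cross_stabilize"),
               "cross")
  expect_equal(resolve_collision(40, "boundary", "cross_boundary_cat"),
               "catastrophe")
  expect_error(resolve_collision(95, "boundary"), "out of")
  expect_error(resolve_collision(0, "boundary"), "out of")
})

test_that("an unconfined microtubule grows at the CTMC drift rate", {
  # huge square domain: the single MT never reaches a wall within t_end
  d <- build_cell_domain(2e5, 0)
  p <- sim_params(n_seeds = 1, t_end = 0.4, avg_window = 0.1,
                  series_window = 0.1, rng_seed = 3)
  r <- run_simulation(d, p)
  len <- sum(r$final_segments[, "len_dimers"])
  expect_equal(nrow(r$events), 0)
  # E[len] ~ alpha * t with rare catastrophe interruptions; generous 5 sd
  expect_lt(abs(len - 1000 * 0.4), 5 * sqrt(1000 * 0.4) + 50)
})

test_that("simulations are reproducible and conserve polymer mass", {
  d <- build_cell_domain(492, 0.85)
  r1 <- run_simulation(d, small_params(rng_seed = 9))
  r2 <- run_simulation(d, small_params(rng_seed = 9))
  expect_identical(r1$events, r2$events)
  expect_identical(r1$hist, r2$hist)
  r3 <- run_simulation(d, small_params(rng_seed = 10))
  expect_false(identical(r1$events, r3$events))

  # the last sampled histogram is the final state: mass conservation
  expect_equal(sum(r1$hist[nrow(r1$hist), ]),
               sum(r1$final_segments[, "len_dimers"]))
  expect_true(all(r1$final_segments[, "len_dimers"] >= 0))
  expect_true(all(r1$mtsd_series >= 0 & r1$mtsd_series <= 90))
})

test_that("all microtubule points stay inside the domain", {
  for (e in c(0.7, 0.95)) {
    d <- build_cell_domain(492, e)
    r <- run_simulation(d, small_params(rng_seed = 21))
    s <- as.data.frame(r$final_segments)
    tipx <- s$x0 + s$dx * s$len_dimers * 8.2
    tipy <- s$y0 + s$dy * s$len_dimers * 8.2
    tol <- 1e-6
    expect_true(all(s$x0 >= -tol & s$x0 <= d$length + tol))
    expect_true(all(s$y0 >= -tol & s$y0 <= d$width + tol))
    expect_true(all(tipx >= -tol & tipx <= d$length + tol))
    expect_true(all(tipy >= -tol & tipy <= d$width + tol))
  }
})

test_that("without crossover no two polylines intersect at interior points", {
  d <- build_cell_domain(492, 0.8)
  r <- run_simulation(d, sim_params(n_seeds = 40, t_end = 1.5,
                                    avg_window = 0.5, series_window = 0.5,
                                    rule_set = "stabilize_no_cross",
                                    rng_seed = 4))
  s <- as.data.frame(r$final_segments)
  s <- s[s$len_dimers > 0, ]
  ends <- cbind(s$x0 + s$dx * s$len_dimers * 8.2,
                s$y0 + s$dy * s$len_dimers * 8.2)
  n <- nrow(s)
  crossings <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (s$mt[i] == s$mt[j]) next
    if (segments_cross(c(s$x0[i], s$y0[i]), ends[i, ],
                       c(s$x0[j], s$y0[j]), ends[j, ]))
      crossings <- crossings + 1
  }
  expect_equal(crossings, 0)
})

test_that("zero-duration run reports the unaligned sentinel", {
  d <- build_cell_domain(492, 0.9)
  r <- run_simulation(d, sim_params(t_end = 0, avg_window = 0,
                                    series_window = 0.01, rng_seed = 1))
  expect_equal(sum(r$final_segments[, "len_dimers"]), 0)
  expect_equal(r$mtsd, 90)
  expect_true(is.na(r$mt_main_direction))
})

test_that("convergence detector handles canonical series", {
  t <- seq(1, 100)
  expect_equal(detect_convergence(rep(30, 100), t, window_s = 20), 0)
  s <- c(rep(80, 40), rep(30, 60))
  expect_equal(detect_convergence(s, t, window_s = 20), 41)
  s2 <- c(rep(30, 99), 80)   # jumps out of the band at the very end
  expect_true(is.na(detect_convergence(s2, t, window_s = 10)))
  expect_error(detect_convergence(numeric(0), numeric(0)), "invalid")
})

test_that("collision summary tabulates outcome frequencies by angle category", {
  d <- build_cell_domain(492, 0.9)
  r <- run_simulation(d, small_params(rng_seed = 33))
  tab <- collision_angle_summary(r$events)
  expect_true(all(tab$frequency >= 0 & tab$frequency <= 1))
  sums <- tapply(tab$frequency, list(tab$target, tab$category), sum)
  expect_true(all(abs(stats::na.omit(as.vector(sums)) - 1) < 1e-9))
  # boundary collisions above theta_critical always end in catastrophe
  steep <- tab[tab$target == "boundary" & tab$category %in% c("31-60", "61-90"), ]
  expect_true(all(steep$outcome == "catastrophe"))
  expect_true(all(steep$frequency == 1))
  # shallow collisions almost always zip
  z <- tab[tab$category == "10-30" & tab$outcome == "zip", ]
  expect_true(all(z$frequency >= 0.95))
  expect_equal(nrow(collision_angle_summary(r$events[0, ])), 0)
})

test_that("sweep table has the expected structure and sem", {
  sw <- sweep_eccentricity(492, c(0.8, 0.9),
                           small_params(rng_seed = 2), runs_per_point = 3)
  expect_equal(nrow(sw$runs), 6)
  expect_equal(nrow(sw$summary), 2)
  d <- sw$runs[sw$runs$eccentricity == 0.8, "mtsd_deg"]
  expect_equal(sw$summary$sem_mtsd[sw$summary$eccentricity == 0.8],
               sd(d) / sqrt(3), tolerance = 1e-12)
  expect_null(sw$fit_comparison)
})
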