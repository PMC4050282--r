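test_that("datasets are reproducible bit-exactly and sized as configured", {
  cfg <- mc_latency_config(seed = 11)
  d1 <- simulate_latency_dataset(cfg)
  d2 <- simulate_latency_dataset(cfg)
  expect_identical(d1$latency_us, d2$latency_us)
  expect_equal(nrow(d1), 2 * 1000)                 # 1,000 points per spike index
  expect_setequal(unique(d1$spike), c(1L, 3L))
})

test_that("a point-like zone with no noise gives the deterministic kinematic line", {
  cfg <- mc_latency_config(zone_length_first_um = 0, zone_length_third_um = 0,
                           zone_center_first_um = 25, zone_start_third_um = 25,
                           decel_factor = 0, noise_sd_us = 0,
                           n_points = 200, seed = 2)
  d <- simulate_latency_dataset(cfg)
  pred <- (abs(d$distance_um - 25) / cfg$v_um_ms - cfg$soma_delay_ms) * 1000
  expect_lt(max(abs(d$latency_us - pred)), 1e-6)
  sdv <- latency_sd_by_spike(transform(d, distance_um = 300))
  # all variance comes from the kinematic line; at fixed distance it is zero
  cfg2 <- mc_latency_config(zone_length_first_um = 0, zone_length_third_um = 0,
                            noise_sd_us = 0, rec_range_um = c(300, 300),
                            n_points = 100, seed = 2)
  d2 <- simulate_latency_dataset(cfg2)
  expect_equal(latency_sd_by_spike(d2)$sd_us, c(0, 0))
})

test_that("a uniform zone yields the analytic latency s.d. L/(v sqrt(12))", {
  cfg <- mc_latency_config(zone_start_third_um = 20, zone_length_third_um = 110,
                           v_um_ms = 176, decel_factor = 0, noise_sd_us = 0,
                           rec_range_um = c(320, 320), n_points = 4000, seed = 5)
  d <- simulate_latency_dataset(cfg)
  s3 <- sd(d$latency_us[d$spike == 3])
  theory <- 110 / (176 * sqrt(12)) * 1000          # ~180 us
  se <- theory / sqrt(2 * (4000 - 1))              # s.e. of an s.d. estimate
  expect_lt(abs(s3 - theory), 3 * se)
  expect_rel(s3, 180, 0.05)
  # third-spike s.d. exceeds first-spike s.d. whenever the zone expands
  expect_gt(s3, sd(d$latency_us[d$spike == 1]))
})

test_that("zone expansion produces a negative latency-shift regression", {
  d <- simulate_latency_dataset(mc_latency_config(seed = 17))
  r <- mc_regression_test(d)
  expect_lt(r$slope_us_per_um, 0)
  expect_lt(r$p, 0.001)
  # matched configs (no expansion, no deceleration) behave as a null
  null_cfg <- mc_latency_config(zone_start_third_um = 20, zone_length_third_um = 5,
                                zone_center_first_um = 22.5, zone_length_first_um = 5,
                                decel_factor = 0, n_points = 400)
  ps <- vapply(1:10, function(s) {
    cfg <- null_cfg; cfg$seed <- 100 + s
    mc_regression_test(simulate_latency_dataset(cfg))$p
  }, 0)
  expect_gte(sum(ps > 0.05), 7)
})

test_that("deceleration alone is most negative proximally, relaxing distally", {
  cfg <- mc_latency_config(zone_start_third_um = 20, zone_length_third_um = 5,
                           zone_center_first_um = 22.5, zone_length_first_um = 5,
                           decel_factor = 1, noise_sd_us = 0,
                           n_points = 2000, seed = 21)
  d <- simulate_latency_dataset(cfg)
  a <- d[d$spike == 1, ]; b <- d[d$spike == 3, ]
  m <- merge(a, b, by = c("trial", "distance_um"))
  delta <- m$latency_us.y - m$latency_us.x
  prox <- mean(delta[m$distance_um < 60])
  dist <- mean(delta[m$distance_um > 250])
  expect_lt(prox, 0)
  expect_gt(dist, prox)                            # returns toward zero distally
})

test_that("regression power grows with the expansion magnitude", {
  med_p <- vapply(c(20, 60, 110), function(L) {
    ps <- vapply(1:5, function(s) {
      cfg <- mc_latency_config(zone_length_third_um = L, n_points = 150,
                               seed = 300 + 7 * s)
      mc_regression_test(simulate_latency_dataset(cfg))$p
    }, 0)
    median(ps)
  }, 0)
  expect_true(all(diff(med_p) < 0))
})

test_that("distinct seeds give distributionally indistinguishable latencies", {
  base <- mc_latency_config(rec_range_um = c(200, 200), n_points = 400)
  draws <- lapply(1:5, function(s) {
    cfg <- base; cfg$seed <- 40 + s
    d <- simulate_latency_dataset(cfg)
    d$latency_us[d$spike == 3]
  })
  for (i in 2:5) {
    ks <- suppressWarnings(stats::ks.test(draws[[1]], draws[[i]]))
    expect_gt(ks$p.value, 0.01)
  }
})
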