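test_that("state sequences respect absorbing, single-step and error cases", {
  ident <- transition_matrix(0, 0)
  class(ident) <- c("transition_matrix", "matrix")  # identity: absorbing
  expect_equal(simulate_state_sequence(ident, 50, initial = "transit"),
               rep("transit", 50))
  g <- transition_matrix(0.3, 0.2)
  expect_equal(simulate_state_sequence(g, 1, initial = "resident"),
               "resident")
  expect_error(simulate_state_sequence(
    matrix(c(0.5, 0.4, 0.2, 0.8), 2, byrow = TRUE), 10), "sum to 1")
  # reproducibility
  expect_identical(simulate_state_sequence(g, 100, seed = 5),
                   simulate_state_sequence(g, 100, seed = 5))
})

test_that("long-run state occupancy matches the stationary distribution", {
  g <- transition_matrix(0.035, 0.017)
  s <- simulate_state_sequence(g, 1e6, seed = 31)
  p_res <- mean(s == "resident")
  # MC standard error for a sticky chain: inflate iid SE by the
  # integrated autocorrelation time (1+rho)/(1-rho), rho = 1 - p_tr - p_rt
  rho <- 1 - 0.035 - 0.017
  se <- sqrt(0.673 * 0.327 / 1e6) * sqrt((1 + rho) / (1 - rho))
  expect_lt(abs(p_res - 0.035 / 0.052), 3 * se)
})

test_that("movement paths obey the drawn speeds and turns", {
  # near-degenerate concentration gives a near-straight path
  mp <- movement_params(mu = c(5, 5), sigma = c(0.005, 0.005),
                        lam = c(0, 0), kappa = c(0.999, 0.999))
  p <- simulate_movement_path(rep("transit", 50), mp, c(100, -40), seed = 32)
  expect_lt(max(abs(diff(p$bearings))), 0.1)

  # Monte-Carlo mean step length: transit mu 5.15 km/h over 6 h
  mp2 <- movement_params(mu = c(5.15, 1), sigma = c(2.5, 0.5),
                         lam = c(0, 0), kappa = c(0.5, 0.5))
  p2 <- simulate_movement_path(rep("transit", 1e4), mp2, c(100, -40),
                               seed = 33)
  d <- great_circle_km(p2$lon[-length(p2$lon)], p2$lat[-length(p2$lat)],
                       p2$lon[-1], p2$lat[-1])
  expect_lt(abs(mean(d) - 5.15 * 6) / (5.15 * 6), 0.02)

  # a single due-south step of one mean degree of arc
  mp3 <- movement_params(mu = c(111.195 / 6, 1), sigma = c(1e-9 + 0.001, 0.5),
                         lam = c(0, 0), kappa = c(0.999, 0.5))
  set.seed(34)
  p3 <- simulate_movement_path("transit", mp3, c(0, -40),
                               initial_bearing_rad = pi)
  expect_equal(p3$lat[2], -41, tolerance = 0.01)

  expect_error(simulate_movement_path("transit", mp3, c(0, -89.9)),
               "latitude")
})

test_that("per-state speed moments and turn distribution are reproduced", {
  mp <- movement_params(mu = c(5.15, 0.89), sigma = c(2.2, 0.4),
                        lam = c(0, pi), kappa = c(0.62, 0.1))
  st <- rep(c("transit", "resident"), each = 5000)
  p <- simulate_movement_path(st, mp, c(90, -50), seed = 350)
  for (s in c("transit", "resident")) {
    i <- st == s
    n <- sum(i)
    mu <- mp$mu[s]; sg <- mp$sigma[s]
    expect_lt(abs(mean(p$speeds[i]) - mu), 3 * sg / sqrt(n))
    expect_lt(abs(sd(p$speeds[i]) - sg), 3 * sg / sqrt(n))  # conservative
  }
  # turn angles follow the wrapped Cauchy by chi-square on 36 bins
  tr <- p$turns[st == "transit"]
  breaks <- seq(-pi, pi, length.out = 37)
  pexp <- vapply(seq_len(36), function(i)
    integrate(dwrapped_cauchy, breaks[i], breaks[i + 1], lam = 0,
              kappa = 0.62)$value, numeric(1))
  chi <- suppressWarnings(
    chisq.test(as.numeric(table(cut(tr, breaks))), p = pexp / sum(pexp)))
  expect_gt(chi$p.value, 0.001)
})

test_that("Argos degradation interpolates truth and scales noise correctly", {
  mp <- movement_params(mu = c(4, 1), sigma = c(1.5, 0.4),
                        lam = c(0, 0), kappa = c(0.5, 0.2))
  p <- simulate_movement_path(rep("transit", 200), mp, c(95, -45), seed = 36)

  # zero error: observations lie exactly on the interpolated true path
  zero_sd <- setNames(rep(0, 6), c("3", "2", "1", "0", "A", "B"))
  obs <- degrade_to_argos(p, error_sd_km = zero_sd, seed = 37)
  lon_t <- approx(as.numeric(p$times), p$lon, xout = as.numeric(obs$date))$y
  lat_t <- approx(as.numeric(p$times), p$lat, xout = as.numeric(obs$date))$y
  expect_equal(obs$lon, lon_t, tolerance = 1e-12)
  expect_equal(obs$lat, lat_t, tolerance = 1e-12)
  expect_true(all(diff(as.numeric(obs$date)) > 0))
  expect_true(all(obs$lc %in% c("3", "2", "1", "0", "A", "B")))

  # class-B-only noise: radial RMSE is sd * sqrt(2) for an isotropic 2-D fix
  pb <- simulate_movement_path(rep("transit", 2500), mp, c(95, -45),
                               seed = 38)
  obs_b <- degrade_to_argos(pb, class_probs = c("3" = 0, "2" = 0, "1" = 0,
                                                "0" = 0, "A" = 0, "B" = 1),
                            mean_gap_hours = 1.2, seed = 39)
  expect_gt(nrow(obs_b), 1e4)
  lon_t <- approx(as.numeric(pb$times), pb$lon, xout = as.numeric(obs_b$date))$y
  lat_t <- approx(as.numeric(pb$times), pb$lat, xout = as.numeric(obs_b$date))$y
  err <- great_circle_km(obs_b$lon, obs_b$lat, lon_t, lat_t)
  rmse <- sqrt(mean(err^2))
  expect_lt(abs(rmse - 10 * sqrt(2)) / (10 * sqrt(2)), 0.05)

  # dropout truncates the record
  t_drop <- p$times[1] + 20 * 3600
  obs_d <- degrade_to_argos(p, dropout_time = t_drop, seed = 40)
  expect_lte(max(as.numeric(obs_d$date)), as.numeric(t_drop))
})

test_that("catch simulation respects supports and point-mass intensities", {
  expect_equal(nrow(simulate_catches(0)), 0)
  x <- simulate_catches(500, lon_window = c(50, 150), seed = 41)
  expect_true(all(x$lon >= 50 & x$lon < 150))
  expect_true(all(x$count >= 1))
  cell <- data.frame(lon = 77, lat = -60, weight = 1)
  y <- simulate_catches(200, intensity = cell, seed = 42)
  expect_true(all(floor(y$lon) == 77 & floor(y$lat) == -60))
  expect_error(simulate_catches(-1), "n_records")
  expect_error(simulate_catches(5, lon_window = c(10, 10)), "degenerate")
})

test_that("simulator output is identical under a fixed seed", {
  g <- transition_matrix(0.1, 0.05)
  mp <- movement_params(c(4, 1), c(2, 0.5), c(0, pi), c(0.6, 0.1))
  p1 <- simulate_movement_path(simulate_state_sequence(g, 100, seed = 43),
                               mp, c(100, -40), seed = 44)
  p2 <- simulate_movement_path(simulate_state_sequence(g, 100, seed = 43),
                               mp, c(100, -40), seed = 44)
  expect_identical(p1, p2)
  o1 <- degrade_to_argos(p1, seed = 45)
  o2 <- degrade_to_argos(p2, seed = 45)
  expect_identical(o1, o2)
})
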