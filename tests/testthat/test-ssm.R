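# The smoother is exact for the linear-Gaussian model, so it must agree
# with brute-force joint-Gaussian conditioning (helper brute_joint_smoother)
# on a small problem.

test_that("smoother matches direct joint-Gaussian conditioning on 5 nodes", {
  set.seed(51)
  grid <- 0:4
  t_obs <- c(0.2, 0.9, 1.4, 2.0, 2.7, 3.3, 3.9)
  y <- c(0.5, 1.9, 2.4, 3.9, 5.5, 6.1, 7.9)
  r_sd <- rep(0.8, length(y))
  for (gamma in c(-0.3, 0, 0.5)) {
    ora <- brute_joint_smoother(t_obs, y, r_sd, grid, gamma, sigma = 1.3,
                                prior_mean = y[1], prior_var = 25)
    sm <- dcrw_smooth(t_obs, y, r_sd, grid, gamma, sigma = 1.3,
                      prior_var = 25)
    expect_equal(sm$mean, ora$mean, tolerance = 1e-8)
    expect_equal(sm$var, ora$var, tolerance = 1e-8)
  }
})

test_that("noiseless on-grid observations are reproduced exactly", {
  set.seed(52)
  t0 <- as.POSIXct("2016-10-01", tz = "UTC")
  n <- 40
  # a gently curving true path sampled exactly at 6-h nodes
  lon <- 100 + cumsum(rnorm(n, 0.08, 0.02))
  lat <- -45 - cumsum(abs(rnorm(n, 0.05, 0.02)))
  obs <- data.frame(id = "w1", date = t0 + (0:(n - 1)) * 21600,
                    lc = "3", lon = lon, lat = lat)
  class(obs) <- c("argos_obs", "data.frame")
  zero_sd <- setNames(rep(0, 6), c("3", "2", "1", "0", "A", "B"))
  fit <- fit_ssm(obs, error_sd_km = zero_sd)
  tr <- regularized_track(fit)
  i <- match(as.numeric(obs$date), as.numeric(tr$date))
  err_km <- great_circle_km(tr$lon[i], tr$lat[i], obs$lon, obs$lat)
  expect_lt(max(err_km), 1e-6)
  # exactly 6-h grid, four estimates per day
  expect_true(all(diff(as.numeric(tr$date)) == 21600))
  days <- format(tr$date, "%Y-%m-%d")
  expect_true(all(table(days[days %in% names(which(table(days) == 4))]) == 4))
})

test_that("smoothing reduces positional error relative to raw class-B fixes", {
  mp <- movement_params(mu = c(4.5, 1), sigma = c(1.8, 0.4),
                        lam = c(0, 0), kappa = c(0.7, 0.2))
  p <- simulate_movement_path(rep("transit", 240), mp, c(95, -48), seed = 53)
  obs <- degrade_to_argos(p, class_probs = c("3" = 0, "2" = 0, "1" = 0,
                                             "0" = 0, "A" = 0, "B" = 1),
                          mean_gap_hours = 2, seed = 54)
  fit <- fit_ssm(obs)
  tr <- regularized_track(fit)
  i <- match(as.numeric(tr$date), as.numeric(p$times))
  keep <- !is.na(i)
  rmse_sm <- sqrt(mean(great_circle_km(tr$lon[keep], tr$lat[keep],
                                       p$lon[i[keep]], p$lat[i[keep]])^2))
  lon_t <- approx(as.numeric(p$times), p$lon, xout = as.numeric(obs$date))$y
  lat_t <- approx(as.numeric(p$times), p$lat, xout = as.numeric(obs$date))$y
  rmse_obs <- sqrt(mean(great_circle_km(obs$lon, obs$lat, lon_t, lat_t)^2))
  expect_lt(rmse_sm, rmse_obs)
  expect_lt(rmse_sm, 10)  # well under the 10 km class-B noise
})

test_that("persistence parameter is recovered for a gamma = 0 random walk", {
  set.seed(55)
  n <- 500
  sigma_true <- 6
  km_per_deg <- pi * 6371.0088 / 180
  x <- cumsum(c(0, rnorm(n - 1, 0, sigma_true)))
  y <- cumsum(c(0, rnorm(n - 1, 0, sigma_true)))
  lat <- -50 + y / km_per_deg
  lon <- 100 + x / (km_per_deg * cos(lat * pi / 180))
  t0 <- as.POSIXct("2016-10-01", tz = "UTC")
  obs <- data.frame(id = "rw", date = t0 + (0:(n - 1)) * 21600,
                    lc = "1", lon = lon, lat = lat)
  class(obs) <- c("argos_obs", "data.frame")
  fit <- fit_ssm(obs)
  expect_lt(abs(fit$par["gamma"]), 3 * fit$se["gamma"] + 1e-6)
  expect_lt(abs(fit$par["sigma"] - sigma_true) / sigma_true, 0.15)
})

test_that("realization draws reproduce the smoother's spread and seed", {
  mp <- movement_params(mu = c(4, 1), sigma = c(1.5, 0.4),
                        lam = c(0, 0), kappa = c(0.6, 0.2))
  p <- simulate_movement_path(rep("transit", 150), mp, c(95, -45), seed = 56)
  obs <- degrade_to_argos(p, mean_gap_hours = 3, seed = 57)
  fit <- fit_ssm(obs)
  rr <- draw_realizations(fit, m = 100, seed = 58, include_point = FALSE)
  tr <- regularized_track(fit)
  # per-node sample SD across realizations approximates the smoother SD
  km_per_deg <- pi * 6371.0088 / 180
  node_sd <- vapply(seq_len(nrow(tr)), function(i) {
    ri <- rr[rr$date == tr$date[i], ]
    dx <- (ri$lon - tr$lon[i]) * km_per_deg * cos(tr$lat[i] * pi / 180)
    dy <- (ri$lat - tr$lat[i]) * km_per_deg
    sqrt((var(dx) + var(dy)) / 2)
  }, numeric(1))
  # compare in aggregate (individual nodes are noisy at m = 100)
  expect_lt(abs(mean(node_sd) - mean(tr$sd_km)) / mean(tr$sd_km), 0.15)

  r1 <- draw_realizations(fit, m = 3, seed = 59)
  r2 <- draw_realizations(fit, m = 3, seed = 59)
  expect_identical(r1, r2)
  expect_error(draw_realizations(fit, m = 0), "m must be")
})

test_that("near-zero process and observation noise pins realizations", {
  set.seed(60)
  t0 <- as.POSIXct("2016-10-01", tz = "UTC")
  n <- 30
  lon <- 100 + (0:(n - 1)) * 0.09
  lat <- -45 - (0:(n - 1)) * 0.04
  obs <- data.frame(id = "w1", date = t0 + (0:(n - 1)) * 21600,
                    lc = "3", lon = lon, lat = lat)
  class(obs) <- c("argos_obs", "data.frame")
  tiny_sd <- setNames(rep(1e-4, 6), c("3", "2", "1", "0", "A", "B"))
  fit <- fit_ssm(obs, error_sd_km = tiny_sd)
  rr <- draw_realizations(fit, m = 5, seed = 61, include_point = FALSE)
  tr <- regularized_track(fit)
  for (r in 1:5) {
    ri <- rr[rr$realization == r, ]
    expect_lt(max(great_circle_km(ri$lon, ri$lat, tr$lon, tr$lat)), 0.05)
  }
})

test_that("long gaps split tracks and the filter enforces preconditions", {
  set.seed(62)
  t0 <- as.POSIXct("2016-10-01", tz = "UTC")
  mk <- function(t_off, n) data.frame(
    id = "w1", date = t0 + t_off + (0:(n - 1)) * 21600, lc = "1",
    lon = 100 + (0:(n - 1)) * 0.1 + rnorm(n, 0, 0.01),
    lat = -45 - (0:(n - 1)) * 0.05 + rnorm(n, 0, 0.01))
  obs <- rbind(mk(0, 20), mk(20 * 21600 + 10 * 86400, 20))
  class(obs) <- c("argos_obs", "data.frame")
  fit <- fit_ssm(obs, gap_split_days = 7)
  expect_equal(length(unique(regularized_track(fit)$segment)), 2)

  expect_error(fit_ssm(obs[1:5, ]), "at least 8")
  short <- mk(0, 10); short$date <- t0 + (0:9) * 3600
  class(short) <- c("argos_obs", "data.frame")
  expect_error(fit_ssm(short), "2 days")
})

test_that("nominal 95% intervals have close-to-nominal coverage", {
  mp <- movement_params(mu = c(4, 1), sigma = c(1.6, 0.4),
                        lam = c(0, 0), kappa = c(0.6, 0.2))
  set.seed(63)
  hits <- 0; tot <- 0
  for (rep in 1:30) {
    p <- simulate_movement_path(rep("transit", 60), mp,
                                c(90 + rep, -45), seed = 100 + rep)
    obs <- degrade_to_argos(p, mean_gap_hours = 3, seed = 200 + rep)
    fit <- try(fit_ssm(obs), silent = TRUE)
    if (inherits(fit, "try-error")) next
    tr <- regularized_track(fit)
    i <- match(as.numeric(tr$date), as.numeric(p$times))
    keep <- which(!is.na(i))
    err <- great_circle_km(tr$lon[keep], tr$lat[keep],
                           p$lon[i[keep]], p$lat[i[keep]])
    # radial check: err^2 / sd^2 ~ chi-square(2) for isotropic axis errors
    hits <- hits + sum(err^2 <= stats::qchisq(0.95, 2) * tr$sd_km[keep]^2)
    tot <- tot + length(keep)
  }
  expect_gt(tot, 500)
  expect_lt(abs(hits / tot - 0.95), 0.04)
})
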