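test_that("forward likelihood matches the exhaustive-path oracle", {
  set.seed(81)
  for (i in 1:10) {
    pars <- random_pars()
    T_ <- sample(2:8, 1)
    speed <- rgamma_speed(T_, 3, 1.5)
    turn <- c(NA, rwrapped_cauchy(T_ - 1, 0, 0.3))
    ll <- forward_loglik(pars, speed, turn, sex = "female")
    expect_equal(ll, brute_forward(pars, speed, turn, "female"),
                 tolerance = 1e-10)
  }
})

test_that("single-step likelihood is the delta-weighted emission mixture", {
  pars <- hmm_pars(mu = c(4, 1), sigma = c(2, 0.5), kappa = c(0.5, 0.1),
                   lam = c(0, pi), tpm = transition_matrix(0.2, 0.1))
  delta <- stationary_distribution(pars$tpm$unknown)
  x <- 2.7
  direct <- log(delta[1] * dgamma_speed(x, 4, 2) +
                delta[2] * dgamma_speed(x, 1, 0.5))
  expect_equal(forward_loglik(pars, x, NA_real_), unname(direct),
               tolerance = 1e-12)
})

test_that("likelihood is invariant to state relabelling", {
  set.seed(82)
  pars <- random_pars()
  swapped <- hmm_pars(mu = pars$mu[2:1, ], sigma = pars$sigma[2:1, ],
                      kappa = pars$kappa[2:1, ], lam = unname(pars$lam[2:1]),
                      tpm = transition_matrix(pars$tpm$unknown[2, 1],
                                              pars$tpm$unknown[1, 2]))
  speed <- rgamma_speed(30, 3, 1.5)
  turn <- c(NA, rwrapped_cauchy(29, 0, 0.4))
  expect_equal(forward_loglik(pars, speed, turn),
               forward_loglik(swapped, speed, turn), tolerance = 1e-10)
})

test_that("missing data rules: first turns skipped, all-missing rejected", {
  pars <- hmm_pars(mu = c(4, 1), sigma = c(2, 0.5), kappa = c(0.5, 0.1),
                   lam = c(0, pi), tpm = transition_matrix(0.2, 0.1))
  speed <- c(3, 2, NA, 1)
  turn <- c(NA, 0.3, -0.2, NA)
  expect_true(is.finite(forward_loglik(pars, speed, turn)))
  expect_error(forward_loglik(pars, rep(NA_real_, 4), rep(NA_real_, 4)),
               "no observed")
})

test_that("viterbi equals exhaustive-path decoding on short series", {
  set.seed(83)
  for (i in 1:6) {
    pars <- random_pars()
    T_ <- 8
    st <- simulate_state_sequence(pars$tpm$unknown, T_)
    si <- match(st, c("transit", "resident"))
    speed <- rgamma_speed(T_, pars$mu[si, 3], pars$sigma[si, 3])
    turn <- c(NA, rwrapped_cauchy(T_ - 1, pars$lam[si[-1]],
                                  pars$kappa[si[-1], 3]))
    ser <- data.frame(id = "x", speed_kmh = speed, turn_rad = turn,
                      sex = "unknown")
    got <- viterbi(pars, ser)$state
    expect_equal(got, brute_viterbi(pars, speed, turn, "unknown"))
  }
})

test_that("viterbi ties break toward transit", {
  # identical emissions and symmetric transitions: everything ties
  pars <- hmm_pars(mu = c(2, 2), sigma = c(1, 1), kappa = c(0.3, 0.3),
                   lam = c(0, 0), tpm = transition_matrix(0.5, 0.5))
  ser <- data.frame(id = "x", speed_kmh = c(2, 2.5, 1.7),
                    turn_rad = c(NA, 0.1, -0.2), sex = "unknown")
  expect_equal(viterbi(pars, ser)$state, rep("transit", 3))
})

test_that("posteriors sum to one and agree with viterbi when separated", {
  pars <- reported_generating_pars()
  set.seed(84)
  ser <- sim_series_direct(pars, 800, sex = "male")
  post <- state_posteriors(pars, ser)
  expect_equal(post$p_transit + post$p_resident, rep(1, nrow(post)),
               tolerance = 1e-10)
  vit <- viterbi(pars, ser)
  argmax <- ifelse(post$p_transit >= 0.5, "transit", "resident")
  expect_gt(mean(vit$state == argmax), 0.95)
  # decoding accuracy in a well-separated regime (mu 3.16 vs 0.89)
  expect_gt(mean(vit$state == ser$true_state), 0.9)
})

test_that("parameter counts follow the four configurations", {
  pars <- reported_generating_pars()
  set.seed(85)
  ser <- rbind(sim_series_direct(pars, 120, "female", "f1"),
               sim_series_direct(pars, 120, "male", "m1"),
               sim_series_direct(pars, 120, "unknown", "u1"))
  counts <- c(10, 14, 22, 26)
  for (k in 1:4) {
    f <- fit_hmm(ser, config = k, n_restarts = 1, seed = k, hessian = FALSE)
    expect_equal(f$n_params, counts[k])
    for (g in f$pars$tpm) expect_equal(rowSums(g), c(transit = 1, resident = 1),
                                       tolerance = 1e-12)
    # states ordered: transit is the faster state
    expect_gt(mean(f$pars$mu[1, ]), mean(f$pars$mu[2, ]))
  }
})

test_that("AIC arithmetic, tie-breaking and data guards work", {
  f1 <- structure(list(loglik = -100, n_params = 10, n_obs = 500,
                       config = hmm_config(1), convergence = 0L,
                       data_sig = c(n = 1, s = 2)), class = "fitted_hmm")
  expect_equal(AIC(f1), 220)
  f2 <- structure(list(loglik = -100, n_params = 14, n_obs = 500,
                       config = hmm_config(2), convergence = 0L,
                       data_sig = c(n = 1, s = 2)), class = "fitted_hmm")
  # equal loglik: fewer parameters wins
  expect_equal(select_model(list(f2, f1))$config$id, 1L)
  f3 <- f2; f3$data_sig <- c(n = 9, s = 9)
  expect_error(select_model(list(f1, f3)), "same data")
})

test_that("fitting recovers generating parameters on a two-track dataset", {
  pars <- hmm_pars(mu = c(5, 1), sigma = c(2, 0.5), kappa = c(0.6, 0.1),
                   lam = c(0, pi), tpm = transition_matrix(0.08, 0.05))
  ser <- quick_series(pars, n = 400, seed = 86)
  fit <- fit_hmm(ser, config = 1, n_restarts = 2, seed = 87)
  expect_equal(unname(fit$pars$mu[, "unknown"]), c(5, 1), tolerance = 0.12)
  expect_equal(unname(fit$pars$kappa[1, "unknown"]), 0.6, tolerance = 0.25)
  expect_equal(fit$pars$tpm$unknown[1, 2], 0.08, tolerance = 0.5)
  # exchangeability: permuted track order changes nothing
  ser2 <- ser[order(ser$id, decreasing = TRUE), ]
  fit2 <- fit_hmm(ser2, config = 1, n_restarts = 2, seed = 87)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-6)
  # working-scale covariance is available and positive
  expect_false(is.null(fit$vcov))
  expect_true(all(diag(fit$vcov) > 0))
})

test_that("exact-zero speeds are handled by an estimated point mass", {
  pars <- hmm_pars(mu = c(5, 1), sigma = c(2, 0.5), kappa = c(0.6, 0.1),
                   lam = c(0, pi), tpm = transition_matrix(0.08, 0.05))
  ser <- quick_series(pars, n = 300, seed = 88)
  set.seed(880)
  ser$speed_kmh[sample(which(ser$true_state == "resident"), 12)] <- 0
  fit <- fit_hmm(ser, config = 1, n_restarts = 1, seed = 89, hessian = FALSE)
  expect_equal(fit$n_params, 12)  # 10 + two zero-mass parameters
  expect_true(all(fit$pars$zeromass >= 0 & fit$pars$zeromass < 1))
  expect_true(is.finite(fit$loglik))
})

test_that("single-state data drives one state's occupancy toward zero", {
  # all data from one gamma/wrapped-Cauchy regime (no switching)
  set.seed(90)
  one_state <- data.frame(
    id = rep(c("a", "b"), each = 300),
    speed_kmh = rgamma_speed(600, 3, 1),
    turn_rad = c(NA, rwrapped_cauchy(299, 0, 0.4),
                 NA, rwrapped_cauchy(299, 0, 0.4)),
    sex = "unknown")
  fit <- suppressWarnings(fit_hmm(one_state, config = 1, n_restarts = 2,
                                  seed = 91, hessian = FALSE))
  occ <- stationary_distribution(fit$pars$tpm$unknown)
  expect_lt(min(occ), 0.12)
})
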