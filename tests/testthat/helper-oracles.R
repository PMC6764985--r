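# Independent oracles and small simulation helpers shared across tests.

# Exhaustive-path HMM log-likelihood: sums the joint probability over all
# 2^T state paths, with emissions computed directly from stats::dgamma and
# the wrapped Cauchy formula (independent of the package's emission code).
brute_emission <- function(pars, speed, turn, sex) {
  t(vapply(seq_along(speed), function(t) {
    vapply(1:2, function(s) {
      mu <- pars$mu[s, sex]; sg <- pars$sigma[s, sex]
      kp <- pars$kappa[s, sex]
      d <- 1
      if (!is.na(speed[t]) && speed[t] > 0)
        d <- d * (1 - pars$zeromass[s]) *
          stats::dgamma(speed[t], shape = (mu / sg)^2, scale = sg^2 / mu)
      if (!is.na(speed[t]) && speed[t] == 0) d <- pars$zeromass[s]
      if (!is.na(turn[t]))
        d <- d * (1 - kp^2) /
          (2 * pi * (1 + kp^2 - 2 * kp * cos(turn[t] - pars$lam[s])))
      d
    }, numeric(1))
  }, numeric(2)))
}

brute_forward <- function(pars, speed, turn, sex) {
  g <- pars$tpm[[sex]]
  delta <- stationary_distribution(g)
  emis <- brute_emission(pars, speed, turn, sex)
  T_ <- length(speed)
  total <- 0
  for (code in 0:(2^T_ - 1)) {
    s <- as.integer(intToBits(code))[seq_len(T_)] + 1L
    p <- delta[s[1]] * emis[1, s[1]]
    if (T_ > 1) for (t in 2:T_) p <- p * g[s[t - 1], s[t]] * emis[t, s[t]]
    total <- total + p
  }
  as.numeric(log(total))
}

brute_viterbi <- function(pars, speed, turn, sex) {
  g <- pars$tpm[[sex]]
  delta <- stationary_distribution(g)
  emis <- brute_emission(pars, speed, turn, sex)
  T_ <- length(speed)
  best <- -Inf; best_path <- NULL
  for (code in 0:(2^T_ - 1)) {
    s <- as.integer(intToBits(code))[seq_len(T_)] + 1L
    p <- log(delta[s[1]]) + log(emis[1, s[1]])
    if (T_ > 1) for (t in 2:T_) p <- p + log(g[s[t - 1], s[t]]) +
        log(emis[t, s[t]])
    if (p > best) { best <- p; best_path <- s }
  }
  c("transit", "resident")[best_path]
}

# Random valid parameterization for oracle comparisons.
random_pars <- function() {
  mu <- c(runif(1, 2.5, 6), runif(1, 0.5, 2))
  hmm_pars(mu = mu, sigma = mu * runif(2, 0.3, 0.7),
           kappa = runif(2, 0.02, 0.9), lam = runif(2, -pi, pi),
           tpm = transition_matrix(runif(1, 0.05, 0.4),
                                   runif(1, 0.05, 0.4)))
}

# Simulate a step/turn series directly from HMM emissions (no geometry).
sim_series_direct <- function(pars, n, sex = "unknown", id = "t1") {
  st <- simulate_state_sequence(pars$tpm[[sex]], n)
  si <- match(st, c("transit", "resident"))
  speed <- rgamma_speed(n, pars$mu[si, sex], pars$sigma[si, sex])
  turn <- rwrapped_cauchy(n, pars$lam[si], pars$kappa[si, sex])
  turn[1] <- NA
  structure(data.frame(id = id, realization = 0L, segment = 1L,
                       date = as.POSIXct("2016-10-01", tz = "UTC") +
                         (seq_len(n) - 1) * 21600,
                       speed_kmh = speed, turn_rad = turn, sex = sex,
                       true_state = st, stringsAsFactors = FALSE),
            class = c("step_turn_series", "data.frame"))
}

# Small two-track dataset for quick fit tests.
quick_series <- function(pars, n = 250, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rbind(sim_series_direct(pars, n, id = "a"),
        sim_series_direct(pars, n, id = "b"))
}

# Brute-force joint-Gaussian smoother for the one-axis regularizing DCRW:
# builds the full covariance of x_{1:T} from the AR(2) recursion and
# conditions directly on the interpolated observations.
brute_joint_smoother <- function(t_obs, y, r_sd, grid, gamma, sigma,
                                 prior_mean, prior_var = 1e4) {
  T_ <- length(grid)
  # x = B e with e = (x1, x2, eta_3..eta_T)
  B <- matrix(0, T_, T_)
  B[1, 1] <- 1; B[2, 2] <- 1
  for (t in 3:T_) {
    B[t, ] <- (1 + gamma) * B[t - 1, ] - gamma * B[t - 2, ]
    B[t, t] <- B[t, t] + 1
  }
  D <- diag(c(prior_var, prior_var, rep(sigma^2, T_ - 2)))
  mean_x <- as.numeric(B %*% c(prior_mean, prior_mean, rep(0, T_ - 2)))
  cov_x <- B %*% D %*% t(B)
  # observation operator: linear interpolation weights
  step <- grid[2] - grid[1]
  H <- matrix(0, length(y), T_)
  for (k in seq_along(y)) {
    j <- min(max(ceiling((t_obs[k] - grid[1]) / step + 1), 2), T_)
    w <- (t_obs[k] - grid[j - 1]) / step
    H[k, j] <- w; H[k, j - 1] <- 1 - w
  }
  S <- H %*% cov_x %*% t(H) + diag(r_sd^2, length(y))
  K <- cov_x %*% t(H) %*% solve(S)
  list(mean = as.numeric(mean_x + K %*% (y - H %*% mean_x)),
       var = diag(cov_x - K %*% H %*% cov_x))
}
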