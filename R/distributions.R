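# Emission distributions and the 2-state transition matrix.

#' Two-state transition matrix
#'
#' Builds the per-6h-step transition probability matrix of the transit /
#' resident behavioural Markov chain from its two off-diagonal elements.
#'
#' @param p_tr Probability of switching transit -> resident in one step.
#' @param p_rt Probability of switching resident -> transit in one step.
#' @return A 2x2 matrix with dimnames `c("transit", "resident")`, rows
#'   summing to one.
#' @examples
#' transition_matrix(0.035, 0.017)
#' @export
transition_matrix <- function(p_tr, p_rt) {
  if (!is.finite(p_tr) || !is.finite(p_rt) ||
      p_tr < 0 || p_tr > 1 || p_rt < 0 || p_rt > 1)
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  m <- matrix(c(1 - p_tr, p_tr, p_rt, 1 - p_rt), 2, 2, byrow = TRUE,
              dimnames = list(STATE_LEVELS, STATE_LEVELS))
  class(m) <- c("transition_matrix", "matrix")
  m
}

#' Validate a transition matrix
#'
#' @param m A square matrix of transition probabilities.
#' @return `m`, invisibly, if valid; otherwise an error.
#' @export
validate_transition_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("transition matrix must be square", call. = FALSE)
  if (any(!is.finite(m)) || any(m < 0) || any(m > 1))
    stop("transition matrix entries must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(m) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1 (tolerance 1e-12)",
         call. = FALSE)
  invisible(m)
}

#' Stationary distribution of a transition matrix
#'
#' For the two-state chain the closed form is
#' `pi_resident = p_tr / (p_tr + p_rt)`; larger chains are solved by the
#' eigenvector equation. The printed pooled transition estimates 0.035 and
#' 0.017 give a stationary resident probability of about 0.673.
#'
#' @param m A valid transition matrix (rows sum to 1).
#' @return Named numeric vector `pi` with `pi %*% m = pi` and `sum(pi) = 1`.
#' @examples
#' stationary_distribution(transition_matrix(0.035, 0.017))
#' @export
stationary_distribution <- function(m) {
  validate_transition_matrix(m)
  if (nrow(m) == 2) {
    p_tr <- m[1, 2]; p_rt <- m[2, 1]
    if (p_tr + p_rt == 0)
      stop("reducible transition matrix: no switching in either direction",
           call. = FALSE)
    pi <- c(p_rt, p_tr) / (p_tr + p_rt)
  } else {
    e <- eigen(t(m))
    i <- which.min(abs(e$values - 1))
    v <- Re(e$vectors[, i])
    if (all(abs(v) < 1e-12)) stop("reducible transition matrix", call. = FALSE)
    pi <- v / sum(v)
    if (any(pi < -1e-10)) stop("reducible transition matrix", call. = FALSE)
    pi <- pmax(pi, 0); pi <- pi / sum(pi)
  }
  names(pi) <- rownames(m)
  pi
}

#' Gamma step-speed parameters
#'
#' Mean/standard-deviation parameterization of the gamma distribution used
#' for step speeds (km/h). Shape and scale are recovered as
#' `shape = mu^2/sigma^2`, `scale = sigma^2/mu`.
#'
#' @param mu Mean step speed, km/h; must be positive.
#' @param sigma Step-speed standard deviation, km/h; must be positive.
#' @return A list of class `gamma_params` with elements `mu`, `sigma`,
#'   `shape`, `scale`.
#' @export
gamma_params <- function(mu, sigma) {
  if (!is.finite(mu) || mu <= 0) stop("mu must be > 0", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  structure(list(mu = mu, sigma = sigma,
                 shape = mu^2 / sigma^2, scale = sigma^2 / mu),
            class = "gamma_params")
}

#' Gamma density in mean/sd parameterization
#'
#' @param x Speeds, km/h; the density is defined for `x > 0`.
#' @param mu,sigma Mean and standard deviation of the gamma distribution.
#' @return Density values. Zero speeds have no gamma density; they are
#'   handled upstream by an explicit zero point mass.
#' @export
dgamma_speed <- function(x, mu, sigma) {
  dgamma(x, shape = mu^2 / sigma^2, scale = sigma^2 / mu)
}

#' Random gamma speeds in mean/sd parameterization
#'
#' @param n Number of draws.
#' @inheritParams dgamma_speed
#' @export
rgamma_speed <- function(n, mu, sigma) {
  rgamma(n, shape = mu^2 / sigma^2, scale = sigma^2 / mu)
}

#' Wrapped Cauchy parameters
#'
#' @param lam Mean turn angle in radians; normalized to `(-pi, pi]`.
#' @param kappa Concentration in `[0, 1)`; 0 is the circular uniform.
#' @return A list of class `wrapped_cauchy_params`.
#' @export
wrapped_cauchy_params <- function(lam, kappa) {
  if (!is.finite(kappa) || kappa < 0 || kappa >= 1)
    stop("kappa must lie in [0, 1)", call. = FALSE)
  structure(list(lam = wrap_to_pi(lam), kappa = kappa),
            class = "wrapped_cauchy_params")
}

#' Wrapped Cauchy density
#'
#' `f(theta) = (1 - kappa^2) / (2 * pi * (1 + kappa^2 - 2 * kappa *
#' cos(theta - lam)))` on `(-pi, pi]`.
#'
#' @param theta Angles in radians.
#' @param lam Mean direction in radians.
#' @param kappa Concentration in `[0, 1)`.
#' @return Density values.
#' @export
dwrapped_cauchy <- function(theta, lam, kappa) {
  if (any(!is.finite(kappa)) || any(kappa < 0) || any(kappa >= 1))
    stop("kappa must lie in [0, 1)", call. = FALSE)
  (1 - kappa^2) / (2 * pi * (1 + kappa^2 - 2 * kappa * cos(theta - lam)))
}

#' Random wrapped Cauchy angles
#'
#' Inverse-CDF sampler: for `U ~ Unif(0,1)`,
#' `theta = lam + 2 * atan(((1 - kappa) / (1 + kappa)) * tan(pi * (U - 1/2)))`
#' wrapped to `(-pi, pi]`.
#'
#' @param n Number of draws.
#' @inheritParams dwrapped_cauchy
#' @export
rwrapped_cauchy <- function(n, lam, kappa) {
  if (any(kappa < 0) || any(kappa >= 1))
    stop("kappa must lie in [0, 1)", call. = FALSE)
  u <- runif(n)
  wrap_to_pi(lam + 2 * atan(((1 - kappa) / (1 + kappa)) * tan(pi * (u - 0.5))))
}
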