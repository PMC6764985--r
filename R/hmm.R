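# Two-state movement HMM: gamma step speeds, wrapped Cauchy turns, optional
# sex effects on movement and/or transition parameters, maximum likelihood
# via quasi-Newton optimization on working (link) scales.

#' HMM sex-covariate configuration
#'
#' The four model formulations compared by AIC: (1) no sex effects, (2) sex
#' on the state transition probabilities, (3) sex on the state movement
#' parameters (step-speed mean and SD, turn concentration), (4) both. The
#' turn-angle mean is estimated per state but never sex-varied.
#'
#' @param id Integer 1-4.
#' @return A list of class `hmm_config`.
#' @export
hmm_config <- function(id) {
  if (!id %in% 1:4) stop("config id must be 1, 2, 3 or 4", call. = FALSE)
  structure(list(id = as.integer(id),
                 sex_on_transitions = id %in% c(2, 4),
                 sex_on_movement = id %in% c(3, 4)),
            class = "hmm_config")
}

.as_config <- function(config) {
  if (inherits(config, "hmm_config")) config else hmm_config(config)
}

#' Natural-scale HMM parameters
#'
#' Bundles emission and transition parameters in the expanded state-by-sex
#' layout used by the likelihood. Scalars per state are accepted and
#' replicated across the three sex levels.
#'
#' @param mu,sigma Gamma step-speed mean and SD (km/h): length-2 vectors
#'   (transit, resident) or 2x3 matrices with columns
#'   `c("female", "male", "unknown")`.
#' @param kappa Wrapped Cauchy concentrations in `[0, 1)`: length-2 vector
#'   or 2x3 matrix.
#' @param lam Length-2 vector of mean turn angles (radians); sex-invariant.
#' @param tpm A single [transition_matrix()] shared by all sexes, or a named
#'   list of one matrix per sex level.
#' @param zeromass Length-2 per-state probability of an exact-zero step
#'   (default 0; the gamma density is undefined at 0, so zero speeds carry an
#'   explicit point mass).
#' @return A list of class `hmm_pars` with 2x3 matrices `mu`, `sigma`,
#'   `kappa`, vector `lam`, per-sex list `tpm`, and `zeromass`.
#' @export
hmm_pars <- function(mu, sigma, kappa, lam, tpm, zeromass = c(0, 0)) {
  expand <- function(x, what) {
    if (is.matrix(x)) {
      stopifnot(nrow(x) == 2, ncol(x) == 3)
      dimnames(x) <- list(STATE_LEVELS, SEX_LEVELS)
      return(x)
    }
    stopifnot(length(x) == 2)
    matrix(x, 2, 3, dimnames = list(STATE_LEVELS, SEX_LEVELS))
  }
  mu <- expand(mu); sigma <- expand(sigma); kappa <- expand(kappa)
  if (any(mu <= 0) || any(sigma <= 0)) stop("mu, sigma must be > 0", call. = FALSE)
  if (any(kappa < 0) || any(kappa >= 1)) stop("kappa must lie in [0, 1)", call. = FALSE)
  stopifnot(length(lam) == 2)
  if (!is.list(tpm)) tpm <- setNames(rep(list(tpm), 3), SEX_LEVELS)
  stopifnot(all(SEX_LEVELS %in% names(tpm)))
  for (s in SEX_LEVELS) validate_transition_matrix(tpm[[s]])
  if (any(zeromass < 0) || any(zeromass >= 1))
    stop("zeromass must lie in [0, 1)", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, kappa = kappa,
                 lam = setNames(wrap_to_pi(lam), STATE_LEVELS),
                 tpm = tpm[SEX_LEVELS],
                 zeromass = setNames(zeromass, STATE_LEVELS)),
            class = "hmm_pars")
}

# ---- working-scale parameterization -------------------------------------

.param_layout <- function(config, has_zero) {
  mv <- if (config$sex_on_movement) SEX_LEVELS else ""
  tv <- if (config$sex_on_transitions) SEX_LEVELS else ""
  dotted <- function(...) {
    x <- paste(..., sep = ".")
    sub("\\.$", "", x)
  }
  nm <- character(0)
  for (p in c("mu", "sigma", "kappa"))
    for (st in STATE_LEVELS) nm <- c(nm, dotted(p, st, mv))
  nm <- c(nm, dotted("lam", STATE_LEVELS))
  for (p in c("ptr", "prt")) nm <- c(nm, dotted(p, tv))
  if (has_zero) nm <- c(nm, dotted("zm", STATE_LEVELS))
  nm
}

# Working scales: log for positive parameters, logit for probabilities and
# the concentration. The turn mean uses the identity (radians): the wrapped
# Cauchy density is periodic in lam, so an unconstrained radian scale keeps
# the likelihood smooth where lam sits near +-pi (as it does in residency),
# and estimates are wrapped to (-pi, pi] only for reporting.
.to_working <- function(value, prefix) {
  switch(prefix,
         mu = , sigma = log(value),
         kappa = , ptr = , prt = , zm = qlogis(pmin(pmax(value, 1e-8), 1 - 1e-8)),
         lam = value)
}

.from_working <- function(value, prefix) {
  switch(prefix,
         mu = , sigma = exp(value),
         kappa = , ptr = , prt = , zm = plogis(value),
         lam = value)
}

.name_prefix <- function(nm) vapply(strsplit(nm, ".", fixed = TRUE),
                                    `[[`, character(1), 1)

.working_to_pars <- function(par, config) {
  pick <- function(prefix, st = NULL, sex = NULL) {
    nm <- prefix
    if (!is.null(st)) nm <- paste(nm, st, sep = ".")
    full <- if (!is.null(sex)) paste(nm, sex, sep = ".") else nm
    if (!full %in% names(par)) full <- nm  # sex-invariant fallback
    .from_working(par[[full]], prefix)
  }
  mk <- function(prefix) {
    m <- matrix(NA_real_, 2, 3, dimnames = list(STATE_LEVELS, SEX_LEVELS))
    for (st in STATE_LEVELS) for (sx in SEX_LEVELS)
      m[st, sx] <- pick(prefix, st, sx)
    m
  }
  tpm <- lapply(setNames(SEX_LEVELS, SEX_LEVELS), function(sx) {
    transition_matrix(pick("ptr", sex = sx), pick("prt", sex = sx))
  })
  zm <- if (any(.name_prefix(names(par)) == "zm"))
    c(pick("zm", "transit"), pick("zm", "resident")) else c(0, 0)
  structure(list(mu = mk("mu"), sigma = mk("sigma"), kappa = mk("kappa"),
                 lam = setNames(wrap_to_pi(c(pick("lam", "transit"),
                                             pick("lam", "resident"))),
                                STATE_LEVELS),
                 tpm = tpm, zeromass = setNames(zm, STATE_LEVELS)),
            class = "hmm_pars")
}

.pars_to_working <- function(pars, config, has_zero) {
  nm <- .param_layout(config, has_zero)
  par <- setNames(numeric(length(nm)), nm)
  for (k in nm) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    prefix <- parts[1]
    v <- switch(prefix,
                mu = , sigma = , kappa =
                  pars[[prefix]][parts[2], if (length(parts) > 2) parts[3] else 1],
                lam = pars$lam[parts[2]],
                ptr = pars$tpm[[if (length(parts) > 1) parts[2] else 1]][1, 2],
                prt = pars$tpm[[if (length(parts) > 1) parts[2] else 1]][2, 1],
                zm = pars$zeromass[parts[2]])
    par[k] <- .to_working(unname(v), prefix)
  }
  par
}

# ---- data preparation ----------------------------------------------------

# Per-row caches (log speed, cos/sin turn) let the likelihood evaluate the
# gamma log-density with scalar parameters per sex group: the hot path of
# the optimizer.
.make_cache <- function(speed, turn) {
  pos <- which(!is.na(speed) & speed > 0)
  list(pos = pos,
       zer = which(!is.na(speed) & speed == 0),
       okt = which(!is.na(turn)),
       logspd = log(speed[pos]),
       cost = cos(turn), sint = sin(turn))
}

.prep_series <- function(series) {
  need <- c("id", "speed_kmh", "turn_rad")
  if (!all(need %in% names(series)))
    stop("series needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(series$sex)) series$sex <- "unknown"
  if (!all(series$sex %in% SEX_LEVELS))
    stop("sex must be one of ", paste(SEX_LEVELS, collapse = ", "),
         call. = FALSE)
  if (is.null(series$realization)) series$realization <- 0L
  if (is.null(series$segment)) series$segment <- 1L
  if (all(is.na(series$speed_kmh) & is.na(series$turn_rad)))
    stop("series contains no observed speeds or turns", call. = FALSE)
  key <- interaction(series$id, series$realization, series$segment,
                     drop = TRUE)
  out <- list(speed = series$speed_kmh, turn = series$turn_rad,
              sex_idx = match(series$sex, SEX_LEVELS),
              sex_chr = series$sex,
              segments = split(seq_len(nrow(series)), key),
              ids = series$id)
  out$cache <- .make_cache(out$speed, out$turn)
  out
}

.emission_matrix <- function(pars, prep) {
  speed <- prep$speed; turn <- prep$turn; sex_idx <- prep$sex_idx
  ch <- prep$cache
  n <- length(speed)
  emis <- matrix(1, n, 2)
  sex_of_pos <- sex_idx[ch$pos]
  sex_of_okt <- sex_idx[ch$okt]
  for (sx in unique(sex_idx)) {
    ip <- ch$pos[sex_of_pos == sx]
    lsp <- ch$logspd[sex_of_pos == sx]
    it <- ch$okt[sex_of_okt == sx]
    for (s in 1:2) {
      mu <- pars$mu[s, sx]; sg <- pars$sigma[s, sx]
      kp <- pars$kappa[s, sx]; zm <- pars$zeromass[s]
      shape <- (mu / sg)^2; scale <- sg^2 / mu
      d <- rep(1, n)
      if (length(ip))
        d[ip] <- (1 - zm) * exp((shape - 1) * lsp - speed[ip] / scale -
                                  shape * log(scale) - lgamma(shape))
      if (length(it)) {
        cosdiff <- ch$cost[it] * cos(pars$lam[s]) +
          ch$sint[it] * sin(pars$lam[s])
        d[it] <- d[it] * (1 - kp^2) /
          (2 * pi * (1 + kp^2 - 2 * kp * cosdiff))
      }
      iz <- ch$zer[sex_idx[ch$zer] == sx]
      if (length(iz)) d[iz] <- zm
      rows <- which(sex_idx == sx)
      emis[rows, s] <- d[rows]
    }
  }
  emis
}

.data_loglik <- function(pars, prep) {
  emis <- .emission_matrix(pars, prep)
  delta <- lapply(pars$tpm, stationary_distribution)
  ll <- 0
  for (rows in prep$segments) {
    sx <- prep$sex_chr[rows[1]]
    ll <- ll + forward_loglik_cpp(emis[rows, , drop = FALSE],
                                  pars$tpm[[sx]], delta[[sx]])
  }
  ll
}

#' Forward-algorithm log-likelihood of one step/turn sequence
#'
#' Scaled forward recursion under natural-scale parameters, with the initial
#' distribution fixed at the stationary distribution of the sex's transition
#' matrix. Missing turns (each segment's first step) contribute the speed
#' density only; missing speeds contribute nothing.
#'
#' @param pars An [hmm_pars()] object.
#' @param speed Step speeds, km/h (`NA` allowed).
#' @param turn Turning angles, radians (`NA` allowed).
#' @param sex Sex level of the animal.
#' @return Log-likelihood (scalar).
#' @export
forward_loglik <- function(pars, speed, turn, sex = "unknown") {
  stopifnot(inherits(pars, "hmm_pars"))
  sex <- match.arg(sex, SEX_LEVELS)
  if (length(speed) == 0) stop("empty series", call. = FALSE)
  if (all(is.na(speed)) && all(is.na(turn)))
    stop("series contains no observed speeds or turns", call. = FALSE)
  mini <- list(speed = speed, turn = turn,
               sex_idx = rep(match(sex, SEX_LEVELS), length(speed)),
               cache = .make_cache(speed, turn))
  emis <- .emission_matrix(pars, mini)
  forward_loglik_cpp(emis, pars$tpm[[sex]],
                     stationary_distribution(pars$tpm[[sex]]))
}

# ---- fitting -------------------------------------------------------------

.moment_init <- function(prep, config) {
  spd <- prep$speed[!is.na(prep$speed) & prep$speed > 0]
  med <- stats::median(spd)
  hi <- spd[spd > med]; lo <- spd[spd <= med]
  mu0 <- c(mean(hi), mean(lo))
  sg0 <- pmax(c(sd(hi), sd(lo)), 0.05 * mu0)
  circ <- function(x) {
    if (length(x) < 5) return(c(0, 0.3))
    c(atan2(mean(sin(x)), mean(cos(x))),
      min(sqrt(mean(sin(x))^2 + mean(cos(x))^2), 0.9))
  }
  fast <- !is.na(prep$speed) & prep$speed > med & !is.na(prep$turn)
  slow <- !is.na(prep$speed) & prep$speed <= med & !is.na(prep$turn)
  cf <- circ(prep$turn[fast]); cs <- circ(prep$turn[slow])
  hmm_pars(mu = mu0, sigma = sg0,
           kappa = pmax(c(cf[2], cs[2]), 0.05),
           lam = c(cf[1], cs[1]),
           tpm = transition_matrix(0.1, 0.1),
           zeromass = c(0.01, 0.01))
}

# Relabel states so that mu(transit) > mu(resident), averaging over sexes.
.order_states <- function(par, config, has_zero) {
  pars <- .working_to_pars(par, config)
  if (mean(pars$mu[1, ]) >= mean(pars$mu[2, ])) return(par)
  swap <- function(x) { x[c(2, 1), , drop = FALSE] }
  pars$mu <- swap(pars$mu); pars$sigma <- swap(pars$sigma)
  pars$kappa <- swap(pars$kappa)
  pars$lam <- setNames(pars$lam[c(2, 1)], STATE_LEVELS)
  pars$zeromass <- setNames(pars$zeromass[c(2, 1)], STATE_LEVELS)
  pars$tpm <- lapply(pars$tpm, function(g)
    transition_matrix(g[2, 1], g[1, 2]))
  .pars_to_working(pars, config, has_zero)
}

#' Fit a two-state movement HMM
#'
#' Maximizes the pooled log-likelihood across all individuals and segments
#' by quasi-Newton optimization on working scales (log speed mean/SD, logit
#' concentration and transition probabilities, `tan(lam/2)` for the turn
#' mean), with the initial state distribution fixed at the stationary
#' distribution of the (sex-appropriate) transition matrix. The best of
#' `n_restarts` jittered initializations is kept and states are relabelled
#' so the transit state has the larger mean speed.
#'
#' @param series A `step_turn_series` data frame (columns `id`, `segment`,
#'   `speed_kmh`, `turn_rad`, `sex`).
#' @param config An [hmm_config()] or its integer id (1-4).
#' @param n_restarts Number of jittered starts (default 10; the first start
#'   is the unjittered moment-based initialization).
#' @param jitter_sd Working-scale SD of the restart jitter.
#' @param seed Optional integer seed (affects restart jitter only).
#' @param init Optional [hmm_pars()] starting values overriding the
#'   moment-based initialization.
#' @param hessian Compute the working-scale covariance (default TRUE).
#' @return An object of class `fitted_hmm`: working-scale `par` and `vcov`,
#'   natural-scale `pars`, `loglik`, `n_params`, `aic`, `config`,
#'   convergence and degeneracy flags.
#' @export
fit_hmm <- function(series, config = 1, n_restarts = 10, jitter_sd = 0.3,
                    seed = NULL, init = NULL, hessian = TRUE) {
  config <- .as_config(config)
  prep <- .prep_series(series)
  if (length(unique(prep$ids)) < 2 && length(prep$segments) < 2)
    stop("need at least 2 series (tracks or segments)", call. = FALSE)
  if ((config$sex_on_movement || config$sex_on_transitions) &&
      !all(SEX_LEVELS %in% unique(prep$sex_chr)))
    stop("sex-covariate configs need every sex level present", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  has_zero <- any(!is.na(prep$speed) & prep$speed == 0)

  init_pars <- if (is.null(init)) .moment_init(prep, config) else init
  par0 <- .pars_to_working(init_pars, config, has_zero)

  negll <- function(par) {
    pars <- .working_to_pars(setNames(par, names(par0)), config)
    ll <- .data_loglik(pars, prep)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  best <- NULL; msgs <- character(0)
  for (r in seq_len(max(1, n_restarts))) {
    start <- if (r == 1) par0 else par0 + rnorm(length(par0), 0, jitter_sd)
    op <- suppressWarnings(
      nlminb(start, negll,
             control = list(eval.max = 4000, iter.max = 1500)))
    msgs <- c(msgs, sprintf("restart %d: code %d (%s), nll %.4f",
                            r, op$convergence, op$message, op$objective))
    # nlminb's relative/X/singular-convergence exits are all usable optima;
    # singular convergence is routine when a warm start sits on a ridge
    ok <- is.finite(op$objective) &&
      (op$convergence == 0 || grepl("convergence", op$message))
    if (ok && (is.null(best) || op$objective < best$objective)) best <- op
  }
  if (is.null(best))
    stop("no restart converged:\n", paste(msgs, collapse = "\n"),
         call. = FALSE)

  par <- .order_states(setNames(best$par, names(par0)), config, has_zero)
  pars <- .working_to_pars(par, config)

  vc <- NULL
  if (hessian) {
    h <- try(optimHess(par, negll), silent = TRUE)
    if (!inherits(h, "try-error")) {
      vc <- try(solve(h), silent = TRUE)
      if (inherits(vc, "try-error") || any(diag(vc) <= 0)) vc <- NULL
    }
    if (!is.null(vc)) dimnames(vc) <- list(names(par), names(par))
  }

  degenerate <- any(pars$kappa > 0.995) || any(pars$sigma < 1e-3)
  if (degenerate)
    warning("possible state collapse: kappa near 1 or sigma near 0")

  ll <- -best$objective
  structure(list(
    config = config, par = par, vcov = vc, pars = pars,
    loglik = ll, n_params = length(par),
    aic = 2 * length(par) - 2 * ll,
    convergence = 0L, messages = msgs, degenerate = degenerate,
    n_obs = length(prep$speed), n_tracks = length(unique(prep$ids)),
    has_zero = has_zero,
    data_sig = c(n = length(prep$speed),
                 s = sum(prep$speed, na.rm = TRUE))
  ), class = "fitted_hmm")
}

#' @export
print.fitted_hmm <- function(x, ...) {
  cat(sprintf("fitted_hmm (config %d%s): %d obs / %d tracks, %d parameters\n",
              x$config$id,
              paste0(if (x$config$sex_on_movement) ", sex on movement" else "",
                     if (x$config$sex_on_transitions) ", sex on transitions" else ""),
              x$n_obs, x$n_tracks, x$n_params))
  cat(sprintf("  loglik %.3f, AIC %.3f\n", x$loglik, x$aic))
  cat("  mean speed mu (km/h):\n")
  print(round(x$pars$mu, 3))
  invisible(x)
}

#' AIC of a fitted HMM
#'
#' `AIC = 2 * n_params - 2 * loglik`.
#'
#' @param object A `fitted_hmm`.
#' @param ... Unused.
#' @param k Penalty per parameter (2 for AIC, `log(n)` gives BIC).
#' @export
AIC.fitted_hmm <- function(object, ..., k = 2) {
  k * object$n_params - 2 * object$loglik
}

#' BIC of a fitted HMM
#' @param object A `fitted_hmm`.
#' @param ... Unused.
#' @export
BIC.fitted_hmm <- function(object, ...) {
  log(object$n_obs) * object$n_params - 2 * object$loglik
}

#' Select the best-supported model
#'
#' Minimum-AIC selection across fits of the same data; ties are broken
#' toward the model with fewer parameters. BIC is available via
#' `criterion = "BIC"`.
#'
#' @param fits List of `fitted_hmm` objects fitted to the same data.
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @return The selected `fitted_hmm`, with attribute `"criteria"` holding
#'   the per-model criterion values.
#' @export
select_model <- function(fits, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  stopifnot(length(fits) >= 1)
  sigs <- vapply(fits, function(f) paste(f$data_sig, collapse = "/"),
                 character(1))
  if (length(unique(sigs)) != 1)
    stop("fits were not computed on the same data", call. = FALSE)
  crit <- vapply(fits, function(f)
    if (criterion == "AIC") AIC(f) else BIC(f), numeric(1))
  np <- vapply(fits, function(f) f$n_params, numeric(1))
  best <- order(crit, np)[1]
  out <- fits[[best]]
  attr(out, "criteria") <- setNames(crit, vapply(fits, function(f)
    paste0("config", f$config$id), character(1)))
  out
}

# ---- decoding ------------------------------------------------------------

.get_pars <- function(object) {
  if (inherits(object, "fitted_hmm")) object$pars
  else if (inherits(object, "hmm_pars")) object
  else stop("expected a fitted_hmm or hmm_pars", call. = FALSE)
}

#' Viterbi decoding of behavioural states
#'
#' Globally most probable state path per segment. Ties are broken toward the
#' transit state.
#'
#' @param object A `fitted_hmm` or [hmm_pars()].
#' @param series A `step_turn_series` data frame.
#' @return `series` with an added character column `state`.
#' @export
viterbi <- function(object, series) {
  pars <- .get_pars(object)
  prep <- .prep_series(series)
  emis <- .emission_matrix(pars, prep)
  lemis <- log(pmax(emis, 1e-300))
  state <- character(length(prep$speed))
  for (rows in prep$segments) {
    sx <- prep$sex_chr[rows[1]]
    ltpm <- log(pmax(pars$tpm[[sx]], 1e-300))
    ldelta <- log(pmax(stationary_distribution(pars$tpm[[sx]]), 1e-300))
    n <- length(rows)
    v <- matrix(-Inf, n, 2); bp <- matrix(1L, n, 2)
    v[1, ] <- ldelta + lemis[rows[1], ]
    if (n > 1) for (t in 2:n) for (s in 1:2) {
      cand <- v[t - 1, ] + ltpm[, s]
      bp[t, s] <- which.max(cand)  # first max: ties go to transit
      v[t, s] <- cand[bp[t, s]] + lemis[rows[t], s]
    }
    path <- integer(n)
    path[n] <- which.max(v[n, ])
    if (n > 1) for (t in (n - 1):1) path[t] <- bp[t + 1, path[t + 1]]
    state[rows] <- STATE_LEVELS[path]
  }
  series$state <- state
  series
}

#' Posterior state probabilities (forward-backward)
#'
#' @param object A `fitted_hmm` or [hmm_pars()].
#' @param series A `step_turn_series` data frame.
#' @return `series` with added columns `p_transit`, `p_resident` summing to
#'   one per step.
#' @export
state_posteriors <- function(object, series) {
  pars <- .get_pars(object)
  prep <- .prep_series(series)
  emis <- .emission_matrix(pars, prep)
  post <- matrix(NA_real_, length(prep$speed), 2)
  for (rows in prep$segments) {
    sx <- prep$sex_chr[rows[1]]
    g <- pars$tpm[[sx]]
    delta <- stationary_distribution(g)
    n <- length(rows)
    alpha <- matrix(0, n, 2); beta <- matrix(0, n, 2)
    a <- delta * emis[rows[1], ]
    cs <- numeric(n); cs[1] <- sum(a); alpha[1, ] <- a / cs[1]
    if (n > 1) for (t in 2:n) {
      a <- (alpha[t - 1, ] %*% g) * emis[rows[t], ]
      cs[t] <- sum(a); alpha[t, ] <- a / cs[t]
    }
    beta[n, ] <- 1
    if (n > 1) for (t in (n - 1):1) {
      beta[t, ] <- as.numeric(g %*% (emis[rows[t + 1], ] * beta[t + 1, ])) /
        cs[t + 1]
    }
    p <- alpha * beta
    post[rows, ] <- p / rowSums(p)
  }
  series$p_transit <- post[, 1]
  series$p_resident <- post[, 2]
  series
}
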