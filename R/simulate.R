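# Ground-truthed simulator: latent behavioural states, true movement path on
# the sphere, Argos-degraded observations, and synthetic catch records.

#' Default per-class Argos position error standard deviations (km)
#'
#' One isotropic per-axis SD for each of the six Argos location classes.
#' These are explicit working values spanning the usual accuracy ordering of
#' the classes; they are configurable everywhere they are consumed.
#'
#' @return Named numeric vector over classes 3, 2, 1, 0, A, B.
#' @export
argos_error_defaults <- function() {
  c("3" = 0.25, "2" = 0.5, "1" = 1.5, "0" = 4, "A" = 6, "B" = 10)
}

#' Default Argos class mixture for simulated tags
#'
#' Weighted toward the low-quality A/B classes that dominate cetacean
#' surface-time-limited transmissions.
#'
#' @return Named probability vector over the six classes, summing to 1.
#' @export
argos_class_defaults <- function() {
  c("3" = 0.05, "2" = 0.08, "1" = 0.12, "0" = 0.15, "A" = 0.25, "B" = 0.35)
}

#' Simulate a latent behavioural state sequence
#'
#' Draws a Markov chain over the states `transit` and `resident` with one
#' state per 6-h step.
#'
#' @param tpm A valid 2x2 [transition_matrix()].
#' @param n_steps Number of steps (>= 1).
#' @param initial `"stationary"` to draw the first state from the stationary
#'   distribution, or one of `"transit"`, `"resident"`.
#' @param seed Optional integer seed for reproducibility.
#' @return Character vector of length `n_steps` over
#'   `c("transit", "resident")`.
#' @export
simulate_state_sequence <- function(tpm, n_steps,
                                    initial = "stationary", seed = NULL) {
  validate_transition_matrix(tpm)
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s <- integer(n_steps)
  if (identical(initial, "stationary")) {
    pi0 <- stationary_distribution(tpm)
    s[1] <- 1L + (runif(1) > pi0[1])
  } else {
    initial <- match.arg(initial, STATE_LEVELS)
    s[1] <- match(initial, STATE_LEVELS)
  }
  if (n_steps > 1) {
    u <- runif(n_steps - 1)
    # row s[t-1], probability of remaining/switching; only 2 states
    for (t in 2:n_steps) {
      s[t] <- if (u[t - 1] <= tpm[s[t - 1], 1]) 1L else 2L
    }
  }
  STATE_LEVELS[s]
}

#' Per-state movement parameters
#'
#' Bundles the gamma step-speed and wrapped Cauchy turning-angle parameters
#' for the transit and resident states, as consumed by
#' [simulate_movement_path()].
#'
#' @param mu,sigma Length-2 vectors (transit, resident): gamma mean and SD of
#'   step speed in km/h.
#' @param lam Length-2 vector of mean turn angles (radians).
#' @param kappa Length-2 vector of turn-angle concentrations in `[0, 1)`.
#' @return A list of class `movement_params`.
#' @export
movement_params <- function(mu, sigma, lam, kappa) {
  stopifnot(length(mu) == 2, length(sigma) == 2,
            length(lam) == 2, length(kappa) == 2)
  for (i in 1:2) {
    gamma_params(mu[i], sigma[i])
    wrapped_cauchy_params(lam[i], kappa[i])
  }
  structure(list(mu = setNames(mu, STATE_LEVELS),
                 sigma = setNames(sigma, STATE_LEVELS),
                 lam = setNames(wrap_to_pi(lam), STATE_LEVELS),
                 kappa = setNames(kappa, STATE_LEVELS)),
            class = "movement_params")
}

#' Simulate a movement path on the sphere
#'
#' Given a latent state sequence, draws per-step speeds from the state's
#' gamma distribution and turning angles from its wrapped Cauchy
#' distribution, then advances the position along great circles: each step
#' covers `speed * step_hours` km on a bearing equal to the previous bearing
#' plus the drawn turn. The state is attached to the step (interval), not the
#' vertex.
#'
#' @param states Character vector of latent states, one per step.
#' @param params A [movement_params()] object.
#' @param start Numeric `c(lon, lat)` start position, decimal degrees;
#'   latitudes beyond +-89.5 are rejected (bearings degenerate at the poles).
#' @param start_time POSIXct time of the first vertex (UTC).
#' @param initial_bearing_rad Reference bearing for the first step's turn,
#'   radians clockwise from north.
#' @param step_hours Step duration, hours (default 6).
#' @param id Track identifier.
#' @param sex One of `"female"`, `"male"`, `"unknown"`.
#' @param seed Optional integer seed.
#' @return A list of class `true_path`: `times` (length n+1), `lon`, `lat`,
#'   `states` (length n), `speeds` (km/h), `turns` (radians), `bearings`,
#'   `id`, `sex`, `step_hours`.
#' @export
simulate_movement_path <- function(states, params, start,
                                   start_time = as.POSIXct("2016-09-15 00:00:00",
                                                           tz = "UTC"),
                                   initial_bearing_rad = 0,
                                   step_hours = 6, id = "sim1",
                                   sex = "unknown", seed = NULL) {
  if (!inherits(params, "movement_params"))
    stop("params must be a movement_params object", call. = FALSE)
  if (length(states) < 1) stop("need at least one step", call. = FALSE)
  if (abs(start[2]) > 89.5)
    stop("start latitude beyond +-89.5 degrees: bearings degenerate near the poles",
         call. = FALSE)
  sex <- match.arg(sex, SEX_LEVELS)
  if (!is.null(seed)) set.seed(seed)
  n <- length(states)
  si <- match(states, STATE_LEVELS)
  if (any(is.na(si))) stop("unknown state labels", call. = FALSE)

  speeds <- as.numeric(rgamma_speed(n, params$mu[si], params$sigma[si]))
  turns <- as.numeric(rwrapped_cauchy(n, params$lam[si], params$kappa[si]))
  bearings <- wrap_to_pi(initial_bearing_rad + cumsum(turns))

  lon <- numeric(n + 1); lat <- numeric(n + 1)
  lon[1] <- wrap_lon(start[1]); lat[1] <- start[2]
  for (t in seq_len(n)) {
    p <- destination_point(lon[t], lat[t], bearings[t], speeds[t] * step_hours)
    lon[t + 1] <- p$lon; lat[t + 1] <- p$lat
  }
  structure(list(
    times = start_time + (0:n) * step_hours * 3600,
    lon = lon, lat = lat, states = states,
    speeds = speeds, turns = turns, bearings = bearings,
    id = id, sex = sex, step_hours = step_hours
  ), class = "true_path")
}

#' @export
print.true_path <- function(x, ...) {
  cat(sprintf("true_path '%s' (%s): %d steps of %g h, %d vertices\n",
              x$id, x$sex, length(x$states), x$step_hours, length(x$lon)))
  cat(sprintf("  resident fraction: %.3f\n", mean(x$states == "resident")))
  invisible(x)
}

#' Convert a true path to a data frame
#'
#' @param x A `true_path`.
#' @param ... Unused.
#' @return Data frame with one row per vertex: `id`, `date`, `lon`, `lat`,
#'   and `state` (the state of the step *starting* at the vertex; `NA` for
#'   the final vertex).
#' @export
as.data.frame.true_path <- function(x, ...) {
  data.frame(id = x$id, sex = x$sex, date = x$times,
             lon = x$lon, lat = x$lat,
             state = c(x$states, NA_character_),
             stringsAsFactors = FALSE)
}

#' Degrade a true path into Argos-like observations
#'
#' Observation times are drawn with exponential gaps (mean `mean_gap_hours`)
#' across the path's time span; each observation takes the true position
#' linearly interpolated in time plus isotropic normal noise with the SD of
#' its randomly assigned Argos class (km, converted to degrees at the local
#' latitude). Observations after `dropout_time` are discarded, emulating tag
#' failure.
#'
#' @param path A `true_path`.
#' @param class_probs Named probability vector over the six Argos classes.
#' @param error_sd_km Named per-class isotropic SD in km.
#' @param mean_gap_hours Mean gap between fixes, hours.
#' @param dropout_time Optional POSIXct after which the tag is silent.
#' @param seed Optional integer seed.
#' @return Data frame of class `argos_obs` with columns `id`, `date`
#'   (POSIXct UTC), `lc`, `lon`, `lat`, times strictly increasing.
#' @export
degrade_to_argos <- function(path,
                             class_probs = argos_class_defaults(),
                             error_sd_km = argos_error_defaults(),
                             mean_gap_hours = 2,
                             dropout_time = NULL, seed = NULL) {
  if (!inherits(path, "true_path")) stop("path must be a true_path", call. = FALSE)
  if (length(path$lon) == 0) stop("empty path", call. = FALSE)
  if (mean_gap_hours <= 0) stop("mean_gap_hours must be > 0", call. = FALSE)
  if (any(error_sd_km < 0)) stop("error SDs must be >= 0", call. = FALSE)
  if (abs(sum(class_probs) - 1) > 1e-8)
    stop("class_probs must sum to 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  t0 <- as.numeric(path$times[1])
  t1 <- as.numeric(path$times[length(path$times)])
  if (!is.null(dropout_time)) t1 <- min(t1, as.numeric(dropout_time))
  span_h <- (t1 - t0) / 3600
  # expected count + margin, then truncate to the (possibly shortened) span
  gaps <- rexp(ceiling(span_h / mean_gap_hours * 1.5) + 25,
               rate = 1 / mean_gap_hours)
  tt <- t0 + cumsum(gaps) * 3600
  tt <- tt[tt <= t1]
  if (length(tt) == 0)
    stop("no observations drawn within the path span", call. = FALSE)

  pt <- as.numeric(path$times)
  lon_t <- approx(pt, path$lon, xout = tt)$y
  lat_t <- approx(pt, path$lat, xout = tt)$y

  lc <- sample(names(class_probs), length(tt), replace = TRUE,
               prob = class_probs)
  sdk <- unname(error_sd_km[lc])
  km_per_deg <- pi * EARTH_RADIUS_KM / 180
  lat_obs <- lat_t + rnorm(length(tt), 0, sdk) / km_per_deg
  lon_obs <- lon_t + rnorm(length(tt), 0, sdk) /
    (km_per_deg * cos(.deg2rad(lat_t)))

  out <- data.frame(id = path$id,
                    date = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
                    lc = lc, lon = wrap_lon(lon_obs), lat = lat_obs,
                    stringsAsFactors = FALSE)
  class(out) <- c("argos_obs", "data.frame")
  out
}

#' Simulate catch records
#'
#' Generates synthetic whaling catch records for exercising the gridding
#' stage: positions uniform in the given window, or drawn from a supplied
#' cell-weight surface.
#'
#' @param n_records Number of records (>= 0).
#' @param lon_window,lat_window Length-2 half-open windows `[min, max)`.
#' @param intensity `NULL` for uniform positions, or a data frame with
#'   columns `lon`, `lat`, `weight` giving 1-degree cell origins sampled in
#'   proportion to `weight` (positions uniform within the chosen cell).
#' @param year_range Length-2 integer range of catch years (inclusive).
#' @param counts_lambda Mean of the Poisson-plus-one catch count per record.
#' @param seed Optional integer seed.
#' @return Data frame with columns `lon`, `lat`, `count`, `year`.
#' @export
simulate_catches <- function(n_records, lon_window = c(0, 150),
                             lat_window = c(-70, -36), intensity = NULL,
                             year_range = c(1929, 1968),
                             counts_lambda = 2, seed = NULL) {
  if (n_records < 0) stop("n_records must be >= 0", call. = FALSE)
  if (diff(lon_window) <= 0 || diff(lat_window) <= 0)
    stop("degenerate window", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (n_records == 0)
    return(data.frame(lon = numeric(0), lat = numeric(0),
                      count = integer(0), year = integer(0)))
  if (is.null(intensity)) {
    lon <- runif(n_records, lon_window[1], lon_window[2])
    lat <- runif(n_records, lat_window[1], lat_window[2])
  } else {
    stopifnot(all(c("lon", "lat", "weight") %in% names(intensity)))
    i <- sample.int(nrow(intensity), n_records, replace = TRUE,
                    prob = intensity$weight)
    lon <- intensity$lon[i] + runif(n_records)
    lat <- intensity$lat[i] + runif(n_records)
  }
  data.frame(lon = wrap_lon(lon), lat = lat,
             count = stats::rpois(n_records, counts_lambda - 1) + 1L,
             year = sample(seq(year_range[1], year_range[2]), n_records,
                           replace = TRUE))
}

#' Generating parameters matching the published pooled estimates
#'
#' Builds the full natural-scale parameter set of the sex-dependent-movement
#' model from the packaged pooled estimates: per-sex transit and resident
#' step-speed means and transit turn concentrations as published, step-speed
#' SDs defaulting to `mu/2`, resident concentration 0.1 (near-uniform
#' turning), turn means 0 (transit) and pi (resident), and the published
#' shared transition probabilities 0.035 / 0.017.
#'
#' @param sigma_factor Step-speed SD as a multiple of the mean (default 0.5).
#' @param kappa_resident Turn concentration of the resident state
#'   (default 0.1).
#' @return An [hmm_pars()] object.
#' @export
reported_generating_pars <- function(sigma_factor = 0.5,
                                     kappa_resident = 0.1) {
  est <- reported_hmm_estimates()
  get1 <- function(p, st, sx)
    est$estimate[est$parameter == p & est$state == st & est$sex == sx]
  mu <- rbind(vapply(SEX_LEVELS, function(s) get1("mu", "transit", s),
                     numeric(1)),
              vapply(SEX_LEVELS, function(s) get1("mu", "resident", s),
                     numeric(1)))
  kap <- rbind(vapply(SEX_LEVELS, function(s) get1("kappa", "transit", s),
                      numeric(1)),
               rep(kappa_resident, 3))
  hmm_pars(mu = mu, sigma = mu * sigma_factor, kappa = kap,
           lam = c(0, pi),
           tpm = transition_matrix(get1("ptr", "all", "all"),
                                   get1("prt", "all", "all")))
}

#' Simulate a study-scale set of ground-truthed tracks
#'
#' Generates `n_tracks` independent tracks (default 12: four females, four
#' males, four unsexed, each of 425 six-hour steps, about 5100 steps in
#' total) under the two-state switching movement model, returning the exact
#' step/turn series with the true latent states attached. Observation noise
#' is not added here; see [degrade_to_argos()] and [fit_ssm()] for the
#' Argos-error pathway.
#'
#' @param n_tracks Number of tracks.
#' @param n_steps Steps per track.
#' @param pars Generating [hmm_pars()] (default
#'   [reported_generating_pars()]).
#' @param sexes Sex per track (default: thirds in the order female, male,
#'   unknown).
#' @param seed Optional integer seed.
#' @return A `step_turn_series` data frame with columns `id`, `realization`,
#'   `segment`, `date`, `speed_kmh`, `turn_rad`, `sex` and `true_state`.
#' @export
simulate_study_tracks <- function(n_tracks = 12, n_steps = 425,
                                  pars = reported_generating_pars(),
                                  sexes = rep(SEX_LEVELS,
                                              each = ceiling(n_tracks / 3))[
                                                seq_len(n_tracks)],
                                  seed = NULL) {
  stopifnot(inherits(pars, "hmm_pars"), length(sexes) == n_tracks)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(n_tracks), function(i) {
    sx <- sexes[i]
    mp <- movement_params(mu = pars$mu[, sx], sigma = pars$sigma[, sx],
                          lam = pars$lam, kappa = pars$kappa[, sx])
    st <- simulate_state_sequence(pars$tpm[[sx]], n_steps)
    p <- simulate_movement_path(st, mp, start = c(70 + 3 * i, -45),
                                id = sprintf("sim%02d", i), sex = sx)
    tr <- as.data.frame(p)
    tr$realization <- 0L; tr$segment <- 1L
    s <- steps_and_turns(tr, step_hours = p$step_hours)
    s$sex <- sx
    s$true_state <- st
    s
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("step_turn_series", "data.frame")
  out
}
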