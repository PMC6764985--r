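# State-space regularization of irregular Argos fixes.
#
# Movement model per planar axis: first-difference correlated random walk
#   x_t = x_{t-1} + gamma * (x_{t-1} - x_{t-2}) + eta_t,  eta ~ N(0, sigma^2)
# on a 6-h grid, with irregular observations tied to the grid by linear
# time-interpolation weights and normal observation noise set by Argos class.
# With state s_t = (x_t, x_{t-1}) this is linear-Gaussian, so maximum
# likelihood uses an exact Kalman filter, the location estimates an RTS
# smoother, and the imputation draws forward-filtering backward-sampling.
# The two planar axes are independent given the shared (gamma, sigma).

.floor6h <- function(t_sec, step_sec) floor(t_sec / step_sec) * step_sec
.ceil6h <- function(t_sec, step_sec) ceiling(t_sec / step_sec) * step_sec

# Map observation times onto grid intervals: obs in (g[j-1], g[j]] attaches
# to filter step j with weight w on x_j (w = 0 reproduces x_{j-1}).
.grid_weights <- function(t_obs, grid) {
  step <- grid[2] - grid[1]
  k <- (t_obs - grid[1]) / step + 1
  j <- pmin(pmax(ceiling(k), 2L), length(grid))
  w <- (t_obs - grid[j - 1]) / step
  list(j = as.integer(j), w = pmin(pmax(w, 0), 1))
}

# One-axis DCRW Kalman filter. y: obs values; j/w: grid attachment; r_sd:
# per-obs noise SD. Returns loglik and, if keep = TRUE, filtered and
# predicted moments for steps 2..T (indexed [, , t]).
.dcrw_filter <- function(y, j, w, r_sd, n_grid, gamma, sigma,
                         prior_mean, prior_var = 1e4, keep = FALSE) {
  A <- matrix(c(1 + gamma, 1, -gamma, 0), 2, 2)
  q <- sigma^2
  m <- c(prior_mean, prior_mean)
  P <- diag(c(prior_var, prior_var))
  ll <- 0
  if (keep) {
    mf <- matrix(NA_real_, 2, n_grid); Pf <- array(NA_real_, c(2, 2, n_grid))
    mp <- mf; Pp <- Pf
  }
  ord <- order(j)
  y <- y[ord]; w <- w[ord]; r_sd <- r_sd[ord]; j <- j[ord]
  k <- 1L
  for (t in 2:n_grid) {
    if (t > 2) {
      m <- A %*% m
      P <- A %*% P %*% t(A)
      P[1, 1] <- P[1, 1] + q
      m <- as.numeric(m)
    }
    if (keep) { mp[, t] <- m; Pp[, , t] <- P }
    while (k <= length(j) && j[k] == t) {
      H <- c(w[k], 1 - w[k])
      PH <- P %*% H
      S <- sum(H * PH) + r_sd[k]^2
      if (S <= 0) S <- 1e-12
      v <- y[k] - sum(H * m)
      K <- as.numeric(PH) / S
      m <- m + K * v
      P <- P - tcrossprod(K, as.numeric(PH))
      P <- (P + t(P)) / 2
      ll <- ll - 0.5 * (log(2 * pi) + log(S) + v^2 / S)
      k <- k + 1L
    }
    if (keep) { mf[, t] <- m; Pf[, , t] <- P }
  }
  out <- list(loglik = ll)
  if (keep) out <- c(out, list(mf = mf, Pf = Pf, mp = mp, Pp = Pp, A = A))
  out
}

.solve2 <- function(M) {
  d <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  if (!is.finite(d) || abs(d) < 1e-300) {
    M <- M + diag(1e-10, 2)
    d <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  }
  matrix(c(M[2, 2], -M[2, 1], -M[1, 2], M[1, 1]), 2, 2) / d
}

# RTS smoother from stored filter output; returns per-node mean/var of x.
.dcrw_smooth_pass <- function(flt, n_grid) {
  A <- flt$A
  ms <- flt$mf; Ps <- flt$Pf
  for (t in (n_grid - 1):2) {
    if (n_grid < 3) break
    J <- flt$Pf[, , t] %*% t(A) %*% .solve2(flt$Pp[, , t + 1])
    ms[, t] <- flt$mf[, t] + J %*% (ms[, t + 1] - flt$mp[, t + 1])
    Ps[, , t] <- flt$Pf[, , t] +
      J %*% (Ps[, , t + 1] - flt$Pp[, , t + 1]) %*% t(J)
  }
  # node values: x_t = s_t[1] for t >= 2; x_1 = s_2[2]
  list(mean = c(ms[2, 2], ms[1, 2:n_grid]),
       var = pmax(c(Ps[2, 2, 2], Ps[1, 1, 2:n_grid]), 0),
       ms = ms, Ps = Ps)
}

# Sample one state path by backward sampling; returns x_1..x_T.
.dcrw_sample_path <- function(flt, n_grid) {
  A <- flt$A
  draw2 <- function(mu, S) {
    S <- (S + t(S)) / 2
    e <- eigen(S, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    as.numeric(mu + e$vectors %*% (sqrt(ev) * rnorm(2)))
  }
  s <- matrix(NA_real_, 2, n_grid)
  s[, n_grid] <- draw2(flt$mf[, n_grid], flt$Pf[, , n_grid])
  if (n_grid >= 3) {
    for (t in (n_grid - 1):2) {
      Sp <- flt$Pp[, , t + 1]
      J <- flt$Pf[, , t] %*% t(A) %*% .solve2(Sp)
      mu <- flt$mf[, t] + J %*% (s[, t + 1] - flt$mp[, t + 1])
      V <- flt$Pf[, , t] - J %*% Sp %*% t(J)
      s[, t] <- draw2(as.numeric(mu), V)
    }
  }
  c(s[2, 2], s[1, 2:n_grid])
}

#' Exact smoother for the one-axis regularizing DCRW
#'
#' Low-level access to the linear-Gaussian smoother used by [fit_ssm()]:
#' given scalar observations at irregular times tied to a regular grid by
#' linear interpolation weights, returns the smoothed mean and variance of
#' the process at every grid node. Exposed so that the smoother can be
#' checked against direct joint-Gaussian conditioning on small problems.
#'
#' @param t_obs Observation times (numeric, same units as `grid`).
#' @param y Observed values.
#' @param r_sd Per-observation noise SD (recycled).
#' @param grid Strictly increasing, equally spaced grid times.
#' @param gamma Persistence parameter of the first-difference correlated
#'   random walk, in `(-1, 1)`.
#' @param sigma Per-step process SD.
#' @param prior_mean Prior mean for the first two states (default: first
#'   observation).
#' @param prior_var Diffuse prior variance (default `1e4`).
#' @return List with `mean`, `var` (length `length(grid)`), and `loglik`.
#' @export
dcrw_smooth <- function(t_obs, y, r_sd, grid, gamma, sigma,
                        prior_mean = NULL, prior_var = 1e4) {
  stopifnot(length(t_obs) == length(y), length(grid) >= 2)
  r_sd <- rep_len(r_sd, length(y))
  if (is.null(prior_mean)) prior_mean <- y[1]
  gw <- .grid_weights(t_obs, grid)
  flt <- .dcrw_filter(y, gw$j, gw$w, r_sd, length(grid), gamma, sigma,
                      prior_mean, prior_var, keep = TRUE)
  sm <- .dcrw_smooth_pass(flt, length(grid))
  list(mean = sm$mean, var = sm$var, loglik = flt$loglik)
}

.validate_argos_obs <- function(obs) {
  need <- c("id", "date", "lc", "lon", "lat")
  if (!all(need %in% names(obs)))
    stop("observations need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(obs$lc %in% ARGOS_CLASSES))
    stop("unknown Argos location class", call. = FALSE)
  invisible(obs)
}

#' Fit the regularizing state-space model to one track
#'
#' Estimates the first-difference correlated random walk (persistence
#' `gamma`, process SD `sigma`) by maximum likelihood on a locally planar
#' azimuthal-equidistant chart about the track's centroid, with observation
#' noise fixed per Argos class, and returns smoothed positions with
#' uncertainties at every 6-h node (four location estimates per day).
#' Gaps longer than `gap_split_days` split the track into independently
#' gridded segments that share the movement parameters.
#'
#' @param obs An `argos_obs` data frame (columns `id`, `date`, `lc`, `lon`,
#'   `lat`) for a single animal.
#' @param step_hours Regular grid step, hours (default 6).
#' @param error_sd_km Named per-class observation SD in km
#'   (default [argos_error_defaults()]).
#' @param gap_split_days Data gaps longer than this split the track.
#' @param prior_var Diffuse prior variance (km^2) on the first two states.
#' @return An object of class `ssm_fit` with elements `par`
#'   (`gamma`, `sigma`), `se`, `loglik`, `convergence`, `track` (the
#'   realization-0 [regularized_track()] data frame) and internal filter
#'   state used by [draw_realizations()].
#' @export
fit_ssm <- function(obs, step_hours = 6,
                    error_sd_km = argos_error_defaults(),
                    gap_split_days = 7, prior_var = 1e4) {
  .validate_argos_obs(obs)
  obs <- obs[order(obs$date), , drop = FALSE]
  if (length(unique(obs$id)) != 1)
    stop("fit_ssm expects a single track id", call. = FALSE)
  if (nrow(obs) < 8)
    stop("need at least 8 observations", call. = FALSE)
  t_sec <- as.numeric(obs$date)
  if (diff(range(t_sec)) < 2 * 86400)
    stop("observations must span at least 2 days", call. = FALSE)
  step_sec <- step_hours * 3600

  lon0 <- mean(wrap_lon(obs$lon)); lat0 <- mean(obs$lat)
  xy <- .project_aeqd(obs$lon, obs$lat, lon0, lat0)
  r_sd <- unname(error_sd_km[obs$lc])

  seg_id <- cumsum(c(1, diff(t_sec) > gap_split_days * 86400))
  segs <- list()
  for (s in unique(seg_id)) {
    i <- which(seg_id == s)
    grid <- seq(.floor6h(min(t_sec[i]), step_sec),
                .ceil6h(max(t_sec[i]), step_sec), by = step_sec)
    if (length(grid) < 3 || length(i) < 4) {
      warning("dropping segment with too few observations or grid nodes")
      next
    }
    gw <- .grid_weights(t_sec[i], grid)
    segs[[length(segs) + 1]] <- list(
      idx = i, grid = grid, j = gw$j, w = gw$w,
      x = xy$x[i], y = xy$y[i], r_sd = r_sd[i])
  }
  if (length(segs) == 0) stop("no fittable segments", call. = FALSE)

  negll <- function(u) {
    gamma <- tanh(u[1]); sigma <- exp(u[2])
    ll <- 0
    for (sg in segs) {
      for (ax in c("x", "y")) {
        ll <- ll + .dcrw_filter(sg[[ax]], sg$j, sg$w, sg$r_sd,
                                length(sg$grid), gamma, sigma,
                                prior_mean = sg[[ax]][1],
                                prior_var = prior_var)$loglik
      }
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  sigma0 <- max(sd(diff(xy$x)), sd(diff(xy$y)), 1) / 2
  best <- NULL
  for (start in list(c(atanh(0.5), log(sigma0)),
                     c(atanh(0.05), log(sigma0 * 2)))) {
    op <- suppressWarnings(nlminb(start, negll,
                                  lower = c(-5, -8), upper = c(5, 8)))
    if (is.null(best) || op$objective < best$objective) best <- op
  }
  if (!best$convergence %in% c(0, 1) || !is.finite(best$objective))
    stop("SSM did not converge: ", best$message, call. = FALSE)

  hess <- try(optimHess(best$par, negll), silent = TRUE)
  se <- c(NA_real_, NA_real_)
  if (!inherits(hess, "try-error")) {
    vc <- try(solve(hess), silent = TRUE)
    if (!inherits(vc, "try-error") && all(diag(vc) > 0)) {
      # delta method back to (gamma, sigma)
      gr <- c(1 - tanh(best$par[1])^2, exp(best$par[2]))
      se <- sqrt(diag(vc)) * gr
    }
  }
  gamma_hat <- tanh(best$par[1]); sigma_hat <- exp(best$par[2])

  rows <- list()
  for (si in seq_along(segs)) {
    sg <- segs[[si]]
    sm <- list()
    for (ax in c("x", "y")) {
      flt <- .dcrw_filter(sg[[ax]], sg$j, sg$w, sg$r_sd, length(sg$grid),
                          gamma_hat, sigma_hat, prior_mean = sg[[ax]][1],
                          prior_var = prior_var, keep = TRUE)
      sm[[ax]] <- .dcrw_smooth_pass(flt, length(sg$grid))
      segs[[si]]$flt[[ax]] <- flt
    }
    ll <- .unproject_aeqd(sm$x$mean, sm$y$mean, lon0, lat0)
    rows[[si]] <- data.frame(
      id = obs$id[1], realization = 0L, segment = si,
      date = as.POSIXct(sg$grid, origin = "1970-01-01", tz = "UTC"),
      lon = ll$lon, lat = ll$lat,
      sd_km = sqrt((sm$x$var + sm$y$var) / 2),
      stringsAsFactors = FALSE)
  }
  track <- do.call(rbind, rows)

  structure(list(
    par = c(gamma = gamma_hat, sigma = sigma_hat),
    se = setNames(se, c("gamma", "sigma")),
    loglik = -best$objective, convergence = best$convergence,
    message = best$message, n_obs = nrow(obs),
    step_hours = step_hours, track = track,
    center = c(lon = lon0, lat = lat0), segs = segs,
    prior_var = prior_var
  ), class = "ssm_fit")
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat(sprintf("ssm_fit: %d obs -> %d nodes (%g h grid), %d segment(s)\n",
              x$n_obs, nrow(x$track), x$step_hours,
              length(unique(x$track$segment))))
  cat(sprintf("  gamma = %.3f (SE %.3f), sigma = %.3f km (SE %.3f), loglik = %.2f\n",
              x$par["gamma"], x$se["gamma"], x$par["sigma"], x$se["sigma"],
              x$loglik))
  invisible(x)
}

#' Extract the regularized track (point estimate)
#'
#' @param fit An `ssm_fit`.
#' @return Data frame with columns `id`, `realization` (0 for the point
#'   estimate), `segment`, `date`, `lon`, `lat`, `sd_km`.
#' @export
regularized_track <- function(fit) {
  stopifnot(inherits(fit, "ssm_fit"))
  fit$track
}

#' Draw track realizations from the smoothing distribution
#'
#' Samples `m` joint realizations of the regular-grid positions from the
#' fitted model's smoothing distribution (forward-filtering backward-
#' sampling), for multiple-imputation analyses that propagate location
#' uncertainty. Realization 0 is reserved for the point estimate.
#'
#' @param fit A converged `ssm_fit`.
#' @param m Number of realizations (>= 1).
#' @param seed Optional integer seed.
#' @param include_point Prepend the realization-0 point estimate
#'   (default TRUE).
#' @return Data frame in the [regularized_track()] layout with realizations
#'   `(0,) 1..m` stacked.
#' @export
draw_realizations <- function(fit, m, seed = NULL, include_point = TRUE) {
  stopifnot(inherits(fit, "ssm_fit"))
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- if (include_point) list(fit$track) else list()
  for (r in seq_len(m)) {
    rows <- list()
    for (si in seq_along(fit$segs)) {
      sg <- fit$segs[[si]]
      xs <- .dcrw_sample_path(sg$flt$x, length(sg$grid))
      ys <- .dcrw_sample_path(sg$flt$y, length(sg$grid))
      ll <- .unproject_aeqd(xs, ys, fit$center["lon"], fit$center["lat"])
      rows[[si]] <- data.frame(
        id = fit$track$id[1], realization = r, segment = si,
        date = as.POSIXct(sg$grid, origin = "1970-01-01", tz = "UTC"),
        lon = ll$lon, lat = ll$lat,
        sd_km = fit$track$sd_km[fit$track$segment == si],
        stringsAsFactors = FALSE)
    }
    out[[length(out) + 1]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}
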