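# Readers and writers for the pipeline's delimited-text interchange
# formats. All timestamps are ISO-8601 UTC.

.fmt_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
.parse_utc <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ",
                                     tz = "UTC")

#' Write / read Argos observations as CSV
#'
#' Columns `id`, `date` (ISO-8601 UTC), `lc`, `lon`, `lat`.
#'
#' @param obs An `argos_obs` data frame.
#' @param file Path.
#' @return `read_argos_csv` returns an `argos_obs` data frame.
#' @export
write_argos_csv <- function(obs, file) {
  out <- data.frame(id = obs$id, date = .fmt_utc(obs$date), lc = obs$lc,
                    lon = obs$lon, lat = obs$lat)
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_argos_csv
#' @export
read_argos_csv <- function(file) {
  x <- read.csv(file, colClasses = c(id = "character", lc = "character"))
  x$date <- .parse_utc(x$date)
  class(x) <- c("argos_obs", "data.frame")
  x
}

#' Write / read regularized tracks as CSV
#'
#' Columns `id`, `realization`, `segment`, `date`, `lon`, `lat`, `sd_km`.
#'
#' @param track A [regularized_track()]-layout data frame.
#' @param file Path.
#' @export
write_track_csv <- function(track, file) {
  out <- track
  out$date <- .fmt_utc(out$date)
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_track_csv
#' @export
read_track_csv <- function(file) {
  x <- read.csv(file, colClasses = c(id = "character"))
  x$date <- .parse_utc(x$date)
  x
}

#' Write / read step/turn series as CSV
#'
#' Columns `id`, `realization`, `segment`, `date`, `speed_kmh`, `turn_rad`
#' (+ `sex` when present).
#'
#' @param series A `step_turn_series` data frame.
#' @param file Path.
#' @export
write_series_csv <- function(series, file) {
  out <- series
  out$date <- .fmt_utc(out$date)
  write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(file) {
  x <- read.csv(file, colClasses = c(id = "character"))
  x$date <- .parse_utc(x$date)
  class(x) <- c("step_turn_series", "data.frame")
  x
}

#' Serialize a fitted HMM to JSON
#'
#' Stores working- and natural-scale parameters, the log-likelihood, AIC,
#' parameter count and convergence record as structured text.
#'
#' @param fit A `fitted_hmm`.
#' @param file Path to write (`.json`).
#' @export
write_fit_json <- function(fit, file) {
  stopifnot(inherits(fit, "fitted_hmm"))
  obj <- list(
    config = fit$config$id,
    sex_on_movement = fit$config$sex_on_movement,
    sex_on_transitions = fit$config$sex_on_transitions,
    working = as.list(fit$par),
    natural = list(mu = fit$pars$mu, sigma = fit$pars$sigma,
                   kappa = fit$pars$kappa, lam = as.list(fit$pars$lam),
                   tpm = lapply(fit$pars$tpm, unclass),
                   zeromass = as.list(fit$pars$zeromass)),
    loglik = fit$loglik, n_params = fit$n_params, aic = fit$aic,
    convergence = fit$convergence, degenerate = fit$degenerate,
    n_obs = fit$n_obs, n_tracks = fit$n_tracks)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Write a pooled parameter table as CSV
#'
#' Columns `parameter`, `state`, `sex`, `estimate`, `lo95`, `hi95`.
#'
#' @param pooled A `pooled_hmm`.
#' @param file Path.
#' @export
write_pooled_csv <- function(pooled, file) {
  write.csv(as.data.frame(pooled), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
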