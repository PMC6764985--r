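# Step speeds and turning angles from regularized tracks.

#' Step speeds and turning angles from a regularized track
#'
#' For each within-segment step the speed is the great-circle step length
#' divided by the step duration; the turning angle is the signed difference
#' of successive forward azimuths wrapped to `(-pi, pi]`, undefined (`NA`)
#' for the first step of each segment. Duplicate consecutive positions give
#' speed 0 and an undefined turn. The step's `date` is the time of its start
#' node, and latent/decoded states downstream attach to steps, not vertices.
#'
#' @param track Data frame in the [regularized_track()] layout (columns `id`,
#'   `realization`, `segment`, `date`, `lon`, `lat`; `sex` is carried through
#'   if present).
#' @param step_hours Step duration in hours used to convert lengths to
#'   speeds (default: inferred from the median time difference).
#' @return Data frame of class `step_turn_series` with columns `id`,
#'   `realization`, `segment`, `date`, `speed_kmh`, `turn_rad` (+ `sex`).
#' @export
steps_and_turns <- function(track, step_hours = NULL) {
  need <- c("id", "date", "lon", "lat")
  if (!all(need %in% names(track)))
    stop("track needs columns ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(track$realization)) track$realization <- 0L
  if (is.null(track$segment)) track$segment <- 1L
  key <- interaction(track$id, track$realization, track$segment, drop = TRUE)
  out <- lapply(split(seq_len(nrow(track)), key), function(i) {
    g <- track[i, , drop = FALSE]
    g <- g[order(g$date), , drop = FALSE]
    n <- nrow(g)
    if (n < 3) return(NULL)
    sh <- step_hours
    if (is.null(sh))
      sh <- as.numeric(stats::median(diff(as.numeric(g$date)))) / 3600
    d <- great_circle_km(g$lon[-n], g$lat[-n], g$lon[-1], g$lat[-1])
    az <- initial_bearing(g$lon[-n], g$lat[-n], g$lon[-1], g$lat[-1])
    az[d == 0] <- NA_real_  # bearing undefined for duplicate positions
    turn <- c(NA_real_, wrap_to_pi(diff(az)))
    res <- data.frame(id = g$id[1], realization = g$realization[1],
                      segment = g$segment[1], date = g$date[-n],
                      speed_kmh = d / sh, turn_rad = turn,
                      stringsAsFactors = FALSE)
    if (!is.null(g$sex)) res$sex <- g$sex[1]
    res
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) stop("no segment has >= 3 positions", call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("step_turn_series", "data.frame")
  out
}

#' Restrict a track to the Southern Ocean
#'
#' Keeps locations strictly south of `lat_cut` (default -36: "beyond 36S" is
#' read as latitude < -36, so a location at exactly -36 is excluded) and
#' re-segments runs broken by the filter so steps are never computed across
#' removed locations.
#'
#' @param track Data frame with at least `id`, `date`, `lat` (typically a
#'   [regularized_track()]).
#' @param lat_cut Latitude cut in decimal degrees (default -36).
#' @return The filtered track with a recomputed `segment` column.
#' @export
filter_southern_ocean <- function(track, lat_cut = -36) {
  keep <- track$lat < lat_cut
  out <- track[keep, , drop = FALSE]
  if (nrow(out) == 0) return(out)
  if (is.null(out$realization)) out$realization <- 0L
  key <- interaction(out$id, out$realization, drop = TRUE)
  # rows that were non-adjacent in the source become new segments
  src <- which(keep)
  brk <- c(TRUE, diff(src) != 1)
  seg <- stats::ave(as.integer(brk), key, FUN = cumsum)
  out$segment <- seg
  rownames(out) <- NULL
  out
}
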