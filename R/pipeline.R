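# End-to-end pipeline: regularize -> filter -> features -> fit four HMM
# configurations -> select -> decode -> pool across imputations -> summarize.

#' Pipeline configuration
#'
#' Bundles every tunable of the analysis with its default: 6-h regular time
#' step, Southern Ocean latitude cut at -36, 100 track realizations for
#' imputation, 10 optimizer restarts, the per-class Argos error SDs, the
#' management-area file and the 7-day gap-split threshold.
#'
#' @param step_hours Regular grid step, hours.
#' @param lat_cut Southern Ocean latitude cut, decimal degrees.
#' @param m Number of imputation realizations (analyses at desk scale
#'   typically use 10).
#' @param n_restarts HMM optimizer restarts.
#' @param seed Integer seed for every stochastic stage.
#' @param error_sd_km Named per-class Argos error SDs (km).
#' @param area_file Management-area GeoJSON (`NULL` = packaged default).
#' @param gap_split_days Track-splitting gap threshold, days.
#' @param configs HMM configurations to compare (default 1:4).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(step_hours = 6, lat_cut = -36, m = 100,
                            n_restarts = 10, seed = 1,
                            error_sd_km = argos_error_defaults(),
                            area_file = NULL, gap_split_days = 7,
                            configs = 1:4) {
  if (step_hours <= 0 || m < 1 || n_restarts < 1)
    stop("invalid configuration", call. = FALSE)
  if (!all(ARGOS_CLASSES %in% names(error_sd_km)))
    stop("error_sd_km must name all six Argos classes", call. = FALSE)
  if (!is.null(area_file) && !file.exists(area_file))
    stop("management area file not found: ", area_file, call. = FALSE)
  structure(list(step_hours = step_hours, lat_cut = lat_cut, m = m,
                 n_restarts = n_restarts, seed = seed,
                 error_sd_km = error_sd_km, area_file = area_file,
                 gap_split_days = gap_split_days, configs = configs),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes regularization, Southern Ocean filtering, feature extraction,
#' fitting of the requested HMM configurations on the point-estimate tracks,
#' AIC selection, refitting of the selected configuration on each of `m`
#' imputed track realizations, Rubin pooling, Viterbi decoding, and
#' per-whale plus overall spatial summaries.
#'
#' @param obs An `argos_obs` data frame covering one or more animals.
#' @param sex Named character vector mapping track `id` to sex level.
#' @param deploy Named list mapping track `id` to `c(lon, lat)` deployment
#'   locations (defaults to each track's first observation).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: every artifact is written there as
#'   delimited text / JSON together with a run manifest.
#' @return A list with elements `ssm_fits`, `tracks`, `series`, `fits`,
#'   `best`, `pooled`, `decoded`, `summaries`, `overall`, `manifest`.
#' @export
run_pipeline <- function(obs, sex, deploy = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  areas <- .stage("config", management_areas(config$area_file))
  .validate_argos_obs(obs)
  ids <- unique(obs$id)
  if (!all(ids %in% names(sex)))
    stop("[stage config] sex must be named for every track id", call. = FALSE)
  set.seed(config$seed)

  ssm_fits <- .stage("regularize", {
    lapply(setNames(ids, ids), function(i)
      fit_ssm(obs[obs$id == i, , drop = FALSE],
              step_hours = config$step_hours,
              error_sd_km = config$error_sd_km,
              gap_split_days = config$gap_split_days))
  })
  tracks <- .stage("impute", {
    do.call(rbind, lapply(ids, function(i)
      draw_realizations(ssm_fits[[i]], m = config$m,
                        seed = config$seed + match(i, ids))))
  })

  make_series <- function(realization) {
    tr <- tracks[tracks$realization == realization, , drop = FALSE]
    tr$sex <- unname(sex[tr$id])
    tr <- filter_southern_ocean(tr, config$lat_cut)
    if (nrow(tr) == 0) stop("no locations south of the latitude cut")
    steps_and_turns(tr, step_hours = config$step_hours)
  }

  series0 <- .stage("features", make_series(0L))

  fits <- .stage("fit", {
    lapply(config$configs, function(k)
      fit_hmm(series0, config = k, n_restarts = config$n_restarts,
              seed = config$seed + 100 + k))
  })
  best <- .stage("select", select_model(fits))

  refits <- .stage("pool", {
    lapply(seq_len(config$m), function(r) {
      sr <- make_series(r)
      fit_hmm(sr, config = best$config, n_restarts = 1,
              init = best$pars, seed = config$seed + 200 + r)
    })
  })
  pooled <- .stage("pool", pool_fits(refits))

  decoded <- .stage("decode", viterbi(attr(pooled, "pars"), series0))

  summaries <- .stage("summarize", {
    lapply(setNames(ids, ids), function(i) {
      tr <- tracks[tracks$realization == 0 & tracks$id == i, , drop = FALSE]
      tr <- filter_southern_ocean(tr, config$lat_cut)
      if (nrow(tr) == 0) return(NULL)
      dc <- decoded[decoded$id == i, , drop = FALSE]
      # step states back onto locations: last location inherits last step
      st <- rep(NA_character_, nrow(tr))
      idx <- match(as.numeric(dc$date), as.numeric(tr$date))
      st[idx[!is.na(idx)]] <- dc$state[!is.na(idx)]
      for (j in seq_along(st)) if (is.na(st[j]) && j > 1) st[j] <- st[j - 1]
      dep <- if (!is.null(deploy) && i %in% names(deploy)) deploy[[i]] else
        c(obs$lon[obs$id == i][1], obs$lat[obs$id == i][1])
      track_summary(tr, st, dep, areas, sex = unname(sex[i]))
    })
  })
  summaries <- summaries[!vapply(summaries, is.null, logical(1))]
  rows <- do.call(rbind, lapply(summaries, function(s)
    data.frame(id = s$id, sex = s$sex,
               max_displacement_km = s$max_displacement_km,
               total_distance_km = s$total_distance_km,
               n_locations = s$n_locations, pct_resident = s$pct_resident,
               stringsAsFactors = FALSE)))
  overall <- if (!is.null(rows) && nrow(rows) >= 2) overall_summary(rows)
             else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("argosmove")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, config_hash = .config_hash(config),
    n_tracks = length(ids), n_obs = nrow(obs),
    selected_config = best$config$id, m = config$m,
    timestamp = .fmt_utc(Sys.time()))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_track_csv(tracks, file.path(out_dir, "tracks.csv"))
    write_series_csv(decoded, file.path(out_dir, "decoded.csv"))
    write_pooled_csv(pooled, file.path(out_dir, "pooled_estimates.csv"))
    for (f in fits)
      write_fit_json(f, file.path(out_dir,
                                  sprintf("fit_config%d.json", f$config$id)))
    if (!is.null(rows))
      write.csv(rows, file.path(out_dir, "track_summaries.csv"),
                row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(ssm_fits = ssm_fits, tracks = tracks, series = series0, fits = fits,
       best = best, pooled = pooled, decoded = decoded,
       summaries = summaries, summary_rows = rows, overall = overall,
       manifest = manifest)
}
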