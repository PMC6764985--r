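# Aggregation of historical catch records onto a 1x1-degree grid.

#' Grid catch records into 1x1-degree cell totals
#'
#' Each record is assigned to the half-open cell `[lon, lon+1) x
#' [lat, lat+1)` containing it (floor convention) and counts are summed per
#' cell. Optional half-open longitude/latitude windows `[min, max)` and an
#' inclusive year range filter records first; the grid total equals the
#' count-sum of the records passing the filters, exactly.
#'
#' @param records Data frame with columns `lon`, `lat`, `count`, `year`.
#' @param lon_window,lat_window Optional length-2 half-open windows.
#' @param years Optional length-2 inclusive year range.
#' @param cell_deg Cell size in degrees (default 1).
#' @return Data frame with columns `cell_lon`, `cell_lat`, `count`, one row
#'   per non-empty cell, ordered by `cell_lon` then `cell_lat`.
#' @export
grid_catches <- function(records, lon_window = NULL, lat_window = NULL,
                         years = NULL, cell_deg = 1) {
  need <- c("lon", "lat", "count")
  if (!all(need %in% names(records)))
    stop("records need columns ", paste(need, collapse = ", "), call. = FALSE)
  if (any(records$lat < -90 | records$lat > 90))
    stop("latitude outside [-90, 90]", call. = FALSE)
  if (any(records$count < 0)) stop("counts must be >= 0", call. = FALSE)
  r <- records
  r$lon <- wrap_lon(r$lon)
  if (!is.null(lon_window))
    r <- r[r$lon >= lon_window[1] & r$lon < lon_window[2], , drop = FALSE]
  if (!is.null(lat_window))
    r <- r[r$lat >= lat_window[1] & r$lat < lat_window[2], , drop = FALSE]
  if (!is.null(years) && !is.null(r$year))
    r <- r[r$year >= years[1] & r$year <= years[2], , drop = FALSE]
  if (nrow(r) == 0)
    return(data.frame(cell_lon = numeric(0), cell_lat = numeric(0),
                      count = numeric(0)))
  cl <- floor(r$lon / cell_deg) * cell_deg
  ct <- floor(r$lat / cell_deg) * cell_deg
  agg <- aggregate(list(count = r$count),
                   by = list(cell_lon = cl, cell_lat = ct), FUN = sum)
  agg <- agg[order(agg$cell_lon, agg$cell_lat), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
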