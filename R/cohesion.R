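#' Read a GPS fix CSV file
#'
#' Expects columns `individual_id,timestamp,easting_m,northing_m` with
#' ISO-8601 UTC timestamps and projected planar coordinates in metres.
#'
#' @param path path to a GPS CSV file.
#' @return `data.frame` with columns `individual` (character), `timestamp`
#'   (`POSIXct`, UTC), `easting`, `northing` (numeric metres).
#' @export
load_gps <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                         stringsAsFactors = FALSE)
  required <- c("individual_id", "timestamp", "easting_m", "northing_m")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("GPS file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (anyNA(ts))
    stop("unparseable timestamp in GPS row(s): ",
         paste(which(is.na(ts)), collapse = ", "), call. = FALSE)
  data.frame(individual = raw$individual_id, timestamp = ts,
             easting = as.numeric(raw$easting_m),
             northing = as.numeric(raw$northing_m),
             stringsAsFactors = FALSE)
}

#' Write GPS fixes to CSV
#'
#' @param fixes GPS `data.frame` as returned by [load_gps()] or
#'   [simulate_gps()].
#' @param path output file path.
#' @export
write_gps <- function(fixes, path) {
  flat <- data.frame(
    individual_id = fixes$individual,
    timestamp = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    easting_m = fixes$easting,
    northing_m = fixes$northing,
    stringsAsFactors = FALSE
  )
  utils::write.csv(flat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subsample GPS fixes to a regular time grid
#'
#' High-frequency tracking data (1 Hz bursts) are reduced to one fix per
#' interval. Per individual, the first fix falling in each interval-length
#' bin (bins aligned to the UTC epoch) is kept and its timestamp is
#' snapped to the bin start, so that fixes of different individuals share
#' a common grid and can be paired exactly.
#'
#' @param fixes GPS `data.frame` (see [load_gps()]).
#' @param interval bin width in seconds (default 300, i.e. 5 minutes).
#' @return The subsampled, grid-aligned GPS `data.frame`, ordered by
#'   individual and time.
#' @export
subsample_fixes <- function(fixes, interval = 300L) {
  if (interval <= 0) stop("`interval` must be positive", call. = FALSE)
  dt <- data.table::as.data.table(fixes)
  dt[, bin := floor(as.numeric(timestamp) / interval) * interval]
  data.table::setorder(dt, individual, timestamp)
  dt <- dt[, .SD[1L], by = .(individual, bin)]
  dt[, timestamp := as.POSIXct(bin, origin = "1970-01-01", tz = "UTC")]
  dt[, bin := NULL]
  data.table::setorder(dt, individual, timestamp)
  out <- as.data.frame(dt)
  out[, c("individual", "timestamp", "easting", "northing")]
}

#' Daily dyadic GPS distances within detected social units
#'
#' Measures the spatial cohesion of each detected community from the
#' tracked subset of its members. For every community, every day and every
#' dyad of tracked members, fixes sharing the same time bin are paired and
#' their Euclidean distance (in projected metres) computed. Distances are
#' averaged within each day (over all dyads and matched bins), giving one
#' value per community-day; the per-window summary reports the mean and
#' the maximum of these daily values. Communities with fewer than two
#' tracked members yield no row; a community whose dyads never share a
#' time bin is omitted with a warning.
#'
#' Sex filtering is the caller's responsibility: pass the tagged (e.g.
#' male-only) subset via `gps_ids`.
#'
#' @param fixes subsampled, grid-aligned GPS fixes
#'   (see [subsample_fixes()]).
#' @param partition a [community_partition()], or a named character vector
#'   mapping individuals to unit labels (e.g. global unit IDs).
#' @param gps_ids optional character vector restricting which individuals'
#'   fixes are used (the tagged subset); default: all in `fixes`.
#' @param window_id label stored in the output (defaults to the
#'   partition's window).
#' @return `data.frame` with columns `unit`, `window_id`,
#'   `mean_daily_distance`, `max_daily_distance`, `n_dyads`, `n_days`.
#' @export
daily_pairwise_distances <- function(fixes, partition, gps_ids = NULL,
                                     window_id = NULL) {
  if (inherits(partition, "community_partition")) {
    window_id <- window_id %||% partition$window_id
    membership <- partition$membership
  } else {
    membership <- partition
    window_id <- window_id %||% "w"
  }
  stopifnot(is.character(membership), !is.null(names(membership)))
  dt <- data.table::as.data.table(fixes)
  if (!is.null(gps_ids)) dt <- dt[individual %in% gps_ids]
  dt <- dt[individual %in% names(membership)]
  empty <- data.frame(unit = character(), window_id = character(),
                      mean_daily_distance = numeric(),
                      max_daily_distance = numeric(),
                      n_dyads = integer(), n_days = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(dt) == 0L) return(empty)
  dt[, unit := membership[individual]]
  dt[, day := as.Date(timestamp, tz = "UTC")]
  # drop units with < 2 tracked members
  tracked <- dt[, .(k = data.table::uniqueN(individual)), by = unit]
  multi <- tracked[k >= 2L, unit]
  no_pairable <- setdiff(tracked$unit, multi)
  dt <- dt[unit %in% multi]
  if (nrow(dt) == 0L) return(empty)
  pairs <- merge(dt, dt, by = c("unit", "day", "timestamp"),
                 allow.cartesian = TRUE,
                 suffixes = c("_i", "_j"))[individual_i < individual_j]
  if (nrow(pairs) == 0L) {
    warning("no dyad shares a time bin in any unit; nothing to summarise")
    return(empty)
  }
  pairs[, dist := sqrt((easting_i - easting_j)^2 + (northing_i - northing_j)^2)]
  daily <- pairs[, .(daily_mean = mean(dist)), by = .(unit, day)]
  n_dyads_by_unit <- pairs[, .(n_dyads = data.table::uniqueN(
    paste(individual_i, individual_j))), by = unit]
  summ <- daily[, .(mean_daily_distance = mean(daily_mean),
                    max_daily_distance = max(daily_mean),
                    n_days = .N), by = unit]
  summ <- merge(summ, n_dyads_by_unit, by = "unit")
  skipped <- setdiff(multi, summ$unit)
  if (length(skipped))
    warning("unit(s) with tracked members but no shared time bins omitted: ",
            paste(skipped, collapse = ", "))
  out <- as.data.frame(summ)
  out$window_id <- as.character(window_id)
  out <- out[order(out$unit),
             c("unit", "window_id", "mean_daily_distance",
               "max_daily_distance", "n_dyads", "n_days")]
  rownames(out) <- NULL
  out
}
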