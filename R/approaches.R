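#' The full grid of unit-detection approaches
#'
#' Enumerates the ten approach configurations: the three time bases
#' crossed with bootstrapping, and — for the sliding bases — with
#' carryover membership detection (carryover is not applicable to the
#' single-window 8-month basis).
#'
#' @param seed seed applied to every configuration.
#' @param n_boot bootstrap replicates per window for the bootstrapped
#'   approaches.
#' @return Named list of [approach_config()] objects.
#' @export
approach_grid <- function(seed = 1L, n_boot = 100L) {
  grid <- expand.grid(basis = c("1-month", "2-month", "8-month"),
                      bootstrap = c(TRUE, FALSE),
                      carryover = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  grid <- grid[!(grid$basis == "8-month" & grid$carryover), ]
  configs <- lapply(seq_len(nrow(grid)), function(i)
    approach_config(grid$basis[i], grid$bootstrap[i], grid$carryover[i],
                    n_boot = n_boot, seed = seed))
  names(configs) <- vapply(configs, format, "")
  configs[order(names(configs))]
}

#' Run one unit-detection approach end to end
#'
#' Builds the focal windows for the configured basis, detects social units
#' in every window, optionally links them into persistent global unit
#' identities (with interpolation of single-window absences and Jaccard
#' stability), and summarises GPS cohesion of the detected units within
#' each window's focal period.
#'
#' Unit counting follows the carryover semantics: approaches with
#' carryover count distinct global unit identities across all windows
#' (the same unit re-detected in consecutive windows is counted once),
#' while approaches without carryover count every per-window community as
#' a separate detection.
#'
#' @param census census `data.frame` (filtered internally).
#' @param config an [approach_config()].
#' @param gps optional GPS fixes; subsampled internally to
#'   `gps_interval`.
#' @param gps_ids optional tagged subset used for cohesion (e.g. the
#'   GPS-tagged males); defaults to all individuals present in `gps`.
#' @param gps_interval subsampling interval in seconds for the GPS data.
#' @param study_start,study_end study period; defaults to the calendar
#'   months spanned by the census.
#' @return Object of class `approach_result`: list with `config`,
#'   `windows`, `partitions`, `dynamic` (or `NULL`), `stability` (or
#'   `NULL`), `cohesion`, `unit_count`, `individuals_included`,
#'   `size_distribution`.
#' @export
run_approach <- function(census, config, gps = NULL, gps_ids = NULL,
                         gps_interval = 300L,
                         study_start = NULL, study_end = NULL) {
  stopifnot(inherits(config, "approach_config"))
  census <- filter_census(census)
  if (nrow(census) == 0L) stop("no usable census records", call. = FALSE)
  study_start <- as.Date(study_start %||% first_of_month(min(census$date)))
  study_end <- as.Date(study_end %||% add_months(first_of_month(max(census$date)), 1L))
  windows <- make_windows(study_start, study_end, config$basis)

  partitions <- lapply(seq_len(nrow(windows)), function(i)
    detect_units(census, windows[i, ], config))
  names(partitions) <- windows$window_id

  dynamic <- NULL; stability <- NULL
  if (config$carryover) {
    dynamic <- interpolate_missing(link_communities(partitions))
    stability <- jaccard_stability(dynamic)
  }

  # per-window member sets labelled the way units are counted
  window_units <- lapply(seq_len(nrow(windows)), function(i) {
    wid <- windows$window_id[i]
    if (config$carryover) {
      a <- dynamic$assignments[dynamic$assignments$window_id == wid, ]
      split(a$individual, a$global_unit)
    } else {
      p <- partitions[[i]]
      if (length(p$membership) == 0L) return(list())
      split(names(p$membership), paste0(wid, "/", p$membership))
    }
  })
  names(window_units) <- windows$window_id

  cohesion <- NULL
  if (!is.null(gps) && nrow(gps)) {
    sub <- subsample_fixes(gps, gps_interval)
    if (is.null(gps_ids)) gps_ids <- unique(sub$individual)
    cohesion <- do.call(rbind, lapply(windows$window_id, function(wid) {
      units <- window_units[[wid]]
      if (length(units) == 0L) return(NULL)
      membership <- stats::setNames(
        rep(names(units), lengths(units)), unlist(units))
      w <- windows[windows$window_id == wid, ]
      focal_fixes <- sub[as.Date(sub$timestamp, tz = "UTC") >= w$focal_start &
                           as.Date(sub$timestamp, tz = "UTC") < w$focal_end, ]
      if (nrow(focal_fixes) == 0L) return(NULL)
      suppressWarnings(
        daily_pairwise_distances(focal_fixes, membership,
                                 gps_ids = gps_ids, window_id = wid))
    }))
  }

  sizes <- unlist(lapply(window_units, lengths), use.names = FALSE)
  unit_count <- if (config$carryover)
    length(unique(dynamic$assignments$global_unit))
  else
    sum(vapply(window_units, length, 0L))
  individuals_included <- length(unique(unlist(window_units, use.names = FALSE)))

  structure(
    list(config = config, windows = windows, partitions = partitions,
         dynamic = dynamic, stability = stability, cohesion = cohesion,
         unit_count = unit_count,
         individuals_included = individuals_included,
         size_distribution = as.integer(sizes %||% integer())),
    class = "approach_result"
  )
}

#' @export
print.approach_result <- function(x, ...) {
  cat(sprintf("<approach_result> %s: %d unit(s), %d individuals, %d window(s)\n",
              format(x$config), x$unit_count, x$individuals_included,
              nrow(x$windows)))
  if (length(x$size_distribution))
    cat("  unit sizes: ", paste(stats::quantile(x$size_distribution, c(0, .5, 1)),
                                collapse = " / "), " (min/median/max)\n", sep = "")
  invisible(x)
}

#' Tidy comparison tables across approaches
#'
#' Collects the results of several approaches into two long-format
#' tables: one row per detected unit per window (size, stability of the
#' following transition if available, cohesion), and one approach-level
#' roll-up (unit counts, individuals included, size quantiles). The
#' tables are schema-stable and suitable for fitting downstream
#' statistical models of how methodological choices shape inferred
#' social units.
#'
#' @param results list of [run_approach()] results.
#' @return List with `units` and `summary` data frames.
#' @export
compare_approaches <- function(results) {
  if (length(results) == 0L) stop("no results to compare", call. = FALSE)
  stopifnot(all(vapply(results, inherits, logical(1), "approach_result")))
  units <- do.call(rbind, lapply(results, function(r) {
    approach <- format(r$config)
    rows <- lapply(r$windows$window_id, function(wid) {
      members <- approach_window_units(r, wid)
      if (length(members) == 0L) return(NULL)
      out <- data.frame(approach = approach, window_id = wid,
                        unit = names(members),
                        size = lengths(members),
                        stringsAsFactors = FALSE)
      out$jaccard_next <- NA_real_
      if (!is.null(r$stability)) {
        s <- r$stability[r$stability$window_t == wid, ]
        out$jaccard_next <- s$jaccard[match(out$unit, s$global_unit)]
      }
      out$mean_daily_distance <- NA_real_
      out$max_daily_distance <- NA_real_
      if (!is.null(r$cohesion)) {
        cc <- r$cohesion[r$cohesion$window_id == wid, ]
        m <- match(out$unit, cc$unit)
        out$mean_daily_distance <- cc$mean_daily_distance[m]
        out$max_daily_distance <- cc$max_daily_distance[m]
      }
      out
    })
    do.call(rbind, rows)
  }))
  rownames(units) <- NULL
  summary <- do.call(rbind, lapply(results, function(r) {
    qs <- if (length(r$size_distribution))
      stats::quantile(r$size_distribution, c(0.25, 0.5, 0.75), names = FALSE)
    else rep(NA_real_, 3L)
    data.frame(approach = format(r$config),
               basis = r$config$basis,
               bootstrap = r$config$bootstrap,
               carryover = r$config$carryover,
               unit_count = r$unit_count,
               individuals_included = r$individuals_included,
               size_q25 = qs[1L], size_median = qs[2L], size_q75 = qs[3L],
               mean_jaccard = if (!is.null(r$stability) && nrow(r$stability))
                 mean(r$stability$jaccard) else NA_real_,
               mean_cohesion = if (!is.null(r$cohesion) && nrow(r$cohesion))
                 mean(r$cohesion$mean_daily_distance) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  list(units = units, summary = summary)
}

# member sets per unit for one window of an approach result, labelled
# with the counting identity used by the approach
approach_window_units <- function(r, wid) {
  if (r$config$carryover) {
    a <- r$dynamic$assignments[r$dynamic$assignments$window_id == wid, ]
    split(a$individual, a$global_unit)
  } else {
    p <- r$partitions[[wid]]
    if (length(p$membership) == 0L) return(list())
    split(names(p$membership), paste0(wid, "/", p$membership))
  }
}

#' Export dynamic membership tables to CSV
#'
#' Writes the membership, lineage and stability tables of a carryover
#' approach in plain CSV schemas.
#'
#' @param result an [run_approach()] result with carryover enabled.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_membership <- function(result, dir) {
  stopifnot(inherits(result, "approach_result"))
  if (is.null(result$dynamic))
    stop("result has no dynamic membership (carryover disabled)", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  a <- result$dynamic$assignments
  utils::write.csv(
    data.frame(window_id = a$window_id, individual_id = a$individual,
               community_id = ifelse(is.na(a$community_id), "", a$community_id),
               global_unit_id = a$global_unit,
               interpolated = as.integer(a$interpolated)),
    file.path(dir, "membership.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(result$dynamic$lineage, file.path(dir, "lineage.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(result$stability))
    utils::write.csv(
      data.frame(global_unit_id = result$stability$global_unit,
                 window_t = result$stability$window_t,
                 window_t1 = result$stability$window_t1,
                 jaccard = result$stability$jaccard),
      file.path(dir, "stability.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
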