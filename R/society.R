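#' Parameters of a synthetic multi-level society
#'
#' Collects and validates the parameters of the society generator. The
#' generator emulates a population organised into stable social units that
#' persist over months, occasionally fission into temporary subunits
#' (hours to weeks), and may merge into supergroups (days to months)
#' during designated date windows. Observation processes mimic field
#' conditions: a twice-daily census that detects each spatial cluster with
#' some probability and identifies only marked, non-overlooked members,
#' and GPS tags on a male subset delivering one fix per 5 minutes.
#'
#' @param n_units number of stable social units (>= 1).
#' @param unit_size_mean mean unit size (>= 2); sizes are Poisson-like
#'   around this mean with a floor of 2.
#' @param study_start,study_end study period as half-open `[start, end)`
#'   dates.
#' @param fission_rate per-unit, per-day probability that a whole unit
#'   fissions into a temporary subunit.
#' @param fission_duration_mean mean duration of a fission, in days;
#'   actual durations are geometric with this mean (support >= 1 day).
#' @param supergroup_windows list of `c(start, end)` date pairs during
#'   which supergroups may exist (half-open intervals).
#' @param supergroup_join_prob probability, per unit and per window, of
#'   joining that window's supergroup. Latent unit identity is retained
#'   while merged.
#' @param marked_fraction fraction of the population individually
#'   identifiable (default 0.90).
#' @param census_detect_prob per-cluster, per-session detection
#'   probability of the census.
#' @param individual_miss_prob probability that a marked member of a
#'   detected cluster is overlooked in one observation.
#' @param multiple_encounter_prob per-session probability that two
#'   detected clusters are recorded together as one 'multiple'
#'   observation (distinct sets encountered at the same place).
#' @param incomplete_prob probability that a record is flagged incomplete.
#' @param n_gps_males_per_unit number of GPS-tagged males per unit.
#' @param gps_interval seconds between GPS fixes (default 300).
#' @param gps_day_start,gps_day_end daily tracking hours (UTC, default
#'   06:00-18:00).
#' @param within_unit_spread isotropic scatter (metres, s.d. per axis) of
#'   individuals around their cluster centroid.
#' @param home_range_scale side (metres) of the square home range within
#'   which a unit's centroid performs a reflected random walk; 0 pins
#'   centroids to the unit's home-range centre.
#' @param unit_spacing distance (metres) between neighbouring units'
#'   home-range centres.
#' @param seed integer; all randomness of the simulator flows from it.
#' @return Object of class `society_params`.
#' @export
society_params <- function(n_units = 8L,
                           unit_size_mean = 20L,
                           study_start = as.Date("2020-09-01"),
                           study_end = as.Date("2021-05-01"),
                           fission_rate = 0.02,
                           fission_duration_mean = 7,
                           supergroup_windows = list(),
                           supergroup_join_prob = 0.5,
                           marked_fraction = 0.9,
                           census_detect_prob = 0.5,
                           individual_miss_prob = 0.2,
                           multiple_encounter_prob = 0.05,
                           incomplete_prob = 0.05,
                           n_gps_males_per_unit = 3L,
                           gps_interval = 300L,
                           gps_day_start = 6L,
                           gps_day_end = 18L,
                           within_unit_spread = 50,
                           home_range_scale = 1000,
                           unit_spacing = 5000,
                           seed = 1L) {
  n_units <- stop_if_not_count(n_units, "n_units", min = 1L)
  if (!is.numeric(unit_size_mean) || unit_size_mean < 2)
    stop("`unit_size_mean` must be >= 2", call. = FALSE)
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (study_start >= study_end) stop("study_start must precede study_end", call. = FALSE)
  for (p in c("fission_rate", "supergroup_join_prob", "marked_fraction",
              "census_detect_prob", "individual_miss_prob",
              "multiple_encounter_prob", "incomplete_prob"))
    stop_if_not_prob(get(p), p)
  if (fission_duration_mean < 1) stop("`fission_duration_mean` must be >= 1 day", call. = FALSE)
  supergroup_windows <- lapply(supergroup_windows, function(w) {
    w <- as.Date(w)
    if (length(w) != 2L || w[1L] >= w[2L])
      stop("each supergroup window must be c(start, end) with start < end", call. = FALSE)
    w
  })
  n_gps_males_per_unit <- stop_if_not_count(n_gps_males_per_unit, "n_gps_males_per_unit")
  gps_interval <- stop_if_not_count(gps_interval, "gps_interval", min = 1L)
  stopifnot(within_unit_spread >= 0, home_range_scale >= 0, unit_spacing >= 0,
            gps_day_start >= 0, gps_day_end <= 24, gps_day_start < gps_day_end)
  structure(
    list(n_units = n_units, unit_size_mean = unit_size_mean,
         study_start = study_start, study_end = study_end,
         fission_rate = fission_rate,
         fission_duration_mean = fission_duration_mean,
         supergroup_windows = supergroup_windows,
         supergroup_join_prob = supergroup_join_prob,
         marked_fraction = marked_fraction,
         census_detect_prob = census_detect_prob,
         individual_miss_prob = individual_miss_prob,
         multiple_encounter_prob = multiple_encounter_prob,
         incomplete_prob = incomplete_prob,
         n_gps_males_per_unit = n_gps_males_per_unit,
         gps_interval = gps_interval,
         gps_day_start = gps_day_start, gps_day_end = gps_day_end,
         within_unit_spread = within_unit_spread,
         home_range_scale = home_range_scale, unit_spacing = unit_spacing,
         seed = as.integer(seed)),
    class = "society_params"
  )
}

#' Simulate ground-truth membership dynamics
#'
#' Generates the latent daily state of the society: each individual's
#' permanent social unit and the spatial cluster it travels with on each
#' day. A unit's members normally share one cluster. Fission temporarily
#' moves a random 20-50% of a unit's members into their own cluster for a
#' geometric-distributed number of days; supergroup membership (drawn per
#' unit per supergroup window) puts whole units into a shared cluster
#' while their latent identities are retained. Units currently merged in a
#' supergroup do not fission. Every simulated day, the clusters partition
#' the population.
#'
#' @param params a [society_params()] object.
#' @return Object of class `society_truth`: a list with `individuals`
#'   (data.frame `individual`, `unit`, `marked`, `gps_male`),
#'   `membership` (data.frame `date`, `individual`, `unit`, `cluster`),
#'   `events` (data.frame `date`, `event`, `units`) and `params`.
#' @export
simulate_membership <- function(params) {
  stopifnot(inherits(params, "society_params"))
  with_seed(derive_seed(params$seed, "membership"), {
    sizes <- pmax(2L, stats::rpois(params$n_units, params$unit_size_mean))
    units <- sprintf("U%02d", seq_len(params$n_units))
    individuals <- data.frame(
      individual = sprintf("ID%03d", seq_len(sum(sizes))),
      unit = rep(units, sizes),
      stringsAsFactors = FALSE
    )
    individuals$marked <- stats::runif(nrow(individuals)) < params$marked_fraction
    individuals$gps_male <- FALSE
    for (u in units) {
      members <- which(individuals$unit == u)
      k <- min(params$n_gps_males_per_unit, length(members))
      if (k > 0L) individuals$gps_male[sample(members, k)] <- TRUE
    }

    dates <- seq(params$study_start, params$study_end - 1L, by = "1 day")
    # supergroup membership: redraw per window per unit
    sg_join <- lapply(seq_along(params$supergroup_windows), function(w)
      units[stats::runif(length(units)) < params$supergroup_join_prob])

    fissions <- list()  # active: unit, members, days_left, id
    next_fission <- 0L
    events <- list()
    day_rows <- vector("list", length(dates))
    unit_members <- split(individuals$individual, individuals$unit)

    for (d in seq_along(dates)) {
      today <- dates[d]
      # supergroup state for today
      sg_of <- stats::setNames(rep(NA_character_, length(units)), units)
      for (w in seq_along(params$supergroup_windows)) {
        win <- params$supergroup_windows[[w]]
        if (today >= win[1L] && today < win[2L] && length(sg_join[[w]]) >= 2L)
          sg_of[sg_join[[w]]] <- sprintf("SG%02d", w)
        if (today == win[1L] && length(sg_join[[w]]) >= 2L)
          events[[length(events) + 1L]] <- data.frame(
            date = today, event = "supergroup_form",
            units = paste(sg_join[[w]], collapse = ";"), stringsAsFactors = FALSE)
        if (today == win[2L] && length(sg_join[[w]]) >= 2L)
          events[[length(events) + 1L]] <- data.frame(
            date = today, event = "supergroup_disband",
            units = paste(sg_join[[w]], collapse = ";"), stringsAsFactors = FALSE)
      }
      # expire fissions
      if (length(fissions)) {
        ended <- vapply(fissions, function(f) f$days_left <= 0L, logical(1))
        for (f in fissions[ended])
          events[[length(events) + 1L]] <- data.frame(
            date = today, event = "fusion", units = f$unit, stringsAsFactors = FALSE)
        fissions <- fissions[!ended]
      }
      fissioned_units <- vapply(fissions, `[[`, "", "unit")
      # new fissions
      for (u in units) {
        if (u %in% fissioned_units || !is.na(sg_of[u])) next
        if (stats::runif(1) < params$fission_rate) {
          members <- unit_members[[u]]
          k <- max(1L, round(length(members) * stats::runif(1, 0.2, 0.5)))
          next_fission <- next_fission + 1L
          fissions[[length(fissions) + 1L]] <- list(
            unit = u, members = sample(members, k),
            days_left = 1L + stats::rgeom(1, 1 / params$fission_duration_mean),
            id = next_fission)
          events[[length(events) + 1L]] <- data.frame(
            date = today, event = "fission", units = u, stringsAsFactors = FALSE)
          fissioned_units <- c(fissioned_units, u)
        }
      }
      # cluster assignment for today
      cluster <- stats::setNames(
        ifelse(is.na(sg_of[individuals$unit]), individuals$unit,
               sg_of[individuals$unit]),
        individuals$individual)
      for (f in fissions)
        cluster[f$members] <- sprintf("%s.f%03d", f$unit, f$id)
      day_rows[[d]] <- data.frame(
        date = today, individual = individuals$individual,
        unit = individuals$unit, cluster = unname(cluster[individuals$individual]),
        stringsAsFactors = FALSE)
      # age fissions
      for (i in seq_along(fissions))
        fissions[[i]]$days_left <- fissions[[i]]$days_left - 1L
    }
    membership <- do.call(rbind, day_rows)
    events <- if (length(events)) do.call(rbind, events) else
      data.frame(date = as.Date(character()), event = character(),
                 units = character(), stringsAsFactors = FALSE)
    structure(list(individuals = individuals, membership = membership,
                   events = events, params = params),
              class = "society_truth")
  })
}

#' @export
print.society_truth <- function(x, ...) {
  cat(sprintf("<society_truth> %d individuals in %d units, %s to %s, %d events\n",
              nrow(x$individuals), length(unique(x$individuals$unit)),
              format(x$params$study_start), format(x$params$study_end),
              nrow(x$events)))
  invisible(x)
}

#' Simulate the census observation process
#'
#' Observes the latent society twice a day (AM and PM sessions). Each
#' spatial cluster is independently detected with `census_detect_prob`.
#' A detected cluster normally yields a 'single' record (one cohesive
#' set); with `multiple_encounter_prob`, two detected clusters of a
#' session are recorded together as one 'multiple' observation. A member
#' is identified only if it is marked and not overlooked
#' (`individual_miss_prob`); unmarked members are tallied in
#' `n_unmarked`. Records in which nobody was identified are not emitted.
#' A fraction `incomplete_prob` of records is flagged incomplete.
#'
#' @param truth a [simulate_membership()] result.
#' @param params the same [society_params()].
#' @return A census `data.frame` (see [census_table()]).
#' @export
simulate_census <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "society_truth"))
  marked <- stats::setNames(truth$individuals$marked, truth$individuals$individual)
  with_seed(derive_seed(params$seed, "census"), {
    rows <- list()
    obs_counter <- 0L
    by_day <- split(truth$membership, truth$membership$date)
    for (day_key in names(by_day)) {
      day <- by_day[[day_key]]
      clusters <- split(day$individual, day$cluster)
      for (session in c("AM", "PM")) {
        detected <- names(clusters)[stats::runif(length(clusters)) < params$census_detect_prob]
        if (length(detected) == 0L) next
        # occasionally two detected clusters are encountered together and
        # recorded as one 'multiple' observation
        groups <- as.list(detected)
        cohesions <- rep("single", length(groups))
        while (length(groups) >= 2L &&
               stats::runif(1) < params$multiple_encounter_prob) {
          pick <- sample(length(groups), 2L)
          merged <- c(groups[[pick[1L]]], groups[[pick[2L]]])
          groups[[pick[1L]]] <- merged
          cohesions[pick[1L]] <- "multiple"
          groups <- groups[-pick[2L]]
          cohesions <- cohesions[-pick[2L]]
        }
        for (gi in seq_along(groups)) {
          members <- unlist(clusters[groups[[gi]]], use.names = FALSE)
          is_marked <- marked[members]
          identified <- members[is_marked &
                                  stats::runif(length(members)) >= params$individual_miss_prob]
          if (length(identified) == 0L) next
          obs_counter <- obs_counter + 1L
          rows[[obs_counter]] <- data.frame(
            date = as.Date(day_key), session = session,
            observation_id = sprintf("obs%06d", obs_counter),
            cohesion = cohesions[gi],
            n_unmarked = sum(!is_marked),
            complete = stats::runif(1) >= params$incomplete_prob,
            stringsAsFactors = FALSE)
          rows[[obs_counter]]$individual_ids <- list(sort(identified))
        }
      }
    }
    if (length(rows) == 0L)
      return(census_table(as.Date(character()), character(), character(),
                          character(), list(), integer(), logical()))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    validate_census(out)
    out
  })
}

# reflected coordinate-wise walk confined to [-half, half]
reflect_into <- function(x, half) {
  if (half <= 0) return(rep(0, length(x)))
  period <- 4 * half
  y <- (x + half) %% period
  ifelse(y <= 2 * half, y - half, 3 * half - y)
}

#' Simulate GPS tracking of the tagged males
#'
#' Each GPS-tagged male produces one fix per `gps_interval` during daily
#' tracking hours, aligned to a common UTC grid. A fix is the male's
#' current cluster centroid plus isotropic Gaussian scatter of scale
#' `within_unit_spread`. Cluster centroids follow a reflected random walk
#' (daily step plus a smaller within-day step) inside a square of side
#' `home_range_scale` around the cluster's home-range centre: the unit's
#' centre, the mean of the member units' centres for a supergroup, or the
#' parent unit's centre plus a persistent offset for a fission subunit.
#' With `home_range_scale = 0` centroids are pinned to those centres.
#'
#' @param truth a [simulate_membership()] result.
#' @param params the same [society_params()].
#' @return `data.frame` with columns `individual`, `timestamp` (UTC),
#'   `easting`, `northing`.
#' @export
simulate_gps <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "society_truth"))
  males <- truth$individuals$individual[truth$individuals$gps_male]
  if (length(males) == 0L)
    return(data.frame(individual = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC"),
                      easting = numeric(), northing = numeric(),
                      stringsAsFactors = FALSE))
  units <- sort(unique(truth$individuals$unit))
  n_side <- ceiling(sqrt(length(units)))
  centers <- cbind(
    easting = ((seq_along(units) - 1L) %% n_side) * params$unit_spacing,
    northing = ((seq_along(units) - 1L) %/% n_side) * params$unit_spacing)
  rownames(centers) <- units
  half <- params$home_range_scale / 2
  day_step <- params$home_range_scale / 10
  fix_step <- params$home_range_scale / 50

  secs <- seq(params$gps_day_start * 3600L,
              params$gps_day_end * 3600L - params$gps_interval,
              by = params$gps_interval)
  n_fix <- length(secs)
  memb <- truth$membership[truth$membership$individual %in% males, ]
  with_seed(derive_seed(params$seed, "gps"), {
    # persistent random-walk offset per unit, advanced daily
    unit_offset <- matrix(0, length(units), 2L, dimnames = list(units, NULL))
    unit_walk <- matrix(0, length(units), 2L, dimnames = list(units, NULL))
    out <- list()
    by_day <- split(memb, memb$date)
    for (day_key in sort(names(by_day))) {
      day <- by_day[[day_key]]
      day_origin <- as.numeric(as.POSIXct(paste0(day_key, " 00:00:00"), tz = "UTC"))
      if (half > 0) {
        unit_walk <- unit_walk + matrix(stats::rnorm(2L * length(units), 0, day_step),
                                        ncol = 2L)
        unit_offset <- matrix(reflect_into(as.vector(unit_walk), half),
                              ncol = 2L, dimnames = dimnames(unit_walk))
      }
      clusters <- split(day$individual, day$cluster)
      for (cl in names(clusters)) {
        cluster_units <- unique(day$unit[day$cluster == cl])
        base <- colMeans(centers[cluster_units, , drop = FALSE]) +
          colMeans(unit_offset[cluster_units, , drop = FALSE])
        if (grepl(".f", cl, fixed = TRUE)) {
          # persistent offset of the fission subunit from its parent path
          off_seed <- derive_seed(params$seed, "fission-offset", cl)
          base <- base + with_seed(off_seed, stats::rnorm(2L, 0, max(half, 1) / 2))
        }
        if (half > 0) {
          steps <- matrix(stats::rnorm(2L * n_fix, 0, fix_step), ncol = 2L)
          path <- matrix(reflect_into(as.vector(apply(steps, 2L, cumsum)), half),
                         ncol = 2L)
        } else {
          path <- matrix(0, n_fix, 2L)
        }
        for (ind in clusters[[cl]]) {
          scatter <- matrix(stats::rnorm(2L * n_fix, 0, params$within_unit_spread),
                            ncol = 2L)
          out[[length(out) + 1L]] <- data.frame(
            individual = ind,
            timestamp = as.POSIXct(day_origin + secs,
                                   origin = "1970-01-01", tz = "UTC"),
            easting = base[1L] + path[, 1L] + scatter[, 1L],
            northing = base[2L] + path[, 2L] + scatter[, 2L],
            stringsAsFactors = FALSE)
        }
      }
    }
    fixes <- do.call(rbind, out)
    fixes <- fixes[order(fixes$individual, fixes$timestamp), ]
    rownames(fixes) <- NULL
    fixes
  })
}

#' Simulate a complete synthetic society
#'
#' Convenience wrapper running [simulate_membership()],
#' [simulate_census()] and [simulate_gps()] from one parameter set.
#'
#' @param params a [society_params()] object.
#' @return List with elements `truth`, `census`, `gps`.
#' @examples
#' sim <- simulate_society(society_params(
#'   n_units = 3, unit_size_mean = 6,
#'   study_start = "2020-09-01", study_end = "2020-11-01", seed = 42))
#' head(sim$census)
#' @export
simulate_society <- function(params = society_params()) {
  truth <- simulate_membership(params)
  list(truth = truth,
       census = simulate_census(truth, params),
       gps = simulate_gps(truth, params))
}

#' Write a simulated society to CSV files
#'
#' Writes `census.csv` and `gps.csv` in the schemas read by
#' [load_census()] and [load_gps()], plus `truth.csv`
#' (`date,individual_id,true_unit_id,cluster_id`) and `events.csv`.
#'
#' @param sim a [simulate_society()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_society <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_census(sim$census, file.path(dir, "census.csv"))
  write_gps(sim$gps, file.path(dir, "gps.csv"))
  truth_flat <- data.frame(
    date = format(sim$truth$membership$date, "%Y-%m-%d"),
    individual_id = sim$truth$membership$individual,
    true_unit_id = sim$truth$membership$unit,
    cluster_id = sim$truth$membership$cluster,
    stringsAsFactors = FALSE
  )
  utils::write.csv(truth_flat, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$truth$events, file.path(dir, "events.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
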