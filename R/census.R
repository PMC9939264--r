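#' Construct a census observation table
#'
#' A census table holds one row per observed aggregation: a cluster of
#' individuals encountered during a morning (`AM`) or evening (`PM`) census
#' session. Each row records whether the observed animals behaved as one
#' cohesive set (`"single"`) or as several distinct sets seen together
#' (`"multiple"`), the identities of the individually marked animals
#' present, the number of unmarked animals, and whether the record is
#' complete.
#'
#' @param date `Date` vector of observation dates.
#' @param session character, `"AM"` or `"PM"`.
#' @param observation_id unique identifier per observed aggregation.
#' @param cohesion character, `"single"` or `"multiple"`.
#' @param individual_ids list of character vectors; identities of the marked
#'   individuals in each aggregation. IDs are opaque, case-sensitive tokens.
#' @param n_unmarked non-negative integer count of unmarked animals present.
#' @param complete logical; `FALSE` flags records with missing information.
#'
#' @return A `data.frame` with one row per aggregation and a list column
#'   `individual_ids`.
#' @seealso [load_census()], [filter_census()]
#' @export
census_table <- function(date, session, observation_id, cohesion,
                         individual_ids, n_unmarked = 0L, complete = TRUE) {
  n <- length(observation_id)
  date <- as.Date(date)
  if (!is.list(individual_ids)) individual_ids <- list(individual_ids)
  individual_ids <- lapply(individual_ids, as.character)
  out <- data.frame(
    date = rep_len(date, n),
    session = rep_len(as.character(session), n),
    observation_id = as.character(observation_id),
    cohesion = rep_len(as.character(cohesion), n),
    n_unmarked = rep_len(as.integer(n_unmarked), n),
    complete = rep_len(as.logical(complete), n),
    stringsAsFactors = FALSE
  )
  out$individual_ids <- rep_len(individual_ids, n)
  validate_census(out)
  out
}

validate_census <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("date", "session", "observation_id", "cohesion",
                "individual_ids", "n_unmarked", "complete")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("census table is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyNA(records$date)) stop("census dates contain NA", call. = FALSE)
  bad <- !records$cohesion %in% c("single", "multiple")
  if (any(bad))
    stop("invalid cohesion label(s): ", paste(unique(records$cohesion[bad]), collapse = ", "),
         call. = FALSE)
  bad <- !records$session %in% c("AM", "PM")
  if (any(bad))
    stop("invalid session label(s): ", paste(unique(records$session[bad]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(records$observation_id))
    stop("duplicate observation_id: ",
         paste(unique(records$observation_id[duplicated(records$observation_id)]),
               collapse = ", "), call. = FALSE)
  if (any(records$n_unmarked < 0)) stop("n_unmarked must be >= 0", call. = FALSE)
  invisible(records)
}

#' Read a census CSV file
#'
#' Expects the columns `date,session,observation_id,cohesion,individual_ids,
#' n_unmarked,complete` with ISO-8601 dates, `AM`/`PM` sessions,
#' `single`/`multiple` cohesion labels, semicolon-delimited individual IDs
#' and `0`/`1` completeness flags. Lines starting with `#` are ignored.
#' Malformed rows are reported with their row number; duplicated
#' `observation_id` values are an error.
#'
#' @param path path to a census CSV file.
#' @return A census `data.frame` (see [census_table()]).
#' @export
load_census <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                         stringsAsFactors = FALSE)
  required <- c("date", "session", "observation_id", "cohesion",
                "individual_ids", "n_unmarked", "complete")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("census file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0L) {
    out <- census_table(as.Date(character()), character(), character(),
                        character(), list(), integer(), logical())
    return(out)
  }
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(date))
    stop("unparseable date in census row(s): ",
         paste(which(is.na(date)), collapse = ", "), call. = FALSE)
  n_unmarked <- suppressWarnings(as.integer(raw$n_unmarked))
  if (anyNA(n_unmarked))
    stop("unparseable n_unmarked in census row(s): ",
         paste(which(is.na(n_unmarked)), collapse = ", "), call. = FALSE)
  if (!all(raw$complete %in% c("0", "1")))
    stop("complete flag must be 0 or 1; offending row(s): ",
         paste(which(!raw$complete %in% c("0", "1")), collapse = ", "),
         call. = FALSE)
  ids <- strsplit(raw$individual_ids, ";", fixed = TRUE)
  ids <- lapply(ids, function(x) x[nzchar(x)])
  census_table(date, raw$session, raw$observation_id, raw$cohesion,
               ids, n_unmarked, raw$complete == "1")
}

#' Write a census table to CSV
#'
#' Inverse of [load_census()]; individual IDs are joined with semicolons and
#' the completeness flag is written as 0/1.
#'
#' @param records census `data.frame`.
#' @param path output file path.
#' @export
write_census <- function(records, path) {
  validate_census(records)
  flat <- data.frame(
    date = format(records$date, "%Y-%m-%d"),
    session = records$session,
    observation_id = records$observation_id,
    cohesion = records$cohesion,
    individual_ids = vapply(records$individual_ids, paste, "", collapse = ";"),
    n_unmarked = records$n_unmarked,
    complete = as.integer(records$complete),
    stringsAsFactors = FALSE
  )
  utils::write.csv(flat, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter census records for network construction
#'
#' Keeps exactly the records usable for association networks: observations
#' of a cohesive set of individuals (`cohesion == "single"`) that are
#' complete. 'Multiple' observations (several distinct sets seen together)
#' and incomplete records are removed because they do not identify a single
#' cohesive aggregation. The operation preserves order and is idempotent.
#'
#' @param records census `data.frame`.
#' @return The subset of `records` with `cohesion == "single"` and
#'   `complete == TRUE`.
#' @export
filter_census <- function(records) {
  validate_census(records)
  keep <- records$cohesion == "single" & records$complete
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Individuals with enough observations in a focal window
#'
#' Returns the IDs observed in at least `min_obs` census records whose date
#' falls inside the window's sampling interval. Individuals seen fewer
#' times are dropped because community assignment is unreliable at very low
#' sighting counts. The default `min_obs = 3` removes individuals observed
#' two or fewer times.
#'
#' @param records filtered census `data.frame` (see [filter_census()]).
#' @param window a single-row window as produced by [make_windows()], or
#'   `NULL` to count over all records.
#' @param min_obs minimum number of records an ID must appear in.
#' @return Character vector of retained IDs (sorted).
#' @export
retained_individuals <- function(records, window = NULL, min_obs = 3L) {
  min_obs <- stop_if_not_count(min_obs, "min_obs", min = 1L)
  sub <- window_records(records, window)
  counts <- table(unlist(sub$individual_ids))
  sort(names(counts)[counts >= min_obs])
}

# records whose date lies in the window's half-open sampling interval
window_records <- function(records, window, interval = c("sampling", "focal")) {
  if (is.null(window)) return(records)
  interval <- match.arg(interval)
  lo <- if (interval == "sampling") window$sampling_start else window$focal_start
  hi <- if (interval == "sampling") window$sampling_end else window$focal_end
  out <- records[records$date >= lo & records$date < hi, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build focal windows over a study period
#'
#' Partitions the study interval into focal windows according to the chosen
#' time basis. Dates are half-open intervals `[start, end)` aligned to
#' calendar months:
#'
#' * `"1-month"`: one window per interior calendar month (the first and
#'   last study months only ever serve as sampling context). Each window
#'   samples census data from one month before through one month after its
#'   focal month (a 3-month sliding window).
#' * `"2-month"`: consecutive, non-overlapping 2-month focal blocks over
#'   the interior months, again sampling one extra month on each side
#'   (4 months in total).
#' * `"8-month"`: a single static window whose focal and sampling interval
#'   is the entire study period.
#'
#' @param study_start,study_end `Date`s delimiting the study period
#'   (half-open; both are floored to the first of their month).
#' @param basis `"1-month"`, `"2-month"` or `"8-month"`.
#' @return A `data.frame` with columns `window_id`, `focal_start`,
#'   `focal_end`, `sampling_start`, `sampling_end`, ordered by `focal_start`.
#' @examples
#' make_windows(as.Date("2020-09-01"), as.Date("2021-05-01"), "1-month")
#' @export
make_windows <- function(study_start, study_end,
                         basis = c("1-month", "2-month", "8-month")) {
  basis <- match.arg(basis)
  study_start <- first_of_month(as.Date(study_start))
  study_end <- as.Date(study_end)
  if (study_start >= study_end) stop("study_start must precede study_end", call. = FALSE)
  months <- seq(study_start, study_end - 1, by = "1 month")
  months <- months[months < study_end]
  if (basis == "8-month") {
    return(data.frame(
      window_id = "full",
      focal_start = study_start, focal_end = study_end,
      sampling_start = study_start, sampling_end = study_end,
      stringsAsFactors = FALSE
    ))
  }
  interior <- months[-c(1L, length(months))]
  block <- if (basis == "1-month") 1L else 2L
  if (length(months) < block + 2L)
    stop(sprintf("study interval too short for the %s basis", basis), call. = FALSE)
  if (basis == "2-month") interior <- interior[seq_len(length(interior) %/% 2L * 2L)]
  starts <- interior[seq(1L, length(interior), by = block)]
  focal_end <- as.Date(vapply(starts, function(s) as.character(add_months(s, block)), ""))
  out <- data.frame(
    window_id = format(starts, "%Y-%m"),
    focal_start = starts,
    focal_end = focal_end,
    sampling_start = as.Date(vapply(starts, function(s) as.character(add_months(s, -1L)), "")),
    sampling_end = as.Date(vapply(focal_end, function(e) as.character(add_months(e, 1L)), "")),
    stringsAsFactors = FALSE
  )
  out[order(out$focal_start), , drop = FALSE]
}

#' Configuration of one unit-detection approach
#'
#' One cell of the approach grid: a window basis crossed with whether the
#' bootstrap meta-network procedure is used, and whether per-window
#' communities are linked into persistent unit identities (carryover).
#' Carryover is not applicable to the 8-month basis, which has a single
#' window.
#'
#' @param basis time basis; `"1-month"`, `"2-month"` or `"8-month"`.
#' @param bootstrap logical; detect on a bootstrapped co-membership
#'   meta-network rather than directly on the observed network.
#' @param carryover logical; link community identities across windows.
#' @param n_boot number of bootstrap replicates (default 100).
#' @param edge_threshold association-index threshold below which edges are
#'   set to zero (default 0.5).
#' @param min_obs minimum number of sightings for an individual to be
#'   retained in a window (default 3).
#' @param walktrap_steps random-walk length for the walktrap algorithm.
#' @param seed integer seed from which all randomness in the approach flows.
#' @return An object of class `approach_config`.
#' @export
approach_config <- function(basis = c("1-month", "2-month", "8-month"),
                            bootstrap = FALSE, carryover = FALSE,
                            n_boot = 100L, edge_threshold = 0.5,
                            min_obs = 3L, walktrap_steps = 4L, seed = 1L) {
  basis <- match.arg(basis)
  stopifnot(is.logical(bootstrap), length(bootstrap) == 1L,
            is.logical(carryover), length(carryover) == 1L)
  if (basis == "8-month" && carryover)
    stop("carryover membership is not applicable to the 8-month basis ",
         "(it has a single sampling period)", call. = FALSE)
  n_boot <- stop_if_not_count(n_boot, "n_boot", min = 1L)
  stop_if_not_prob(edge_threshold, "edge_threshold")
  min_obs <- stop_if_not_count(min_obs, "min_obs", min = 1L)
  walktrap_steps <- stop_if_not_count(walktrap_steps, "walktrap_steps", min = 1L)
  structure(
    list(basis = basis, bootstrap = bootstrap, carryover = carryover,
         n_boot = n_boot, edge_threshold = edge_threshold, min_obs = min_obs,
         walktrap_steps = walktrap_steps, seed = as.integer(seed)),
    class = "approach_config"
  )
}

#' @export
format.approach_config <- function(x, ...) {
  paste0(x$basis,
         if (x$bootstrap) "+boot" else "",
         if (x$carryover) "+carry" else "")
}

#' @export
print.approach_config <- function(x, ...) {
  cat("<approach_config> ", format(x), "\n", sep = "")
  cat(sprintf("  n_boot=%d edge_threshold=%g min_obs=%d walktrap_steps=%d seed=%d\n",
              x$n_boot, x$edge_threshold, x$min_obs, x$walktrap_steps, x$seed))
  invisible(x)
}
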