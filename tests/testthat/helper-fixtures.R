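# Programmatic fixtures shared across test files.

# Quick census table from a list of ID vectors.
quick_census <- function(id_sets, date = as.Date("2021-01-01"),
                         cohesion = "single", complete = TRUE,
                         session = "AM") {
  n <- length(id_sets)
  census_table(
    date = rep_len(date, n),
    session = rep_len(session, n),
    observation_id = sprintf("o%03d", seq_len(n)),
    cohesion = rep_len(cohesion, n),
    individual_ids = id_sets,
    n_unmarked = 0L,
    complete = rep_len(complete, n)
  )
}

# A window covering one calendar month, sampling == focal.
month_window <- function(start = "2021-01-01", months = 1L, id = "w") {
  s <- as.Date(start)
  e <- seq(s, by = paste(months, "months"), length.out = 2L)[2L]
  data.frame(window_id = id, focal_start = s, focal_end = e,
             sampling_start = s, sampling_end = e, stringsAsFactors = FALSE)
}

# Planted two-unit supergroup fixture: units A (8 members) and B (7)
# observed mostly in shared aggregations with at most 8 identified
# individuals per record, plus six well-sampled context units. The
# meta-network walktrap lumps A and B into one 15-member community that
# exceeds the observed-size cap (M = 8), so the oversize check must
# split it back into the two true units.
oversize_fixture <- function(seed = 5L, n_unit_records = 3L, n_shared = 14L) {
  set.seed(seed)
  A <- sprintf("a%d", 1:8)
  B <- sprintf("b%d", 1:7)
  ctx <- lapply(1:6, function(u) sprintf("c%d_%d", u, 1:6))
  ids <- list()
  for (u in 1:6) for (r in 1:10) ids[[length(ids) + 1L]] <- ctx[[u]]
  for (r in seq_len(n_unit_records)) ids[[length(ids) + 1L]] <- A
  for (r in seq_len(n_unit_records)) ids[[length(ids) + 1L]] <- B
  for (r in seq_len(n_shared)) ids[[length(ids) + 1L]] <- sample(c(A, B), 8L)
  records <- quick_census(ids, date = as.Date("2021-01-01") + seq_along(ids) %% 28)
  list(records = records, unit_a = A, unit_b = B)
}

# Deterministic full-observation society: every cluster detected, every
# member marked and identified, no fission, no record-quality noise.
perfect_params <- function(n_units = 2L, unit_size_mean = 6L,
                           study_start = "2020-09-01",
                           study_end = "2020-12-01", seed = 1L, ...) {
  society_params(
    n_units = n_units, unit_size_mean = unit_size_mean,
    study_start = study_start, study_end = study_end,
    fission_rate = 0, marked_fraction = 1,
    census_detect_prob = 1, individual_miss_prob = 0,
    multiple_encounter_prob = 0, incomplete_prob = 0,
    seed = seed, ...
  )
}
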