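#' Community partition of one focal window
#'
#' @param window_id window identifier token.
#' @param membership named character vector mapping each retained
#'   individual to a community label.
#' @param method_tag short description of the detection configuration.
#' @return Object of class `community_partition`.
#' @export
community_partition <- function(window_id, membership, method_tag = "") {
  stopifnot(is.character(membership) || length(membership) == 0L,
            !is.null(names(membership)) || length(membership) == 0L)
  if (anyDuplicated(names(membership)))
    stop("an individual appears twice in the partition", call. = FALSE)
  structure(
    list(window_id = as.character(window_id),
         membership = membership,
         method_tag = as.character(method_tag)),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  sizes <- table(x$membership)
  cat(sprintf("<community_partition> window %s [%s]: %d individuals in %d communities\n",
              x$window_id, x$method_tag, length(x$membership), length(sizes)))
  if (length(sizes)) print(sort(as.integer(sizes), decreasing = TRUE))
  invisible(x)
}

# relabel communities deterministically: C01, C02, ... in order of each
# community's first individual (by sorted individual ID)
canonical_labels <- function(membership) {
  if (length(membership) == 0L) return(membership)
  membership <- membership[order(names(membership))]
  first_seen <- membership[!duplicated(membership)]
  new <- sprintf("C%02d", seq_along(first_seen))
  names(new) <- first_seen
  out <- new[membership]
  names(out) <- names(membership)
  out
}

#' Walktrap community detection on an association network
#'
#' Runs the walktrap algorithm (random-walk distance agglomeration) on the
#' positive edges of a weighted network and cuts the merge dendrogram at
#' the level of maximal modularity. Individuals with no positive edges
#' become singleton communities. The result is deterministic for a fixed
#' input and number of steps.
#'
#' @param net symmetric non-negative weight matrix with individual IDs as
#'   dimnames (an SRI network or a co-membership meta-network).
#' @param steps random-walk length (default 4, the algorithm's conventional
#'   default).
#' @param window_id,method_tag metadata stored on the partition.
#' @return A [community_partition()].
#' @export
walktrap_communities <- function(net, steps = 4L, window_id = "w", method_tag = "walktrap") {
  if (NCOL(net) == 0L)
    return(community_partition(window_id, character(), method_tag))
  ids <- colnames(net)
  if (is.null(ids)) stop("network must carry individual IDs as dimnames", call. = FALSE)
  w <- unclass(net)
  attributes(w) <- attributes(w)["dim"]
  dimnames(w) <- list(ids, ids)
  diag(w) <- 0
  if (any(w < 0)) stop("negative edge weights are not allowed", call. = FALSE)
  if (all(w == 0)) {
    membership <- stats::setNames(as.character(seq_along(ids)), ids)
    return(community_partition(window_id, canonical_labels(membership), method_tag))
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE)
  wt <- igraph::cluster_walktrap(g, steps = steps)
  membership <- stats::setNames(as.character(igraph::membership(wt)), ids)
  community_partition(window_id, canonical_labels(membership), method_tag)
}

#' Bootstrapped co-membership meta-network
#'
#' Quantifies the uncertainty of community assignment by resampling the
#' observed aggregations with replacement. Each replicate rebuilds the
#' group-by-individual matrix, the SRI network and its thresholded form,
#' and re-runs walktrap. The meta-network entry for a pair of individuals
#' is the proportion of replicates in which both were present (appeared in
#' at least one resampled aggregation) and were assigned to the same
#' community. Pairs never jointly present get 0; the diagonal is 1.
#'
#' @param records filtered census records for one window.
#' @param ids retained individual IDs.
#' @param config an [approach_config()]; uses `n_boot`, `edge_threshold`
#'   and `walktrap_steps`.
#' @param seed integer seed for the resampling (defaults to `config$seed`).
#' @param resample set to `FALSE` to skip resampling and score the observed
#'   network itself (diagnostic/testing hook).
#' @return Symmetric matrix of co-membership probabilities in `[0, 1]`
#'   with unit diagonal.
#' @export
bootstrap_metanetwork <- function(records, ids, config, seed = config$seed,
                                  resample = TRUE) {
  stopifnot(inherits(config, "approach_config"))
  ids <- sort(unique(as.character(ids)))
  gbi <- build_gbi(records, ids)
  n_row <- nrow(gbi)
  if (n_row == 0L) stop("no usable census rows for the meta-network", call. = FALSE)
  k <- length(ids)
  co <- matrix(0L, k, k, dimnames = list(ids, ids))
  both <- matrix(0L, k, k, dimnames = list(ids, ids))
  n_rep <- if (resample) config$n_boot else 1L
  with_seed(seed, {
    for (b in seq_len(n_rep)) {
      rows <- if (resample) sample.int(n_row, n_row, replace = TRUE) else seq_len(n_row)
      x <- gbi[rows, , drop = FALSE]
      present <- colSums(x) > 0L
      if (sum(present) == 0L) next
      pres_idx <- which(present)
      pvec <- as.integer(present)
      both <- both + outer(pvec, pvec)
      if (sum(present) == 1L) { co[pres_idx, pres_idx] <- co[pres_idx, pres_idx] + 1L; next }
      xb <- x[, present, drop = FALSE]
      xb <- xb[rowSums(xb) > 0L, , drop = FALSE]
      sri <- simple_ratio_index(xb)
      thr <- threshold_network(sri, config$edge_threshold)
      part <- walktrap_communities(thr, steps = config$walktrap_steps)
      memb <- part$membership[colnames(xb)]
      same <- outer(memb, memb, "==")
      storage.mode(same) <- "integer"
      co[pres_idx, pres_idx] <- co[pres_idx, pres_idx] + same
    }
  })
  probs <- ifelse(both > 0L, co / both, 0)
  diag(probs) <- 1
  dimnames(probs) <- list(ids, ids)
  probs
}

# largest number of identified individuals in any single cohesive
# aggregation of the window; the cap used by the oversize check
max_observed_group_size <- function(records) {
  singles <- records[records$cohesion == "single", , drop = FALSE]
  if (nrow(singles) == 0L) return(0L)
  max(lengths(singles$individual_ids))
}

#' Recursively split communities larger than any observed aggregation
#'
#' In sparse data, community detection tends to return whole connected
#' components, which can lump several social units observed together (for
#' example in a supergroup) into one community. This check compares each
#' detected community against the largest number of identified individuals
#' seen in any single cohesive aggregation of the window (`M`). Any
#' community larger than `M` cannot have been observed as one aggregation,
#' so the full bootstrap + walktrap procedure is re-run on the census
#' records restricted to that community's members, recursively, until no
#' community exceeds `M`, a re-run fails to split (fixed point), or the
#' recursion depth is exhausted.
#'
#' @param partition a [community_partition()] from the meta-network path.
#' @param records the window's filtered census records.
#' @param config the [approach_config()] in use.
#' @param depth maximum recursion depth (default 10); exceeding it keeps
#'   the current partition with a warning.
#' @param seed seed from which each community's re-run derives its own
#'   stream.
#' @return A [community_partition()] in which no community exceeds the
#'   observed-size cap unless a re-run could not split it.
#' @export
oversize_split <- function(partition, records, config, depth = 10L,
                           seed = config$seed) {
  m_cap <- max_observed_group_size(records)
  if (m_cap == 0L) return(partition)
  membership <- partition$membership
  sizes <- table(membership)
  oversized <- names(sizes)[sizes > m_cap]
  if (length(oversized) == 0L) return(partition)
  if (depth <= 0L) {
    warning("oversize split: recursion depth exhausted; accepting current partition")
    return(partition)
  }
  for (lab in oversized) {
    members <- names(membership)[membership == lab]
    sub_records <- restrict_records(records, members)
    sub_seed <- derive_seed(seed, partition$window_id, lab)
    sub_meta <- bootstrap_metanetwork(sub_records, members, config, seed = sub_seed)
    sub_part <- walktrap_communities(sub_meta, steps = config$walktrap_steps,
                                     window_id = partition$window_id,
                                     method_tag = partition$method_tag)
    if (length(unique(sub_part$membership)) <= 1L) next  # fixed point: no split
    sub_part <- oversize_split(sub_part, sub_records, config,
                               depth = depth - 1L, seed = sub_seed)
    relabel <- intersect(members, names(sub_part$membership))
    membership[relabel] <- paste0(lab, ".", sub_part$membership[relabel])
  }
  community_partition(partition$window_id, canonical_labels(membership),
                      partition$method_tag)
}

# restrict census records to a set of individuals, dropping rows that no
# longer identify anyone
restrict_records <- function(records, members) {
  kept_ids <- lapply(records$individual_ids, intersect, y = members)
  keep <- lengths(kept_ids) > 0L
  out <- records[keep, , drop = FALSE]
  out$individual_ids <- kept_ids[keep]
  rownames(out) <- NULL
  out
}

#' Detect social units in one focal window
#'
#' Applies the full per-window detection pipeline: restrict the census to
#' the window's sampling interval, drop under-observed individuals, build
#' the SRI network, and run walktrap either directly on the thresholded
#' observed network (`bootstrap = FALSE`) or on the bootstrapped
#' co-membership meta-network followed by the oversize-splitting check
#' (`bootstrap = TRUE`). The meta-network is passed to walktrap
#' un-thresholded, as a weighted graph over its positive entries.
#'
#' @param records filtered census records (the full study; the window's
#'   sampling interval is selected internally).
#' @param window single-row window `data.frame` from [make_windows()].
#' @param config an [approach_config()].
#' @return A [community_partition()]; empty (with a warning) when no
#'   individual passes the observation filter.
#' @export
detect_units <- function(records, window, config) {
  stopifnot(inherits(config, "approach_config"))
  records <- filter_census(records)
  sub <- window_records(records, window)
  ids <- retained_individuals(sub, NULL, config$min_obs)
  tag <- format(config)
  if (length(ids) == 0L) {
    warning(sprintf("window %s: no individual passes the observation filter", window$window_id))
    return(community_partition(window$window_id, character(), tag))
  }
  if (length(ids) == 1L) {
    return(community_partition(window$window_id,
                               stats::setNames("C01", ids), tag))
  }
  if (!config$bootstrap) {
    gbi <- build_gbi(sub, ids)
    net <- threshold_network(simple_ratio_index(gbi), config$edge_threshold)
    return(walktrap_communities(net, steps = config$walktrap_steps,
                                window_id = window$window_id, method_tag = tag))
  }
  seed <- derive_seed(config$seed, "meta", window$window_id)
  meta <- bootstrap_metanetwork(sub, ids, config, seed = seed)
  part <- walktrap_communities(meta, steps = config$walktrap_steps,
                               window_id = window$window_id, method_tag = tag)
  oversize_split(part, sub, config, seed = derive_seed(seed, "split"))
}
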