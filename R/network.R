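#' Build a group-by-individual matrix
#'
#' Converts filtered census records into a binary matrix with one row per
#' observed aggregation and one column per retained individual; a cell is 1
#' when the individual was identified in that aggregation. Rows containing
#' no retained individual are dropped.
#'
#' @param records filtered census `data.frame` (see [filter_census()]).
#' @param ids character vector of retained individual IDs
#'   (see [retained_individuals()]).
#' @return Integer 0/1 matrix; rownames are observation IDs, colnames are
#'   the sorted retained IDs.
#' @export
build_gbi <- function(records, ids) {
  validate_census(records)
  ids <- sort(unique(as.character(ids)))
  if (length(ids) == 0L) stop("`ids` is empty: no retained individuals", call. = FALSE)
  gbi <- matrix(0L, nrow = nrow(records), ncol = length(ids),
                dimnames = list(records$observation_id, ids))
  for (r in seq_len(nrow(records))) {
    present <- intersect(records$individual_ids[[r]], ids)
    gbi[r, present] <- 1L
  }
  gbi[rowSums(gbi) > 0L, , drop = FALSE]
}

#' Simple ratio index association network
#'
#' Computes, for every pair of individuals, the simple ratio index (SRI):
#' the number of aggregations in which the two were observed together,
#' divided by the number of aggregations in which at least one of them was
#' observed. The SRI estimates the proportion of time a dyad spends
#' together, ranging from 0 (never together) to 1 (always together). The
#' sampling unit of the denominator is the single census observation row;
#' pairs with a zero denominator get weight 0.
#'
#' The integer numerator and denominator matrices are attached as
#' attributes `"numerator"` and `"denominator"` so that downstream
#' thresholding can make exact boundary decisions on the underlying
#' ratios (see [threshold_network()]).
#'
#' @param gbi group-by-individual matrix from [build_gbi()].
#' @return Symmetric numeric matrix of SRI weights with zero diagonal.
#' @export
simple_ratio_index <- function(gbi) {
  if (ncol(gbi) < 2L) stop("need at least 2 individuals to build a network", call. = FALSE)
  x <- gbi > 0L
  storage.mode(x) <- "integer"
  together <- crossprod(x)              # co-occurrence counts
  n_obs <- diag(together)
  either <- outer(n_obs, n_obs, "+") - together
  sri <- ifelse(either > 0L, together / either, 0)
  diag(sri) <- 0
  diag(together) <- 0L
  dimnames(sri) <- dimnames(together)
  attr(sri, "numerator") <- together
  attr(sri, "denominator") <- either
  sri
}

#' Zero out weak network edges
#'
#' Sets association weights strictly below `threshold` to zero and leaves
#' weights greater than or equal to `threshold` untouched. Community
#' detection is far more sensitive to edge presence than to edge weight,
#' so sub-threshold dyads are treated as not associated.
#'
#' When the network carries exact integer `"numerator"`/`"denominator"`
#' attributes (as produced by [simple_ratio_index()]), the boundary
#' decision is made on the underlying ratio (`num >= threshold * den`),
#' so that a dyad seen together in exactly half of its sightings is kept
#' at the default threshold of 0.5 regardless of floating-point rounding.
#'
#' @param net symmetric association matrix.
#' @param threshold weight in `[0, 1]`; edges with weight `< threshold`
#'   are zeroed.
#' @return The thresholded matrix (attributes updated in step).
#' @export
threshold_network <- function(net, threshold = 0.5) {
  stop_if_not_prob(threshold, "threshold")
  num <- attr(net, "numerator")
  den <- attr(net, "denominator")
  if (!is.null(num) && !is.null(den)) {
    keep <- num >= threshold * den & den > 0L
  } else {
    keep <- net >= threshold
  }
  out <- ifelse(keep, net, 0)
  diag(out) <- 0
  dimnames(out) <- dimnames(net)
  if (!is.null(num)) {
    num[!keep] <- 0L
    attr(out, "numerator") <- num
    attr(out, "denominator") <- den
  }
  out
}

#' Export positive network edges as an edge list
#'
#' @param net symmetric association matrix with individual IDs as dimnames.
#' @return `data.frame` with columns `id_i`, `id_j`, `sri` for weights
#'   greater than zero, with `id_i < id_j` lexicographically.
#' @export
sri_edgelist <- function(net) {
  ids <- colnames(net)
  idx <- which(upper.tri(net) & net > 0, arr.ind = TRUE)
  out <- data.frame(
    id_i = ids[idx[, 1L]],
    id_j = ids[idx[, 2L]],
    sri = net[idx],
    stringsAsFactors = FALSE
  )
  swap <- out$id_i > out$id_j
  tmp <- out$id_i[swap]; out$id_i[swap] <- out$id_j[swap]; out$id_j[swap] <- tmp
  out[order(out$id_i, out$id_j), , drop = FALSE]
}
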