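#' Link per-window communities into persistent social-unit identities
#'
#' Matches communities in consecutive focal windows by membership overlap
#' and assigns global unit identifiers, so that a social unit detected in
#' several windows keeps one identity over time. A community at window
#' `t+1` continues the global identity of the community at window `t` with
#' which it shares the most members, provided the overlap is a mutual
#' majority: strictly more than half of both communities' members. When
#' several candidates tie on overlap, the larger source community wins,
#' then the lexicographically smaller label. Communities without a
#' mutual-majority predecessor start a new global identity (birth);
#' communities without a successor end theirs (death). When at least two
#' successor communities each draw a majority of their members from one
#' source, a split is recorded; when at least two sources each send a
#' majority of their members into one successor, a merge is recorded.
#'
#' @param partitions list of [community_partition()] objects ordered by
#'   window.
#' @return Object of class `dynamic_membership`: a list with
#'   `assignments` (data.frame `window_id`, `individual`, `community_id`,
#'   `global_unit`, `interpolated`), `lineage` (data.frame `from_window`,
#'   `to_window`, `relation`, `source_units`, `target_units`) and
#'   `windows` (ordered window IDs).
#' @export
link_communities <- function(partitions) {
  if (length(partitions) < 2L)
    stop("need at least two window partitions to link communities", call. = FALSE)
  stopifnot(all(vapply(partitions, inherits, logical(1), "community_partition")))
  windows <- unname(vapply(partitions, `[[`, "", "window_id"))
  if (anyDuplicated(windows)) stop("duplicate window_id in partitions", call. = FALSE)

  comm_members <- lapply(partitions, function(p) split(names(p$membership), p$membership))
  global_of <- vector("list", length(partitions))  # community label -> global id
  next_gid <- 0L
  new_gid <- function() { next_gid <<- next_gid + 1L; sprintf("G%03d", next_gid) }

  global_of[[1L]] <- stats::setNames(
    vapply(seq_along(comm_members[[1L]]), function(i) new_gid(), ""),
    names(comm_members[[1L]]))
  lineage <- list()

  for (t in seq_len(length(partitions) - 1L)) {
    src <- comm_members[[t]]
    dst <- comm_members[[t + 1L]]
    gsrc <- global_of[[t]]
    gdst <- stats::setNames(rep(NA_character_, length(dst)), names(dst))

    overlap <- matrix(0L, length(src), length(dst),
                      dimnames = list(names(src), names(dst)))
    for (a in names(src)) for (b in names(dst))
      overlap[a, b] <- length(intersect(src[[a]], dst[[b]]))
    src_sizes <- lengths(src)[names(src)]
    dst_sizes <- lengths(dst)[names(dst)]

    # candidate continuations: mutual majority (>= half of both, with at
    # least one strict majority or the documented tie-break)
    cand <- list()
    for (b in names(dst)) {
      ok <- names(src)[overlap[, b] > 0.5 * src_sizes &
                         overlap[, b] > 0.5 * dst_sizes[b]]
      if (length(ok) == 0L) next
      o <- overlap[ok, b]
      ord <- order(-o, -src_sizes[ok], ok)
      cand[[b]] <- data.frame(src = ok[ord][1L], dst = b,
                              o = o[ord][1L], stringsAsFactors = FALSE)
    }
    cand <- do.call(rbind, cand)
    continued_src <- character(); continued_dst <- character()
    if (!is.null(cand) && nrow(cand)) {
      # enforce one successor per source: keep the largest overlap
      cand <- cand[order(-cand$o, -dst_sizes[cand$dst], cand$dst), , drop = FALSE]
      cand <- cand[!duplicated(cand$src), , drop = FALSE]
      gdst[cand$dst] <- gsrc[cand$src]
      continued_src <- cand$src
      continued_dst <- cand$dst
      for (i in seq_len(nrow(cand)))
        lineage[[length(lineage) + 1L]] <- data.frame(
          from_window = windows[t], to_window = windows[t + 1L],
          relation = "continue",
          source_units = gsrc[cand$src[i]], target_units = gsrc[cand$src[i]],
          stringsAsFactors = FALSE)
    }
    # births
    for (b in setdiff(names(dst), continued_dst)) gdst[b] <- new_gid()

    # splits: one source feeding a majority of members of >= 2 successors
    for (a in names(src)) {
      fed <- names(dst)[overlap[a, ] > 0.5 * dst_sizes]
      if (length(fed) >= 2L)
        lineage[[length(lineage) + 1L]] <- data.frame(
          from_window = windows[t], to_window = windows[t + 1L],
          relation = "split", source_units = gsrc[a],
          target_units = paste(sort(gdst[fed]), collapse = ";"),
          stringsAsFactors = FALSE)
    }
    # merges: >= 2 sources each sending a majority of their members into
    # one successor
    for (b in names(dst)) {
      feeders <- names(src)[overlap[, b] > 0.5 * src_sizes]
      if (length(feeders) >= 2L)
        lineage[[length(lineage) + 1L]] <- data.frame(
          from_window = windows[t], to_window = windows[t + 1L],
          relation = "merge",
          source_units = paste(sort(gsrc[feeders]), collapse = ";"),
          target_units = gdst[b], stringsAsFactors = FALSE)
    }
    # births / deaths
    for (b in setdiff(names(dst), continued_dst))
      lineage[[length(lineage) + 1L]] <- data.frame(
        from_window = windows[t], to_window = windows[t + 1L],
        relation = "birth", source_units = "",
        target_units = gdst[b], stringsAsFactors = FALSE)
    for (a in setdiff(names(src), continued_src))
      lineage[[length(lineage) + 1L]] <- data.frame(
        from_window = windows[t], to_window = windows[t + 1L],
        relation = "death", source_units = gsrc[a],
        target_units = "", stringsAsFactors = FALSE)
    global_of[[t + 1L]] <- gdst
  }

  assignments <- do.call(rbind, lapply(seq_along(partitions), function(t) {
    p <- partitions[[t]]
    if (length(p$membership) == 0L) return(NULL)
    data.frame(window_id = windows[t],
               individual = names(p$membership),
               community_id = unname(p$membership),
               global_unit = unname(global_of[[t]][p$membership]),
               interpolated = FALSE,
               stringsAsFactors = FALSE)
  }))
  rownames(assignments) <- NULL
  lineage <- if (length(lineage)) do.call(rbind, lineage) else
    data.frame(from_window = character(), to_window = character(),
               relation = character(), source_units = character(),
               target_units = character(), stringsAsFactors = FALSE)
  rownames(lineage) <- NULL
  structure(list(assignments = assignments, lineage = lineage, windows = windows),
            class = "dynamic_membership")
}

#' @export
print.dynamic_membership <- function(x, ...) {
  cat(sprintf("<dynamic_membership> %d windows, %d global units, %d assignments (%d interpolated)\n",
              length(x$windows), length(unique(x$assignments$global_unit)),
              nrow(x$assignments), sum(x$assignments$interpolated)))
  invisible(x)
}

#' Re-add temporarily missing individuals to their unit
#'
#' An individual that is absent from one window but assigned to the same
#' global unit in both the previous and the next window was most likely
#' simply unobserved; interpolation re-adds it to that unit in the gap
#' window, flagged with `interpolated = TRUE`. Only single-window gaps are
#' filled; longer absences are treated as genuine. Existing assignments
#' are never modified, and the operation is idempotent.
#'
#' @param dyn a [link_communities()] result.
#' @return The `dynamic_membership` object with interpolated rows added.
#' @export
interpolate_missing <- function(dyn) {
  stopifnot(inherits(dyn, "dynamic_membership"))
  a <- dyn$assignments
  windows <- dyn$windows
  if (length(windows) < 3L) return(dyn)
  added <- list()
  for (t in 2:(length(windows) - 1L)) {
    prev <- a[a$window_id == windows[t - 1L], ]
    cur <- a[a$window_id == windows[t], ]
    nxt <- a[a$window_id == windows[t + 1L], ]
    miss <- setdiff(intersect(prev$individual, nxt$individual), cur$individual)
    if (length(miss) == 0L) next
    g_prev <- stats::setNames(prev$global_unit, prev$individual)[miss]
    g_next <- stats::setNames(nxt$global_unit, nxt$individual)[miss]
    same <- miss[g_prev == g_next]
    if (length(same) == 0L) next
    added[[length(added) + 1L]] <- data.frame(
      window_id = windows[t], individual = same,
      community_id = NA_character_,
      global_unit = unname(g_prev[same]),
      interpolated = TRUE, stringsAsFactors = FALSE)
  }
  if (length(added)) {
    a <- rbind(a, do.call(rbind, added))
    a <- a[order(match(a$window_id, windows), a$individual), ]
    rownames(a) <- NULL
    dyn$assignments <- a
  }
  dyn
}

#' Jaccard stability of social units across consecutive windows
#'
#' For every global unit present in both windows of a consecutive pair,
#' computes the Jaccard similarity of its member sets: the number of
#' individuals assigned to the unit in both windows divided by the number
#' assigned in either window. 1 indicates a perfectly stable membership,
#' 0 a complete turnover. Interpolated members count as present. Units
#' absent from either window of a pair yield no record.
#'
#' @param dyn a `dynamic_membership` (after [interpolate_missing()] if
#'   interpolation is wanted).
#' @return `data.frame` with columns `global_unit`, `window_t`,
#'   `window_t1`, `jaccard`.
#' @export
jaccard_stability <- function(dyn) {
  stopifnot(inherits(dyn, "dynamic_membership"))
  a <- dyn$assignments
  windows <- dyn$windows
  out <- list()
  for (t in seq_len(length(windows) - 1L)) {
    m1 <- a[a$window_id == windows[t], ]
    m2 <- a[a$window_id == windows[t + 1L], ]
    for (g in intersect(unique(m1$global_unit), unique(m2$global_unit))) {
      s1 <- m1$individual[m1$global_unit == g]
      s2 <- m2$individual[m2$global_unit == g]
      out[[length(out) + 1L]] <- data.frame(
        global_unit = g, window_t = windows[t], window_t1 = windows[t + 1L],
        jaccard = length(intersect(s1, s2)) / length(union(s1, s2)),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  } else {
    data.frame(global_unit = character(), window_t = character(),
               window_t1 = character(), jaccard = numeric(),
               stringsAsFactors = FALSE)
  }
}
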