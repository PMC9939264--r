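# Independent oracles used to cross-check the pipeline implementations.

# Brute-force simple ratio index: per-pair loop over GBI rows.
sri_oracle <- function(gbi) {
  ids <- colnames(gbi)
  k <- length(ids)
  out <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    together <- 0L; either <- 0L
    for (r in seq_len(nrow(gbi))) {
      a <- gbi[r, i] > 0; b <- gbi[r, j] > 0
      if (a && b) together <- together + 1L
      if (a || b) either <- either + 1L
    }
    out[i, j] <- if (either > 0L) together / either else 0
  }
  out
}

# Independent walktrap implementation (Pons-Latapy): exact recomputation of
# the random-walk distances and Ward-style merge costs at every step,
# cutting the merge sequence at maximal weighted modularity. O(n^3)-ish;
# for small test graphs only.
walktrap_oracle <- function(W, steps = 4L) {
  n <- nrow(W)
  A <- W
  diag(A) <- 1                       # self-loops make the walk aperiodic
  d <- rowSums(A)
  P <- A / d
  Pt <- diag(n)
  for (s in seq_len(steps)) Pt <- Pt %*% P
  members <- as.list(seq_len(n))
  vecs <- lapply(seq_len(n), function(i) Pt[i, ])
  cadj <- lapply(seq_len(n), function(i) which(W[i, ] > 0))
  alive <- seq_len(n)
  m2 <- sum(W)
  modularity_of <- function(memb) {
    q <- 0
    for (l in unique(memb)) {
      idx <- memb == l
      q <- q + sum(W[idx, idx]) / m2 - (sum(W[idx, , drop = FALSE]) / m2)^2
    }
    q
  }
  dsig <- function(a, b) {
    na <- length(members[[a]]); nb <- length(members[[b]])
    na * nb / (na + nb) * sum((vecs[[a]] - vecs[[b]])^2 / d) / n
  }
  nxt <- n
  mods <- numeric(n - 1L)
  membs <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- NULL; bestv <- Inf
    for (a in alive) for (b in cadj[[a]]) if (b %in% alive && b > a) {
      v <- dsig(a, b)
      if (v < bestv) { bestv <- v; best <- c(a, b) }
    }
    if (is.null(best)) {  # disconnected remainder: merge cheapest pair
      for (a in alive) for (b in alive) if (b > a) {
        v <- dsig(a, b)
        if (v < bestv) { bestv <- v; best <- c(a, b) }
      }
    }
    a <- best[1L]; b <- best[2L]; nxt <- nxt + 1L
    members[[nxt]] <- c(members[[a]], members[[b]])
    na <- length(members[[a]]); nb <- length(members[[b]])
    vecs[[nxt]] <- (na * vecs[[a]] + nb * vecs[[b]]) / (na + nb)
    cadj[[nxt]] <- setdiff(union(cadj[[a]], cadj[[b]]), c(a, b))
    for (x in cadj[[nxt]]) cadj[[x]] <- union(setdiff(cadj[[x]], c(a, b)), nxt)
    alive <- c(setdiff(alive, c(a, b)), nxt)
    memb <- integer(n)
    for (kk in seq_along(alive)) memb[members[[alive[kk]]]] <- kk
    mods[step] <- modularity_of(memb)
    membs[[step]] <- memb
  }
  best_level <- which.max(mods)
  out <- membs[[best_level]]
  names(out) <- colnames(W)
  out
}

# Random weighted graph with planted block structure: communities are
# well-defined, so independent community-detection implementations must
# agree on the recovered partition.
random_planted_graph <- function(n_blocks, sizes, p_in = 0.9, p_out = 0.08,
                                 w_in = c(0.6, 1), w_out = c(0.05, 0.3)) {
  n <- sum(sizes)
  lab <- rep(seq_len(n_blocks), sizes)
  W <- matrix(0, n, n, dimnames = list(paste0("v", 1:n), paste0("v", 1:n)))
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if (lab[i] == lab[j]) {
      if (stats::runif(1) < p_in) W[i, j] <- W[j, i] <- stats::runif(1, w_in[1], w_in[2])
    } else {
      if (stats::runif(1) < p_out) W[i, j] <- W[j, i] <- stats::runif(1, w_out[1], w_out[2])
    }
  }
  list(W = W, labels = lab)
}

# Adjusted Rand index / NMI between two labelled partitions.
ari <- function(x, y) {
  stopifnot(length(x) == length(y))
  igraph::compare(as.integer(as.factor(x)), as.integer(as.factor(y)),
                  method = "adjusted.rand")
}
nmi <- function(x, y) {
  igraph::compare(as.integer(as.factor(x)), as.integer(as.factor(y)),
                  method = "nmi")
}

# Exact partition agreement, robust to label names.
same_partition <- function(x, y) {
  x <- x[order(names(x))]; y <- y[order(names(y))]
  if (!identical(names(x), names(y))) return(FALSE)
  identical(as.integer(factor(x, levels = unique(x))),
            as.integer(factor(y, levels = unique(y))))
}

# Drop auxiliary attributes (numerator/denominator) for plain comparisons.
plain <- function(m) {
  out <- as.vector(m)
  dim(out) <- dim(m)
  dimnames(out) <- dimnames(m)
  out
}
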