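part_of <- function(window_id, members_by_unit) {
  membership <- stats::setNames(
    rep(names(members_by_unit), lengths(members_by_unit)),
    unlist(members_by_unit))
  community_partition(window_id, membership, "test")
}

test_that("stable communities keep one global identity with 'continue' lineage", {
  units <- list(u1 = c("A", "B", "C"), u2 = c("D", "E"))
  parts <- lapply(c("w1", "w2", "w3"), part_of, members_by_unit = units)
  dyn <- link_communities(parts)
  expect_equal(length(unique(dyn$assignments$global_unit)), 2L)
  expect_true(all(dyn$lineage$relation == "continue"))
  per_ind <- split(dyn$assignments$global_unit, dyn$assignments$individual)
  expect_true(all(vapply(per_ind, function(g) length(unique(g)) == 1L, logical(1))))
})

test_that("an even split produces two fresh identities and a split record", {
  big <- sprintf("I%02d", 1:20)
  parts <- list(
    part_of("w1", list(u = big)),
    part_of("w2", list(h1 = big[1:10], h2 = big[11:20]))
  )
  dyn <- link_communities(parts)
  g1 <- unique(dyn$assignments$global_unit[dyn$assignments$window_id == "w1"])
  g2 <- unique(dyn$assignments$global_unit[dyn$assignments$window_id == "w2"])
  expect_length(g2, 2L)
  expect_false(g1 %in% g2)
  expect_true("split" %in% dyn$lineage$relation)
  expect_true("death" %in% dyn$lineage$relation)
  expect_equal(sum(dyn$lineage$relation == "birth"), 2L)
})

test_that("a dominant successor continues the identity; the minority splits off", {
  big <- sprintf("I%02d", 1:20)
  parts <- list(
    part_of("w1", list(u = big)),
    part_of("w2", list(main = big[1:15], rest = big[16:20]))
  )
  dyn <- link_communities(parts)
  a <- dyn$assignments
  g_w1 <- unique(a$global_unit[a$window_id == "w1"])
  g_main <- unique(a$global_unit[a$window_id == "w2" & a$individual == "I01"])
  g_rest <- unique(a$global_unit[a$window_id == "w2" & a$individual == "I20"])
  expect_equal(g_main, g_w1)
  expect_false(g_rest == g_w1)
  expect_true("split" %in% dyn$lineage$relation)
})

test_that("merging units yields a merge record", {
  parts <- list(
    part_of("w1", list(a = c("A", "B", "C"), b = c("D", "E", "F"))),
    part_of("w2", list(ab = c("A", "B", "C", "D", "E", "F")))
  )
  dyn <- link_communities(parts)
  expect_true("merge" %in% dyn$lineage$relation)
})

test_that("linking tracks latent units through per-window membership churn", {
  # 5% of individuals genuinely switch units between windows; communities
  # are detected perfectly; the linker must keep every latent unit under
  # one global identity
  set.seed(31)
  inds <- sprintf("I%02d", 1:60)
  lab <- rep(c("u1", "u2", "u3"), each = 20L)
  truth_rows <- list()
  parts <- list()
  for (w in 1:6) {
    if (w > 1L) {
      churn <- runif(length(lab)) < 0.05
      lab[churn] <- sample(c("u1", "u2", "u3"), sum(churn), replace = TRUE)
    }
    truth_rows[[w]] <- data.frame(window_id = sprintf("w%d", w),
                                  individual = inds, latent = lab,
                                  stringsAsFactors = FALSE)
    parts[[w]] <- part_of(sprintf("w%d", w), split(inds, lab))
  }
  dyn <- link_communities(parts)
  truth_tab <- do.call(rbind, truth_rows)
  merged <- merge(dyn$assignments, truth_tab, by = c("window_id", "individual"))
  expect_gte(nmi(merged$global_unit, merged$latent), 0.95)
})

test_that("interpolation fills exactly the single-window gaps with a stable unit", {
  p1 <- part_of("w1", list(g = c("A", "B", "C"), h = c("D", "E", "F")))
  p2 <- part_of("w2", list(g = c("B", "C"), h = c("D", "E", "F")))
  p3 <- part_of("w3", list(g = c("A", "B", "C"), h = c("E", "F")))
  p4 <- part_of("w4", list(g = c("A", "B", "C"), h = c("D", "E", "F")))
  dyn <- interpolate_missing(link_communities(list(p1, p2, p3, p4)))
  a <- dyn$assignments
  # A missing only from w2, same unit before and after -> re-added
  added <- a[a$window_id == "w2" & a$individual == "A", ]
  expect_equal(nrow(added), 1L)
  expect_true(added$interpolated)
  g_of_A <- unique(a$global_unit[a$individual == "A" & a$window_id != "w2"])
  expect_equal(added$global_unit, g_of_A)
  # D missing only from w3 -> re-added there too
  expect_equal(sum(a$window_id == "w3" & a$individual == "D"), 1L)
})

test_that("interpolation refuses unit changes and multi-window gaps", {
  # A in g at w1 but in h at w3: no fill
  p1 <- part_of("w1", list(g = c("A", "B", "C"), h = c("D", "E")))
  p2 <- part_of("w2", list(g = c("B", "C"), h = c("D", "E")))
  p3 <- part_of("w3", list(g = c("B", "C"), h = c("A", "D", "E")))
  dyn <- interpolate_missing(link_communities(list(p1, p2, p3)))
  expect_equal(sum(dyn$assignments$window_id == "w2" &
                     dyn$assignments$individual == "A"), 0L)

  # A absent from w2 and w3: a two-window gap stays open
  q1 <- part_of("w1", list(g = c("A", "B", "C")))
  q2 <- part_of("w2", list(g = c("B", "C")))
  q3 <- part_of("w3", list(g = c("B", "C")))
  q4 <- part_of("w4", list(g = c("A", "B", "C")))
  dyn2 <- interpolate_missing(link_communities(list(q1, q2, q3, q4)))
  expect_equal(sum(dyn2$assignments$individual == "A"), 2L)
})

test_that("interpolation never alters existing rows and is idempotent", {
  p1 <- part_of("w1", list(g = c("A", "B", "C")))
  p2 <- part_of("w2", list(g = c("B", "C")))
  p3 <- part_of("w3", list(g = c("A", "B", "C")))
  dyn <- link_communities(list(p1, p2, p3))
  once <- interpolate_missing(dyn)
  twice <- interpolate_missing(once)
  expect_identical(once$assignments, twice$assignments)
  orig <- dyn$assignments
  merged <- merge(orig, once$assignments,
                  by = c("window_id", "individual"), suffixes = c("", ".new"))
  expect_equal(merged$global_unit, merged$global_unit.new)
  expect_false(any(merged$interpolated.new[!merged$interpolated]))
})

test_that("Jaccard stability matches set arithmetic and respects identity", {
  p1 <- part_of("w1", list(g = c("A", "B", "C")))
  p2 <- part_of("w2", list(g = c("A", "B", "C")))
  dyn <- link_communities(list(p1, p2))
  st <- jaccard_stability(dyn)
  expect_equal(st$jaccard, 1)

  big <- sprintf("I%02d", 1:20)
  swapped <- c(big[1:18], "N1", "N2")
  dyn2 <- link_communities(list(part_of("w1", list(u = big)),
                                part_of("w2", list(u = swapped))))
  st2 <- jaccard_stability(dyn2)
  expect_equal(st2$jaccard, 18 / 22)

  # a unit absent from the second window yields no record
  dyn3 <- link_communities(list(part_of("w1", list(u = c("A", "B"), v = c("C", "D"))),
                                part_of("w2", list(u = c("A", "B")))))
  st3 <- jaccard_stability(dyn3)
  expect_equal(nrow(st3), 1L)
})

test_that("Jaccard is invariant to relabelling of global identities", {
  p1 <- part_of("w1", list(x = c("A", "B", "C", "D"), y = c("E", "F")))
  p2 <- part_of("w2", list(q = c("A", "B", "C"), r = c("E", "F")))
  st <- jaccard_stability(link_communities(list(p1, p2)))
  expect_setequal(round(st$jaccard, 10), round(c(3 / 4, 1), 10))
})
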