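test_that("cluster identification finds the documented structures", {
  cs <- identify_clusters(c(1, 1, 2, 5, 9, 9, 10, 10, 10))
  tab <- as.data.frame(cs)
  expect_equal(tab$low, c(1, 8))
  expect_equal(tab$high, c(3, 10))
  expect_equal(tab$member_count, c(3, 5))
  expect_equal(tab$mean_rating, c(4 / 3, 9.6))
  expect_equal(cs$r_mode, 5L)
  # the rating 5 belongs to no cluster
  expect_true(all(5 < tab$low | 5 > tab$high))

  uni <- identify_clusters(rep(4, 7))
  expect_length(uni$clusters, 1)
  expect_true(uni$clusters[[1]]$low <= 4 && uni$clusters[[1]]$high >= 4)
  expect_equal(uni$clusters[[1]]$member_count, 7L)
  expect_equal(uni$clusters[[1]]$mean_rating, 4)

  cs2 <- identify_clusters(c(5, 5, 7, 7))
  expect_length(cs2$clusters, 1)
  expect_equal(cs2$clusters[[1]][c("low", "high", "member_count")],
               list(low = 5L, high = 7L, member_count = 4L))
})

test_that("cluster identification matches the exhaustive oracle", {
  set.seed(77)
  for (case in 1:40) {
    q <- sample(5:10, 1)
    scores <- sample.int(q, sample(1:10, 1), replace = TRUE)
    v <- sample(1:4, 1)
    p <- sample(c(0.5, 0.6, 0.75), 1)
    got <- identify_clusters(scores, clustering_params(v, p), q)
    want <- oracle_clusters(scores, v = v, p = p, q = q)
    tab <- as.data.frame(got)
    expect_equal(got$r_mode, want$r_mode)
    expect_equal(tab$low, want$table$low)
    expect_equal(tab$high, want$table$high)
    expect_equal(tab$member_count, want$table$count)
    expect_equal(tab$mean_rating, want$table$mean)
  }
})

test_that("cluster sets satisfy their structural invariants", {
  set.seed(88)
  for (case in 1:40) {
    scores <- sample.int(10, sample(2:12, 1), replace = TRUE)
    p <- sample(c(0.5, 0.7), 1)
    cs <- identify_clusters(scores, clustering_params(3, p))
    tab <- as.data.frame(cs)
    # disjoint, ordered intervals of width <= 3
    expect_true(all(diff(tab$low) > 0))
    if (nrow(tab) > 1)
      expect_true(all(tab$low[-1] > tab$high[-nrow(tab)]))
    expect_true(all(tab$high - tab$low + 1 <= 3))
    # every cluster passes the secondary threshold; means lie inside
    expect_true(all(tab$member_count >= p * cs$r_mode - 1e-9))
    expect_true(all(tab$member_count >= 1))
    expect_true(all(tab$mean_rating >= tab$low & tab$mean_rating <= tab$high))
    expect_equal(cs$r_mode, max(tab$member_count))
  }
})

test_that("target assignment picks the nearest cluster with midway ties to the larger", {
  cs <- identify_clusters(c(1, 1, 2, 5, 9, 9, 10, 10, 10))
  # rating 5: two points from [1,3], three from [8,10] -> lower cluster
  tgt <- assign_target_cluster(5, cs)
  expect_equal(tgt$low, 1L)
  # rating 2 sits inside [1,3]
  expect_equal(assign_target_cluster(2, cs)$low, 1L)
  # exactly midway between [1,3] (3 raters) and [7,9] (5 raters): larger wins
  mid <- structure(list(clusters = list(
    list(low = 1L, high = 3L, member_count = 3L, mean_rating = 2),
    list(low = 7L, high = 9L, member_count = 5L, mean_rating = 8)),
    r_mode = 5L, scale_max = 10L), class = "cluster_set")
  expect_equal(assign_target_cluster(5, mid)$low, 7L)
  # counts tied as well: the lower cluster wins
  tie <- structure(list(clusters = list(
    list(low = 1L, high = 3L, member_count = 3L, mean_rating = 2),
    list(low = 7L, high = 9L, member_count = 3L, mean_rating = 8)),
    r_mode = 3L, scale_max = 10L), class = "cluster_set")
  expect_equal(assign_target_cluster(5, tie)$low, 1L)
  # single cluster: chosen whatever the rating
  one <- identify_clusters(rep(9, 4))
  expect_equal(assign_target_cluster(1, one)$member_count, 4L)
  # empty set is an error for the caller to handle
  empty <- structure(list(clusters = list(), r_mode = 0L, scale_max = 10L),
                     class = "cluster_set")
  expect_error(assign_target_cluster(5, empty), "empty")
})

test_that("the conformity update interpolates, rounds half-up and clamps", {
  expect_equal(update_rating(7, 2.4, gci = 0), 7L)
  expect_equal(update_rating(2, 9.4, gci = 1), 9L)
  expect_equal(update_rating(2, 9.4, gci = 0.5), 6L)   # round(5.7)
  expect_equal(update_rating(3, 4, gci = 0.5), 4L)     # round(3.5) half-up
  expect_equal(update_rating(c(1, 10), 5, gci = 0.2), c(2L, 9L))
  expect_error(update_rating(5, 5, gci = 1.2), "gci")
  expect_error(update_rating(5, 5, gci = -0.1), "gci")
})

test_that("the update lands between the old rating and the rounded target", {
  set.seed(19)
  for (case in 1:200) {
    prev <- sample.int(10, 1)
    tgt <- runif(1, 1, 10)
    gci <- runif(1)
    new <- update_rating(prev, tgt, gci)
    lohi <- range(c(prev, floor(tgt + 0.5)))
    expect_gte(new, lohi[1]); expect_lte(new, lohi[2])
    expect_true(new >= 1 && new <= 10)
  }
  # gci = 0 is the identity on whole columns
  expect_equal(update_rating(1:10, 3.7, gci = 0), 1:10)
})
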