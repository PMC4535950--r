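one_item <- function(scores, q = 10L) rating_matrix(cbind(scores), scale_max = q)

test_that("De Moivre index flags unanimity and nothing else", {
  expect_equal(index_de_moivre(one_item(c(5, 5, 5)))$per_item, 1)
  expect_equal(index_de_moivre(one_item(c(5, 5, 7)))$per_item, 0)
  two <- rating_matrix(cbind(c(4, 4, 4), c(4, 4, 5)))
  rep2 <- index_de_moivre(two)
  expect_equal(rep2$per_item, c(1, 0))
  expect_equal(rep2$study_wide, 0.5)
})

test_that("pairwise agreement counts agreeing expert pairs", {
  expect_equal(index_pwa(one_item(c(5, 5, 7)))$per_item, 1 / 3)
  expect_equal(index_pwa(one_item(c(6, 6, 6, 6)))$per_item, 1)
  expect_equal(index_pwa(one_item(c(1, 5, 9)))$per_item, 0)
})

test_that("ratings matrices with fewer than 2 experts are rejected", {
  expect_error(rating_matrix(matrix(5, nrow = 1)), "at least 2 experts")
  expect_error(rating_matrix(cbind(c(3, 11))), "must lie in")
  expect_error(rating_matrix(cbind(c(3.5, 2))), "integers")
})

test_that("clustered PWA counts within-cluster pairs only", {
  m <- make_fixture("bimodal-9v3")
  cs <- identify_clusters(m[, 1])
  expect_equal(index_cpwa(m, list(cs))$per_item, 26 / 72)
  # unanimous panel, one cluster holding the score
  u <- one_item(rep(4, 6))
  expect_equal(index_cpwa(u)$per_item, 1)
  # clusters that no score falls into contribute nothing
  fake <- structure(list(clusters = list(
    list(low = 9L, high = 10L, member_count = 0L, mean_rating = 9.5)),
    r_mode = 0L, scale_max = 10L), class = "cluster_set")
  expect_equal(index_cpwa(one_item(c(4, 4, 5)), list(fake))$per_item, 0)
  # overlapping clusters are invalid input
  bad <- structure(list(clusters = list(
    list(low = 1L, high = 3L, member_count = 1L, mean_rating = 2),
    list(low = 3L, high = 5L, member_count = 1L, mean_rating = 4)),
    r_mode = 1L, scale_max = 10L), class = "cluster_set")
  expect_error(index_cpwa(one_item(c(2, 4, 6)), list(bad)), "overlapping")
})

test_that("extremities CPWA uses only the two extreme groups", {
  m <- make_fixture("bimodal-9v3")
  expect_equal(index_xcpwa(m)$per_item, 26 / 72)
  expect_equal(index_xcpwa(one_item(rep(5, 8)))$per_item, 0)
  expect_equal(index_xcpwa(one_item(rep(10, 8)))$per_item, 1)
  expect_error(extreme_groups(c(1, 5), c(5, 10)), "overlap")
})

test_that("Fleiss' kappa matches hand-computed values", {
  # two items rated unanimously at different scores: P = 1, Pe = 0.5
  m <- rating_matrix(cbind(c(4, 4, 4), c(9, 9, 9)))
  expect_equal(index_fleiss_kappa(m)$study_wide, 1)
  # single item (5,5,7): P = 1/3, Pe = 5/9, KF = -0.5
  expect_equal(index_fleiss_kappa(one_item(c(5, 5, 7)))$study_wide, -0.5)
  # degenerate: every expert identical everywhere -> 1 by convention
  expect_equal(index_fleiss_kappa(rating_matrix(matrix(7, 4, 3)))$study_wide, 1)
  expect_length(index_fleiss_kappa(m)$per_item, 0)
})

test_that("Conger's kappa equals Fleiss' when expert marginals coincide", {
  m <- rating_matrix(cbind(c(1, 1), c(2, 2)))
  expect_equal(index_conger_kappa(m)$study_wide, 1)
  # same per-rating marginals for both experts, imperfect agreement
  m2 <- rating_matrix(cbind(c(1, 2), c(2, 1), c(3, 3)))
  expect_equal(index_conger_kappa(m2)$study_wide,
               index_fleiss_kappa(m2)$study_wide)
  # the marginal correction can only raise kappa when P < 1
  m3 <- rating_matrix(cbind(c(5, 5, 7)))
  expect_gte(index_conger_kappa(m3)$study_wide,
             index_fleiss_kappa(m3)$study_wide)
})

test_that("mode index reports the modal share, ties included", {
  expect_equal(index_mode(one_item(c(5, 5, 7)))$per_item, 2 / 3)
  expect_equal(index_mode(make_fixture("tied-modes"))$per_item, 0.5)
  expect_equal(index_mode(one_item(rep(3, 5)))$per_item, 1)
})

test_that("clustered mode reports the modal cluster's share", {
  m <- make_fixture("bimodal-9v3")
  expect_equal(index_clustered_mode(m)$per_item, 5 / 9)
  u <- one_item(rep(4, 6))
  expect_equal(index_clustered_mode(u)$per_item, 1)
  empty <- structure(list(clusters = list(), r_mode = 0L, scale_max = 10L),
                     class = "cluster_set")
  expect_equal(index_clustered_mode(u, list(empty))$per_item, 0)
})

test_that("IQR index follows the interpolated-rank rule", {
  expect_equal(index_iqr(one_item(rep(6, 4)))$per_item, 0)
  expect_equal(index_iqr(one_item(c(1, 2, 3, 4)))$per_item, 1.5)
  expect_equal(index_iqr(one_item(c(2, 2, 2, 9)))$per_item, 1.75)
  m <- rating_matrix(cbind(c(1, 2, 3, 4), c(2, 2, 2, 9)))
  expect_equal(index_iqr(m)$study_wide, (1.5 + 1.75) / 2)
})

test_that("IQR consensus predicate applies the threshold per item", {
  m <- rating_matrix(cbind(c(4, 4, 5, 5), c(1, 4, 7, 10)))
  expect_equal(iqr_consensus(m), c(TRUE, FALSE))
  expect_equal(iqr_consensus(index_iqr(m), threshold = 8), c(TRUE, TRUE))
})

test_that("index invariants hold on randomised matrices", {
  set.seed(421)
  for (case in 1:25) {
    m <- random_matrix(sample(2:8, 1), sample(1:6, 1))
    reports <- consensus_indices(m)
    sw <- study_wide_values(reports)
    bounded <- c("DM", "PWA", "CPWA", "XCPWA", "M", "CM")
    for (nm in bounded) {
      expect_true(all(reports[[nm]]$per_item >= 0 &
                        reports[[nm]]$per_item <= 1))
      expect_equal(sw[[nm]], mean(reports[[nm]]$per_item))
    }
    expect_true(all(reports$IQR$per_item >= 0 &
                      reports$IQR$per_item <= 9))
    expect_lte(sw[["KF"]], 1)
    expect_lte(sw[["KC"]], 1)
    # brute-force pair enumeration agrees with the closed form
    expect_equal(reports$PWA$per_item,
                 vapply(seq_len(ncol(m)), function(i)
                   oracle_pwa_item(m[, i]), numeric(1)))
    # the modal cluster holds at least the modal score's raters
    expect_true(all(reports$CM$per_item >= reports$M$per_item))
    # chance-agreement correction only shrinks P_e
    if (sw[["KF"]] < 1) expect_gte(sw[["KC"]], sw[["KF"]])
    # expert and item order are irrelevant
    perm <- m[sample(nrow(m)), sample(ncol(m)), drop = FALSE]
    sw2 <- study_wide_values(
      consensus_indices(rating_matrix(perm, scale_max = 10L)))
    expect_equal(sw2, sw)
  }
})

test_that("unanimity everywhere maximises every index", {
  m <- rating_matrix(matrix(8L, nrow = 5, ncol = 4))
  sw <- study_wide_values(consensus_indices(m))
  expect_equal(unname(sw[c("DM", "PWA", "M", "CM")]), rep(1, 4))
  expect_equal(sw[["IQR"]], 0)
})
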