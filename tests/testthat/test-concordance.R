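test_that("discrepancy scores match the published scoring scheme", {
  expect_equal(discrepancy_score("NLAA", "no effect"), 1)
  expect_equal(discrepancy_score("no effect", "jeopardy"), -3)
  expect_equal(discrepancy_score("LAA", "no jeopardy"), 0)
  expect_equal(discrepancy_score("LAA", "jeopardy"), 0)
  expect_equal(discrepancy_score("proposed no jeopardy", "no jeopardy"), 0)
  expect_equal(discrepancy_score("proposed no jeopardy", "jeopardy"), -1)
  expect_equal(discrepancy_score("proposed jeopardy", "jeopardy"), 0)
  expect_error(discrepancy_score("nonsense", "jeopardy"), "unknown")
})

test_that("raising the agency category never decreases the score", {
  sm <- score_matrix()
  # the three-point agency severity ladder: no effect < NLAA < LAA
  for (i in 1:4) {
    expect_true(all(diff(sm[i, 1:3]) >= 0))
  }
  # agreement cells all carry weight zero; weights symmetric in |score|
  w <- default_weight_matrix()
  expect_true(all(w[sm == 0] == 0))
  expect_true(all(w %in% c(0, 0.25, 0.5, 0.75, 1)))
  expect_equal(w, abs(sm) * 0.25, ignore_attr = TRUE)
})

test_that("the concordance table counts pairs and is order invariant", {
  pairs <- tibble::tibble(
    agency_proposed = c("NLAA", "no effect", "NLAA", "missing"),
    expert_final = c("NLAA", "no effect", "no effect", "NLAA")
  )
  tab <- build_concordance_table(pairs)
  expect_equal(attr(tab, "N"), 3)
  expect_equal(attr(tab, "n_excluded"), 1)
  expect_equal(unclass(tab)["NLAA", "NLAA"], 1)
  expect_equal(unclass(tab)["no effect", "NLAA"], 1)
  shuffled <- build_concordance_table(pairs[c(3, 1, 4, 2), ])
  expect_identical(unclass(tab), unclass(shuffled))
  empty <- build_concordance_table(pairs[0, ])
  expect_equal(attr(empty, "N"), 0)
})

test_that("weighted kappa matches hand-evaluated and limiting cases", {
  # 2x2 hand evaluation: observed 0.2, expected 0.5, kappa 0.6
  m <- matrix(c(8, 2, 2, 8), 2, byrow = TRUE)
  w <- matrix(c(0, 1, 1, 0), 2)
  N <- sum(m)
  res <- list(observed = sum(w * m) / N,
              expected = sum(w * outer(rowSums(m), colSums(m))) / N^2)
  expect_equal(res$observed, 0.2)
  expect_equal(res$expected, 0.5)
  # the package routine, padded into the 4x5 shape it operates on
  m45 <- matrix(0, 4, 5, dimnames = dimnames(score_matrix()))
  m45[1:2, 1:2] <- m
  w45 <- matrix(0, 4, 5)
  w45[1:2, 1:2] <- w
  expect_equal(weighted_kappa(m45, w45)$kappa, 0.6)

  # perfect agreement: all mass on zero-weight cells
  perf <- matrix(0, 4, 5, dimnames = dimnames(score_matrix()))
  perf[score_matrix() == 0] <- 10
  expect_equal(weighted_kappa(perf)$kappa, 1)

  # exact independence: cells equal to r_i c_j / N
  r <- c(10, 20, 40, 30); cl <- c(20, 30, 10, 25, 15)
  ind <- outer(r, cl) / sum(r)
  dimnames(ind) <- dimnames(score_matrix())
  expect_equal(weighted_kappa(ind)$kappa, 0, tolerance = 1e-12)

  # invariance to multiplying all counts by a positive constant
  rnd <- matrix(rpois(20, 30) + 1, 4, 5, dimnames = dimnames(score_matrix()))
  expect_equal(weighted_kappa(rnd)$kappa, weighted_kappa(rnd * 7)$kappa)

  # degenerate margins give an undefined-kappa error
  degen <- matrix(0, 4, 5, dimnames = dimnames(score_matrix()))
  degen[2, 2] <- 5
  expect_error(weighted_kappa(degen), class = "concord7_degenerate_kappa")
})

test_that("score distributions partition the pairs with percentages to 100", {
  pairs <- tibble::tibble(
    agency = c("A", "A", "B", "B", "B"),
    agency_proposed = c("NLAA", "no effect", "no effect", "NLAA", "LAA"),
    expert_final = c("no effect", "NLAA", "no effect", "NLAA", "NLAA")
  )
  pairs$score <- discrepancy_score(pairs$agency_proposed, pairs$expert_final)
  dist <- score_distribution(pairs)
  expect_equal(sum(dist$n), nrow(pairs))
  sums <- tapply(dist$pct, dist$agency, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  a <- dist[dist$agency == "A", ]
  expect_equal(a$pct[a$score == 1], 50)
  expect_equal(a$pct[a$score == -1], 50)
})

test_that("underestimation share counts negative disagreements", {
  expect_equal(underestimation_share(c(-1, -1, -2, 1)), 0.75)
  expect_equal(underestimation_share(c(-3)), 1)
  expect_equal(underestimation_share(c(0, 0, 2)), 0)
  expect_error(underestimation_share(c(0, 0)),
               class = "concord7_no_disagreement")
})

test_that("KS statistic equals the brute-force sup-distance oracle", {
  expect_equal(ks_agency_test(c(0, 0, 1), c(0, 1, 1), min_n = 1)$D, 1 / 3)
  # identical distributions and disjoint supports
  expect_equal(ks_agency_test(rep(c(-1, 2), 20), rep(c(-1, 2), 10),
                              min_n = 1)$D, 0)
  expect_equal(ks_agency_test(rep(-3, 25), rep(3, 25), min_n = 1)$D, 1)
  # random multisets over the score support
  set.seed(42)
  for (k in 1:50) {
    x <- sample(-3:3, sample(2:40, 1), replace = TRUE)
    y <- sample(-3:3, sample(2:40, 1), replace = TRUE)
    expect_equal(ks_agency_test(x, y, min_n = 1)$D, ks_D_oracle(x, y))
  }
})

test_that("per-agency KS honours the minimum-n filter and reference choice", {
  set.seed(7)
  pairs <- tibble::tibble(
    agency = c(rep("Big", 60), rep("Tiny", 5)),
    score = c(sample(-3:3, 60, replace = TRUE), rep(0, 5))
  )
  res <- ks_by_agency(pairs, min_n = 20)
  expect_true(res$skipped[res$agency == "Tiny"])
  expect_false(res$skipped[res$agency == "Big"])
  loo <- ks_by_agency(pairs, min_n = 20, leave_one_out = TRUE)
  big_pooled <- res$D[res$agency == "Big"]
  big_loo <- loo$D[loo$agency == "Big"]
  expect_equal(big_loo, ks_D_oracle(pairs$score[pairs$agency == "Big"],
                                    pairs$score[pairs$agency == "Tiny"]))
  expect_lte(big_pooled, big_loo)
  expect_error(ks_agency_test(1:5, numeric(0)), "empty reference")
})
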