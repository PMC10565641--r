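# Independent Fisher oracle: enumerate all tables with the observed margins
# via dhyper and sum those no more probable than the observed table.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; N <- a + b + c + d; c1 <- a + c
  xs <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- dhyper(xs, r1, N - r1, c1)
  pobs <- dhyper(a, r1, N - r1, c1)
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

test_that("the hypergeometric upper tail matches exact rational arithmetic", {
  # C(5,3)C(15,1) + C(5,4)C(15,0) over C(20,4) = 155/4845
  expect_equal(hypergeom_upper_tail(3, 5, 4, 20), 155 / 4845, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(0, 5, 4, 20), 1.0)
  expect_equal(hypergeom_upper_tail(5, 5, 5, 5), 1.0)
})

test_that("the hypergeometric tail agrees with phyper over random parameters", {
  set.seed(17)
  for (i in 1:200) {
    N <- sample(5:2000, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_upper_tail(k, K, n, N),
                 phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_error(hypergeom_upper_tail(6, 5, 4, 20), "exceeds")
  expect_error(hypergeom_upper_tail(1, 25, 4, 20), "exceed N")
})

test_that("the hypergeometric tail agrees with Monte-Carlo sampling", {
  set.seed(23)
  for (i in 1:3) {
    N <- sample(20:200, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    draws <- rhyper(1e5, K, N - K, n)
    k <- as.integer(quantile(draws, 0.8))
    if (k > min(K, n)) k <- min(K, n)
    p <- hypergeom_upper_tail(k, K, n, N)
    phat <- mean(draws >= k)
    se <- sqrt(p * (1 - p) / 1e5)
    expect_lt(abs(phat - p), 3 * se + 1e-12)
  }
})

test_that("BH step-up q-values match hand computation and p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.07), 0.07)

  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_fdr(p), p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.1, 1.2)), class = "degscan_validation_error")
})

test_that("BH q-values are monotone along sorted p-values and lie in [0,1]", {
  set.seed(13)
  for (i in 1:10) {
    p <- sort(runif(40))
    q <- bh_fdr(p)
    expect_true(all(diff(q) >= -1e-12))
    expect_true(all(q >= 0 & q <= 1))
  }
})

test_that("overrepresentation analysis reproduces the worked example", {
  universe <- sprintf("G%02d", 1:20)
  sets <- list(S1 = universe[1:5])
  cand <- universe[c(1, 2, 3, 6)]  # overlap 3 with S1
  res <- ora(cand, sets, universe)
  expect_equal(res$k, 3L)
  expect_equal(res$K, 5L)
  expect_equal(res$n, 4L)
  expect_equal(res$N, 20L)
  expect_equal(res$p_value, 155 / 4845, tolerance = 1e-12)
  expect_equal(res$fold_enrichment, 3.0)

  # a set disjoint from the candidates has k = 0, p = 1
  res2 <- ora(cand, list(S2 = universe[11:15]), universe)
  expect_equal(res2$k, 0L)
  expect_equal(res2$p_value, 1.0)
})

test_that("ora is invariant to candidate and universe ordering", {
  set.seed(29)
  universe <- sprintf("G%03d", 1:100)
  sets <- list(A = sample(universe, 20), B = sample(universe, 35))
  cand <- sample(universe, 25)
  r1 <- ora(cand, sets, universe)
  r2 <- ora(sample(cand), sets, sample(universe))
  expect_equal(r1, r2)
})

test_that("ora drops out-of-universe candidates and rejects an empty universe", {
  universe <- sprintf("G%02d", 1:20)
  expect_message(res <- ora(c(universe[1:3], "ALIEN"),
                            list(S = universe[1:5]), universe),
                 "outside the universe")
  expect_equal(res$n, 3L)
  expect_error(ora("A", list(S = "A"), character(0)),
               class = "degscan_validation_error")
})

test_that("BH is applied across all sets tested in one call", {
  universe <- sprintf("G%03d", 1:60)
  sets <- list(A = universe[1:10], B = universe[11:30], C = universe[31:40])
  cand <- universe[c(1:6, 35:40)]
  res <- ora(cand, sets, universe)
  expect_equal(res$q_value, bh_fdr(res$p_value), tolerance = 1e-12)
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"), tolerance = 1e-12)
})

test_that("the two-sided Fisher test follows the minimum-likelihood convention", {
  expect_equal(fisher_exact_2x2(two_by_two(1, 1, 1, 1)), 1.0)
  expect_equal(fisher_exact_2x2(two_by_two(8, 3, 1, 9)),
               oracle_fisher(8, 3, 1, 9), tolerance = 1e-12)

  set.seed(47)
  for (i in 1:100) {
    cells <- as.integer(rmultinom(1, sample(5:80, 1), runif(4, 0.05, 1)))
    t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    expect_equal(fisher_exact_2x2(t),
                 oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(t),
                 fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-7)
    # invariance under simultaneous row and column swap
    expect_equal(fisher_exact_2x2(t),
                 fisher_exact_2x2(two_by_two(cells[4], cells[3],
                                             cells[2], cells[1])),
                 tolerance = 1e-12)
  }
})

test_that("odds ratios follow the arithmetic, with Haldane correction on zeros", {
  expect_equal(odds_ratio(two_by_two(10, 5, 2, 8)), 8.0)
  expect_equal(odds_ratio(two_by_two(5, 5, 5, 5)), 1.0)
  expect_equal(odds_ratio(two_by_two(3, 0, 2, 4), haldane = TRUE),
               (3.5 * 4.5) / (0.5 * 2.5))
  expect_warning(or <- odds_ratio(two_by_two(3, 0, 2, 4)), "infinite")
  expect_identical(or, Inf)
})

test_that("printed-style percentages round half-up to one decimal", {
  expect_equal(proportion_percent(146, 184), 79.3)
  expect_equal(proportion_percent(20, 33), 60.6)
  expect_equal(proportion_percent(8, 11), 72.7)
  expect_equal(proportion_percent(0, 7), 0.0)
  # half-up, not banker's: 12.5% at zero decimals goes to 13
  expect_equal(proportion_percent(1, 8, decimals = 0), 13)
  expect_error(proportion_percent(5, 0), class = "degscan_validation_error")
  expect_error(proportion_percent(8, 7), class = "degscan_validation_error")
})
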