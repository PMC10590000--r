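test_that("ordered pair enumeration is n(n-1)", {
  expect_equal(nrow(enumerate_pairs(c("A", "B", "C"))), 6L)
  expect_equal(nrow(enumerate_pairs(sprintf("D%03d", 1:113))), 12656L)
  expect_equal(nrow(enumerate_pairs("A")), 0L)
  p <- enumerate_pairs(c("A", "B"))
  expect_true(all(p$d1 != p$d2))
})

test_that("co-occurrence counting and the strict threshold", {
  ev <- toy_events(
    list("P1", "A", "2010-01-01"), list("P1", "B", "2011-01-01"),
    list("P2", "A", "2010-01-01"), list("P2", "B", "2010-01-01"),  # tie
    list("P3", "B", "2010-01-01"), list("P3", "A", "2011-01-01"),
    list("P4", "A", "2010-01-01"))
  pc <- pair_cooccurrence(enumerate_pairs(c("A", "B")), ev,
                          c("P1", "P2", "P3", "P4"))
  ab <- pc[pc$d1 == "A" & pc$d2 == "B"]
  expect_equal(ab$n_both, 3L)
  expect_equal(ab$n_d2_after, 1L)  # P1 only; P3 reversed, P2 tied
  expect_equal(ab$n_ties, 1L)
  # strict > floor(fraction x n): exactly the floor is dropped
  pairs <- data.table::data.table(d1 = "A", d2 = "B", n_both = 5L)
  expect_equal(nrow(cooccurrence_filter(pairs, 1000, 0.005)), 0L)
  pairs$n_both <- 6L
  expect_equal(nrow(cooccurrence_filter(pairs, 1000, 0.005)), 1L)
})

test_that("exact binomial tail matches closed forms", {
  bt <- binomial_direction_test(8, 10)
  expect_equal(bt$p, 56 / 1024, tolerance = 1e-12)
  expect_equal(bt$fraction, 0.8)
  expect_equal(binomial_direction_test(20, 20)$p, 2^-20, tolerance = 1e-15)
  # 5 of 10: fraction not > 0.5, p = upper tail from the median
  bt5 <- binomial_direction_test(5, 10)
  expect_false(bt5$fraction > 0.5)
  # ties are removed from the trial count
  btt <- binomial_direction_test(8, 12, n_ties = 2)
  expect_equal(btt$n_trials, 10L)
  expect_equal(btt$p, 56 / 1024, tolerance = 1e-12)
  expect_false(binomial_direction_test(0, 4, n_ties = 4)$testable)
  # large-count normal approximation stays close to exact
  pe <- binomial_direction_test(330, 600)$p
  pa <- binomial_direction_test(330, 600, method = "approx")$p
  expect_equal(pa, pe, tolerance = 0.02)
})

test_that("binomial test equals brute-force ordering enumeration (n <= 8)", {
  for (n in c(1, 3, 5, 8)) {
    g <- as.matrix(expand.grid(rep(list(0:1), n)))
    s <- rowSums(g)
    for (k in 0:n) {
      oracle <- mean(s >= k)
      expect_equal(binomial_direction_test(k, n)$p, oracle, tolerance = 1e-12,
                   info = sprintf("n=%d k=%d", n, k))
    }
  }
})

test_that("direction antisymmetry: at most one orientation can pass", {
  set.seed(5)
  for (i in 1:25) {
    n_both <- sample(5:40, 1)
    ties <- sample(0:3, 1)
    ties <- min(ties, n_both)
    after <- sample(0:(n_both - ties), 1)
    f1 <- binomial_direction_test(after, n_both, ties)
    f2 <- binomial_direction_test(n_both - ties - after, n_both, ties)
    if (isTRUE(f1$testable)) {
      expect_false(isTRUE(f1$fraction > 0.5) && isTRUE(f2$fraction > 0.5))
    }
  }
})

test_that("univariate logistic OR equals the 2x2 cross-product ratio", {
  # 200 exposed participants: 100 with D1 at baseline+1y; 30 of them get D2,
  # 10 of the 100 without D1 get D2
  n <- 200
  p <- toy_participants(n, seed = 8)
  ids <- p$participant_id
  rows <- list()
  for (i in 1:100) rows <- c(rows, list(list(ids[i], "D1", "2008-01-01")))
  for (i in 1:30) rows <- c(rows, list(list(ids[i], "D2", "2012-01-01")))
  for (i in 101:110) rows <- c(rows, list(list(ids[i], "D2", "2012-01-01")))
  ev <- do.call(toy_events, rows)
  lt <- logistic_pair_test(p, ev, "D1", "D2", ids)
  expect_true(lt$estimable)
  expect_equal(lt$or, (30 * 90) / (70 * 10), tolerance = 1e-4)
  # identical rates in both arms: OR = 1
  rows0 <- c(rows[1:100],
             lapply(ids[c(1:20, 101:120)],
                    function(id) list(id, "D2", "2012-01-01")))
  ev0 <- do.call(toy_events, rows0)
  lt0 <- logistic_pair_test(p, ev0, "D1", "D2", ids)
  expect_equal(lt0$or, 1, tolerance = 1e-6)
  # zero cell: non-estimable, no continuity correction
  rows1 <- c(rows[1:100], lapply(ids[1:15],
                                 function(id) list(id, "D2", "2012-01-01")))
  ev1 <- do.call(toy_events, rows1)
  expect_false(logistic_pair_test(p, ev1, "D1", "D2", ids)$estimable)
})

test_that("staged selection is the conjunction of all three criteria", {
  # D2 follows D1 often (direction passes) but D2 is MORE common without D1,
  # so the odds ratio is < 1 and the pair must be rejected
  n <- 300
  p <- toy_participants(n, seed = 12)
  ids <- p$participant_id
  rows <- list()
  for (i in 1:100) rows <- c(rows, list(list(ids[i], "D1", "2008-01-01")))
  for (i in 1:30) rows <- c(rows, list(list(ids[i], "D2", "2012-01-01")))
  for (i in 101:260) rows <- c(rows, list(list(ids[i], "D2", "2012-01-01")))
  ev <- do.call(toy_events, rows)
  res <- run_pair_inference(p, ev, c("D1", "D2"), ids)
  r <- res[res$d1 == "D1" & res$d2 == "D2"]
  expect_true(r$passed_cooccurrence)
  expect_true(r$direction_ok)   # all 30 D2 strictly after D1
  expect_lt(r$or, 1)
  expect_false(r$association_ok)
  expect_equal(r$stage_exited, "association")
  expect_false(any(res$confirmed))
})
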