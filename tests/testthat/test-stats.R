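test_that("identical values give p_split = 1 and sufficiency", {
  st <- split_sufficiency_test(rep(5, 20), seed = 1)
  expect_equal(st$p_split, 1)
  expect_true(st$sufficient)
  expect_equal(st$n_repetitions, 15L)
  expect_length(st$p_values, 15L)
})

test_that("split test needs at least four values", {
  expect_error(split_sufficiency_test(c(1, 2, 3)), "at least 4")
})

test_that("split test is reproducible under a fixed seed", {
  set.seed(4)
  v <- rnorm(30)
  a <- split_sufficiency_test(v, seed = 10)
  b <- split_sufficiency_test(v, seed = 10)
  expect_identical(a$p_values, b$p_values)
  # shuffling the input changes the draws, not the scale of p_split
  c2 <- split_sufficiency_test(sample(v), seed = 10)
  expect_gt(c2$p_split, 0.1)
})

test_that("well-sampled Gaussian data is usually deemed sufficient", {
  set.seed(20)
  suff <- vapply(1:60, function(i) {
    split_sufficiency_test(rnorm(40), seed = i)$sufficient
  }, logical(1))
  expect_gte(mean(suff), 0.75)
})

test_that("random splitting is insensitive to balanced mixtures", {
  # random halves of a pooled bimodal sample receive near-equal shares of
  # each mode, so the Welch p-values stay near-uniform and p_split stays
  # far above the 0.1 flag; the screen detects half-vs-half disagreement,
  # not multimodality
  set.seed(21)
  p_splits <- vapply(1:30, function(i) {
    v <- c(rnorm(20, 0, 1), rnorm(20, 10, 1))
    split_sufficiency_test(v, seed = i)$p_split
  }, numeric(1))
  expect_gt(mean(p_splits), 0.3)
  expect_lt(mean(p_splits), 0.7)
  expect_true(all(p_splits >= 0.1))
})

test_that("degenerate zero-variance halves score 1 or 0 by mean equality", {
  st <- split_sufficiency_test(c(0, 0, 4, 4), n_repetitions = 100, seed = 2)
  expect_true(all(st$p_values >= 0 & st$p_values <= 1))
  # permutations splitting into two constant unequal halves score p = 0
  expect_true(any(st$p_values == 0))
  # and all-identical halves would score p = 1 (covered by the rule)
  st1 <- split_sufficiency_test(rep(3, 6), n_repetitions = 5, seed = 1)
  expect_true(all(st1$p_values == 1))
})

test_that("Welch t separates far-apart groups and matches stats::t.test", {
  out <- compare_groups(c(1, 2, 3), c(101, 102, 103), method = "welch_t")
  expect_lt(out$p_value, 0.01)
  expect_equal(out$p_value,
               t.test(c(1, 2, 3), c(101, 102, 103))$p.value)
  expect_equal(out$summary$mean, c(2, 102))
})

test_that("Mann-Whitney on identical groups gives p = 1 and is rank-based", {
  out <- suppressWarnings(
    compare_groups(c(1, 2, 3), c(1, 2, 3), method = "mann_whitney"))
  expect_equal(out$p_value, 1)
  set.seed(3)
  a <- rlnorm(12); b <- rlnorm(12, 0.8)
  p_raw <- compare_groups(a, b, method = "mann_whitney")$p_value
  p_log <- compare_groups(log(a), log(b), method = "mann_whitney")$p_value
  expect_equal(p_raw, p_log)
})

test_that("Tukey-adjusted p-values are 1 for three identical groups", {
  g <- c(1, 2, 3)
  out <- compare_groups(list(a = g, b = g, c = g), method = "anova_tukey")
  expect_equal(out$pairwise$p_adj, rep(1, 3))
  expect_equal(nrow(out$summary), 3L)
})

test_that("unknown methods and undersized groups are rejected", {
  expect_error(compare_groups(1:3, 1:3, method = "bogus"))
  expect_error(compare_groups(1, 1:5, method = "welch_t"), "at least 2")
})

test_that("Welch test keeps nominal type-I error on Gaussian nulls", {
  set.seed(30)
  rej <- vapply(1:2000, function(i) {
    t.test(rnorm(20), rnorm(20), var.equal = FALSE)$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})
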