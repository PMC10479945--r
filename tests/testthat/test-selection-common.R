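# Shared selection machinery: relevance, collinearity, separation, SA.

test_that("ANOVA F matches hand computation and aov", {
  X <- cbind(c(1, 2, 3, 4, 5, 6))
  y <- c(0, 0, 0, 1, 1, 1)
  expect_equal(anova_f_relevance(X, y), 13.5)  # between 13.5 / within 1
  set.seed(3)
  Xr <- matrix(rnorm(40 * 4), 40, 4)
  yr <- rep(0:1, each = 20)
  f_pkg <- anova_f_relevance(Xr, yr)
  f_aov <- apply(Xr, 2, function(x)
    summary(stats::aov(x ~ factor(yr)))[[1]][["F value"]][1])
  expect_equal(f_pkg, unname(f_aov), tolerance = 1e-10)
  expect_equal(anova_f_relevance(cbind(rep(2, 10)), rep(0:1, 5)), 0)
  # a column identical to the labels separates perfectly
  f_id <- anova_f_relevance(cbind(yr, Xr), yr)
  expect_true(f_id[1] == Inf || f_id[1] > max(f_id[-1]))
  expect_error(anova_f_relevance(Xr, rep(1, 40)), class = "specsel_param_error")
})

test_that("pearson matrix handles duplicates, negation, degeneracy", {
  set.seed(5)
  x <- rnorm(30)
  X <- cbind(x, x, -x, rnorm(30), rep(1, 30))
  R <- pearson_matrix(X)
  expect_equal(R[1, 2], 1)
  expect_equal(R[1, 3], -1)
  expect_equal(R[5, 1], 0)  # zero-variance column
  expect_equal(diag(R), rep(1, 5))
  expect_equal(R, t(R))
  expect_true(all(R >= -1 & R <= 1))
  big <- matrix(rnorm(4000), 2000, 2)
  expect_lt(abs(pearson_matrix(big)[1, 2]), 0.1)
  expect_error(pearson_matrix(matrix(1, 1, 3)), class = "specsel_param_error")
})

test_that("sequential collinearity removal drops the duplicate, keeps signals", {
  set.seed(11)
  a <- rnorm(10); b <- rnorm(10)
  X <- cbind(a, a, b)  # two duplicated columns + one independent
  cand <- feature_subset(1:3, c(500, 510, 700), relevance = c(3, 2, 1))
  out <- sequential_collinearity_removal(cand, X, k = 2)
  expect_equal(sort(out$indices), c(1, 3))  # one duplicate dropped
  R <- abs(pearson_matrix(X[, out$indices]))
  expect_true(all(R[upper.tri(R)] < 1))
  # uncorrelated pool, k = pool size: returned in relevance order
  Xu <- matrix(rnorm(200 * 4), 200, 4)
  cu <- feature_subset(1:4, c(400, 500, 600, 700), relevance = c(2, 9, 5, 7))
  outu <- sequential_collinearity_removal(cu, Xu, k = 4)
  expect_equal(outu$indices, c(2L, 4L, 3L, 1L))
  out1 <- sequential_collinearity_removal(cu, Xu, k = 1)
  expect_equal(out1$indices, 2L)
  expect_error(sequential_collinearity_removal(cu, Xu, k = 0),
               class = "specsel_param_error")
})

test_that("discard-all-above-threshold variant prunes whole clusters", {
  set.seed(12)
  a <- rnorm(40)
  X <- cbind(a, a + rnorm(40, 0, 0.01), a + rnorm(40, 0, 0.01), rnorm(40))
  cand <- feature_subset(1:4, c(500, 505, 510, 800), relevance = 4:1)
  out <- sequential_collinearity_removal(cand, X, k = 3, discard_all_above = 0.9)
  expect_equal(sort(out$indices), c(1, 4))  # both near-copies pruned at once
})

test_that("minimum separation filter follows the greedy relevance scan", {
  cand <- feature_subset(1:4, c(500, 510, 545, 700), relevance = c(4, 3, 2, 1))
  out <- min_separation_filter(cand, 20)
  expect_equal(out$nm, c(500, 545, 700))
  # min 0 removes only exact duplicates
  cand2 <- feature_subset(1:3, c(500, 500.0, 510), relevance = c(3, 2, 1))
  expect_error(feature_subset(c(1, 1, 2), c(500, 500, 510)),
               class = "specsel_param_error")
  cand2 <- feature_subset(1:3, c(500, 500, 510), relevance = c(3, 2, 1))
  out2 <- min_separation_filter(cand2, 0)
  expect_equal(out2$nm, c(500, 510))
  one <- feature_subset(5, 623, 1)
  expect_equal(min_separation_filter(one, 30)$indices, 5L)
  expect_error(min_separation_filter(cand, -1), class = "specsel_param_error")
  # property: pairwise distances all >= min_nm
  set.seed(2)
  for (i in 1:10) {
    nm <- sort(sample(400:1800, 30))
    c3 <- feature_subset(seq_along(nm), nm, relevance = runif(30))
    o <- min_separation_filter(c3, 25)
    if (length(o$nm) > 1) expect_gte(min(dist(o$nm)), 25)
  }
})

test_that("simulated annealing honors its contracts", {
  pool <- feature_subset(1:8, seq(400, 750, by = 50), relevance = 8:1)
  # constant cost: initial (top-k by relevance) returned unchanged
  r <- sa_select(pool, 3, function(s) 0.7,
                 sa_config(iterations = 50, seed = 1, max_cost = NA))
  expect_equal(sort(r$subset$indices), 1:3)
  expect_equal(r$best_cost, 0.7)
  # k = pool size: identity, no search iterations
  calls <- 0
  r2 <- sa_select(pool, 8, function(s) { calls <<- calls + 1; 0.42 },
                  sa_config(iterations = 10, seed = 1))
  expect_setequal(r2$subset$indices, 1:8)
  expect_equal(r2$best_cost, 0.42)
  expect_equal(calls, 1)  # scored once, never searched
  # inactivation on an initially perfect state
  r3 <- sa_select(pool, 3, function(s) 1.0, sa_config(iterations = 100, seed = 1))
  expect_false(r3$activated)
  expect_length(r3$trace, 1)
  # best-ever trace is monotone non-decreasing
  set.seed(4)
  noisy_cost <- function(s) mean(s %in% c(2, 5, 7)) + stats::runif(1, 0, 1e-6)
  r4 <- sa_select(pool, 3, noisy_cost,
                  sa_config(iterations = 300, seed = 9, max_cost = NA))
  expect_true(all(diff(r4$trace) >= 0))
  expect_error(sa_select(pool, 9, function(s) 1, sa_config()),
               class = "specsel_param_error")
})

test_that("simulated annealing finds a planted optimum on a small pool", {
  pool <- feature_subset(1:10, seq(400, 850, by = 50),
                         relevance = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  target <- c(1, 4, 6)  # low-relevance members: not the initial state
  cost <- function(sel) length(intersect(sel, target)) / 3
  hits <- 0
  for (s in 1:5) {
    r <- sa_select(pool, 3, cost, sa_config(iterations = 800, seed = s))
    if (setequal(r$subset$indices, target)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
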