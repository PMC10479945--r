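# Ensemble framework: the three univariate filters, the shadow-feature RF
# wrapper, SB/LC finalization, SHAP, ranges and inclusion curves.

mk_filter_toy <- function(n = 100, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  info <- y + rnorm(n, 0, 0.3)
  X <- cbind(info, info, rnorm(n), rnorm(n), rnorm(n))
  colnames(X) <- NULL
  list(X = X, y = y)
}

test_that("mRMR penalises redundancy with already-selected features", {
  toy <- mk_filter_toy()
  r <- mrmr_rank(toy$X, toy$y, top_k = 5)
  expect_equal(r$indices[1], 1L)        # max-relevance first pick
  expect_false(r$indices[2] == 2L)      # duplicate demoted below noise
  expect_equal(length(r$indices), 5)
  expect_equal(length(mrmr_rank(toy$X, toy$y, top_k = 99)$indices), 5)
})

test_that("mutual information ranks an identity feature at ln 2", {
  set.seed(2)
  n <- 400
  y <- rep(0:1, each = n / 2)
  X <- cbind(as.numeric(y), rnorm(n), rnorm(n))
  r <- mi_rank(X, y, top_k = 3, seed = 1)
  expect_equal(r$indices[1], 1L)
  expect_equal(r$relevance[1], log(2), tolerance = 1e-6)
  expect_lt(max(r$relevance[-1]), 0.1)  # independent features near zero
  r2 <- mi_rank(X, y, top_k = 3, seed = 1)
  expect_identical(r$relevance, r2$relevance)
})

test_that("ReliefF weights behave at the extremes", {
  set.seed(3)
  n <- 80
  y <- rep(0:1, each = n / 2)
  X <- cbind(y + rnorm(n, 0, 0.05),   # near-perfect separator
             rep(0.5, n),             # constant
             rnorm(n))
  r <- relieff_rank(X, y, top_k = 3, n_neighbors = 10)
  w <- r$relevance[order(r$indices)]
  expect_equal(which.max(w), 1L)
  expect_gt(w[1], 0.3)
  expect_equal(w[2], 0)
  expect_true(all(w >= -1 & w <= 1))
})

test_that("the shadow-feature wrapper confirms signal and rejects noise", {
  set.seed(4)
  n <- 120
  y <- rep(0:1, each = n / 2)
  X <- cbind(y + rnorm(n, 0, 0.4), matrix(rnorm(n * 30), n, 30))
  cfg <- list(max_iter = 30, alpha = 0.05, trees = 100)
  r <- boruta_rf(X, y, cfg = cfg, seed = 9)
  expect_true(1L %in% r$indices)               # planted feature confirmed
  expect_lte(length(r$indices), 4)             # few false confirmations
  expect_true(all(r$indices %in% seq_len(ncol(X))))  # shadows never returned
  expect_error(boruta_rf(X[, 0, drop = FALSE], y), class = "specsel_param_error")
  expect_error(boruta_rf(X, y, cfg = list(max_iter = 5, alpha = .05, trees = 0)),
               class = "specsel_param_error")
})

test_that("SB finalization forms a band, LC spreads and decorrelates", {
  set.seed(5)
  n <- 90
  wl <- seq(1150, 1450, by = 10)
  y <- rep(0:1, each = n / 2)
  base <- rnorm(n)
  # correlated cluster of informative bins around one band at 1210 nm
  X <- sapply(seq_along(wl), function(j) {
    w <- exp(-((wl[j] - 1210) / 30)^2)
    w * (y + 0.3 * base) + rnorm(n, 0, 0.3)
  })
  ranked <- feature_subset(seq_along(wl), wl,
                           relevance = anova_f_relevance(X, y))
  ranked <- sequential_collinearity_removal(ranked, X, k = length(wl),
                                            discard_all_above = 1.01)
  sb <- finalize_sb(ranked, X, y, k = 6)
  expect_lte(diff(range(sb$nm)), 2 * 60)       # narrow spectral band
  expect_true(all(sb$indices %in% ranked$indices))
  sb1 <- finalize_sb(ranked, X, y, k = 1)
  expect_equal(sb1$indices,
               ranked$indices[which.max(anova_f_relevance(X, y)[ranked$indices])])
  lc <- finalize_lc(ranked, X, y, k = 5)
  if (length(lc$nm) > 1) {
    expect_gte(min(dist(lc$nm)), 20)
    R <- abs(pearson_matrix(X[, lc$indices]))
    expect_lt(max(R[upper.tri(R)]), 1)
  }
  expect_warning(finalize_sb(feature_subset(1:2, wl[1:2], 1:2), X, y, k = 6),
                 "only 2")
})

test_that("tree-SHAP contributions are locally accurate", {
  set.seed(6)
  n <- 150
  X <- matrix(rnorm(n * 4), n, 4)
  y <- as.integer(X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.3) > 0)
  tr <- 1:100; te <- 101:150
  s <- shap_summary(X[tr, ], y[tr], X[te, ], feature_names = paste0("f", 1:4),
                    seed = 3)
  resid <- abs(s$base_value + rowSums(s$contributions) - s$margin)
  expect_lt(max(resid), 1e-6)
  expect_gt(s$mean_abs[["f1"]], max(s$mean_abs[c("f3", "f4")]))
  # single-feature model: the lone contribution is exactly margin - base
  s1 <- shap_summary(X[tr, 1, drop = FALSE], y[tr], X[te, 1, drop = FALSE],
                     feature_names = "f1", nrounds = 1, max_depth = 1, seed = 3)
  expect_equal(as.numeric(s1$contributions), s1$margin - s1$base_value,
               tolerance = 1e-7)
})

test_that("duplicated feature columns share their joint contribution", {
  set.seed(7)
  n <- 200
  x <- rnorm(n)
  y <- as.integer(x + rnorm(n, 0, 0.4) > 0)
  Xd <- cbind(x, x, rnorm(n))
  tr <- 1:150; te <- 151:200
  sd_ <- shap_summary(Xd[tr, ], y[tr], Xd[te, ], feature_names = c("a", "b", "z"),
                      seed = 5)
  s1 <- shap_summary(Xd[tr, c(1, 3)], y[tr], Xd[te, c(1, 3)],
                     feature_names = c("a", "z"), seed = 5)
  joint <- sd_$contributions[, "a"] + sd_$contributions[, "b"]
  expect_gt(stats::cor(joint, s1$contributions[, "a"]), 0.95)
  expect_gt(sd_$mean_abs[["a"]] + sd_$mean_abs[["b"]], sd_$mean_abs[["z"]])
})

test_that("range partition slices the axis and aggregates incrementally", {
  cfg <- small_band_config(n_per_class = 40, seed = 51)
  d <- generate_dataset(cfg)$dataset
  prot <- eval_protocol(folds = 4, repeats = 1, seed = 51)
  ecfg <- ensemble_config(top_k = 40,
                          boruta = list(max_iter = 25, alpha = 0.05, trees = 100))
  reps <- partition_and_aggregate(d, "tissue2", cfg = ecfg, k = 5,
                                  protocol = prot,
                                  ranges = c("VIS", "VIS/NIR/SWIR"))
  expect_true(all(reps[["VIS"]]$subset$nm < 700))
  # the SWIR-only planted bands cannot appear in the VIS report
  expect_false(any(bands_recovered(reps[["VIS"]]$subset$nm,
                                   list(chromophore_band(1500, 80, "bandC")),
                                   slack_nm = 0)))
  # the full-range slice equals the no-partition path, same seed
  direct <- run_ensemble_framework(d, "tissue2", k = 5, protocol = prot,
                                   cfg = ecfg, finalization = "LC")
  expect_identical(reps[["VIS/NIR/SWIR"]]$subset, direct$subset)
})

test_that("sequential inclusion curves are consistent with full-subset CV", {
  cfg <- small_band_config(n_per_class = 40, seed = 52)
  d <- generate_dataset(cfg)$dataset
  prot <- eval_protocol(folds = 4, repeats = 1, seed = 52)
  fs <- feature_subset(c(10, 40, 80), d$wavelengths[c(10, 40, 80)],
                       relevance = 3:1)
  curve <- sequential_inclusion_curve(fs, d, "tissue2", prot)
  expect_equal(nrow(curve), 3)
  full <- cv_balanced_accuracy(d, fs$indices, prot, "tissue2")
  expect_equal(curve$mean[3], full$mean)
  expect_equal(curve$sd[3], full$sd)
})

test_that("ensemble invariants: union, confirmation and finalization nest", {
  cfg <- small_band_config(n_per_class = 40, seed = 53)
  d <- generate_dataset(cfg)$dataset
  prot <- eval_protocol(folds = 4, repeats = 1, seed = 53)
  ecfg <- ensemble_config(top_k = 30,
                          boruta = list(max_iter = 25, alpha = 0.05, trees = 100))
  r <- run_ensemble_framework(d, "tissue2", k = 5, protocol = prot,
                              cfg = ecfg, finalization = c("SB", "LC"))
  flt <- r$lc$extra$filters
  union_idx <- sort(unique(c(flt$mrmr$indices, flt$mi$indices,
                             flt$relieff$indices)))
  expect_gte(length(union_idx), length(flt$mrmr$indices))
  confirmed <- r$lc$extra$confirmed
  expect_true(all(confirmed$indices %in% union_idx))
  expect_true(all(r$sb$subset$indices %in% confirmed$indices))
  expect_true(all(r$lc$subset$indices %in% confirmed$indices))
  expect_true(all(bands_recovered(r$lc$subset$nm, ovr_truth(cfg, "tissue2"),
                                  slack_nm = 20)))
})
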